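Package: viraltriage
Title: Triage of Virus-Derived Contigs in Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decides whether virus-derived contigs in an insect genome
    assembly represent an exogenous infection or endogenous viral elements.
    Implements taxonomically stratified reciprocal-homology triage of gene
    hits, contig co-occupancy summaries, Hi-C interaction fractions, and a
    nonparametric GC/depth contrast cascade (Shapiro-Wilk gate,
    Kruskal-Wallis omnibus, pairwise Wilcoxon with Holm adjustment) feeding
    a transparent decision table. Also provides calibrated divergence
    scaling of ultrametric species trees, presence/copy-number inventories
    for curated gene sets from profile-search results (meiosis toolkit,
    NALDV core genes), viral-genome QC (sliding-window coverage,
    zero-coverage regions, GATK-style hard filtering of pooled-sample SNP
    calls with allele-depth minor allele frequencies), and a synthetic-data
    generator that emulates the statistical structure of the real data so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
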