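---
title: "Deciding whether viral contigs are exogenous or endogenous"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding whether viral contigs are exogenous or endogenous}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viraltriage)
library(dplyr)
```

## The problem

Parasitoid wasps have an unusually intimate relationship with large DNA
viruses. Some lineages have domesticated viral machinery into their own
genomes — polydnaviruses and virus-like particles that are produced in the
ovaries and injected into hosts during parasitism — while others carry
active, free-replicating infections. When a genome assembly of such a wasp
contains contigs full of viral genes, both histories are plausible, and
they have very different biological meanings. This package implements a
triage: it assembles three independent tiers of evidence and reduces them
to a transparent verdict.

The three tiers, and the intuition behind each:

* **Gene co-occupancy.** An endogenous element is physically embedded in
  host chromatin, so its contigs tend to also carry ordinary eukaryotic
  genes (and sometimes BUSCO single-copy orthologs). A clean exogenous
  genome assembles into contigs carrying viral genes only.
* **Hi-C behaviour.** Chromatin-proximity ligation links loci that share a
  nucleus and come close in space. Contigs belonging to host chromosomes
  interact broadly with the rest of the genome; a viral episome interacts
  almost exclusively with itself. The two summary numbers are the fraction
  of all contacts involving viral contigs (`f_involved`) and, among those,
  the fraction with both ends viral (`f_viral_viral`).
* **Composition and coverage.** A free-replicating virus has its own
  nucleotide composition and its own copy number per cell, so viral
  contigs separate from host contigs in GC fraction and mean read depth.

## Gene-level triage

Each predicted gene brings a table of database hits annotated with the
subject's taxonomic category (`viral`, `eukaryote_braconid`,
`eukaryote_other`, `bacterial`, `other`). The rule in
`classify_gene_hits()` mirrors a reciprocal search: the initial
viral-restricted search (significance threshold E ≤ 1e-05) nominates the
gene, and the unrestricted search can demote it if any non-viral subject
scores better. "Better" is a strictly smaller E-value; at equal E-values
a higher bit-score wins; and a residual exact tie demotes the gene. The
tie policy is a design choice: the demotion step exists to minimise false
viral calls, so ambiguity is resolved against the viral call.

Non-viral genes take the category of their best passing hit, which is how
eukaryotic co-occupancy on viral-flagged contigs is detected by
`summarize_contigs()`. Unresolvable taxids are mapped to `other` with a
warning rather than an error, because real taxonomy dumps routinely
contain stale identifiers; a hard failure would make the triage brittle
for exactly the inputs it is meant for.

## Hi-C fractions

`compute_hic_fractions()` weights by contact count (read pairs), not by
unique contig pairs — both are derivable from the same table, but the
count-weighted figure is the one that answers "what fraction of the
library's ligation events involve viral sequence". Same-contig (cis)
pairs of a viral contig count as viral–viral, since the share is defined
over viral interactions without excluding cis events. When no contact
involves a viral contig the conditional share is reported as undefined
(`NA`), never as zero: an absent denominator is evidence of absence of
coverage, not of enrichment.

## The statistical cascade

`run_cascade()` contrasts per-contig GC or mean depth between groups
(typically `viral` versus `reference`, where the reference set is
caller-supplied: Hi-C chromosome scaffolds when available, otherwise
BUSCO-bearing contigs). The steps:

1. **Shapiro–Wilk per group.** The route is `nonparametric` as soon as
   any group rejects normality at α. Contig GC/depth distributions are
   heavy-tailed in practice (repeat content, collapsed duplications,
   copy-number variation), so this gate essentially always fires. The
   route field records the gate's outcome; the tests executed are always
   the nonparametric pair below. A parametric ANOVA branch is deliberately
   not implemented — the data this method targets reject normality, and a
   silent switch of test families depending on a marginal gate would make
   results harder to compare across assemblies. Groups larger than 5000
   contigs are subsampled with a fixed seed for the gate only (the test is
   degenerate at large n); constant groups force the nonparametric route
   with a warning.
2. **Kruskal–Wallis omnibus** across all groups.
3. **Pairwise two-sided Wilcoxon rank-sum** for every group pair, exact
   when the smaller group has ≤ 8 observations and the data are tie-free,
   otherwise the normal approximation with continuity correction and
   midranks. Holm adjustment across the pairs: it controls FWER without
   independence assumptions and never reports less than the raw p — the
   conservative default for a small family of follow-up tests.

Group sizes below 3 are refused: a rank test on two observations is
noise presented as inference.

`outlier_sensitivity()` re-runs the cascade with designated high-depth
contigs excluded and again with them as their own third group. This
mirrors standard practice when a couple of contigs have extreme depth
(amplified segments, collapsed repeats): the conclusion should not hinge
on them, and moving them to a separate group shows whether they alone
differ from everything else.

## The decision table

`decide()` is a pure function of its evidence record:

| verdict | co-occupancy | Hi-C | GC/depth |
|---|---|---|---|
| `exogenous` | none | `f_involved > 0` and `f_viral_viral >` threshold | at least one metric significant |
| `endogenous_candidate` | present | (any) | neither metric significant |
| `ambiguous` | anything else | | |

The viral–viral enrichment threshold defaults to 0.5 ("most viral
contacts are with other viral contigs") and is exposed as an argument:
the underlying argument for exogeneity is verbal, not a published cutoff,
so the package makes the operating point explicit rather than hiding it.
Requiring `f_involved > 0` ensures the exclusion of viral contigs from
chromosome scaffolds is informative — contigs with no Hi-C coverage at
all could have been left out of scaffolds for lack of data, not for lack
of chromatin contact. Conflicting evidence (co-occupancy together with
significant composition differences) is deliberately left `ambiguous`
rather than forced into either call.

## Divergence scaling

`calibrate_tree()` turns a relative-units ultrametric species tree into
absolute time with a single known divergence: `k = T_cal / L_cal` in MYA
per unit, where `L_cal` is the tip-to-tip path length between the
calibration pair. `pairwise_divergence()` multiplies `k` by the full
tip-to-tip path — the literal arithmetic of the calibration. Because a
tip-to-tip path on an ultrametric tree is twice the MRCA height, an
alternative `mrca-height` convention (factor `T_cal / (L_cal / 2)`
applied to MRCA heights) is also provided; the two coincide exactly on
ultrametric trees, and both are exposed because published divergence
figures do not always state which convention was read off the scaled
tree. Non-ultrametric input is accepted with a warning (checked at
relative tolerance 1e-6), since that is the one situation where the
conventions diverge. All arithmetic is done at full precision; rounding
(e.g. the 2-dp display of the scaling factor) happens only at display.

## Gene inventories

`select_hits()` filters profile-search (hmmsearch-style) hits at
E ≤ 1e-15 — the stringency appropriate for curated gene-family models
searched against a whole proteome — and resolves each peptide to at most
one gene model (smallest E-value, score breaking ties). That uniqueness
rule is what makes the matrix cells read as copy numbers: without it a
single peptide matched by two related models (e.g. MSH4 and MSH5) would
inflate both counts. Reading "top hits" per model instead is supported
via `unique_target = FALSE`. `build_matrix()` keeps explicit zero
rows/columns so absences are visible, and carries per-cell provenance
(which peptides produced each count). `core_report()` reduces a matrix
to presence of a core set: the meiosis-specific subset
(`core_meiosis_genes()`: SPO11, DMC1, MND1, HOP2, REC8, MSH4, MSH5,
CORT) for reproductive-mode questions, or the 12-gene NALDV core
(`naldv_core_genes()`) as a completeness checklist for candidate viral
genomes. Both sets are data — arguments with defaults — not hard-coded
logic, because core-gene definitions are themselves literature
conventions that move.

## Viral-genome QC

`windowed_depth()` profiles coverage in 500-bp windows slid by 100 bp
(the defaults used for the viral genome figure this reproduces); a final
partial window is averaged over its actual length rather than padded.
`find_zero_regions()` reports maximal zero-coverage runs 1-based
inclusive, with an opt-in circular mode that merges a run spanning the
origin — the candidate genome is circular but depth tracks are
linearised. BED export converts to 0-based half-open.

`hard_filter()` applies the GATK hard-filtering recommendations to a
pooled-sample call set. The published conditions are removal conditions
(QD < 2, QUAL < 30, SOR > 3, FS > 60, MQ < 40, MQRankSum < −12.5,
ReadPosRankSum < −8); retention therefore uses the complements with ≥/≤,
so boundary values pass, matching GATK's own filter-expression
semantics. Missing annotations pass their criterion (rank-sum statistics
are undefined at sites without heterozygous coverage; GATK does not fail
such sites) and the count of such passes is recorded. The minor allele
frequency (threshold 0.1) is computed from the single pooled sample's
allele depths, `min(ref, Σalt) / total` — for a pool of five haploid
individuals the AD fields carry the frequency information directly,
whereas a called genotype at ploidy 5 quantises it; the genotype route is
accepted as an argument for interface completeness. Zero total depth
makes the MAF undefined and fails the record explicitly.

## What the simulator does and does not emulate

`sim_config()` defaults encode the study conditions: 50 reference
contigs at GC 29.5 ± 2% and depth 175 ± 40× versus 20 viral contigs at
GC 34.0 ± 2% and depth 258 ± 40×; Hi-C involvement 0.15% with
viral–viral share 83.8%; a pooled pentaploid call set. GC variance is
created where the tests look for it — between contigs, via a per-contig
target drawn from the group distribution — while bases within a contig
are i.i.d. at that target. Depth is attached per contig for the
contrasts, with a separate negative-binomial per-base track
(`simulate_depth_track()`) where base resolution matters. A single
global seed derives fixed per-operation substreams, so artifacts are
individually reproducible and jointly independent.

The simulator deliberately does **not** emulate: within-contig GC
autocorrelation (isochores, repeats), mapping artefacts that correlate
depth with composition, Hi-C distance-decay or restriction-site bias,
linkage between variant sites, or assembly error. Passing tests
therefore demonstrate that the statistical machinery recovers the
contrasts it targets under the stated conditions — not that those
contrasts are unconfounded in real assemblies, where repeat content and
mapping bias can move both GC and depth.

## Problem sizes and numerical choices

The replicate studies shipped with the package use 200 simulated
assemblies for power at the study effect sizes (20 vs 50 contigs), 1000
for the null rejection rate, and 10^5–10^6 simulated Hi-C contacts when
checking the involvement fractions — sizes at which the binomial error
of the checked quantities is well below the tolerances asserted.
Tie-breaks are everywhere deterministic (documented orderings plus input
order as the final key), so all results are permutation-invariant and
reproducible. Degenerate inputs have defined behaviour rather than
crashes: empty hit tables give `no_hit`, an undefined viral–viral share
is `NA`, all-ambiguous sequences have `NA` GC, header-only VCFs
round-trip.

## Known limitations

* The decision table is a faithful formalisation of a verbal argument;
  its Hi-C enrichment threshold (0.5) is an explicit operating point, not
  an estimated quantity.
* The cascade treats contigs as exchangeable observations; very unequal
  contig lengths violate that silently (length-weighted variants are out
  of scope).
* Genome-scale conclusions (which contigs of a real assembly are viral)
  depend on the upstream homology searches and assembly, which this
  package consumes but does not run.
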