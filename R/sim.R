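#' Simulate labelled host and viral contigs
#'
#' Draws a per-contig GC target from the group's GC distribution, then
#' realises a sequence with bases i.i.d. at that target.  Depth targets are
#' drawn per contig but not realised at base level here (see
#' [simulate_depth_track()]).  Truth labels are returned alongside so
#' downstream tests never re-derive them.
#'
#' @param cfg A [sim_config()].
#' @param n_rate Fraction of bases replaced by `N` (default 0: alphabet is
#'   strictly A/C/G/T).
#' @return A list with `contigs` (tibble: `contig_id`, `sequence`) and
#'   `truth` (tibble: `contig_id`, `group` in `{host, viral}`, `length`,
#'   `gc_target`, `gc_realized`, `depth_target`).
#' @examples
#' sim <- simulate_contigs(sim_config(seed = 7, n_host_contigs = 3,
#'                                    n_viral_contigs = 2,
#'                                    contig_len_min = 500,
#'                                    contig_len_max = 1000))
#' sim$truth
#' @export
simulate_contigs <- function(cfg, n_rate = 0) {
  validate_sim_config(cfg)
  if (n_rate < 0 || n_rate > 1)
    abort("invalid sim_config field `n_rate`: must be a fraction in [0, 1]",
          class = "viraltriage_config_error")
  with_substream(cfg$seed, 101L, {
    truth <- draw_contig_truth(cfg)
    seqs <- purrr::map2_chr(truth$length, truth$gc_target, function(len, gc) {
      p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
      bases <- sample(names(p), len, replace = TRUE, prob = p)
      if (n_rate > 0) {
        is_n <- runif(len) < n_rate
        bases[is_n] <- "N"
      }
      paste(bases, collapse = "")
    })
    truth$gc_realized <- vapply(seqs, compute_gc, numeric(1), USE.NAMES = FALSE)
    list(
      contigs = tibble(contig_id = truth$contig_id, sequence = seqs),
      truth = truth
    )
  })
}

draw_contig_truth <- function(cfg) {
  n <- cfg$n_host_contigs + cfg$n_viral_contigs
  group <- rep(c("host", "viral"), c(cfg$n_host_contigs, cfg$n_viral_contigs))
  ids <- sprintf("%s_%03d", group,
                 c(seq_len(cfg$n_host_contigs), seq_len(cfg$n_viral_contigs)))
  gc_mean <- ifelse(group == "viral", cfg$viral_gc_mean, cfg$host_gc_mean)
  gc_sd <- ifelse(group == "viral", cfg$viral_gc_sd, cfg$host_gc_sd)
  dp_mean <- ifelse(group == "viral", cfg$viral_depth_mean, cfg$host_depth_mean)
  dp_sd <- ifelse(group == "viral", cfg$viral_depth_sd, cfg$host_depth_sd)
  tibble(
    contig_id = ids,
    group = group,
    length = if (n > 0) {
      sample(seq.int(cfg$contig_len_min, cfg$contig_len_max), n, replace = TRUE)
    } else integer(0),
    gc_target = pmin(pmax(rnorm(n, gc_mean, gc_sd), 0.01), 0.99),
    gc_realized = NA_real_,
    depth_target = pmax(rnorm(n, dp_mean, dp_sd), 0)
  )
}

#' Simulate per-contig metrics without sequence synthesis
#'
#' Fast path for the statistical-contrast machinery: draws the contig-level
#' GC fraction and mean depth directly from the group distributions, so
#' large replicate studies of the test cascade need not realise sequences.
#' Group labels follow the contrast's convention: `viral` versus
#' `reference` (Hi-C scaffolds or BUSCO-bearing contigs).
#'
#' @inheritParams simulate_contigs
#' @return A tibble with `contig_id`, `length`, `gc`, `mean_depth`, `group`.
#' @export
simulate_contig_metrics <- function(cfg) {
  validate_sim_config(cfg)
  with_substream(cfg$seed, 107L, {
    truth <- draw_contig_truth(cfg)
    tibble(
      contig_id = truth$contig_id,
      length = truth$length,
      gc = truth$gc_target,
      mean_depth = truth$depth_target,
      group = ifelse(truth$group == "viral", "viral", "reference")
    )
  })
}

#' Simulate Hi-C contact pairs
#'
#' Each contact independently involves a viral contig with probability
#' `p_viral_involved`; involved contacts are viral-viral with probability
#' `p_viral_viral_given_involved` (both ends drawn with replacement, so
#' same-contig cis pairs occur) and viral-host otherwise.  Uninvolved
#' contacts are host-host.
#'
#' @inheritParams simulate_contigs
#' @param truth Truth tibble from [simulate_contigs()] (columns `contig_id`,
#'   `group`).
#' @return A tibble with `contig_a`, `contig_b`, `count` (identical
#'   unordered pairs aggregated), carrying attribute `n_pairs`.
#' @export
simulate_hic_pairs <- function(cfg, truth) {
  validate_sim_config(cfg)
  hosts <- truth$contig_id[truth$group %in% c("host", "reference")]
  virals <- truth$contig_id[truth$group == "viral"]
  if (length(hosts) < 1)
    abort("simulate_hic_pairs() needs at least one host contig in `truth`",
          class = "viraltriage_config_error")
  if (cfg$p_viral_involved > 0 && length(virals) < 1)
    abort("p_viral_involved > 0 but `truth` has no viral contigs",
          class = "viraltriage_config_error")
  with_substream(cfg$seed, 211L, {
    n <- cfg$n_hic_pairs
    involved <- runif(n) < cfg$p_viral_involved
    vv <- involved & (runif(n) < cfg$p_viral_viral_given_involved)
    vh <- involved & !vv
    a <- character(n)
    b <- character(n)
    pick <- function(pool, k) pool[sample.int(length(pool), k, replace = TRUE)]
    if (any(!involved)) {
      a[!involved] <- pick(hosts, sum(!involved))
      b[!involved] <- pick(hosts, sum(!involved))
    }
    if (any(vv)) {
      a[vv] <- pick(virals, sum(vv))
      b[vv] <- pick(virals, sum(vv))
    }
    if (any(vh)) {
      a[vh] <- pick(virals, sum(vh))
      b[vh] <- pick(hosts, sum(vh))
    }
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    out <- tibble(contig_a = lo, contig_b = hi) |>
      count(.data$contig_a, .data$contig_b, name = "count") |>
      arrange(.data$contig_a, .data$contig_b)
    attr(out, "n_pairs") <- n
    out
  })
}

#' Simulate a per-base depth track
#'
#' Negative-binomial per-base depths around a target mean, with optional
#' forced zero-coverage regions for exercising dropout detection.
#'
#' @param length Sequence length in bp.
#' @param mean_depth Target mean depth.
#' @param size Negative-binomial dispersion (larger = less overdispersed).
#' @param zero_regions Optional tibble/data.frame with `start`, `end`
#'   (1-based inclusive) forced to depth 0.
#' @param seed Integer seed.
#' @param sequence_id Sequence name in the returned track.
#' @return A depth-track tibble: `sequence_id`, `pos`, `depth`.
#' @export
simulate_depth_track <- function(length, mean_depth, size = 10,
                                 zero_regions = NULL, seed = 1L,
                                 sequence_id = "seq1") {
  stopifnot(length >= 1, mean_depth >= 0)
  with_substream(seed, 307L, {
    depth <- stats::rnbinom(length, size = size, mu = mean_depth)
    if (!is.null(zero_regions) && nrow(zero_regions) > 0) {
      for (i in seq_len(nrow(zero_regions))) {
        depth[seq.int(zero_regions$start[i], zero_regions$end[i])] <- 0L
      }
    }
    tibble(sequence_id = sequence_id, pos = seq_len(length), depth = as.integer(depth))
  })
}

#' Simulate a pooled-sample SNP call set with GATK-style site annotations
#'
#' Generates VCF-shaped records whose INFO metrics (QD, SOR, FS, MQ,
#' MQRankSum, ReadPosRankSum), QUAL, variant type and allele depths are
#' drawn either inside or outside the hard-filter passing ranges, with the
#' fraction of deliberate violations per criterion set by `p_fail`.  The
#' truth columns record whether each record should survive
#' [hard_filter()] and why not.
#'
#' @inheritParams simulate_contigs
#' @param p_fail Named numeric vector of per-criterion violation
#'   probabilities; names among `qd, qual, sor, fs, mq, mqranksum,
#'   readposranksum, maf, indel`.  Unnamed criteria default to 0.
#' @param thresholds A [hard_filter_thresholds()] defining pass ranges.
#' @return A tibble of records with columns `chrom, pos, id, ref, alt,
#'   qual, qd, sor, fs, mq, mq_rank_sum, read_pos_rank_sum, ad_ref, ad_alt`
#'   plus truth columns `truth_retained` (logical) and `truth_reasons`
#'   (list of character).
#' @export
simulate_vcf <- function(cfg, p_fail = c(qd = 0.05, qual = 0.05, sor = 0.05,
                                         fs = 0.05, mq = 0.05,
                                         mqranksum = 0.03, readposranksum = 0.03,
                                         maf = 0.1, indel = 0.05),
                         thresholds = hard_filter_thresholds(ploidy = cfg$ploidy)) {
  validate_sim_config(cfg)
  p <- function(key) if (key %in% names(p_fail)) unname(p_fail[[key]]) else 0
  n <- cfg$n_variants
  with_substream(cfg$seed, 401L, {
    fail_mask <- function(key) runif(n) < p(key)
    f_qd <- fail_mask("qd"); qd <- ifelse(f_qd, runif(n, 0, thresholds$qd_min * 0.99),
                                          runif(n, thresholds$qd_min, 40))
    f_qual <- fail_mask("qual"); qual <- ifelse(f_qual, runif(n, 0, thresholds$qual_min * 0.99),
                                                runif(n, thresholds$qual_min, 3000))
    f_sor <- fail_mask("sor"); sor <- ifelse(f_sor, runif(n, thresholds$sor_max * 1.01, 10),
                                             runif(n, 0, thresholds$sor_max))
    f_fs <- fail_mask("fs"); fs <- ifelse(f_fs, runif(n, thresholds$fs_max * 1.01, 200),
                                          runif(n, 0, thresholds$fs_max))
    f_mq <- fail_mask("mq"); mq <- ifelse(f_mq, runif(n, 0, thresholds$mq_min * 0.99),
                                          runif(n, thresholds$mq_min, 60))
    f_mqrs <- fail_mask("mqranksum")
    mqrs <- ifelse(f_mqrs, runif(n, -30, thresholds$mqranksum_min * 1.01),
                   runif(n, thresholds$mqranksum_min, 12.5))
    f_rprs <- fail_mask("readposranksum")
    rprs <- ifelse(f_rprs, runif(n, -20, thresholds$readposranksum_min * 1.01),
                   runif(n, thresholds$readposranksum_min, 8))
    f_indel <- fail_mask("indel")
    f_maf <- fail_mask("maf")

    maf_target <- draw_maf(cfg$maf_distribution, n)
    maf_target <- ifelse(f_maf, runif(n, 0, thresholds$maf_min * 0.9),
                         pmax(maf_target, thresholds$maf_min))
    total <- sample(100:400, n, replace = TRUE)
    minor <- pmin(round(maf_target * total), floor(total / 2))
    minor_is_ref <- runif(n) < 0.5
    ad_ref <- ifelse(minor_is_ref, minor, total - minor)
    ad_alt <- total - ad_ref

    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- purrr::map_chr(ref, function(r) sample(setdiff(bases, r), 1))
    ref <- ifelse(f_indel, paste0(ref, "T"), ref)

    records <- tibble(
      chrom = "MhFV_sim", pos = sort(sample.int(160000L, max(n, 1)))[seq_len(n)],
      id = ".", ref = ref, alt = alt, qual = qual,
      qd = qd, sor = sor, fs = fs, mq = mq,
      mq_rank_sum = mqrs, read_pos_rank_sum = rprs,
      ad_ref = as.integer(ad_ref), ad_alt = as.integer(ad_alt)
    )
    if (n == 0) {
      records <- records[0, ]
      records$truth_retained <- logical(0)
      records$truth_reasons <- list()
      return(records)
    }
    maf_real <- minor_allele_frequency(records$ad_ref, records$ad_alt)
    reasons <- purrr::pmap(
      list(f_indel, f_qd, f_qual, f_sor, f_fs, f_mq, f_mqrs, f_rprs,
           !is.na(maf_real) & maf_real < thresholds$maf_min),
      function(ind, qd, qu, so, fsf, mqf, mr, rp, mf) {
        c(if (ind) "not_snp", if (qd) "QD", if (qu) "QUAL", if (so) "SOR",
          if (fsf) "FS", if (mqf) "MQ", if (mr) "MQRankSum",
          if (rp) "ReadPosRankSum", if (mf) "MAF")
      }
    )
    records$truth_retained <- lengths(reasons) == 0
    records$truth_reasons <- reasons
    records
  })
}

draw_maf <- function(dist, n) {
  switch(dist$name,
    uniform = runif(n, dist$min %||% 0, dist$max %||% 0.5),
    beta = {
      x <- stats::rbeta(n, dist$shape1 %||% 2, dist$shape2 %||% 5)
      pmin(x, 1 - x)
    },
    abort(sprintf("invalid sim_config field `maf_distribution`: unknown distribution '%s'",
                  dist$name), class = "viraltriage_config_error")
  )
}

#' Simulate a random ultrametric tree
#'
#' Coalescent topology rescaled so every root-to-tip path equals `height`.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Integer seed.
#' @param height Root-to-tip height in relative time units.
#' @return An [ape::rcoal()]-style `phylo` object, exactly ultrametric.
#' @examples
#' tr <- simulate_ultrametric_tree(6, seed = 3, height = 0.5)
#' max(ape::node.depth.edgelength(tr))
#' @export
simulate_ultrametric_tree <- function(n_taxa, seed = 1L, height = 1) {
  if (n_taxa < 2) abort("n_taxa must be >= 2", class = "viraltriage_input_error")
  if (height <= 0) abort("height must be > 0", class = "viraltriage_input_error")
  with_substream(seed, 503L, {
    tr <- ape::rcoal(n_taxa, tip.label = sprintf("t%02d", seq_len(n_taxa)))
    cur <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * (height / cur)
    tr
  })
}

#' Simulate gene loci and homology hit tables with planted triage truth
#'
#' Plumbing for end-to-end pipeline tests: places `genes_per_contig` genes
#' on each contig and gives every gene on a viral contig a strong viral
#' best hit, every host gene a strong eukaryotic best hit, plus optional
#' noise hits and optional planted eukaryotic hits on viral contigs
#' (endogenous-like co-occupancy).
#'
#' @inheritParams simulate_hic_pairs
#' @param plant_eukaryotic If `TRUE`, roughly half the genes on each viral
#'   contig receive a eukaryote (braconid) hit better than their viral hit.
#' @return A list: `loci` (gene loci tibble), `hits` (homology-hit tibble),
#'   `taxon_map` (taxid to category tibble), `busco_genes` (character).
#' @export
simulate_gene_hits <- function(cfg, truth, plant_eukaryotic = FALSE) {
  validate_sim_config(cfg)
  with_substream(cfg$seed, 601L, {
    taxon_map <- tibble(
      taxid = c(10001L, 20001L, 20002L, 30001L, 40001L),
      category = c("viral", "eukaryote_braconid", "eukaryote_other",
                   "bacterial", "other")
    )
    loci <- truth |>
      dplyr::rowwise() |>
      dplyr::reframe(
        gene_id = sprintf("%s_g%02d", .data$contig_id, seq_len(cfg$genes_per_contig)),
        contig_id = .data$contig_id,
        start = seq(1L, by = 1000L, length.out = cfg$genes_per_contig),
        end = seq(900L, by = 1000L, length.out = cfg$genes_per_contig),
        strand = sample(c("+", "-"), cfg$genes_per_contig, replace = TRUE),
        group = .data$group
      )
    hits <- purrr::pmap_dfr(
      list(loci$gene_id, loci$group),
      function(gid, grp) {
        viral_gene <- grp == "viral"
        e_main <- 10^runif(1, -40, -10)
        main <- tibble(
          query_id = gid,
          subject_id = if (viral_gene) "viral_prot" else "wasp_prot",
          subject_taxon = if (viral_gene) 10001L else 20001L,
          evalue = e_main,
          bitscore = round(runif(1, 100, 400), 1)
        )
        out <- main
        if (viral_gene && plant_eukaryotic && runif(1) < 0.5) {
          out <- bind_rows(out, tibble(
            query_id = gid, subject_id = "braconid_prot",
            subject_taxon = 20001L, evalue = e_main / 100,
            bitscore = main$bitscore + 10
          ))
        }
        if (runif(1) < cfg$hit_noise_rate) {
          out <- bind_rows(out, tibble(
            query_id = gid, subject_id = "bact_prot",
            subject_taxon = 30001L, evalue = 10^runif(1, -8, -3),
            bitscore = round(runif(1, 40, 80), 1)
          ))
        }
        out
      }
    )
    busco <- loci$gene_id[loci$group != "viral" & seq_len(nrow(loci)) %% 3 == 0]
    list(loci = select(loci, -"group"), hits = hits,
         taxon_map = taxon_map, busco_genes = busco)
  })
}
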