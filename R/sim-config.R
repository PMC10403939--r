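#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator.  Defaults encode the
#' contrasts observed in the study system this package models: host contigs
#' at ~29.5% GC and ~175x depth versus viral contigs at ~34.0% GC and ~258x
#' depth, Hi-C libraries in which only ~0.15% of contacts involve viral
#' contigs and ~83.8% of those are viral-viral, and a pooled pentaploid
#' (five haploid individuals) variant call set.
#'
#' @param seed Integer seed; the same config and seed reproduce every
#'   artifact byte for byte.
#' @param n_host_contigs,n_viral_contigs Number of contigs per group.
#' @param host_gc_mean,host_gc_sd,viral_gc_mean,viral_gc_sd Per-contig GC
#'   target distribution (fractions in `[0,1]`); the sd creates
#'   between-contig variance, matching the observation unit of the
#'   downstream tests (contigs, not bases).
#' @param host_depth_mean,host_depth_sd,viral_depth_mean,viral_depth_sd
#'   Per-contig mean sequencing depth distribution (reads, >= 0).
#' @param contig_len_min,contig_len_max Contig length range in bp.
#' @param n_hic_pairs Number of Hi-C contact pairs to draw.
#' @param p_viral_involved Probability a contact involves >= 1 viral contig.
#' @param p_viral_viral_given_involved Probability an involved contact has
#'   both ends viral.
#' @param genes_per_contig Genes simulated per contig for hit-table plumbing.
#' @param hit_noise_rate Fraction of genes receiving a spurious off-category
#'   hit in simulated hit tables.
#' @param ploidy Ploidy written into simulated VCF genotypes (default 5:
#'   one pooled sample of five haploid individuals).
#' @param n_variants Number of simulated VCF records.
#' @param maf_distribution Named list describing the minor-allele-frequency
#'   distribution, e.g. `list(name = "uniform", min = 0.02, max = 0.5)` or
#'   `list(name = "beta", shape1 = 2, shape2 = 5)` (values folded into
#'   `[0, 0.5]`).
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_viral_contigs = 5, n_host_contigs = 10)
#' cfg$viral_gc_mean
#' @export
sim_config <- function(seed = 1L,
                       n_host_contigs = 50L,
                       n_viral_contigs = 20L,
                       host_gc_mean = 0.295, host_gc_sd = 0.02,
                       viral_gc_mean = 0.340, viral_gc_sd = 0.02,
                       host_depth_mean = 175, host_depth_sd = 40,
                       viral_depth_mean = 258, viral_depth_sd = 40,
                       contig_len_min = 2000L, contig_len_max = 20000L,
                       n_hic_pairs = 100000L,
                       p_viral_involved = 0.0015,
                       p_viral_viral_given_involved = 0.838,
                       genes_per_contig = 5L,
                       hit_noise_rate = 0.02,
                       ploidy = 5L,
                       n_variants = 100L,
                       maf_distribution = list(name = "uniform", min = 0.02, max = 0.5)) {
  cfg <- list(
    seed = seed,
    n_host_contigs = n_host_contigs, n_viral_contigs = n_viral_contigs,
    host_gc_mean = host_gc_mean, host_gc_sd = host_gc_sd,
    viral_gc_mean = viral_gc_mean, viral_gc_sd = viral_gc_sd,
    host_depth_mean = host_depth_mean, host_depth_sd = host_depth_sd,
    viral_depth_mean = viral_depth_mean, viral_depth_sd = viral_depth_sd,
    contig_len_min = contig_len_min, contig_len_max = contig_len_max,
    n_hic_pairs = n_hic_pairs,
    p_viral_involved = p_viral_involved,
    p_viral_viral_given_involved = p_viral_viral_given_involved,
    genes_per_contig = genes_per_contig,
    hit_noise_rate = hit_noise_rate,
    ploidy = ploidy, n_variants = n_variants,
    maf_distribution = maf_distribution
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    abort(sprintf("invalid sim_config field `%s`: %s", field, why),
          class = "viraltriage_config_error")
  }
  num1 <- function(field) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x)) bad(field, "must be a single non-missing number")
    x
  }
  for (f in c("seed", "n_host_contigs", "n_viral_contigs", "contig_len_min",
              "contig_len_max", "n_hic_pairs", "genes_per_contig", "ploidy",
              "n_variants")) {
    x <- num1(f)
    if (x < 0) bad(f, "must be non-negative")
  }
  for (f in c("host_gc_mean", "viral_gc_mean", "p_viral_involved",
              "p_viral_viral_given_involved", "hit_noise_rate")) {
    x <- num1(f)
    if (x < 0 || x > 1) bad(f, "must be a fraction in [0, 1]")
  }
  for (f in c("host_gc_sd", "viral_gc_sd", "host_depth_sd", "viral_depth_sd")) {
    if (num1(f) < 0) bad(f, "must be a non-negative sd")
  }
  for (f in c("host_depth_mean", "viral_depth_mean")) {
    if (num1(f) < 0) bad(f, "must be non-negative")
  }
  if (cfg$contig_len_min < 1) bad("contig_len_min", "must be >= 1")
  if (cfg$contig_len_max < cfg$contig_len_min)
    bad("contig_len_max", "must be >= contig_len_min")
  if (cfg$ploidy < 1) bad("ploidy", "must be >= 1")
  if (!is.list(cfg$maf_distribution) || is.null(cfg$maf_distribution$name))
    bad("maf_distribution", "must be a named list with a `name` element")
  cfg
}
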