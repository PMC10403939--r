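test_that("GC computation handles symmetry, boundaries and ambiguity codes", {
  expect_equal(compute_gc("ATGC"), 0.5)
  expect_equal(compute_gc("AAAA"), 0)
  expect_equal(compute_gc("atgc"), 0.5)
  expect_equal(compute_gc("GCNNN"), 1)  # N excluded from the denominator
  expect_true(is.na(compute_gc("NNNN")))
  expect_error(compute_gc(""), class = "viraltriage_input_error")
})

test_that("GC matches a per-character tally on random sequences", {
  withr::local_seed(31)
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 10000, TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    chars <- strsplit(s, "")[[1]]
    want <- sum(chars %in% c("G", "C")) / sum(chars %in% c("A", "C", "G", "T"))
    expect_equal(compute_gc(s), want)
  }
})

test_that("the exact small-sample Wilcoxon equals exhaustive enumeration", {
  # the canonical separated case: p = 2 * (1/20) = 0.10
  m <- tibble::tibble(
    contig_id = sprintf("c%d", 1:6), length = 1000L,
    gc = c(1, 2, 3, 4, 5, 6) / 10, mean_depth = 100,
    group = rep(c("viral", "reference"), each = 3)
  )
  res <- run_cascade(m, "gc")
  expect_true(res$pairwise$exact)
  expect_equal(res$pairwise$raw_p, 0.10)
  expect_equal(res$pairwise$raw_p, oracle_wilcoxon_exact(c(0.1, 0.2, 0.3),
                                                         c(0.4, 0.5, 0.6)))
  # random tie-free small samples agree with enumeration
  withr::local_seed(33)
  for (rep in 1:20) {
    nx <- sample(3:6, 1); ny <- sample(3:8, 1)
    x <- round(stats::rnorm(nx), 6); y <- round(stats::rnorm(ny, 0.5), 6)
    mm <- tibble::tibble(
      contig_id = sprintf("c%d", seq_len(nx + ny)), length = 1L,
      gc = 0.3, mean_depth = c(x, y),
      group = rep(c("viral", "reference"), c(nx, ny))
    )
    got <- run_cascade(mm, "depth")$pairwise$raw_p
    expect_equal(got, oracle_wilcoxon_exact(x, y), tolerance = 1e-12)
  }
})

test_that("the cascade records the normality gate and enforces preconditions", {
  m <- simulate_contig_metrics(sim_config(seed = 41))
  res <- run_cascade(m, "gc")
  expect_s3_class(res, "cascade_result")
  expect_identical(nrow(res$shapiro), 2L)
  expect_true(all(res$pairwise$adjusted_p >= res$pairwise$raw_p))
  expect_true(all(res$pairwise$raw_p >= 0 & res$pairwise$raw_p <= 1))
  # fewer than 3 contigs in a group is an input error
  too_small <- m[c(1:5, which(m$group == "viral")[1:2]), ]
  expect_error(run_cascade(too_small, "gc"), class = "viraltriage_input_error")
  # a constant group forces the nonparametric route with a warning
  const <- m |> dplyr::mutate(gc = ifelse(group == "viral", 0.3, gc))
  expect_warning(resc <- run_cascade(const, "gc"), "constant")
  expect_identical(resc$route, "nonparametric")
  # tidy/glance expose the tables
  expect_identical(nrow(tidy(res)), 1L)
  expect_identical(glance(res)$metric, "gc")
})

test_that("Holm-adjusted p-values are monotone in raw-p rank order", {
  m <- simulate_contig_metrics(sim_config(seed = 43))
  m$group[1:15] <- "outlierish"
  res <- run_cascade(m, "depth")
  pw <- res$pairwise[order(res$pairwise$raw_p), ]
  expect_true(all(diff(pw$adjusted_p) >= -1e-12))
  expect_equal(res$pairwise$adjusted_p,
               stats::p.adjust(res$pairwise$raw_p, "holm"),
               tolerance = 1e-12)
})

test_that("two-group Kruskal-Wallis agrees with Wilcoxon in rejection on large samples", {
  withr::local_seed(47)
  for (rep in 1:10) {
    shift <- sample(c(0, 0.3), 1)
    m <- tibble::tibble(
      contig_id = sprintf("c%d", 1:300), length = 1L, gc = 0.3,
      mean_depth = c(stats::rnorm(150), stats::rnorm(150, shift)),
      group = rep(c("reference", "viral"), each = 150)
    )
    res <- run_cascade(m, "depth")
    expect_identical(res$omnibus_p < 0.05, res$pairwise$raw_p < 0.05)
  }
})

test_that("the paper-scale GC contrast is detected with high power", {
  hits <- purrr::map_lgl(1:60, function(i) {
    m <- simulate_contig_metrics(sim_config(seed = 5000 + i))
    res <- run_cascade(m, "gc")
    min(res$pairwise$adjusted_p) < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("outlier sensitivity reruns the contrast three ways", {
  m <- simulate_contig_metrics(sim_config(seed = 51))
  # empty outlier set: with == without
  s0 <- outlier_sensitivity(m, "depth", outliers = character())
  expect_equal(s0$with$pairwise, s0$without$pairwise)
  # plant two extreme-depth viral contigs (the scaffold-90/995 situation)
  v_idx <- which(m$group == "viral")[1:2]
  m2 <- m
  m2$mean_depth[v_idx] <- 5 * 258
  out_ids <- m2$contig_id[v_idx]
  # both planted outliers share one value, so the separate-group run
  # warns that its Shapiro-Wilk gate is undefined for that group
  s <- suppressWarnings(outlier_sensitivity(m2, "depth", outliers = out_ids))
  without_mean <- mean(s$without$data$value[s$without$data$group == "viral"])
  expect_lt(abs(without_mean - 258), 2 * 40 / sqrt(18) * 3)
  expect_false(any(out_ids %in% s$without$data$contig_id))
  # outliers as their own group: three pairwise comparisons
  expect_identical(nrow(s$separate_group$pairwise), 3L)
  # outliers must exist and be viral
  expect_error(outlier_sensitivity(m, "depth", outliers = "nope"),
               class = "viraltriage_input_error")
  ref_id <- m$contig_id[m$group == "reference"][1]
  expect_error(outlier_sensitivity(m, "depth", outliers = ref_id),
               class = "viraltriage_input_error")
})

make_cascade <- function(p, metric = "gc") {
  # minimal synthetic cascade_result carrying a chosen adjusted p
  structure(list(
    metric = metric, alpha = 0.05,
    shapiro = tibble::tibble(group = c("reference", "viral"), n = 10,
                             shapiro_p = 0.001),
    route = "nonparametric", omnibus_stat = 1, omnibus_p = p,
    pairwise = tibble::tibble(group_a = "reference", group_b = "viral",
                              statistic = 1, raw_p = p, adjusted_p = p,
                              exact = FALSE),
    data = tibble::tibble(contig_id = "c", value = 1, group = "viral")
  ), class = "cascade_result")
}

test_that("the decision table reproduces the three published evidence patterns", {
  clean <- tibble::tibble(contig_id = "v1", n_genes = 5L, n_viral = 5L,
                          n_eukaryotic = 0L, n_braconid = 0L, n_busco = 0L,
                          viral_flag = TRUE)
  cooccupied <- tibble::tibble(contig_id = "v1", n_genes = 16L, n_viral = 6L,
                               n_eukaryotic = 10L, n_braconid = 10L,
                               n_busco = 0L, viral_flag = TRUE)
  hic_good <- tibble::tibble(total = 10000L, n_involved = 15L,
                             n_viral_viral = 13L, f_involved = 0.0015,
                             f_viral_viral = 0.838)
  # M.-hyperodae-like: clean contigs, episome-like Hi-C, both metrics apart
  call <- decide(clean, hic_good, make_cascade(6.7e-08), make_cascade(1.6e-03, "depth"))
  expect_identical(call$verdict, "exogenous")
  # Moroccan-like: co-occupancy and no metric separation
  call2 <- decide(cooccupied, hic_good, make_cascade(0.12), make_cascade(0.88, "depth"))
  expect_identical(call2$verdict, "endogenous_candidate")
  # French-like: co-occupancy but both metrics separated
  call3 <- decide(cooccupied, hic_good, make_cascade(1.9e-02), make_cascade(7.4e-03, "depth"))
  expect_identical(call3$verdict, "ambiguous")
  # missing evidence is an input error
  expect_error(decide(clean, NULL, make_cascade(0.01), make_cascade(0.01)),
               class = "viraltriage_input_error")
})

test_that("decide() is a pure function of its evidence", {
  clean <- tibble::tibble(contig_id = "v1", n_genes = 2L, n_viral = 2L,
                          n_eukaryotic = 0L, n_braconid = 0L, n_busco = 0L,
                          viral_flag = TRUE)
  hic <- tibble::tibble(total = 100L, n_involved = 10L, n_viral_viral = 9L,
                        f_involved = 0.1, f_viral_viral = 0.9)
  a <- decide(clean, hic, make_cascade(0.01), make_cascade(0.2, "depth"))
  b <- decide(clean, hic, make_cascade(0.01), make_cascade(0.2, "depth"))
  expect_identical(tidy(a), tidy(b))
  expect_identical(a$verdict, "exogenous")
  # undefined viral-viral share can never support exogenous
  hic0 <- tibble::tibble(total = 100L, n_involved = 0L, n_viral_viral = 0L,
                         f_involved = 0, f_viral_viral = NA_real_)
  expect_identical(decide(clean, hic0, make_cascade(0.01),
                          make_cascade(0.01, "depth"))$verdict, "ambiguous")
})

test_that("the full sim-triage-classify pipeline recovers planted truth", {
  verdicts <- purrr::map_chr(1:25, function(i) {
    cfg <- sim_config(seed = 7000 + i, genes_per_contig = 2L,
                      n_hic_pairs = 20000L)
    m <- simulate_contig_metrics(cfg)
    truth <- tibble::tibble(contig_id = m$contig_id,
                            group = ifelse(m$group == "viral", "viral", "host"))
    gh <- simulate_gene_hits(cfg, truth)
    calls <- triage_genes(gh$hits, gh$taxon_map)
    summ <- summarize_contigs(calls, gh$loci, gh$busco_genes)
    hic <- compute_hic_fractions(simulate_hic_pairs(cfg, truth),
                                 truth$contig_id[truth$group == "viral"])
    decide(summ, hic, run_cascade(m, "gc"), run_cascade(m, "depth"))$verdict
  })
  expect_gte(mean(verdicts == "exogenous"), 0.95)
})
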