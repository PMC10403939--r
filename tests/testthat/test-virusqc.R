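track_of <- function(depth, sid = "s") {
  tibble::tibble(sequence_id = sid, pos = seq_along(depth),
                 depth = as.integer(depth))
}

test_that("windowed depth handles constancy, arithmetic and short sequences", {
  const <- track_of(rep(7L, 1200))
  w <- windowed_depth(const, 500, 100)
  expect_true(all(w$mean_depth == 7))
  w2 <- windowed_depth(track_of(1:4), 2, 2)
  expect_identical(w2$window_start, c(1L, 3L))
  expect_equal(w2$mean_depth, c(1.5, 3.5))
  expect_warning(w3 <- windowed_depth(track_of(1:4), 10, 2), "exceeds")
  expect_identical(nrow(w3), 1L)
  expect_equal(w3$mean_depth, 2.5)
  expect_error(windowed_depth(track_of(1:4), 0, 1),
               class = "viraltriage_input_error")
})

test_that("windowed depth matches the slice-and-average oracle", {
  for (rep in 1:6) {
    depth <- withr::with_seed(100 + rep, stats::rnbinom(10000, 10, mu = 150))
    got <- windowed_depth(track_of(depth), 500, 100)
    want <- oracle_windows(depth, 500, 100)
    expect_identical(nrow(got), nrow(want))
    expect_identical(got$window_start, as.integer(want[, 1]))
    expect_equal(got$mean_depth, want[, 2])
    # window-count identity for L >= W
    n_full <- floor((length(depth) - 500) / 100) + 1
    expect_true(nrow(got) %in% c(n_full, n_full + 1))
  }
})

test_that("zero regions are maximal runs with correct summaries", {
  all_pos <- find_zero_regions(track_of(c(3, 1, 4, 1)))
  expect_identical(nrow(all_pos$regions), 0L)
  expect_identical(all_pos$summary$total_bp, 0L)
  z <- find_zero_regions(track_of(c(0, 0, 3, 0)))
  expect_identical(z$regions$start, c(1L, 4L))
  expect_identical(z$regions$end, c(2L, 4L))
  expect_identical(z$summary$n_regions, 2L)
  expect_identical(z$summary$total_bp, 3L)
  expect_equal(z$summary$mean_length, 1.5)
})

test_that("circular mode merges a run spanning the origin", {
  z <- find_zero_regions(track_of(c(0, 0, 5, 0, 0, 0)), circular = TRUE)
  expect_identical(nrow(z$regions), 1L)
  expect_true(z$regions$wraps)
  expect_identical(z$regions$length, 5L)
  # linear mode keeps the two runs apart
  zl <- find_zero_regions(track_of(c(0, 0, 5, 0, 0, 0)))
  expect_identical(nrow(zl$regions), 2L)
})

test_that("zero regions match the linear-scan oracle and conserve positions", {
  for (rep in 1:6) {
    depth <- withr::with_seed(200 + rep,
                              ifelse(stats::runif(5000) < 0.05, 0L,
                                     stats::rnbinom(5000, 5, mu = 80) + 1L))
    z <- find_zero_regions(track_of(depth))
    want <- oracle_zero_regions(depth)
    if (is.null(want)) {
      expect_identical(nrow(z$regions), 0L)
    } else {
      expect_identical(z$regions$start, as.integer(want[, "start"]))
      expect_identical(z$regions$end, as.integer(want[, "end"]))
    }
    expect_identical(sum(z$regions$length), sum(depth == 0))
  }
})

test_that("BED export converts to 0-based half-open coordinates", {
  z <- find_zero_regions(track_of(c(0, 0, 3, 0)))
  path <- withr::local_tempfile(fileext = ".bed")
  write_zero_regions_bed(z$regions, path)
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                         col_types = "cii", progress = FALSE)
  expect_identical(bed$start, c(0L, 3L))
  expect_identical(bed$end, c(2L, 4L))
})

base_record <- function(...) {
  r <- tibble::tibble(
    chrom = "v", pos = 100L, id = ".", ref = "A", alt = "G", qual = 1000,
    qd = 20, sor = 1, fs = 5, mq = 55, mq_rank_sum = 0, read_pos_rank_sum = 0,
    ad_ref = 60L, ad_alt = 40L
  )
  mods <- list(...)
  for (nm in names(mods)) r[[nm]] <- mods[[nm]]
  r
}

test_that("the hard filter applies each published removal condition", {
  expect_true(hard_filter(base_record())$retained)
  low_qd <- hard_filter(base_record(qd = 1.9))
  expect_false(low_qd$retained)
  expect_identical(low_qd$reasons[[1]], "QD")
  # boundary values pass (the filter expression states failure)
  expect_true(hard_filter(base_record(qd = 2, qual = 30, sor = 3, fs = 60,
                                      mq = 40, mq_rank_sum = -12.5,
                                      read_pos_rank_sum = -8))$retained)
  # an indel passing all metrics is still removed
  indel <- hard_filter(base_record(ref = "A", alt = "AT"))
  expect_false(indel$retained)
  expect_identical(indel$reasons[[1]], "not_snp")
  # missing INFO metrics pass their criterion, and the count is logged
  na_rec <- hard_filter(base_record(mq_rank_sum = NA_real_))
  expect_true(na_rec$retained)
  expect_identical(attr(na_rec, "n_missing_info"), 1)
  # absent or zero allele depths fail the MAF criterion explicitly
  expect_identical(hard_filter(base_record(ad_ref = NA_integer_))$reasons[[1]],
                   "no_AD")
  expect_identical(hard_filter(base_record(ad_ref = 0L, ad_alt = 0L))$reasons[[1]],
                   "no_depth")
  expect_identical(hard_filter(base_record(ad_ref = 95L, ad_alt = 5L))$reasons[[1]],
                   "MAF")
})

test_that("hard filtering matches sim truth and the predicate oracle", {
  v <- simulate_vcf(sim_config(seed = 81, n_variants = 120))
  out <- hard_filter(v)
  expect_identical(out$retained, v$truth_retained)
  t <- hard_filter_thresholds()
  for (i in seq_len(nrow(v))) {
    expect_identical(out$retained[i],
                     oracle_hard_filter_row(as.list(v[i, ]), t))
  }
  # per-record: output invariant under reordering
  perm <- withr::with_seed(82, sample.int(nrow(v)))
  out_perm <- hard_filter(v[perm, ])
  expect_identical(out_perm$retained, out$retained[perm])
})

test_that("relaxing any single threshold never reduces retention", {
  v <- simulate_vcf(sim_config(seed = 83, n_variants = 150))
  n0 <- sum(hard_filter(v)$retained)
  relaxed <- list(
    hard_filter_thresholds(qd_min = 1), hard_filter_thresholds(qual_min = 10),
    hard_filter_thresholds(sor_max = 5), hard_filter_thresholds(fs_max = 100),
    hard_filter_thresholds(mq_min = 20),
    hard_filter_thresholds(mqranksum_min = -20),
    hard_filter_thresholds(readposranksum_min = -15),
    hard_filter_thresholds(maf_min = 0.01)
  )
  for (t in relaxed) expect_gte(sum(hard_filter(v, t)$retained), n0)
})

test_that("MAF arithmetic matches the min/sum oracle", {
  expect_equal(minor_allele_frequency(90L, 10L), 0.10)
  expect_equal(minor_allele_frequency(50L, 50L), 0.50)
  expect_true(is.na(minor_allele_frequency(0L, 0L)))
  withr::local_seed(85)
  ref <- sample(0:200, 200, TRUE)
  alt <- sample(0:200, 200, TRUE)
  want <- vapply(seq_along(ref), function(i) {
    tot <- ref[i] + alt[i]
    if (tot == 0) NA_real_ else min(ref[i], alt[i]) / tot
  }, numeric(1))
  expect_equal(minor_allele_frequency(ref, alt), want)
})

test_that("best-hit selection follows the lowest-E / highest-score rule", {
  hits <- tibble::tibble(
    query_id = c("q1", "q1"), subject = c("first", "second"),
    evalue = c(1e-10, 1e-10), bitscore = c(200, 180)
  )
  expect_identical(select_best_hits(hits, "blast")$subject, "first")
  # stable input order on full ties
  tie <- dplyr::mutate(hits, bitscore = 200)
  expect_identical(select_best_hits(tie, "blast")$subject, "first")
  dom <- tibble::tibble(query_id = "q1", subject = c("keep", "drop"),
                        evalue = 1e-9, bitscore = 100,
                        independent_evalue = c(4e-04, 6e-04))
  expect_identical(select_best_hits(dom, "domain")$subject, "keep")
})

test_that("best-hit selection matches the sort oracle on random tables", {
  withr::local_seed(87)
  for (rep in 1:100) {
    hits <- tibble::tibble(
      query_id = sample(sprintf("q%d", 1:8), 30, TRUE),
      subject = sprintf("s%02d", 1:30),
      evalue = signif(10^stats::runif(30, -20, -2), 2),
      bitscore = sample(50:70, 30, TRUE)
    )
    got <- select_best_hits(hits, "blast")
    want <- hits[oracle_best_blast(hits), ]
    expect_identical(got[order(got$query_id), ],
                     want[order(want$query_id), ])
  }
})
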