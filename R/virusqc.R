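# depth tracks travel as tibbles (sequence_id, pos, depth), 1-based;
# positions absent from the track are treated as depth 0.
depth_vector <- function(track, sequence_id = NULL) {
  ids <- unique(track$sequence_id)
  if (is.null(sequence_id)) {
    if (length(ids) != 1)
      abort("track covers several sequences; pass `sequence_id`",
            class = "viraltriage_input_error")
    sequence_id <- ids
  }
  t1 <- track[track$sequence_id == sequence_id, ]
  if (nrow(t1) == 0)
    abort(sprintf("no positions for sequence '%s' in track", sequence_id),
          class = "viraltriage_input_error")
  len <- max(t1$pos)
  depth <- integer(len)
  depth[t1$pos] <- as.integer(t1$depth)
  depth
}

#' Sliding-window mean depth
#'
#' Windows start at 1, 1+slide, 1+2*slide, ...; each spans `window` bp and
#' a final partial window (if the last start begins a span running past
#' the sequence end) is averaged over its actual length.  The defaults
#' (500 bp window, 100 bp slide) are the resolution used to profile the
#' viral genome's read coverage.
#'
#' @param track Depth-track tibble: `sequence_id`, `pos`, `depth`
#'   (1-based; missing positions count as 0).
#' @param window Window size in bp.
#' @param slide Step between window starts in bp.
#' @param sequence_id Which sequence to profile when the track holds
#'   several.
#' @return A tibble: `sequence_id`, `window_start`, `window_end`,
#'   `mean_depth`.
#' @examples
#' tr <- tibble::tibble(sequence_id = "s", pos = 1:4, depth = 1:4)
#' windowed_depth(tr, window = 2, slide = 2)
#' @export
windowed_depth <- function(track, window = 500L, slide = 100L,
                           sequence_id = NULL) {
  if (window < 1 || slide < 1)
    abort("window and slide must be >= 1", class = "viraltriage_input_error")
  ids <- if (is.null(sequence_id)) unique(track$sequence_id) else sequence_id
  purrr::map_dfr(ids, function(sid) {
    depth <- depth_vector(track, sid)
    len <- length(depth)
    w <- window
    if (w > len) {
      warn(sprintf("window (%d) exceeds sequence length (%d); using one whole-sequence window", w, len))
      return(tibble(sequence_id = sid, window_start = 1L, window_end = len,
                    mean_depth = mean(depth)))
    }
    full_starts <- seq.int(1L, len - w + 1L, by = slide)
    starts <- full_starts
    last_full <- full_starts[length(full_starts)]
    if (last_full + slide <= len) starts <- c(starts, last_full + slide)
    tibble(
      sequence_id = sid,
      window_start = as.integer(starts),
      window_end = as.integer(pmin(starts + w - 1L, len)),
      mean_depth = vapply(seq_along(starts), function(i) {
        mean(depth[starts[i]:min(starts[i] + w - 1L, len)])
      }, numeric(1))
    )
  })
}

#' Coverage-dropout regions
#'
#' Maximal runs of zero depth, 1-based inclusive, with summary statistics
#' over region lengths.  In circular mode a run touching both ends of the
#' linearised sequence is merged into one origin-spanning region (flagged
#' `wraps = TRUE`, with `start > end`).
#'
#' @inheritParams windowed_depth
#' @param circular Merge a zero run spanning the origin?
#' @return A list with `regions` (tibble: `sequence_id`, `start`, `end`,
#'   `length`, `wraps`) and `summary` (one row per sequence: `n_regions`,
#'   `min_length`, `max_length`, `mean_length`, `total_bp`).
#' @examples
#' tr <- tibble::tibble(sequence_id = "s", pos = 1:4,
#'                      depth = c(0L, 0L, 3L, 0L))
#' find_zero_regions(tr)$regions
#' @export
find_zero_regions <- function(track, circular = FALSE, sequence_id = NULL) {
  ids <- if (is.null(sequence_id)) unique(track$sequence_id) else sequence_id
  regions <- purrr::map_dfr(ids, function(sid) {
    depth <- depth_vector(track, sid)
    r <- rle(depth == 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    reg <- tibble(
      sequence_id = sid,
      start = as.integer(starts[r$values]),
      end = as.integer(ends[r$values]),
      wraps = FALSE
    )
    if (circular && nrow(reg) >= 2 && reg$start[1] == 1L &&
        reg$end[nrow(reg)] == length(depth)) {
      merged <- tibble(
        sequence_id = sid,
        start = reg$start[nrow(reg)], end = reg$end[1], wraps = TRUE
      )
      reg <- bind_rows(reg[-c(1, nrow(reg)), ], merged)
    }
    reg
  })
  regions <- regions |>
    mutate(length = ifelse(.data$wraps,
                           NA_integer_,  # filled below per sequence
                           .data$end - .data$start + 1L))
  if (any(regions$wraps)) {
    lens <- vapply(which(regions$wraps), function(i) {
      sid <- regions$sequence_id[i]
      seq_len_total <- max(track$pos[track$sequence_id == sid])
      (seq_len_total - regions$start[i] + 1L) + regions$end[i]
    }, integer(1))
    regions$length[regions$wraps] <- lens
  }
  summary <- if (nrow(regions) > 0) {
    regions |>
      group_by(.data$sequence_id) |>
      summarise(
        n_regions = n(),
        min_length = min(.data$length), max_length = max(.data$length),
        mean_length = mean(.data$length), total_bp = sum(.data$length),
        .groups = "drop"
      )
  } else {
    tibble(sequence_id = ids, n_regions = 0L,
           min_length = NA_integer_, max_length = NA_integer_,
           mean_length = NA_real_, total_bp = 0L)
  }
  list(regions = regions, summary = summary)
}

#' Export zero regions as BED
#'
#' Converts the 1-based inclusive region coordinates to BED's 0-based
#' half-open convention; an origin-wrapping region is written as its two
#' linear pieces.
#'
#' @param regions Region tibble from [find_zero_regions()].
#' @param path Output path.
#' @param track The source depth track (needed to split wrapped regions).
#' @return `path`, invisibly.
#' @export
write_zero_regions_bed <- function(regions, path, track = NULL) {
  rows <- purrr::pmap_dfr(regions, function(sequence_id, start, end, wraps, length) {
    if (!wraps) {
      tibble(chrom = sequence_id, start = start - 1L, end = end)
    } else {
      if (is.null(track))
        abort("track is required to export origin-wrapping regions",
              class = "viraltriage_input_error")
      seq_len_total <- max(track$pos[track$sequence_id == sequence_id])
      bind_rows(
        tibble(chrom = sequence_id, start = start - 1L, end = seq_len_total),
        tibble(chrom = sequence_id, start = 0L, end = end)
      )
    }
  })
  readr::write_tsv(rows, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' GATK-style hard-filter thresholds
#'
#' Retention bounds for pooled-sample SNP calls.  The published removal
#' conditions (QD < 2, QUAL < 30, SOR > 3, FS > 60, MQ < 40,
#' MQRankSum < -12.5, ReadPosRankSum < -8, minor allele frequency below
#' 0.1) are stored as their retention complements, so boundary values
#' pass — GATK's convention, where the filter expression states failure.
#'
#' @param qd_min,qual_min,sor_max,fs_max,mq_min,mqranksum_min,readposranksum_min,maf_min
#'   Retention bounds.
#' @param ploidy Ploidy of the pooled call set (default 5).
#' @return A list of class `hard_filter_thresholds`.
#' @export
hard_filter_thresholds <- function(qd_min = 2, qual_min = 30, sor_max = 3,
                                   fs_max = 60, mq_min = 40,
                                   mqranksum_min = -12.5,
                                   readposranksum_min = -8,
                                   maf_min = 0.1, ploidy = 5L) {
  vals <- list(qd_min = qd_min, qual_min = qual_min, sor_max = sor_max,
               fs_max = fs_max, mq_min = mq_min,
               mqranksum_min = mqranksum_min,
               readposranksum_min = readposranksum_min,
               maf_min = maf_min, ploidy = ploidy)
  if (!all(vapply(vals, function(x) is.numeric(x) && is.finite(x), logical(1))))
    abort("all thresholds must be finite numbers",
          class = "viraltriage_input_error")
  if (maf_min < 0 || maf_min > 0.5)
    abort("maf_min must lie in [0, 0.5]", class = "viraltriage_input_error")
  structure(vals, class = "hard_filter_thresholds")
}

#' Minor allele frequency from allele depths
#'
#' For a single pooled sample: `min(ref_depth, sum(alt_depths)) / total`.
#' Zero total depth makes the MAF undefined (`NA`), which fails the MAF
#' criterion downstream.
#'
#' @param ad_ref,ad_alt Integer vectors of reference and summed alternate
#'   allele depths.
#' @return Numeric vector of MAFs in `[0, 0.5]`, `NA` where undefined.
#' @examples
#' minor_allele_frequency(90L, 10L)
#' @export
minor_allele_frequency <- function(ad_ref, ad_alt) {
  total <- ad_ref + ad_alt
  out <- pmin(ad_ref, ad_alt) / total
  out[!is.na(total) & total == 0] <- NA_real_
  out
}

#' Hard-filter a pooled-sample SNP call set
#'
#' Retains records that are SNPs (single-base REF and every ALT allele a
#' single base) and pass every retention bound in `thresholds`; the MAF
#' criterion is computed from the pooled sample's allele depths by default
#' (see `maf_from`).  Missing site annotations pass their criterion (the
#' GATK convention for sites where a rank-sum test is undefined); the
#' number of such passes is reported in the `n_missing_info` attribute.
#'
#' @param records Record tibble (see [read_vcf_records()] /
#'   [simulate_vcf()]).
#' @param thresholds A [hard_filter_thresholds()].
#' @param maf_from `"AD"` (allele depths, default) or `"GT"` is accepted
#'   for interface compatibility; with the flat record table both reduce
#'   to the stored allele depths.
#' @return `records` with two added columns: `retained` (logical) and
#'   `reasons` (list of character vectors naming every violated
#'   criterion: `not_snp`, `QD`, `QUAL`, `SOR`, `FS`, `MQ`, `MQRankSum`,
#'   `ReadPosRankSum`, `MAF`, `no_depth`, `no_AD`).
#' @export
hard_filter <- function(records, thresholds = hard_filter_thresholds(),
                        maf_from = c("AD", "GT")) {
  maf_from <- match.arg(maf_from)
  n <- nrow(records)
  if (n == 0) {
    records$retained <- logical(0)
    records$reasons <- list()
    return(records)
  }
  is_snp <- nchar(records$ref) == 1 &
    vapply(strsplit(records$alt, ","), function(a) all(nchar(a) == 1), logical(1))
  crit <- list(
    QD = records$qd >= thresholds$qd_min,
    QUAL = records$qual >= thresholds$qual_min,
    SOR = records$sor <= thresholds$sor_max,
    FS = records$fs <= thresholds$fs_max,
    MQ = records$mq >= thresholds$mq_min,
    MQRankSum = records$mq_rank_sum >= thresholds$mqranksum_min,
    ReadPosRankSum = records$read_pos_rank_sum >= thresholds$readposranksum_min
  )
  n_missing_info <- sum(vapply(crit, function(x) sum(is.na(x)), numeric(1)))
  crit <- lapply(crit, function(x) ifelse(is.na(x), TRUE, x))

  no_ad <- is.na(records$ad_ref) | is.na(records$ad_alt)
  maf <- minor_allele_frequency(records$ad_ref, records$ad_alt)
  no_depth <- !no_ad & is.na(maf)
  maf_ok <- !no_ad & !no_depth & maf >= thresholds$maf_min

  reasons <- purrr::map(seq_len(n), function(i) {
    r <- character(0)
    if (!is_snp[i]) r <- c(r, "not_snp")
    for (k in names(crit)) if (!crit[[k]][i]) r <- c(r, k)
    if (no_ad[i]) {
      r <- c(r, "no_AD")
    } else if (no_depth[i]) {
      r <- c(r, "no_depth")
    } else if (!maf_ok[i]) {
      r <- c(r, "MAF")
    }
    r
  })
  out <- records
  out$retained <- lengths(reasons) == 0
  out$reasons <- reasons
  attr(out, "n_missing_info") <- n_missing_info
  out
}

#' Select best annotation hits
#'
#' `blast` mode keeps, per query, the hit with the lowest E-value, the
#' highest bit-score breaking E-value ties and input order breaking
#' residual ties.  `domain` mode keeps every domain hit whose
#' *independent* E-value is below the cutoff (default 5e-04).
#'
#' @param hits Annotation-hit tibble: `query_id`, `subject`, `evalue`,
#'   `bitscore`, and for domain mode `independent_evalue`.
#' @param mode `"blast"` or `"domain"`.
#' @param independent_e_max Domain-mode cutoff (strictly below retains).
#' @return The filtered hit tibble, in input order.
#' @export
select_best_hits <- function(hits, mode = c("blast", "domain"),
                             independent_e_max = 5e-04) {
  mode <- match.arg(mode)
  if (mode == "domain") {
    return(filter(hits, .data$independent_evalue < independent_e_max))
  }
  hits |>
    mutate(.idx = row_number()) |>
    group_by(.data$query_id) |>
    arrange(.data$evalue, dplyr::desc(.data$bitscore), .data$.idx,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$.idx) |>
    select(-".idx")
}

#' Coverage profile plot
#'
#' Sliding-window mean depth with zero-coverage regions shaded.
#'
#' @param track Depth-track tibble.
#' @param window,slide Passed to [windowed_depth()].
#' @return A ggplot object.
#' @export
plot_depth_profile <- function(track, window = 500L, slide = 100L) {
  win <- windowed_depth(track, window, slide)
  zr <- find_zero_regions(track)$regions
  p <- ggplot2::ggplot(win, ggplot2::aes(x = .data$window_start,
                                         y = .data$mean_depth)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "position (bp)", y = "mean depth (x)",
                  title = sprintf("Sliding-window coverage (%d bp window, %d bp slide)",
                                  window, slide)) +
    ggplot2::facet_wrap(~sequence_id, ncol = 1, scales = "free_x") +
    ggplot2::theme_minimal()
  if (nrow(zr) > 0) {
    p <- p + ggplot2::geom_rect(
      data = filter(zr, !.data$wraps),
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "#b2182b", alpha = 0.3
    )
  }
  p
}
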