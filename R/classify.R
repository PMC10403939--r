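#' GC fraction of a nucleotide sequence
#'
#' (#G + #C) / (#A + #C + #G + #T), case-insensitive.  IUPAC ambiguity
#' codes are excluded from the denominator; an all-ambiguous sequence has
#' undefined GC and returns `NA`.
#'
#' @param sequence A non-empty nucleotide string.
#' @return GC fraction in `[0, 1]`, or `NA` if no unambiguous bases.
#' @examples
#' compute_gc("ATGC")
#' @export
compute_gc <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence))
    abort("compute_gc() expects a single non-empty sequence string",
          class = "viraltriage_input_error")
  counts <- Biostrings::letterFrequency(
    Biostrings::DNAString(toupper(sequence)), c("A", "C", "G", "T"))
  denom <- sum(counts)
  if (denom == 0) return(NA_real_)
  unname((counts[["C"]] + counts[["G"]]) / denom)
}

#' Two-sample Wilcoxon rank-sum test, exact for small tie-free samples
#'
#' Two-sided; exact null distribution when the smaller group has at most
#' `exact_max` observations and there are no ties, normal approximation
#' with continuity correction (and midranks) otherwise.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest min-group size for which the exact null is used.
#' @return A list with `statistic` (W, as in [stats::wilcox.test()]),
#'   `p_value`, and `exact` (logical).
#' @keywords internal
wilcoxon_pair <- function(x, y, exact_max = 8) {
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && min(length(x), length(y)) <= exact_max
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value, exact = use_exact)
}

#' Run the nonparametric contrast cascade on contig metrics
#'
#' The published route for comparing viral contigs against reference
#' contigs: a Shapiro-Wilk normality check per group decides the route
#' (any group rejecting at `alpha` means nonparametric), a Kruskal-Wallis
#' rank-sum omnibus tests for any group difference, and two-sided pairwise
#' Wilcoxon rank-sum tests with Holm adjustment localise it.  The
#' nonparametric tests are always the ones executed — the route field
#' records what the gate indicated (the parametric branch is intentionally
#' not implemented; the data this method targets rejected normality).
#'
#' @param metrics Contig-metrics tibble: `contig_id`, `gc`, `mean_depth`,
#'   `group` (any number of groups >= 2, each with >= 3 contigs).
#' @param metric `"gc"` or `"depth"`.
#' @param alpha Significance threshold (default 0.05).
#' @param exclude Optional character vector of contig ids dropped before
#'   testing (outlier handling).
#' @param shapiro_max Groups larger than this are subsampled (fixed
#'   seed) for the Shapiro-Wilk gate, which is undefined above n = 5000.
#' @param min_group Smallest allowed group size (default 3; the
#'   separate-outlier-group analysis relaxes it, since an outlier group
#'   is often a single contig).
#' @return A `cascade_result`: list with `metric`, `alpha`, `shapiro`
#'   (tibble of per-group p-values), `route`, `omnibus_stat`, `omnibus_p`,
#'   `pairwise` (tibble: `group_a`, `group_b`, `statistic`, `raw_p`,
#'   `adjusted_p`, `exact`), and the analysed `data`.
#' @examples
#' m <- simulate_contig_metrics(sim_config(seed = 2))
#' res <- run_cascade(m, "gc")
#' glance(res)
#' @export
run_cascade <- function(metrics, metric = c("gc", "depth"), alpha = 0.05,
                        exclude = NULL, shapiro_max = 5000L, min_group = 3L) {
  metric <- match.arg(metric)
  value_col <- if (metric == "gc") "gc" else "mean_depth"
  d <- metrics
  if (!is.null(exclude)) d <- filter(d, !(.data$contig_id %in% exclude))
  d <- tibble(contig_id = d$contig_id, value = d[[value_col]], group = d$group)
  groups <- sort(unique(d$group))
  if (length(groups) < 2)
    abort("run_cascade() needs >= 2 groups after exclusion",
          class = "viraltriage_input_error")
  sizes <- table(d$group)
  if (any(sizes < min_group))
    abort(sprintf("group(s) with fewer than %d contigs: %s", min_group,
                  paste(names(sizes)[sizes < min_group], collapse = ", ")),
          class = "viraltriage_input_error")

  shapiro <- purrr::map_dfr(groups, function(g) {
    x <- d$value[d$group == g]
    if (length(x) > shapiro_max)
      x <- withr::with_seed(20230805L, sample(x, shapiro_max))
    if (length(unique(x)) == 1) {
      warn(sprintf("group '%s' is constant; Shapiro-Wilk undefined, route forced nonparametric", g))
      return(tibble(group = g, n = length(x), shapiro_p = NA_real_))
    }
    if (length(x) < 3)  # Shapiro-Wilk undefined below n = 3
      return(tibble(group = g, n = length(x), shapiro_p = NA_real_))
    tibble(group = g, n = length(x), shapiro_p = shapiro.test(x)$p.value)
  })
  route <- if (any(is.na(shapiro$shapiro_p)) || any(shapiro$shapiro_p < alpha, na.rm = TRUE))
    "nonparametric" else "parametric"

  kw <- kruskal.test(d$value, factor(d$group))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(p) {
    w <- wilcoxon_pair(d$value[d$group == p[1]], d$value[d$group == p[2]])
    tibble(group_a = p[1], group_b = p[2], statistic = w$statistic,
           raw_p = w$p_value, exact = w$exact)
  })
  pairwise$adjusted_p <- p.adjust(pairwise$raw_p, method = "holm")
  pairwise <- select(pairwise, "group_a", "group_b", "statistic", "raw_p",
                     "adjusted_p", "exact")

  structure(
    list(metric = metric, alpha = alpha, shapiro = shapiro, route = route,
         omnibus_stat = unname(kw$statistic), omnibus_p = kw$p.value,
         pairwise = pairwise, data = d),
    class = "cascade_result"
  )
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("Contig contrast cascade on %s (alpha = %g, route: %s)\n",
              x$metric, x$alpha, x$route))
  cat(sprintf("Kruskal-Wallis chi-squared = %.4g, p = %.3g\n",
              x$omnibus_stat, x$omnibus_p))
  cat("Pairwise Wilcoxon (Holm-adjusted):\n")
  print(as.data.frame(x$pairwise), row.names = FALSE)
  invisible(x)
}

#' @rdname run_cascade
#' @param x A `cascade_result`.
#' @param ... Unused.
#' @export
tidy.cascade_result <- function(x, ...) {
  mutate(x$pairwise, metric = x$metric, .before = 1)
}

#' @rdname run_cascade
#' @export
glance.cascade_result <- function(x, ...) {
  tibble(
    metric = x$metric, route = x$route, n_groups = nrow(x$shapiro),
    omnibus_stat = x$omnibus_stat, omnibus_p = x$omnibus_p,
    min_adjusted_p = min(x$pairwise$adjusted_p), alpha = x$alpha
  )
}

#' @rdname run_cascade
#' @param object A `cascade_result`.
#' @export
autoplot.cascade_result <- function(object, ...) {
  lab <- if (object$metric == "gc") "GC fraction" else "mean depth (x)"
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$group, y = .data$value,
                               fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = 21, alpha = 0.7) +
    ggplot2::labs(
      x = NULL, y = lab,
      title = sprintf("%s by contig group", lab),
      subtitle = sprintf("Kruskal-Wallis p = %.2g; min Holm-adjusted Wilcoxon p = %.2g",
                         object$omnibus_p, min(object$pairwise$adjusted_p))
    ) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Sensitivity of the cascade to designated outlier contigs
#'
#' Re-runs the contrast three ways: as-is, with the outliers excluded, and
#' with the outliers moved to their own third group — mirroring how
#' extreme-depth contigs were handled in the source analyses (e.g. two
#' viral contigs at ~879x mean depth).
#'
#' @inheritParams run_cascade
#' @param outliers Character vector of contig ids; must lie in the viral
#'   group.
#' @return A list of class `outlier_sensitivity` with `with`, `without`
#'   and `separate_group` cascade results.
#' @export
outlier_sensitivity <- function(metrics, metric = c("gc", "depth"),
                                alpha = 0.05, outliers = character()) {
  metric <- match.arg(metric)
  unknown <- setdiff(outliers, metrics$contig_id)
  if (length(unknown) > 0)
    abort(sprintf("outlier contig(s) not in data: %s", paste(unknown, collapse = ", ")),
          class = "viraltriage_input_error")
  not_viral <- setdiff(outliers,
                       metrics$contig_id[metrics$group == "viral"])
  if (length(not_viral) > 0)
    abort(sprintf("outlier contig(s) not in the viral group: %s",
                  paste(not_viral, collapse = ", ")),
          class = "viraltriage_input_error")
  sep <- mutate(metrics, group = ifelse(.data$contig_id %in% outliers,
                                        "outlier", .data$group))
  structure(
    list(
      with = run_cascade(metrics, metric, alpha),
      without = run_cascade(metrics, metric, alpha, exclude = outliers),
      # the outlier group may be tiny (often 1-2 contigs), so the
      # separate-group run relaxes the group-size floor
      separate_group = if (length(outliers) > 0)
        run_cascade(sep, metric, alpha, min_group = 1L)
      else run_cascade(metrics, metric, alpha)
    ),
    class = "outlier_sensitivity"
  )
}

#' @export
print.outlier_sensitivity <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "==\n")
    print(x[[nm]])
  }
  invisible(x)
}

# smallest Holm-adjusted p among pairwise comparisons involving `group`
min_adjusted_p_for <- function(cascade, group = "viral") {
  pw <- cascade$pairwise
  sel <- pw$group_a == group | pw$group_b == group
  if (!any(sel)) return(NA_real_)
  min(pw$adjusted_p[sel])
}

#' Decide exogenous vs endogenous from the assembled evidence
#'
#' A transparent decision table over three evidence tiers:
#' co-occupancy (are there eukaryotic or BUSCO genes on viral-flagged
#' contigs?), Hi-C behaviour (do viral contigs have contacts, and are
#' those contacts predominantly viral-viral?), and the GC/depth contrasts.
#' `exogenous` requires clean viral contigs (no eukaryotic/BUSCO
#' co-occupancy), episome-like Hi-C behaviour (`f_involved > 0` and
#' `f_viral_viral` above `vv_enrichment`), and at least one significant
#' metric contrast.  `endogenous_candidate` requires co-occupancy with
#' neither metric significant.  Everything else is `ambiguous`.
#'
#' @param summary Contig triage summaries from [summarize_contigs()].
#' @param hic One-row fractions tibble from [compute_hic_fractions()].
#' @param gc_result,depth_result `cascade_result`s from [run_cascade()].
#' @param alpha Significance threshold applied to the Holm-adjusted
#'   pairwise p-values involving the viral group.
#' @param vv_enrichment Minimum viral-viral share among viral-involved
#'   Hi-C contacts to count as episome-like (default 0.5; the study system
#'   showed 0.838).
#' @return A `triage_call`: list with `verdict` in
#'   `{exogenous, endogenous_candidate, ambiguous}` and an `evidence`
#'   one-row tibble recording every input to the table.
#' @export
decide <- function(summary, hic, gc_result, depth_result, alpha = 0.05,
                   vv_enrichment = 0.5) {
  if (missing(summary) || missing(hic) || missing(gc_result) ||
      missing(depth_result) || is.null(summary) || is.null(hic) ||
      is.null(gc_result) || is.null(depth_result))
    abort("decide() requires all four evidence pieces",
          class = "viraltriage_input_error")
  viral_rows <- filter(summary, .data$viral_flag)
  euk_cooccupancy <- nrow(viral_rows) > 0 &&
    any(viral_rows$n_eukaryotic > 0 | viral_rows$n_busco > 0)
  hic_episome <- hic$f_involved > 0 && !is.na(hic$f_viral_viral) &&
    hic$f_viral_viral > vv_enrichment
  gc_p <- min_adjusted_p_for(gc_result)
  depth_p <- min_adjusted_p_for(depth_result)
  gc_sig <- !is.na(gc_p) && gc_p < alpha
  depth_sig <- !is.na(depth_p) && depth_p < alpha

  verdict <- if (!euk_cooccupancy && hic_episome && (gc_sig || depth_sig)) {
    "exogenous"
  } else if (euk_cooccupancy && !gc_sig && !depth_sig) {
    "endogenous_candidate"
  } else {
    "ambiguous"
  }
  structure(
    list(
      verdict = verdict,
      evidence = tibble(
        euk_cooccupancy = euk_cooccupancy,
        n_viral_contigs = nrow(viral_rows),
        f_involved = hic$f_involved,
        f_viral_viral = hic$f_viral_viral,
        hic_episome = hic_episome,
        gc_adjusted_p = gc_p, gc_significant = gc_sig,
        depth_adjusted_p = depth_p, depth_significant = depth_sig,
        alpha = alpha, vv_enrichment = vv_enrichment
      )
    ),
    class = "triage_call"
  )
}

#' @export
print.triage_call <- function(x, ...) {
  cat(sprintf("Verdict: %s\n", x$verdict))
  ev <- x$evidence
  cat(sprintf("  eukaryotic/BUSCO co-occupancy on viral contigs: %s\n",
              ev$euk_cooccupancy))
  cat(sprintf("  Hi-C: f_involved = %.4g, f_viral_viral = %s (episome-like: %s)\n",
              ev$f_involved,
              ifelse(is.na(ev$f_viral_viral), "undefined",
                     sprintf("%.3f", ev$f_viral_viral)),
              ev$hic_episome))
  cat(sprintf("  GC contrast: adjusted p = %.3g (significant: %s)\n",
              ev$gc_adjusted_p, ev$gc_significant))
  cat(sprintf("  depth contrast: adjusted p = %.3g (significant: %s)\n",
              ev$depth_adjusted_p, ev$depth_significant))
  invisible(x)
}

#' @rdname decide
#' @param x A `triage_call`.
#' @param ... Unused.
#' @export
tidy.triage_call <- function(x, ...) {
  mutate(x$evidence, verdict = x$verdict, .before = 1)
}
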