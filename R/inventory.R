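#' Curated gene sets
#'
#' `core_meiosis_genes()` is the default meiosis-specific subset of the
#' meiosis detection toolkit (genes with no known role outside meiosis,
#' so their conservation implies meiotic capability).
#' `naldv_core_genes()` is the 12-gene core shared by nuclear
#' arthropod-specific large dsDNA viruses, used as a completeness
#' checklist for candidate viral genomes.  Both are data, not code:
#' every consumer takes the set as an argument.
#'
#' @return Character vector of gene-model names.
#' @export
core_meiosis_genes <- function() {
  c("SPO11", "DMC1", "MND1", "HOP2", "REC8", "MSH4", "MSH5", "CORT")
}

#' @rdname core_meiosis_genes
#' @export
naldv_core_genes <- function() {
  c("DNApol", "helicase", "lef-5", "lef-8", "lef-9", "p33",
    "pif-0", "pif-1", "pif-2", "pif-3", "pif-5", "ac81")
}

#' Select significant profile-search hits
#'
#' Keeps hits at or below the E-value threshold (default 1e-15, the
#' hmmsearch cutoff used for the meiosis toolkit survey).  When
#' `unique_target = TRUE` (default) a peptide hit by several gene models
#' within one assembly is assigned to the single model with the smallest
#' E-value (score breaking ties, input order breaking residual ties), so
#' copy numbers are never double-counted; within a (taxon, model) cell one
#' hit is retained per distinct peptide.
#'
#' @param hits Profile-hit tibble: `model_id`, `target_id`, `taxon_id`,
#'   `evalue`, `score`.
#' @param e_threshold Retention threshold on the E-value.
#' @param unique_target Assign each peptide to at most one model?
#' @return The retained hits (same columns), one row per
#'   (taxon, model, target).
#' @export
select_hits <- function(hits, e_threshold = 1e-15, unique_target = TRUE) {
  if (any(is.na(hits$evalue)) || any(hits$evalue < 0))
    abort("negative or missing E-values in profile hits",
          class = "viraltriage_format_error")
  h <- hits |>
    mutate(.idx = row_number()) |>
    filter(.data$evalue <= e_threshold)
  if (unique_target) {
    h <- h |>
      group_by(.data$taxon_id, .data$target_id) |>
      arrange(.data$evalue, dplyr::desc(.data$score), .data$.idx,
              .by_group = TRUE) |>
      slice(1) |>
      ungroup()
  } else {
    # keep best row per (taxon, model, target)
    h <- h |>
      group_by(.data$taxon_id, .data$model_id, .data$target_id) |>
      arrange(.data$evalue, dplyr::desc(.data$score), .data$.idx,
              .by_group = TRUE) |>
      slice(1) |>
      ungroup()
  }
  h |>
    arrange(.data$.idx) |>
    select(-".idx")
}

#' Build a taxa x gene-model copy-number matrix
#'
#' Cell (taxon, model) is the number of distinct retained peptides for
#' that model in that assembly; zero means absent.  Taxa or models with no
#' hits appear as all-zero rows/columns so absences are explicit.
#'
#' @param retained Retained hits from [select_hits()].
#' @param taxa Character vector of row labels (assemblies/species).
#' @param models Character vector of column labels (gene models).
#' @return An `inventory_matrix`: list with `counts` (integer matrix,
#'   taxa x models) and `provenance` (named list, `"taxon|model"` to the
#'   retained peptide ids).
#' @export
build_matrix <- function(retained, taxa, models) {
  if (length(taxa) == 0 || length(models) == 0)
    abort("taxa and models must be non-empty", class = "viraltriage_input_error")
  counts <- matrix(0L, nrow = length(taxa), ncol = length(models),
                   dimnames = list(taxa, models))
  provenance <- list()
  keep <- retained |>
    filter(.data$taxon_id %in% taxa, .data$model_id %in% models) |>
    distinct(.data$taxon_id, .data$model_id, .data$target_id) |>
    arrange(.data$taxon_id, .data$model_id, .data$target_id)
  if (nrow(keep) > 0) {
    cells <- keep |>
      group_by(.data$taxon_id, .data$model_id) |>
      summarise(n = n(), targets = list(.data$target_id), .groups = "drop")
    for (i in seq_len(nrow(cells))) {
      counts[cells$taxon_id[i], cells$model_id[i]] <- cells$n[i]
      provenance[[paste(cells$taxon_id[i], cells$model_id[i], sep = "|")]] <-
        cells$targets[[i]]
    }
  }
  structure(list(counts = counts, provenance = provenance),
            class = "inventory_matrix")
}

#' @export
print.inventory_matrix <- function(x, ...) {
  cat(sprintf("Inventory matrix: %d taxa x %d gene models (%d retained hits)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' @rdname build_matrix
#' @param x An `inventory_matrix`.
#' @param ... Unused.
#' @return `tidy()`: long tibble `taxon`, `model`, `copy_number`.
#' @export
tidy.inventory_matrix <- function(x, ...) {
  as_tibble(x$counts, rownames = "taxon") |>
    tidyr::pivot_longer(-"taxon", names_to = "model",
                        values_to = "copy_number")
}

#' @rdname build_matrix
#' @param object An `inventory_matrix`.
#' @export
autoplot.inventory_matrix <- function(object, ...) {
  d <- tidy(object) |>
    mutate(status = factor(pmin(.data$copy_number, 3L), levels = 0:3,
                           labels = c("0", "1", "2", "3+")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$taxon,
                                  fill = .data$status)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_manual(values = c("0" = "white", "1" = "#74add1",
                                          "2" = "#4575b4", "3+" = "#313695"),
                               name = "copies") +
    ggplot2::labs(x = NULL, y = NULL, title = "Gene inventory") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Report presence of a core gene set per taxon
#'
#' Presence means copy number >= 1.  Used both for the meiosis-specific
#' toolkit subset (asexual lineages retaining them imply automixis) and
#' for the 12-gene NALDV core checklist on candidate viral genomes.
#'
#' @param matrix An `inventory_matrix` from [build_matrix()].
#' @param core Character vector of core gene-model names; must all be
#'   columns of `matrix`.
#' @return One row per taxon: `taxon`, `n_core_present`, `missing`
#'   (list-column of lexicographically sorted absent models),
#'   `missing_label` (comma-joined string for display).
#' @export
core_report <- function(matrix, core) {
  if (length(core) == 0)
    abort("core gene set must be non-empty", class = "viraltriage_input_error")
  absent <- setdiff(core, colnames(matrix$counts))
  if (length(absent) > 0)
    abort(sprintf("core gene(s) missing from matrix columns: %s",
                  paste(sort(absent), collapse = ", ")),
          class = "viraltriage_input_error")
  sub <- matrix$counts[, core, drop = FALSE]
  purrr::map_dfr(rownames(sub), function(t) {
    miss <- sort(core[sub[t, ] < 1])
    tibble(taxon = t, n_core_present = sum(sub[t, ] >= 1),
           missing = list(miss),
           missing_label = paste(miss, collapse = ","))
  })
}

#' Write an inventory matrix as TSV
#'
#' @param x An `inventory_matrix`.
#' @param path Output path (wide layout; use `tidy(x)` with
#'   [readr::write_tsv()] for the long layout).
#' @return `path`, invisibly.
#' @export
write_inventory_matrix <- function(x, path) {
  readr::write_tsv(as_tibble(x$counts, rownames = "taxon"), path,
                   progress = FALSE)
  invisible(path)
}
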