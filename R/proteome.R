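#' Normalize each sample to the mean total abundance
#'
#' TMT channel intensities carry arbitrary per-sample loading: the first
#' preprocessing step rescales every sample column so that all column totals
#' are equal (to the mean of the original totals). Within-sample proportions
#' are preserved exactly, so any positive per-sample scale factor is absorbed.
#'
#' @param abundance Data frame with `protein_id` first and one nonnegative
#'   numeric column per sample.
#' @return A tibble of the same shape with equalized column totals.
#' @examples
#' ab <- tibble::tibble(protein_id = c("a", "b"), s1 = c(1, 3), s2 = c(2, 6))
#' normalize_total_abundance(ab)
#' @export
normalize_total_abundance <- function(abundance) {
  samples <- check_abundance(abundance)
  totals <- vapply(abundance[samples], sum, numeric(1))
  zero <- samples[totals <= 0 | !is.finite(totals)]
  if (length(zero) > 0) {
    abort(paste0("Sample(s) with non-positive or non-finite total abundance: ",
                 toString(zero), "."), class = "polarscope_zero_total")
  }
  target <- mean(totals)
  out <- abundance
  for (s in samples) out[[s]] <- abundance[[s]] * (target / totals[[s]])
  as_tibble(out)
}

#' Log2 fold changes relative to averaged control samples
#'
#' For every non-control sample, each protein's abundance is divided by the
#' mean abundance of that protein across the control samples, and log2
#' transformed. Proteins whose control mean is zero have no defined fold
#' change; they are dropped from the output and reported via
#' [dropped_proteins()].
#'
#' @param abundance Normalized abundance table (see
#'   [normalize_total_abundance()]).
#' @param design Data frame with `sample_id`, `subtype`, `donor`,
#'   `is_control` describing every sample column.
#' @return A tibble (`protein_id` + one log2FC column per non-control
#'   sample) of class `polarscope_fc`, with attributes `centered = FALSE`
#'   and `dropped` (character vector of dropped protein ids).
#' @seealso [median_center()], [mean_by_subtype()]
#' @export
log2_fold_change_vs_control <- function(abundance, design) {
  samples <- check_abundance(abundance, design, require_controls = TRUE)
  design <- design[design$sample_id %in% samples, ]
  ctrl <- design$sample_id[design$is_control]
  test <- design$sample_id[!design$is_control]
  if (length(test) == 0) {
    abort("All samples are controls; nothing to compare.",
          class = "polarscope_bad_argument")
  }
  ctrl_mean <- rowMeans(as.matrix(abundance[ctrl]))
  keep <- is.finite(ctrl_mean) & ctrl_mean > 0
  dropped <- abundance$protein_id[!keep]
  if (length(dropped) > 0) {
    inform(sprintf("Dropped %d protein(s) with zero control mean: %s",
                   length(dropped), toString(utils::head(dropped, 5))))
  }
  fc <- log2(as.matrix(abundance[keep, test, drop = FALSE]) / ctrl_mean[keep])
  new_fc_tbl(matrix_to_tbl(fc, abundance$protein_id[keep]),
             centered = FALSE, dropped = as.character(dropped))
}

new_fc_tbl <- function(tbl, centered, dropped = character()) {
  structure(as_tibble(tbl), centered = centered, dropped = dropped,
            class = c("polarscope_fc", class(as_tibble(tbl))))
}

#' @rdname log2_fold_change_vs_control
#' @param fc A `polarscope_fc` tibble.
#' @export
dropped_proteins <- function(fc) attr(fc, "dropped") %||% character()

#' @rdname log2_fold_change_vs_control
#' @export
is_centered <- function(fc) isTRUE(attr(fc, "centered"))

#' Median-center log2 fold changes per sample
#'
#' Subtracts the per-sample (column) median from every log2FC column, the
#' final preprocessing step before aggregation. After centering every column
#' median is exactly zero.
#'
#' @param fc A `polarscope_fc` tibble from [log2_fold_change_vs_control()].
#' @return The centered `polarscope_fc` tibble (`centered` attribute set).
#' @export
median_center <- function(fc) {
  if (!inherits(fc, "polarscope_fc")) {
    abort("`fc` must be created by log2_fold_change_vs_control().",
          class = "polarscope_bad_argument")
  }
  if (is_centered(fc)) {
    abort("`fc` is already median-centered.", class = "polarscope_already_centered")
  }
  out <- fc
  for (s in setdiff(names(fc), "protein_id")) {
    out[[s]] <- fc[[s]] - stats::median(fc[[s]], na.rm = TRUE)
  }
  new_fc_tbl(out, centered = TRUE, dropped = dropped_proteins(fc))
}

#' Aggregate per-sample log2 fold changes to per-subtype means
#'
#' Averages the log2FC columns of each polarized subtype's replicates
#' (arithmetic mean across donors). Missing values are ignored when at least
#' one finite replicate exists; proteins averaged from fewer than the full
#' replicate count are listed in the `incomplete` attribute.
#'
#' @param fc A `polarscope_fc` tibble (typically median-centered).
#' @param design Sample design table (see [log2_fold_change_vs_control()]).
#' @return A tibble `protein_id` + one mean-log2FC column per subtype, class
#'   `polarscope_subtype_means`; attribute `incomplete` is a tibble
#'   (`protein_id`, `subtype`, `n_finite`, `n_samples`) of partial means.
#' @export
mean_by_subtype <- function(fc, design) {
  samples <- setdiff(names(fc), "protein_id")
  design <- design[design$sample_id %in% samples & !design$is_control, ]
  unmapped <- setdiff(samples, design$sample_id)
  if (length(unmapped) > 0) {
    abort(paste0("Fold-change sample(s) without a subtype in `design`: ",
                 toString(unmapped), "."), class = "polarscope_unmapped_sample")
  }
  subtypes <- unique(design$subtype)
  m <- as.matrix(fc[samples])
  means <- matrix(NA_real_, nrow(m), length(subtypes),
                  dimnames = list(NULL, subtypes))
  incomplete <- list()
  for (st in subtypes) {
    cols <- design$sample_id[design$subtype == st]
    if (length(cols) == 0) {
      abort(sprintf("Subtype '%s' has zero samples.", st),
            class = "polarscope_bad_argument")
    }
    block <- m[, cols, drop = FALSE]
    n_finite <- rowSums(is.finite(block))
    means[, st] <- rowMeans(block, na.rm = TRUE)
    means[n_finite == 0, st] <- NA_real_
    partial <- which(n_finite > 0 & n_finite < length(cols))
    if (length(partial) > 0) {
      incomplete[[st]] <- tibble(protein_id = fc$protein_id[partial],
                                 subtype = st,
                                 n_finite = n_finite[partial],
                                 n_samples = length(cols))
    }
  }
  structure(matrix_to_tbl(means, fc$protein_id),
            incomplete = dplyr::bind_rows(incomplete),
            class = c("polarscope_subtype_means", class(tibble())))
}

#' @rdname mean_by_subtype
#' @param means A `polarscope_subtype_means` tibble.
#' @export
incomplete_means <- function(means) {
  attr(means, "incomplete") %||%
    tibble(protein_id = character(), subtype = character(),
           n_finite = integer(), n_samples = integer())
}

#' Run the full proteome processing and classification chain
#'
#' Convenience composition: total-abundance normalization, control-referenced
#' log2 fold change, median centering (optional), per-subtype aggregation,
#' threshold classification, core-proteome extraction and Venn overlap
#' counts, with optional surface-atlas filtering applied first.
#'
#' @inheritParams log2_fold_change_vs_control
#' @inheritParams classify_polarity
#' @param atlas Optional surface-protein atlas (character vector or
#'   [read_atlas()] output); when supplied, results are restricted to atlas
#'   proteins after fold-change computation, emulating surfaceome curation.
#' @param center Median-center before aggregation (default TRUE).
#' @return A list of class `proteome_result` with elements `normalized`,
#'   `fc`, `subtype_means`, `calls`, `core`, `differential`, `venn` and,
#'   when an atlas was given, `surface_report`.
#' @examples
#' sim <- simulate_proteome(n_proteins = 60, seed = 4)
#' res <- run_proteome_pipeline(sim$abundance, sim$design)
#' head(res$core)
#' @export
run_proteome_pipeline <- function(abundance, design, atlas = NULL,
                                  up_threshold = 1, down_threshold = -1,
                                  boundary_inclusive = TRUE, center = TRUE) {
  normalized <- normalize_total_abundance(abundance)
  fc <- log2_fold_change_vs_control(normalized, design)
  if (center) fc <- median_center(fc)
  surface_report <- NULL
  if (!is.null(atlas)) {
    fc <- filter_surface(fc, atlas)
    surface_report <- attr(fc, "surface_report")
  }
  means <- mean_by_subtype(fc, design)
  calls <- classify_polarity(means, up_threshold = up_threshold,
                             down_threshold = down_threshold,
                             boundary_inclusive = boundary_inclusive)
  structure(list(
    normalized = normalized,
    fc = fc,
    subtype_means = means,
    calls = calls,
    core = core_proteome(calls),
    differential = differential_proteome(calls),
    venn = venn_overlap(calls),
    surface_report = surface_report
  ), class = "proteome_result")
}

#' @export
print.proteome_result <- function(x, ...) {
  st <- setdiff(names(x$calls), "protein_id")
  cat(sprintf("<proteome_result> %d proteins, subtypes: %s\n",
              nrow(x$calls), toString(st)))
  cat(sprintf("  core: %d, differential in >=1 subtype: %d\n",
              length(x$core), length(x$differential)))
  invisible(x)
}
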