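#' Simulate a TMT-style protein abundance experiment with planted truth
#'
#' Generates a proteins x samples abundance table emulating the structure of a
#' multiplexed isobaric-label (TMT) experiment comparing polarized macrophage
#' subtypes against unstimulated (M0) controls: a log-normal baseline per
#' protein, a planted log2 effect for each non-core protein in exactly one
#' subtype, multiplicative log-normal measurement noise, and a per-sample
#' loading factor that the normalization step must absorb.
#'
#' A fraction `frac_core` of proteins is "core": no planted effect in any
#' subtype, emulating the stable core proteome shared by all polarization
#' states. The remaining proteins are assigned uniformly to one subtype and
#' one direction (up/down) at `effect_log2fc`. Control samples never carry a
#' planted effect. A random subset of proteins is additionally flagged as
#' surface-localized and returned as a synthetic surface-protein atlas so that
#' surfaceome filtering can be exercised.
#'
#' @param n_proteins Number of proteins (>= 10).
#' @param subtypes Character vector of polarized subtype labels
#'   (default `c("M1", "M2a", "M2c")`). Must not contain `control_label`.
#' @param n_replicates Donors/replicates per subtype (default 3).
#' @param n_controls Number of control samples (default 2).
#' @param frac_core Fraction of proteins with no planted effect (default 0.5).
#' @param effect_log2fc Magnitude of planted log2 fold changes (default 2).
#' @param noise_sd Log2-scale standard deviation of measurement noise
#'   (default 0.3).
#' @param loading_spread Loading factors are drawn uniformly from
#'   `[1 - loading_spread, 1 + loading_spread]` (default 0.1).
#' @param frac_surface Fraction of proteins flagged surface-localized and
#'   placed in the synthetic atlas (default 0.2).
#' @param baseline_log2_mean,baseline_log2_sd Mean and sd of the log2
#'   baseline abundance distribution (defaults 10 and 2, spanning the dynamic
#'   range typical of TMT data).
#' @param control_label Subtype label used for control samples (default "M0").
#' @param seed Integer seed; identical parameters and seed give identical
#'   output.
#'
#' @return A list of class `proteome_sim` with components:
#' \describe{
#'   \item{abundance}{tibble, `protein_id` + one numeric column per sample.}
#'   \item{design}{tibble with `sample_id`, `subtype`, `donor`, `is_control`.}
#'   \item{truth}{list with `proteins` (tibble: `protein_id`, `is_core`,
#'     `is_surface`, one `planted_<subtype>` column per subtype),
#'     `loading` (tibble: `sample_id`, `loading_factor`), `atlas`
#'     (character vector of surface protein ids) and `noise_sd`.}
#' }
#' @examples
#' sim <- simulate_proteome(n_proteins = 50, seed = 1)
#' dim(sim$abundance)
#' mean(sim$truth$proteins$is_core)
#' @export
simulate_proteome <- function(n_proteins,
                              subtypes = c("M1", "M2a", "M2c"),
                              n_replicates = 3,
                              n_controls = 2,
                              frac_core = 0.5,
                              effect_log2fc = 2,
                              noise_sd = 0.3,
                              loading_spread = 0.1,
                              frac_surface = 0.2,
                              baseline_log2_mean = 10,
                              baseline_log2_sd = 2,
                              control_label = "M0",
                              seed = 1) {
  n_proteins <- check_count(n_proteins, "n_proteins", min = 10L)
  n_replicates <- check_count(n_replicates, "n_replicates")
  n_controls <- check_count(n_controls, "n_controls")
  frac_core <- check_fraction(frac_core, "frac_core")
  frac_surface <- check_fraction(frac_surface, "frac_surface")
  effect_log2fc <- check_scalar(effect_log2fc, "effect_log2fc", min = 0)
  noise_sd <- check_scalar(noise_sd, "noise_sd", min = 0)
  loading_spread <- check_fraction(loading_spread, "loading_spread")
  if (!is.character(subtypes) || length(subtypes) == 0 || anyDuplicated(subtypes)) {
    abort("`subtypes` must be a nonempty character vector without duplicates.",
          class = "polarscope_bad_argument")
  }
  if (control_label %in% subtypes) {
    abort(sprintf("Unknown subtype layout: control label '%s' clashes with `subtypes`.",
                  control_label), class = "polarscope_bad_argument")
  }

  with_seed(seed, {
    protein_id <- sprintf("P%05d", seq_len(n_proteins))
    n_core <- round(frac_core * n_proteins)
    is_core <- rep(FALSE, n_proteins)
    if (n_core > 0) is_core[sample.int(n_proteins, n_core)] <- TRUE
    is_surface <- stats::runif(n_proteins) < frac_surface

    planted <- matrix(0, n_proteins, length(subtypes),
                      dimnames = list(protein_id, subtypes))
    idx <- which(!is_core)
    if (length(idx) > 0) {
      target <- sample(seq_along(subtypes), length(idx), replace = TRUE)
      sign <- sample(c(-1, 1), length(idx), replace = TRUE)
      planted[cbind(idx, target)] <- sign * effect_log2fc
    }

    design <- dplyr::bind_rows(
      tibble(sample_id = sprintf("%s_ctrl%d", control_label, seq_len(n_controls)),
             subtype = control_label,
             donor = sprintf("d%d", seq_len(n_controls)),
             is_control = TRUE),
      tidyr::expand_grid(subtype = subtypes, donor = sprintf("d%d", seq_len(n_replicates))) |>
        dplyr::mutate(sample_id = paste(.data$subtype, .data$donor, sep = "_"),
                      is_control = FALSE) |>
        dplyr::select("sample_id", "subtype", "donor", "is_control")
    )

    n_samples <- nrow(design)
    loading <- stats::runif(n_samples, 1 - loading_spread, 1 + loading_spread)
    baseline <- 2^stats::rnorm(n_proteins, baseline_log2_mean, baseline_log2_sd)

    values <- matrix(0, n_proteins, n_samples,
                     dimnames = list(protein_id, design$sample_id))
    for (j in seq_len(n_samples)) {
      eff <- if (design$is_control[j]) 0 else planted[, design$subtype[j]]
      noise <- if (noise_sd > 0) stats::rnorm(n_proteins, 0, noise_sd) else 0
      values[, j] <- baseline * 2^(eff + noise) * loading[j]
    }

    planted_tbl <- as_tibble(as.data.frame(planted))
    names(planted_tbl) <- paste0("planted_", subtypes)
    structure(list(
      abundance = matrix_to_tbl(values, protein_id),
      design = design,
      truth = list(
        proteins = dplyr::bind_cols(
          tibble(protein_id = protein_id, is_core = is_core, is_surface = is_surface),
          planted_tbl),
        loading = tibble(sample_id = design$sample_id, loading_factor = loading),
        atlas = protein_id[is_surface],
        noise_sd = noise_sd
      )
    ), class = "proteome_sim")
  })
}

#' @export
print.proteome_sim <- function(x, ...) {
  cat(sprintf(
    "<proteome_sim> %d proteins x %d samples (%d controls); %d core, %d surface\n",
    nrow(x$abundance), nrow(x$design), sum(x$design$is_control),
    sum(x$truth$proteins$is_core), sum(x$truth$proteins$is_surface)))
  invisible(x)
}
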