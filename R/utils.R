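#' Internal validation helpers
#'
#' Shared argument checks. All user-facing errors are raised with
#' `rlang::abort()` so they carry a class and a readable message.
#' @noRd
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d, got %s.",
                  name, min, deparse(x)), class = "polarscope_bad_argument")
  }
  as.integer(x)
}

#' @noRd
check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1], got %s.",
                  name, deparse(x)), class = "polarscope_bad_argument")
  }
  as.numeric(x)
}

#' @noRd
check_scalar <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > min else x >= min)
  if (!ok) {
    abort(sprintf("`%s` must be a single finite number %s %s, got %s.",
                  name, if (strict) ">" else ">=", format(min), deparse(x)),
          class = "polarscope_bad_argument")
  }
  as.numeric(x)
}

#' Validate an abundance table + design pair
#'
#' An abundance table has `protein_id` as its first column and one numeric
#' column per sample; the design maps every sample column to a subtype,
#' donor and control status.
#' @noRd
check_abundance <- function(abundance, design = NULL, require_controls = FALSE) {
  if (!is.data.frame(abundance) || ncol(abundance) < 2L) {
    abort("`abundance` must be a data frame with a `protein_id` column and >= 1 sample column.",
          class = "polarscope_bad_argument")
  }
  if (names(abundance)[1] != "protein_id") {
    abort("The first column of `abundance` must be `protein_id`.",
          class = "polarscope_bad_argument")
  }
  dup <- unique(abundance$protein_id[duplicated(abundance$protein_id)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate protein_id value(s): ", toString(utils::head(dup, 5)), "."),
          class = "polarscope_duplicate_ids")
  }
  samples <- setdiff(names(abundance), "protein_id")
  bad <- samples[!vapply(abundance[samples], is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("Non-numeric sample column(s): ", toString(bad), "."),
          class = "polarscope_bad_argument")
  }
  if (!is.null(design)) {
    need <- c("sample_id", "subtype", "is_control")
    miss <- setdiff(need, names(design))
    if (length(miss) > 0) {
      abort(paste0("`design` is missing column(s): ", toString(miss), "."),
            class = "polarscope_bad_argument")
    }
    unmapped <- setdiff(samples, design$sample_id)
    if (length(unmapped) > 0) {
      abort(paste0("Sample column(s) not present in `design`: ", toString(unmapped), "."),
            class = "polarscope_unmapped_sample")
    }
    if (require_controls && !any(design$is_control[design$sample_id %in% samples])) {
      abort("No control samples in `design`; >= 1 control is required for fold-change computation.",
            class = "polarscope_no_controls")
    }
  }
  invisible(samples)
}

#' @noRd
abundance_values <- function(abundance) {
  m <- as.matrix(abundance[setdiff(names(abundance), "protein_id")])
  rownames(m) <- abundance$protein_id
  m
}

#' @noRd
matrix_to_tbl <- function(m, ids) {
  out <- as_tibble(as.data.frame(m, check.names = FALSE))
  dplyr::bind_cols(tibble(protein_id = ids), out)
}

#' Evaluate code under a fixed RNG seed, restoring global RNG state after
#' @noRd
with_seed <- function(seed, code) {
  seed <- check_count(seed, "seed", min = 0L)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Split an RNG seed into independent substream seeds
#'
#' Keeps derived seeds below 2^31 so they remain valid R integers.
#' @noRd
derive_seed <- function(seed, k) {
  (as.integer(seed) * 7919L + k * 104729L) %% 2147483647L
}
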