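#' Classify proteins as up, down or unchanged per subtype
#'
#' Applies the study's threshold rule to per-subtype mean log2 fold changes:
#' a protein is `up` in a subtype when its mean log2FC is at or above
#' `up_threshold`, `down` at or below `down_threshold`, and `unchanged`
#' otherwise (the core band). With `boundary_inclusive = FALSE` the
#' comparisons are strict. Proteins with a missing mean receive `NA`.
#'
#' @param means A `polarscope_subtype_means` tibble (or any data frame with
#'   `protein_id` plus one numeric mean-log2FC column per subtype).
#' @param up_threshold Log2FC at/above which a protein is called up
#'   (default +1).
#' @param down_threshold Log2FC at/below which a protein is called down
#'   (default -1).
#' @param boundary_inclusive Include the thresholds themselves
#'   (default TRUE).
#' @return A tibble `protein_id` + one call column per subtype (values
#'   `"up"`, `"down"`, `"unchanged"` or `NA`), class `polarscope_calls`,
#'   with the rule stored in attributes.
#' @examples
#' m <- tibble::tibble(protein_id = c("CR1", "CD63"), M1 = c(-3.02, 1.44))
#' classify_polarity(m)
#' @export
classify_polarity <- function(means, up_threshold = 1, down_threshold = -1,
                              boundary_inclusive = TRUE) {
  if (up_threshold <= down_threshold) {
    abort("`up_threshold` must exceed `down_threshold`.",
          class = "polarscope_bad_argument")
  }
  subtypes <- setdiff(names(means), "protein_id")
  out <- tibble(protein_id = means$protein_id)
  for (st in subtypes) {
    v <- means[[st]]
    up <- if (boundary_inclusive) v >= up_threshold else v > up_threshold
    down <- if (boundary_inclusive) v <= down_threshold else v < down_threshold
    out[[st]] <- dplyr::case_when(up ~ "up", down ~ "down",
                                  is.na(v) ~ NA_character_,
                                  TRUE ~ "unchanged")
  }
  structure(out,
            up_threshold = up_threshold, down_threshold = down_threshold,
            boundary_inclusive = boundary_inclusive,
            class = c("polarscope_calls", class(tibble())))
}

call_matrix <- function(calls) {
  m <- as.matrix(calls[setdiff(names(calls), "protein_id")])
  rownames(m) <- calls$protein_id
  m
}

#' Core and differential proteomes from a call table
#'
#' The core proteome is the set of proteins called `unchanged` in every
#' subtype (mean log2FC strictly inside the threshold band everywhere); the
#' differential proteome is its complement among fully classified proteins
#' (up or down in at least one subtype). Proteins with any `NA` call belong
#' to neither set.
#'
#' @param calls A `polarscope_calls` tibble from [classify_polarity()].
#' @return Character vector of protein ids.
#' @export
core_proteome <- function(calls) {
  m <- call_matrix(calls)
  calls$protein_id[rowSums(m == "unchanged") == ncol(m) & !apply(is.na(m), 1, any)]
}

#' @rdname core_proteome
#' @export
differential_proteome <- function(calls) {
  m <- call_matrix(calls)
  calls$protein_id[rowSums(m == "up" | m == "down", na.rm = TRUE) > 0]
}

#' Venn overlap of per-subtype differential sets
#'
#' Counts, for each subtype, the proteins differential (up or down) in that
#' subtype, and for every combination of subtypes the proteins differential
#' in exactly that combination — the numbers a Venn diagram of consistently
#' up/downregulated proteins displays.
#'
#' @param calls A `polarscope_calls` tibble covering >= 2 subtypes.
#' @return A list of class `venn_overlap`: `per_subtype` (tibble `subtype`,
#'   `n_differential`), `regions` (tibble with one logical membership column
#'   per subtype plus `n`, covering all non-empty combinations) and `union`
#'   (total differential proteins). `tidy()` returns the regions.
#' @examples
#' m <- tibble::tibble(protein_id = c("p1", "p2", "p3"),
#'                     A = c(2, 2, 0), B = c(0, -2, 2))
#' venn_overlap(classify_polarity(m))
#' @export
venn_overlap <- function(calls) {
  m <- call_matrix(calls)
  if (ncol(m) < 2) {
    abort("`venn_overlap()` needs >= 2 subtypes.", class = "polarscope_bad_argument")
  }
  diff <- (m == "up" | m == "down")
  diff[is.na(diff)] <- FALSE
  subtypes <- colnames(m)
  per_subtype <- tibble(subtype = subtypes, n_differential = colSums(diff))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(subtypes)))
  names(combos) <- subtypes
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  key <- apply(diff, 1, paste, collapse = "")
  combo_key <- apply(combos, 1, function(r) paste(as.logical(r), collapse = ""))
  n <- vapply(combo_key, function(k) sum(key == k), integer(1))
  regions <- dplyr::arrange(dplyr::bind_cols(as_tibble(combos), tibble(n = unname(n))),
                            dplyr::desc(rowSums(dplyr::pick(dplyr::all_of(subtypes)))))
  structure(list(per_subtype = per_subtype,
                 regions = as_tibble(regions),
                 union = sum(rowSums(diff) > 0)),
            class = "venn_overlap")
}

#' @export
tidy.venn_overlap <- function(x, ...) x$regions

#' @export
print.venn_overlap <- function(x, ...) {
  cat(sprintf("<venn_overlap> union of differential sets: %d proteins\n", x$union))
  print(x$per_subtype)
  invisible(x)
}

#' Restrict proteins to a cell-surface atlas
#'
#' Filters a fold-change table, call table or plain identifier set down to
#' proteins present in a surface-protein atlas (e.g. a Cell Surface Protein
#' Atlas-style identifier list), removing intracellular proteins from a
#' surfaceome data set. Matching is case-insensitive.
#'
#' @param x A data frame with a `protein_id` column, or a character vector
#'   of identifiers.
#' @param atlas A character vector of surface identifiers or the result of
#'   [read_atlas()].
#' @return `x` restricted to atlas proteins (same type). For data frames the
#'   attribute `surface_report` holds `retained` and `total` counts. When
#'   nothing is retained a warning is emitted and the empty result returned.
#' @export
filter_surface <- function(x, atlas) {
  ids <- if (inherits(atlas, "surface_atlas")) atlas$identifiers else atlas
  if (!is.character(ids) || length(ids) == 0) {
    abort("`atlas` must be a nonempty character vector (or read_atlas() result).",
          class = "polarscope_bad_argument")
  }
  ids <- tolower(ids)
  target <- if (is.data.frame(x)) x$protein_id else x
  keep <- tolower(target) %in% ids
  retained <- sum(keep)
  inform(sprintf("Surface filtering retained %d/%d proteins.", retained, length(keep)))
  if (retained == 0) {
    warn("No proteins matched the surface atlas; returning an empty set.")
  }
  if (is.data.frame(x)) {
    out <- x[keep, , drop = FALSE]
    attr(out, "surface_report") <- list(retained = retained, total = length(keep))
    # preserve fc class metadata through subsetting
    if (inherits(x, "polarscope_fc")) {
      out <- new_fc_tbl(out, centered = is_centered(x), dropped = dropped_proteins(x))
      attr(out, "surface_report") <- list(retained = retained, total = length(keep))
    }
    out
  } else {
    x[keep]
  }
}
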