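#' Hierarchical leaf order of proteins
#'
#' Orders proteins by agglomerative hierarchical clustering of their log2FC
#' profiles (Euclidean distance, complete linkage by default) — the row
#' order a clustered heatmap displays. The permutation respects the merge
#' order; for a single protein the trivial order is returned.
#'
#' @param x Data frame with `protein_id` plus numeric profile columns.
#' @param linkage_method Agglomeration method passed to [stats::hclust()]
#'   (default "complete").
#' @param metric Distance metric passed to [stats::dist()]
#'   (default "euclidean").
#' @return Integer vector: a permutation of `seq_len(nrow(x))`, named by
#'   protein id.
#' @examples
#' m <- tibble::tibble(protein_id = c("a", "b", "c"),
#'                     M1 = c(0, 0.1, 5), M2a = c(0, 0, 5))
#' hierarchical_order(m)
#' @export
hierarchical_order <- function(x, linkage_method = "complete",
                               metric = "euclidean") {
  vals <- as.matrix(x[setdiff(names(x), "protein_id")])
  if (!all(is.finite(vals))) {
    abort("Profiles contain non-finite values; remove or impute them first.",
          class = "polarscope_bad_argument")
  }
  n <- nrow(vals)
  ord <- if (n == 1) 1L else stats::hclust(stats::dist(vals, method = metric),
                                           method = linkage_method)$order
  names(ord) <- x$protein_id[ord]
  ord
}

#' Principal component scores of samples
#'
#' PCA of samples in protein-profile space: columns of `x` are samples,
#' proteins are features, features are centered before decomposition. Scores
#' follow a deterministic sign convention (the largest-magnitude loading of
#' each component is positive), so results do not depend on LAPACK sign
#' choices.
#'
#' @param x Data frame with `protein_id` plus one numeric column per sample
#'   (e.g. a `polarscope_fc` tibble).
#' @param k Number of components to return (default 2); truncated with a
#'   warning if it exceeds the rank of the data.
#' @return Tibble (`sample_id`, `PC1` ... `PCk`) of class `polarscope_pca`;
#'   attributes `explained_variance` (fraction per component,
#'   non-increasing) and `loadings`. `glance()` returns the variance table,
#'   `tidy()` the scores in long form.
#' @examples
#' sim <- simulate_proteome(n_proteins = 40, seed = 2)
#' fc <- log2_fold_change_vs_control(normalize_total_abundance(sim$abundance),
#'                                   sim$design)
#' pca_scores(fc)
#' @export
pca_scores <- function(x, k = 2) {
  samples <- setdiff(names(x), "protein_id")
  if (length(samples) < 2) {
    abort("PCA needs >= 2 samples.", class = "polarscope_bad_argument")
  }
  k <- check_count(k, "k")
  m <- t(as.matrix(x[samples]))  # samples x proteins
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  rank <- sum(p$sdev > max(p$sdev) * 1e-10)
  if (k > rank) {
    warn(sprintf("k = %d exceeds the rank (%d); returning %d component(s).",
                 k, rank, rank))
    k <- rank
  }
  scores <- p$x[, seq_len(k), drop = FALSE]
  loadings <- p$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- p$sdev^2 / sum(p$sdev^2)
  out <- dplyr::bind_cols(tibble(sample_id = samples),
                          as_tibble(as.data.frame(scores)))
  structure(out,
            explained_variance = ev[seq_len(k)],
            loadings = loadings,
            class = c("polarscope_pca", class(tibble())))
}

#' @rdname pca_scores
#' @export
explained_variance <- function(x) attr(x, "explained_variance")

#' @export
glance.polarscope_pca <- function(x, ...) {
  ev <- explained_variance(x)
  tibble(component = paste0("PC", seq_along(ev)),
         explained_variance = ev,
         cumulative = cumsum(ev))
}

#' @export
tidy.polarscope_pca <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"sample_id",
                      names_to = "component", values_to = "score")
}

#' @param object A `polarscope_pca` object.
#' @param design Optional design table; when given, points are coloured by
#'   subtype.
#' @param ... Unused.
#' @rdname pca_scores
#' @export
autoplot.polarscope_pca <- function(object, design = NULL, ...) {
  df <- as_tibble(object)
  ev <- explained_variance(object)
  if (!is.null(design)) {
    df <- dplyr::left_join(df, design[c("sample_id", "subtype")], by = "sample_id")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                          colour = .data$subtype))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ev[min(2, length(ev))]),
                  title = "Sample scores in protein-profile space") +
    ggplot2::theme_minimal()
}
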