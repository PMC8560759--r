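#' Principal component morphospace
#'
#' Centred (not scaled) PCA of the feature matrix, with a deterministic sign
#' convention: on each axis the loading of largest magnitude is made
#' positive.
#'
#' @param x numeric matrix (pips x features), no missing cells.
#' @return List of class `pip_pca`: `scores`, `loadings`, `variance_ratio`,
#'   `center`.
#' @export
pip_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows")
  if (anyNA(x)) stop("missing cells in feature matrix")
  if (all(apply(x, 2, stats::var) < .Machine$double.eps)) {
    stop("constant matrix: no variance to decompose")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_ratio = pc$sdev^2 / sum(pc$sdev^2),
                 center = pc$center),
            class = "pip_pca")
}

#' @export
print.pip_pca <- function(x, ...) {
  cat(sprintf("<pip_pca> %d x %d; PC1+PC2 = %.1f%% of variance\n",
              nrow(x$scores), ncol(x$scores),
              100 * sum(x$variance_ratio[1:min(2, length(x$variance_ratio))])))
  invisible(x)
}

#' Per-cultivar centroids in the PC1-PC2 plane
#'
#' @param pca a [pip_pca()] result (or a score matrix).
#' @param cultivar_ids character vector aligned with the score rows.
#' @return Data frame: cultivar_id, n_pips, PC1, PC2.
#' @export
variety_centroids <- function(pca, cultivar_ids) {
  scores <- if (inherits(pca, "pip_pca")) pca$scores else as.matrix(pca)
  if (length(cultivar_ids) != nrow(scores)) {
    stop("cultivar_ids length (", length(cultivar_ids),
         ") does not match score rows (", nrow(scores), ")")
  }
  s2 <- scores[, 1:2, drop = FALSE]
  agg <- rowsum(s2, cultivar_ids)
  n <- as.vector(table(cultivar_ids)[rownames(agg)])
  data.frame(cultivar_id = rownames(agg), n_pips = n,
             PC1 = agg[, 1] / n, PC2 = agg[, 2] / n,
             row.names = NULL, stringsAsFactors = FALSE)
}
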