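#' Linear discriminant model with pooled covariance and equal priors
#'
#' Gaussian classes with a shared covariance matrix estimated as the pooled
#' within-class scatter divided by (n - k). Priors are equal: the balanced
#' resampling scheme trains on the same number of rows per class, so
#' proportional priors would only re-introduce the imbalance the scheme
#' removes. If the pooled covariance is numerically singular a ridge of
#' 1e-8 * tr(S)/p is added to the diagonal and flagged.
#'
#' @param x numeric matrix (rows x features).
#' @param y class labels; every class needs >= 2 rows and n - k >= 2.
#' @param ridge ridge fraction used when the covariance cannot be inverted.
#' @return List of class `pip_lda`: `means`, `cov_inv`, `labels`, `n_c`,
#'   `ridge_used`.
#' @export
fit_lda <- function(x, y, ridge = 1e-8) {
  x <- as.matrix(x)
  y <- factor(y)
  n <- nrow(x); k <- nlevels(y); p <- ncol(x)
  if (k < 2L) stop("need at least 2 classes")
  n_c <- as.vector(table(y))
  if (any(n_c < 2L)) {
    stop("class with fewer than 2 rows: ",
         paste(levels(y)[n_c < 2L], collapse = ", "))
  }
  if (n - k < 2L) stop("too few rows for pooled covariance")
  means <- rowsum(x, y) / n_c
  S <- crossprod(x - means[y, , drop = FALSE])
  covm <- S / (n - k)
  ridge_used <- FALSE
  ch <- tryCatch(chol(covm), error = function(e) NULL)
  if (is.null(ch) || min(diag(ch)) < sqrt(.Machine$double.eps) * max(diag(ch))) {
    covm <- covm + diag(ridge * sum(diag(covm)) / p, p)
    ch <- chol(covm)
    ridge_used <- TRUE
  }
  structure(list(means = means, cov_inv = chol2inv(ch),
                 labels = levels(y), n_c = n_c, n = n, p = p,
                 ridge_used = ridge_used),
            class = "pip_lda")
}

lda_scores <- function(cov_inv, means, x) {
  # discriminant scores x' W mu_c - mu_c' W mu_c / 2 (equal priors)
  G <- x %*% cov_inv %*% t(means)
  const <- 0.5 * rowSums((means %*% cov_inv) * means)
  sweep(G, 2L, const)
}

softmax_rows <- function(s) {
  s <- s - apply(s, 1L, max)
  e <- exp(s)
  e / rowSums(e)
}

#' Posterior class probabilities under a fitted LDA
#'
#' Softmax of the discriminant scores; each row sums to 1.
#'
#' @param model a [fit_lda()] model.
#' @param x matrix (or vector) of observations on the training feature
#'   schema.
#' @return Matrix (rows x classes) of posterior probabilities.
#' @export
posterior <- function(model, x) {
  stopifnot(inherits(model, "pip_lda"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != model$p) {
    stop("feature dimension mismatch: model has ", model$p, ", data has ",
         ncol(x))
  }
  pr <- softmax_rows(lda_scores(model$cov_inv, model$means, x))
  colnames(pr) <- model$labels
  pr
}

#' Predicted classes under a fitted LDA
#' @param model a [fit_lda()] model.
#' @param x observation matrix.
#' @return Character vector of class labels.
#' @export
predict_lda <- function(model, x) {
  pr <- posterior(model, x)
  model$labels[max.col(pr, ties.method = "first")]
}

#' Leave-one-out cross-validated LDA predictions
#'
#' Each row is classified by the model refitted without it. The refits use
#' exact rank-one downdates of the pooled scatter (Sherman-Morrison), which
#' agree with brute-force refitting to numerical precision.
#'
#' @param x matrix, `y` labels (each class >= 2 rows; >= 3 to stay
#'   classifiable when one of its rows is held out).
#' @param y class labels.
#' @param ridge ridge fraction, as in [fit_lda()].
#' @return List: `class` (LOO predicted label per row), `posterior`
#'   (rows x classes), `ridge_used`.
#' @export
loocv_predict <- function(x, y, ridge = 1e-8) {
  x <- as.matrix(x)
  y <- factor(y)
  n <- nrow(x); k <- nlevels(y); p <- ncol(x)
  n_c <- as.vector(table(y))
  if (any(n_c < 2L)) stop("every class needs >= 2 rows for LOOCV")
  means <- rowsum(x, y) / n_c
  S <- crossprod(x - means[y, , drop = FALSE])
  lam <- 0
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch) || min(diag(ch)) < sqrt(.Machine$double.eps) * max(diag(ch))) {
    lam <- ridge * sum(diag(S)) / p
    S <- S + diag(lam, p)
    ch <- chol(S)
  }
  Sinv <- chol2inv(ch)
  yi <- as.integer(y)
  post <- matrix(NA_real_, n, k, dimnames = list(rownames(x), levels(y)))
  scale_out <- n - 1L - k
  if (scale_out < 1L) stop("too few rows for leave-one-out refits")
  for (i in seq_len(n)) {
    c0 <- yi[i]
    nc <- n_c[c0]
    u <- x[i, ] - means[c0, ]
    alpha <- nc / (nc - 1)
    Su <- Sinv %*% u
    denom <- 1 - alpha * sum(u * Su)
    beta <- alpha / denom
    m2 <- means
    m2[c0, ] <- (nc * means[c0, ] - x[i, ]) / (nc - 1)
    # Sinv' %*% t(m2) via Sherman-Morrison, scaled to the covariance inverse
    P <- Sinv %*% t(m2)
    P <- (P + beta * Su %*% (crossprod(Su, t(m2)))) * scale_out
    sc <- drop(x[i, ] %*% P) - 0.5 * colSums(t(m2) * P)
    sc <- sc - max(sc)
    e <- exp(sc)
    post[i, ] <- e / sum(e)
  }
  list(class = levels(y)[max.col(post, ties.method = "first")],
       posterior = post, ridge_used = lam > 0)
}

#' Per-class LOOCV accuracies
#'
#' @inheritParams loocv_predict
#' @return List: `per_class` (named proportions correct), `overall`,
#'   `predictions`.
#' @export
loocv_accuracies <- function(x, y, ridge = 1e-8) {
  y <- factor(y)
  cv <- loocv_predict(x, y, ridge = ridge)
  correct <- cv$class == as.character(y)
  per_class <- vapply(levels(y), function(l) mean(correct[y == l]), 0)
  list(per_class = per_class, overall = mean(correct), predictions = cv$class)
}

confusion_fraction <- function(truth, pred, labels) {
  tab <- table(factor(truth, labels), factor(pred, labels))
  sw <- rowSums(tab)
  sw[sw == 0] <- 1
  as.matrix(tab / sw)
}

#' Balanced-resampling LDA permutation ensemble
#'
#' Each of `n_perm` permutations draws the minimal group size from every
#' class without replacement, fits an LDA on the balanced subset and records
#' leave-one-out per-class accuracies and the LOO confusion matrix. A
#' shuffled-label null model is fitted on the identical row draw of each
#' permutation, giving the chance-alone accuracy distribution.
#'
#' @param x feature matrix.
#' @param y class labels; rows with NA labels are dropped.
#' @param n_perm number of permutations (default 100).
#' @param seed integer master seed.
#' @param min_per_class smallest admissible minimal group size (default 5).
#' @return List of class `pip_ensemble`: `models` (list of [fit_lda()]
#'   fits), `indices`, `class_acc` (n_perm x k), `null_class_acc`,
#'   `overall_acc`, `null_overall_acc`, `confusions` (k x k x n_perm, row
#'   fractions), `labels`, `m` (rows per class), `seed`.
#' @export
balanced_ensemble <- function(x, y, n_perm = 100L, seed = 1L,
                              min_per_class = 5L) {
  x <- as.matrix(x)
  y <- as.character(y)
  keep <- !is.na(y)
  x <- x[keep, , drop = FALSE]; y <- y[keep]
  y <- factor(y)
  k <- nlevels(y)
  if (k < 2L) stop("need at least 2 classes")
  m <- min(table(y))
  if (m < min_per_class) {
    stop("minimal group size ", m, " is below ", min_per_class)
  }
  rows_by_class <- split(seq_along(y), y)
  set.seed(seed)
  labels <- levels(y)
  class_acc <- null_class_acc <- matrix(NA_real_, n_perm, k,
                                        dimnames = list(NULL, labels))
  overall <- null_overall <- numeric(n_perm)
  confusions <- array(NA_real_, c(k, k, n_perm),
                      dimnames = list(labels, labels, NULL))
  models <- indices <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    idx <- unlist(lapply(rows_by_class, sample, size = m), use.names = FALSE)
    yb <- y[idx]
    xb <- x[idx, , drop = FALSE]
    models[[b]] <- fit_lda(xb, yb)
    indices[[b]] <- idx
    acc <- loocv_accuracies(xb, yb)
    class_acc[b, ] <- acc$per_class[labels]
    overall[b] <- acc$overall
    confusions[, , b] <- confusion_fraction(yb, acc$predictions, labels)
    ynull <- sample(as.character(yb))
    accn <- loocv_accuracies(xb, ynull)
    null_class_acc[b, ] <- accn$per_class[labels]
    null_overall[b] <- accn$overall
  }
  structure(list(models = models, indices = indices,
                 class_acc = class_acc, null_class_acc = null_class_acc,
                 overall_acc = overall, null_overall_acc = null_overall,
                 confusions = confusions, labels = labels, m = m,
                 n_perm = n_perm, seed = seed),
            class = "pip_ensemble")
}

#' @export
print.pip_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<pip_ensemble> %d classes x %d permutations, %d rows",
                     "/class\n  median class accuracy: %s\n"),
              length(x$labels), x$n_perm, x$m,
              paste(x$labels,
                    sprintf("%.0f%%", 100 * apply(x$class_acc, 2, stats::median)),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Cross-validated accuracy of a tree node split
#'
#' Classes in `node_leaves` are relabelled "node", the rest "rest", and a
#' balanced two-class ensemble is run; the median overall LOOCV accuracy is
#' returned. Structureless data yields ~50%.
#'
#' @param x feature matrix; `y` class labels per row.
#' @param y class labels.
#' @param node_leaves labels forming one side of the split.
#' @param n_perm,seed,min_per_class as in [balanced_ensemble()].
#' @return Median overall accuracy (scalar, in \[0, 1\]).
#' @export
node_accuracy <- function(x, y, node_leaves, n_perm = 100L, seed = 1L,
                          min_per_class = 5L) {
  y <- as.character(y)
  present <- unique(stats::na.omit(y))
  if (!length(intersect(node_leaves, present)) ||
      !length(setdiff(present, node_leaves))) {
    stop("node split leaves one side empty")
  }
  ybin <- ifelse(is.na(y), NA, ifelse(y %in% node_leaves, "node", "rest"))
  ens <- balanced_ensemble(x, ybin, n_perm = n_perm, seed = seed,
                           min_per_class = min_per_class)
  stats::median(ens$overall_acc)
}

#' Median confusion matrix and significance against the null
#'
#' Cells are per-permutation row percentages, summarised by their median and
#' renormalised so every row sums to 100. The per-class significance flag is
#' TRUE when the median LOOCV class accuracy exceeds the maximum class
#' accuracy observed among the shuffled-label null permutations.
#'
#' @param ensemble a [balanced_ensemble()].
#' @return List of class `confusion_summary`: `matrix` (k x k, percent),
#'   `class_accuracy` (median, percent), `null_max` (percent),
#'   `significant` (logical per class).
#' @export
confusion_summary <- function(ensemble) {
  stopifnot(inherits(ensemble, "pip_ensemble"))
  med <- apply(ensemble$confusions, c(1, 2), stats::median) * 100
  rs <- rowSums(med)
  rs[rs == 0] <- 1
  med <- med / rs * 100
  structure(list(
    matrix = med,
    class_accuracy = 100 * apply(ensemble$class_acc, 2, stats::median),
    null_max = 100 * apply(ensemble$null_class_acc, 2, max),
    significant = apply(ensemble$class_acc, 2, stats::median) >
      apply(ensemble$null_class_acc, 2, max)),
    class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("<confusion_summary> median row %, * = above null max\n")
  m <- round(x$matrix, 1)
  rownames(m) <- paste0(rownames(m), ifelse(x$significant, " *", ""))
  print(m)
  invisible(x)
}

#' Standard cofactor model definitions
#'
#' Returns, for each named model, the metadata column providing the class
#' label and the row filter applied before training. `use` drops mixed-use
#' cultivars; `geo_use` crosses core-region geography with use; genetic
#' models use the SNP/SSR group columns (NA labels are dropped by the
#' ensemble); `ssr4` is the SSR grouping without its smallest
#' Italian/Central-European table class; `status` separates wild from
#' domesticated material.
#'
#' @return Named list; each element has `column`(s) and `drop` (function of
#'   the metadata data frame returning labels).
#' @export
cofactor_models <- function() {
  list(
    use = function(meta) ifelse(meta$use %in% c("wine", "table"),
                                meta$use, NA),
    geo = function(meta) meta$geo_group,
    geo_use = function(meta) ifelse(
      meta$use %in% c("wine", "table") & !is.na(meta$geo_group),
      paste(meta$geo_group, meta$use, sep = "_"), NA),
    snp4 = function(meta) meta$snp4,
    ssr5 = function(meta) meta$ssr5,
    ssr4 = function(meta) ifelse(meta$ssr5 %in% "ITACE_Table", NA, meta$ssr5),
    status = function(meta) meta$status
  )
}
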