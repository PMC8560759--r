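#' Standardised per-level mean feature matrix
#'
#' Averages the feature matrix within each cofactor level, then standardises
#' every column to zero mean and unit variance across levels (so raw pip
#' length in mm cannot dominate the subsequent correlation distance).
#'
#' @param x numeric feature matrix (pips x features).
#' @param labels cofactor level per row; NA rows are dropped.
#' @return Matrix (levels x features) with attribute `n_per_level`.
#' @export
group_mean_matrix <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  keep <- !is.na(labels)
  x <- x[keep, , drop = FALSE]
  labels <- labels[keep]
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least 2 cofactor levels")
  if (any(tab == 0L)) stop("level with zero pips")
  m <- rowsum(x, labels) / as.vector(tab[sort(unique(labels))])
  m <- m[order(rownames(m)), , drop = FALSE]
  m <- scale(m)
  if (any(!is.finite(m))) stop("constant feature column across levels")
  attr(m, "n_per_level") <- as.vector(tab[rownames(m)])
  m
}

#' Correlation distance between matrix rows
#'
#' d(u, v) = 1 - Pearson correlation of the rows; in \[0, 2\].
#'
#' @param x numeric matrix, >= 2 rows.
#' @return A symmetric zero-diagonal distance matrix.
#' @export
correlation_distance <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) stop("zero-variance row: correlation undefined")
  d <- 1 - stats::cor(t(x))
  diag(d) <- 0
  d
}

#' UPGMA (average-linkage) clustering
#'
#' Rows are ordered lexicographically by label before clustering so that
#' distance ties break deterministically. Node heights follow the
#' ultrametric depth convention (merge distance / 2), so two leaves joined
#' at average distance d sit at depth d/2 and their cophenetic tip-to-tip
#' distance is d.
#'
#' @param d symmetric distance matrix with row/column names, or a `dist`.
#' @return An `hclust` object.
#' @export
upgma <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
      stop("distance matrix must be symmetric")
    }
    if (is.null(rownames(d))) rownames(d) <- colnames(d) <- seq_len(nrow(d))
    o <- order(rownames(d))
    d <- stats::as.dist(d[o, o])
  }
  hc <- stats::hclust(d, method = "average")
  hc$height <- hc$height / 2
  hc
}

## Leaf label sets of every internal node of an hclust tree, in merge order.
hclust_leaf_sets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    leaves <- character(0)
    for (k in kids) {
      leaves <- c(leaves, if (k < 0) hc$labels[-k] else sets[[k]])
    }
    sets[[i]] <- sort(leaves)
  }
  sets
}

## Probit-scale WLS fit of the multiscale bootstrap probabilities of one
## node: z_r = qnorm(1 - BP_r) ~ v sqrt(r) + c / sqrt(r), weights
## B phi(z_r)^2 / (BP_r (1 - BP_r)); AU = 1 - pnorm(v - c). Scales where BP
## is exactly 0 or 1 carry no probit information and are excluded from the
## fit (standard multiscale-bootstrap practice); the remaining values are
## clamped to [1/(2B), 1 - 1/(2B)]. Returns au = NA when fewer than two
## scales are usable (callers fall back to the clamped BP).
au_from_bp <- function(bp, r_grid, B) {
  lo <- 1 / (2 * B)
  usable <- bp > 0 & bp < 1
  bpc <- pmin(pmax(bp, lo), 1 - lo)
  z <- stats::qnorm(1 - bpc)
  w <- B * stats::dnorm(z)^2 / (bpc * (1 - bpc))
  ok <- usable & is.finite(z) & is.finite(w) & w > 0
  if (sum(ok) < 2L) {
    return(list(au = NA_real_, v = NA_real_, c = NA_real_,
                n_scales = sum(ok)))
  }
  X <- cbind(sqrt(r_grid[ok]), 1 / sqrt(r_grid[ok]))
  fit <- stats::lm.wfit(X, z[ok], w[ok])
  vc <- unname(fit$coefficients)
  list(au = 1 - stats::pnorm(vc[1] - vc[2]), v = vc[1], c = vc[2],
       n_scales = sum(ok))
}

#' Multiscale bootstrap AU node support
#'
#' For each resampling proportion r in the grid, feature columns of the
#' level-mean matrix are resampled with replacement to round(p * r) columns,
#' the tree is rebuilt (correlation distance + UPGMA), and the per-node
#' bootstrap probability BP_r is the fraction of replicates containing the
#' node's leaf set. Probit-transformed values z_r = qnorm(1 - BP_r) are
#' fitted by weighted least squares to z(r) = v * sqrt(r) + c / sqrt(r) with
#' weights B * dnorm(z_r)^2 / (BP_r (1 - BP_r)); the approximately unbiased
#' p-value is AU = 1 - pnorm(v - c). BP at r = 1 is reported alongside.
#' Scales where BP is exactly 0 or 1 carry no probit information and are
#' excluded; remaining values are clamped to \[1/(2B), 1 - 1/(2B)\]. Nodes
#' with fewer than two usable scales (e.g. recovered in every replicate at
#' every scale) take the clamped BP as their AU value.
#'
#' @param x standardised level-mean matrix ([group_mean_matrix()]).
#' @param tree observed `hclust` tree of `x` (rebuilt if NULL).
#' @param r_grid resampling proportions (default 0.5 to 1.4 by 0.1).
#' @param B bootstrap replicates per proportion (default 100).
#' @param seed integer seed.
#' @param unit `"features"` resamples the feature columns (default);
#'   `"pips"` resamples rows of the optional per-pip data before averaging
#'   (requires `pip_features` and `pip_labels`).
#' @param pip_features,pip_labels per-pip matrix and level labels, only for
#'   `unit = "pips"`.
#' @return List of class `node_support_tree`: `tree` (hclust), `nodes` (data
#'   frame: node, leaves, au, bp, n_scales), `r_grid`, `B`, `bp_table`.
#' @export
multiscale_bootstrap_au <- function(x, tree = NULL,
                                    r_grid = seq(0.5, 1.4, by = 0.1),
                                    B = 100L, seed = 1L,
                                    unit = c("features", "pips"),
                                    pip_features = NULL, pip_labels = NULL) {
  unit <- match.arg(unit)
  x <- as.matrix(x)
  if (nrow(x) < 4L) stop("need at least 4 leaves for node support")
  if (length(r_grid) < 2L) stop("need at least 2 resampling proportions")
  if (any(r_grid <= 0)) stop("resampling proportions must be positive")
  B <- as.integer(B)
  if (B < 10L) stop("B must be >= 10")
  if (is.null(tree)) tree <- upgma(correlation_distance(x))
  obs_sets <- hclust_leaf_sets(tree)
  keys <- vapply(obs_sets, paste, "", collapse = "\r")
  p <- ncol(x)
  set.seed(seed)
  bp <- matrix(0, length(obs_sets), length(r_grid),
               dimnames = list(NULL, paste0("r", r_grid)))
  for (ri in seq_along(r_grid)) {
    m <- max(2L, round(p * r_grid[ri]))
    hits <- numeric(length(obs_sets))
    for (b in seq_len(B)) {
      if (unit == "features") {
        cols <- sample.int(p, m, replace = TRUE)
        xb <- x[, cols, drop = FALSE]
      } else {
        if (is.null(pip_features) || is.null(pip_labels)) {
          stop("unit = 'pips' needs `pip_features` and `pip_labels`")
        }
        rows <- sample.int(nrow(pip_features),
                           max(2L, round(nrow(pip_features) * r_grid[ri])),
                           replace = TRUE)
        xb <- tryCatch(group_mean_matrix(pip_features[rows, , drop = FALSE],
                                         pip_labels[rows]),
                       error = function(e) NULL)
        if (is.null(xb) || nrow(xb) != nrow(x)) next
      }
      hb <- tryCatch(upgma(correlation_distance(xb)),
                     error = function(e) NULL)
      if (is.null(hb)) next
      bkeys <- vapply(hclust_leaf_sets(hb), paste, "", collapse = "\r")
      hits <- hits + (keys %in% bkeys)
    }
    bp[, ri] <- hits / B
  }
  nodes <- data.frame(node = seq_along(obs_sets),
                      leaves = vapply(obs_sets, paste, "", collapse = ","),
                      au = NA_real_, bp = bp[, which.min(abs(r_grid - 1))],
                      n_scales = NA_integer_, stringsAsFactors = FALSE)
  lo <- 1 / (2 * B)
  for (i in seq_along(obs_sets)) {
    fit <- au_from_bp(bp[i, ], r_grid, B)
    nodes$n_scales[i] <- fit$n_scales
    if (is.na(fit$au)) {
      # degenerate scale curve (e.g. node recovered in every replicate):
      # AU falls back to the clamped BP at r = 1
      nodes$au[i] <- min(max(nodes$bp[i], lo), 1 - lo)
    } else {
      nodes$au[i] <- fit$au
    }
  }
  structure(list(tree = tree, nodes = nodes, r_grid = r_grid, B = B,
                 bp_table = bp, seed = seed, unit = unit),
            class = "node_support_tree")
}

#' @export
print.node_support_tree <- function(x, ...) {
  cat(sprintf("<node_support_tree> %d leaves, %d nodes, B=%d per scale\n",
              length(x$tree$labels), nrow(x$nodes), x$B))
  print(x$nodes[, c("node", "leaves", "au", "bp",
                    intersect("cv_accuracy", names(x$nodes)))], digits = 3)
  invisible(x)
}

#' Export an annotated tree to newick
#'
#' Internal nodes are labelled "AU|BP|cv" (percent-scaled, 1 decimal;
#' missing fields left empty); branch lengths come from the UPGMA merge
#' heights. The file round-trips through [ape::read.tree()].
#'
#' @param support a `node_support_tree` (optionally carrying per-node
#'   `cv_accuracy` from the classifier).
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
export_newick <- function(support, path) {
  stopifnot(inherits(support, "node_support_tree"))
  phy <- ape::as.phylo(support$tree)
  # as.phylo.hclust assumes merge-distance heights and halves them; our
  # heights are already ultrametric depths, so restore them
  phy$edge.length <- phy$edge.length * 2
  sets <- hclust_leaf_sets(support$tree)
  keys <- vapply(sets, paste, "", collapse = "\r")
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.1f", 100 * v))
  cv <- if ("cv_accuracy" %in% names(support$nodes)) {
    support$nodes$cv_accuracy
  } else rep(NA_real_, nrow(support$nodes))
  lab <- paste(fmt(support$nodes$au), fmt(support$nodes$bp), fmt(cv),
               sep = "|")
  # map hclust nodes -> phylo internal nodes by leaf set
  ntip <- length(phy$tip.label)
  phy_sets <- vector("list", phy$Nnode)
  order_nodes <- rev(ape::postorder(phy))
  get_leaves <- function(node) {
    if (node <= ntip) return(phy$tip.label[node])
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    sort(unlist(lapply(kids, get_leaves)))
  }
  phy$node.label <- vapply(seq_len(phy$Nnode) + ntip, function(nd) {
    key <- paste(get_leaves(nd), collapse = "\r")
    i <- match(key, keys)
    if (is.na(i)) "" else lab[i]
  }, character(1))
  ape::write.tree(phy, file = path)
  invisible(path)
}
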