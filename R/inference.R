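#' Classify new pips with a balanced ensemble
#'
#' Every model of the ensemble votes on every pip; the final label is the
#' plurality vote ("majority rule"). Ties are broken by the higher median
#' posterior probability, then lexicographically (tied pips are recorded in
#' the `ties` attribute). The median posterior per class is the median, over
#' the ensemble's models, of that class's posterior probability.
#'
#' @param ensemble a [balanced_ensemble()].
#' @param x_new matrix of new pips on the training feature schema.
#' @return Data frame of class `pip_classification`: pip_id, final label,
#'   vote count and fraction of the winning class, median posterior of the
#'   winning class, plus per-class vote counts and median posteriors as
#'   attribute matrices `votes` and `median_posterior`.
#' @export
classify_pips <- function(ensemble, x_new) {
  stopifnot(inherits(ensemble, "pip_ensemble"))
  x_new <- as.matrix(x_new)
  n <- nrow(x_new)
  k <- length(ensemble$labels)
  votes <- matrix(0L, n, k, dimnames = list(rownames(x_new), ensemble$labels))
  post <- array(NA_real_, c(n, k, ensemble$n_perm))
  for (b in seq_len(ensemble$n_perm)) {
    pr <- posterior(ensemble$models[[b]], x_new)
    post[, , b] <- pr
    w <- max.col(pr, ties.method = "first")
    votes[cbind(seq_len(n), w)] <- votes[cbind(seq_len(n), w)] + 1L
  }
  medpost <- apply(post, c(1, 2), stats::median)
  dimnames(medpost) <- dimnames(votes)
  final <- character(n)
  tied <- logical(n)
  for (i in seq_len(n)) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1L) {
      tied[i] <- TRUE
      best <- top[medpost[i, top] == max(medpost[i, top])]
      top <- best[order(ensemble$labels[best])][1]
    }
    final[i] <- ensemble$labels[top]
  }
  if (any(tied)) {
    message(sum(tied), " pip(s) had tied plurality votes; ties broken by ",
            "median posterior then label order")
  }
  wi <- match(final, ensemble$labels)
  out <- data.frame(
    pip_id = if (is.null(rownames(x_new))) as.character(seq_len(n))
             else rownames(x_new),
    label = final,
    votes = votes[cbind(seq_len(n), wi)],
    vote_fraction = votes[cbind(seq_len(n), wi)] / ensemble$n_perm,
    median_posterior = medpost[cbind(seq_len(n), wi)],
    tied = tied,
    stringsAsFactors = FALSE)
  attr(out, "votes") <- votes
  attr(out, "median_posterior") <- medpost
  class(out) <- c("pip_classification", "data.frame")
  out
}

filter_stat <- function(cls, type) {
  switch(type,
         posterior = cls$median_posterior,
         vote = cls$vote_fraction,
         stop("unknown filter type: ", type))
}

filter_curve <- function(ensemble, x_eval, y_eval, cutoffs, type) {
  y_eval <- as.character(y_eval)
  keep <- !is.na(y_eval)
  x_eval <- as.matrix(x_eval)[keep, , drop = FALSE]
  y_eval <- y_eval[keep]
  cls <- classify_pips(ensemble, x_eval)
  stat <- filter_stat(cls, type)
  classes <- ensemble$labels
  rows <- list()
  for (cut in cutoffs) {
    kept <- stat >= cut
    overall_acc <- if (any(kept)) mean(cls$label[kept] == y_eval[kept]) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      cutoff = cut, class = "overall",
      accuracy = overall_acc, retention = mean(kept),
      n_retained = sum(kept), stringsAsFactors = FALSE)
    for (cl in classes) {
      inc <- y_eval == cl
      keptc <- kept & inc
      rows[[length(rows) + 1L]] <- data.frame(
        cutoff = cut, class = cl,
        accuracy = if (any(keptc)) mean(cls$label[keptc] == cl) else NA_real_,
        retention = if (any(inc)) mean(kept[inc]) else NA_real_,
        n_retained = sum(keptc), stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), type = type,
            class = c("filter_curve", "data.frame"))
}

#' Posterior-probability filtering curve
#'
#' At each cut-off, pips whose winning-class median posterior is below the
#' cut-off are filtered out; the curve reports the accuracy among retained
#' pips and the proportion of the original sample retained, overall and per
#' true class. Retention is 1 at cut-off 0 and nonincreasing.
#'
#' @param ensemble a [balanced_ensemble()].
#' @param x_eval,y_eval labelled evaluation pips.
#' @param cutoffs cut-off grid in \[0, 1\].
#' @return Data frame of class `filter_curve`: cutoff, class, accuracy,
#'   retention, n_retained. Accuracy is NA where nothing is retained.
#' @export
posterior_filter_curve <- function(ensemble, x_eval, y_eval,
                                   cutoffs = seq(0, 1, by = 0.05)) {
  filter_curve(ensemble, x_eval, y_eval, cutoffs, "posterior")
}

#' Vote-proportion filtering curve
#'
#' As [posterior_filter_curve()], with the winning class's vote fraction
#' across the ensemble's models as the filtering statistic. A cut-off of 0.5
#' retains exactly the pips attributed to their winning class at least 50%
#' of the time.
#'
#' @inheritParams posterior_filter_curve
#' @export
vote_filter_curve <- function(ensemble, x_eval, y_eval,
                              cutoffs = seq(0, 1, by = 0.05)) {
  filter_curve(ensemble, x_eval, y_eval, cutoffs, "vote")
}

#' Two-stage inference on an archaeological assemblage
#'
#' Stage 1 applies the wild/domesticated status ensemble by majority rule
#' and discards pips labelled wild. Stage 2 applies every cofactor ensemble
#' to the survivors and reports class proportions under three filtering
#' schemes: none, median posterior >= 0.8, and vote fraction >= 0.5
#' (inclusive). The mean length of domesticated-type pips is reported per
#' phase.
#'
#' @param status_ensemble two-class [balanced_ensemble()] whose labels
#'   include "wild"; the other label is treated as domesticated.
#' @param cofactor_ensembles named list of [balanced_ensemble()]s.
#' @param phases named list; each element needs `x` (feature matrix) and
#'   optionally `lengths_mm` (named by pip).
#' @param posterior_cutoff,vote_cutoff filtering thresholds.
#' @return List of class `archaeo_report`: per phase, `n_input`, `n_wild`,
#'   `wild_fraction`, `n_domesticated`, `mean_length_mm`, and `proportions`
#'   (data frame: model, scheme, class, n, proportion).
#' @export
archaeo_inference <- function(status_ensemble, cofactor_ensembles, phases,
                              posterior_cutoff = 0.8, vote_cutoff = 0.5) {
  stopifnot(inherits(status_ensemble, "pip_ensemble"),
            "wild" %in% status_ensemble$labels)
  report <- list()
  for (ph in names(phases)) {
    x <- as.matrix(phases[[ph]]$x)
    st <- classify_pips(status_ensemble, x)
    wild <- st$label == "wild"
    surv <- which(!wild)
    lens <- phases[[ph]]$lengths_mm
    entry <- list(n_input = nrow(x), n_wild = sum(wild),
                  wild_fraction = mean(wild),
                  n_domesticated = length(surv),
                  mean_length_mm = if (!is.null(lens) && length(surv))
                    mean(lens[st$pip_id[surv]]) else NA_real_)
    props <- list()
    if (length(surv) == 0L) {
      message("phase ", ph, ": no domesticated survivors; stage 2 skipped")
      entry$proportions <- data.frame()
    } else {
      xs <- x[surv, , drop = FALSE]
      for (mod in names(cofactor_ensembles)) {
        cls <- classify_pips(cofactor_ensembles[[mod]], xs)
        schemes <- list(
          none = rep(TRUE, nrow(cls)),
          posterior_0.8 = cls$median_posterior >= posterior_cutoff,
          vote_0.5 = cls$vote_fraction >= vote_cutoff)
        for (sch in names(schemes)) {
          kept <- cls$label[schemes[[sch]]]
          tab <- table(factor(kept, cofactor_ensembles[[mod]]$labels))
          props[[length(props) + 1L]] <- data.frame(
            phase = ph, model = mod, scheme = sch,
            class = names(tab), n = as.vector(tab),
            proportion = if (length(kept)) as.vector(tab) / length(kept)
                         else NA_real_,
            n_retained = length(kept), stringsAsFactors = FALSE)
        }
      }
      entry$proportions <- do.call(rbind, props)
    }
    report[[ph]] <- entry
  }
  structure(report, class = "archaeo_report")
}

#' @export
print.archaeo_report <- function(x, ...) {
  for (ph in names(x)) {
    e <- x[[ph]]
    cat(sprintf("phase %s: %d pips, %d (%.0f%%) wild type, %d domesticated",
                ph, e$n_input, e$n_wild, 100 * e$wild_fraction,
                e$n_domesticated))
    if (!is.na(e$mean_length_mm)) {
      cat(sprintf(", mean length %.2f mm", e$mean_length_mm))
    }
    cat("\n")
  }
  invisible(x)
}

#' One-tailed Wilcoxon rank test that y exceeds x
#'
#' Rank-sum (Mann-Whitney) test of the alternative that values in `y` are
#' stochastically greater than those in `x`, with midranks for ties. The
#' p-value is exact for combined sample sizes up to 12 without ties, and
#' uses the normal approximation with continuity correction otherwise.
#'
#' @param x,y numeric vectors (e.g. pip lengths of two berry size classes).
#' @return List of class `wilcoxon_result`: `W` (rank-sum statistic of `y`
#'   vs `x`), `p_value` (one-sided), `n_x`, `n_y`, `exact`.
#' @export
wilcoxon_one_tail <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("empty group")
  use_exact <- (length(x) + length(y)) <= 12 && !anyDuplicated(c(x, y))
  ht <- stats::wilcox.test(y, x, alternative = "greater",
                           exact = use_exact, correct = TRUE)
  structure(list(W = unname(ht$statistic), p_value = ht$p.value,
                 n_x = length(x), n_y = length(y), exact = use_exact),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon rank test (one-tail, y > x): W = %g, P = %.3g%s\n",
              x$W, x$p_value, if (x$exact) " (exact)" else ""))
  invisible(x)
}

#' Infer a berry size class from mean pip length
#'
#' Nearest size class by absolute distance between the assemblage's mean
#' domesticated pip length and the median pip length of each reference size
#' class.
#'
#' @param mean_length_mm mean pip length of the assemblage (mm).
#' @param reference_lengths named list of numeric vectors (reference pip
#'   lengths per size class) or a named vector of class median lengths.
#' @return List: `size_class`, `distance_profile` (named, mm).
#' @export
infer_berry_size <- function(mean_length_mm, reference_lengths) {
  if (!length(reference_lengths)) stop("empty reference")
  meds <- if (is.list(reference_lengths)) {
    vapply(reference_lengths, stats::median, 0)
  } else reference_lengths
  prof <- abs(mean_length_mm - meds)
  list(size_class = names(prof)[which.min(prof)], distance_profile = prof)
}
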