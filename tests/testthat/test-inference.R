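# a small well-separated two-class ensemble reused across tests
toy_ensemble <- function() {
  memo("toy_ensemble", {
    set.seed(20)
    x <- rbind(matrix(rnorm(120, 0, 0.5), 60), matrix(rnorm(120, 4, 0.5), 60))
    colnames(x) <- c("f1", "f2")
    y <- rep(c("left", "right"), each = 60)
    list(x = x, y = y,
         ens = balanced_ensemble(x, y, n_perm = 40, seed = 21))
  })
}

# overlapping three-class data where filtering genuinely trades sample size
# for accuracy
overlap_ensemble <- function() {
  memo("overlap_ensemble", {
    set.seed(22)
    mu <- rbind(c(0, 0), c(1.6, 0), c(0.8, 1.4))
    x <- do.call(rbind, lapply(1:3, function(c) {
      sweep(matrix(rnorm(80 * 2), 80, 2), 2, mu[c, ], "+")
    }))
    colnames(x) <- c("f1", "f2")
    y <- rep(c("a", "b", "c"), each = 80)
    list(x = x, y = y,
         ens = balanced_ensemble(x, y, n_perm = 40, seed = 23))
  })
}

test_that("majority-rule classification votes, ties and posteriors are
           coherent", {
  toy <- toy_ensemble()
  cls <- classify_pips(toy$ens, rbind(`at_left` = c(0, 0),
                                      `at_right` = c(4, 4)))
  expect_identical(cls$label, c("left", "right"))
  expect_identical(cls$votes, c(40L, 40L))        # unanimous at archetypes
  expect_gt(min(cls$median_posterior), 0.99)

  # votes sum to n_perm and the final label is the argmax of the votes
  cls2 <- classify_pips(toy$ens, matrix(rnorm(100, 2, 2), 50, 2))
  v <- attr(cls2, "votes")
  expect_true(all(rowSums(v) == toy$ens$n_perm))
  untied <- !cls2$tied
  expect_identical(cls2$label[untied],
                   colnames(v)[max.col(v[untied, ], "first")])
  expect_true(all(attr(cls2, "median_posterior") >= 0 &
                    attr(cls2, "median_posterior") <= 1))
})

test_that("filter curves retain everything at cut-off 0, shrink as the
           cut-off rises, and die above the largest statistic", {
  ov <- overlap_ensemble()
  for (curve_fun in list(posterior_filter_curve, vote_filter_curve)) {
    fc <- curve_fun(ov$ens, ov$x, ov$y, cutoffs = seq(0, 1, by = 0.1))
    overall <- fc[fc$class == "overall", ]
    expect_equal(overall$retention[overall$cutoff == 0], 1)
    expect_true(all(diff(overall$retention) <= 1e-12))
    expect_true(all(diff(overall$n_retained) <= 0L))
    # per-class retention is monotone too
    for (cl in c("a", "b", "c")) {
      expect_true(all(diff(fc$retention[fc$class == cl]) <= 1e-12))
    }
  }
  # cut-off above the maximum observed statistic: nothing retained
  cls <- classify_pips(ov$ens, ov$x)
  hi <- max(cls$median_posterior)
  fc2 <- posterior_filter_curve(ov$ens, ov$x, ov$y,
                                cutoffs = c(0, min(1, hi + 1e-6)))
  top <- fc2[fc2$class == "overall" & fc2$cutoff > hi, ]
  if (nrow(top)) {
    expect_identical(top$n_retained, 0L)
    expect_true(is.na(top$accuracy))
  }
  # filtering trades sample for accuracy on overlapping classes
  fo <- posterior_filter_curve(ov$ens, ov$x, ov$y, cutoffs = c(0, 0.8))
  o0 <- fo[fo$class == "overall" & fo$cutoff == 0, ]
  o8 <- fo[fo$class == "overall" & fo$cutoff == 0.8, ]
  expect_gt(o8$accuracy, o0$accuracy)
  expect_lt(o8$retention, o0$retention)
  # vote cut-off 0.5 retains exactly the pips with >= 50% plurality votes
  vc <- vote_filter_curve(ov$ens, ov$x, ov$y, cutoffs = 0.5)
  cls_all <- classify_pips(ov$ens, ov$x)
  expect_identical(vc$n_retained[vc$class == "overall"],
                   sum(cls_all$vote_fraction >= 0.5))
})

test_that("one-tailed Wilcoxon matches exact enumeration and behaves under
           symmetry", {
  w <- wilcoxon_one_tail(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_value, 1 / 20)       # 1 of choose(6,3) orderings
  expect_equal(w$W, 9)                  # Mann-Whitney U = n1*n2
  expect_true(w$exact)

  set.seed(30)
  v <- rnorm(30)
  ws <- wilcoxon_one_tail(v, v + 1e-12)
  expect_gt(ws$p_value, 0.4)
  expect_lt(ws$p_value, 0.6)

  # generated size classes separate at the configured shifts
  fx <- small_reference()
  meta <- fx$ref$metadata; pips <- fx$ref$pips
  size <- meta$berry_size[match(pips$cultivar_id, meta$cultivar_id)]
  lens <- split(pips$length_mm, size)
  expect_lt(wilcoxon_one_tail(lens$small, lens$medium)$p_value, 1e-3)
  expect_lt(wilcoxon_one_tail(lens$small, lens$large)$p_value, 1e-3)
  expect_error(wilcoxon_one_tail(numeric(0), 1:3), "empty")
})

test_that("berry size inference picks the nearest reference class", {
  ref <- list(small = c(4.8, 5.0, 5.2), medium = c(5.8, 6.0, 6.2),
              large = c(6.8, 7.0, 7.2))
  expect_identical(infer_berry_size(6.0, ref)$size_class, "medium")
  expect_identical(infer_berry_size(8.5, ref)$size_class, "large")
  prof <- infer_berry_size(5.1, ref)$distance_profile
  expect_identical(names(which.min(prof)), "small")
  expect_error(infer_berry_size(5, list()), "empty")
})

test_that("two-stage archaeological inference conserves pips and respects
           the filtering schemes", {
  toy <- toy_ensemble()
  ov <- overlap_ensemble()
  set.seed(40)
  xnew <- rbind(matrix(rnorm(60, 0, 0.5), 30), matrix(rnorm(40, 4, 0.5), 20))
  colnames(xnew) <- c("f1", "f2")
  rownames(xnew) <- paste0("p", 1:50)
  status <- balanced_ensemble(
    rbind(toy$x), ifelse(toy$y == "left", "wild", "domesticated"),
    n_perm = 20, seed = 41)
  lens <- setNames(runif(50, 5, 7), rownames(xnew))
  rep1 <- archaeo_inference(status, list(shape = ov$ens),
                            list(ph = list(x = xnew, lengths_mm = lens)))
  e <- rep1$ph
  expect_identical(e$n_input, 50L)
  expect_identical(e$n_wild + e$n_domesticated, 50L)
  pr <- e$proportions
  for (sch in unique(pr$scheme)) {
    sub <- pr[pr$scheme == sch, ]
    if (sub$n_retained[1] > 0) {
      expect_equal(sum(sub$proportion), 1, tolerance = 1e-12)
      expect_identical(sum(sub$n), sub$n_retained[1])
    }
  }
  # posterior-filtered retention cannot exceed the unfiltered count
  expect_lte(pr$n_retained[pr$scheme == "posterior_0.8"][1],
             pr$n_retained[pr$scheme == "none"][1])

  # an all-wild assemblage leaves stage 2 empty
  allwild <- matrix(rnorm(40, 0, 0.5), 20, 2,
                    dimnames = list(paste0("w", 1:20), c("f1", "f2")))
  expect_message(
    rep0 <- archaeo_inference(status, list(shape = ov$ens),
                              list(ph = list(x = allwild))),
    "skipped")
  expect_identical(rep0$ph$n_domesticated, 0L)
  expect_identical(nrow(rep0$ph$proportions), 0L)
})
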