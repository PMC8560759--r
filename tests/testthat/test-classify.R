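test_that("LDA boundary, posteriors and degeneracies behave as Gaussian
           discriminant theory predicts", {
  set.seed(1)
  x <- matrix(c(rnorm(60, 0), rnorm(60, 10)), ncol = 1)
  y <- rep(c("lo", "hi"), each = 60)
  f <- fit_lda(x, y)
  # posterior is exactly 1/2 at the midpoint of the class means
  mid <- mean(f$means)
  pmid <- posterior(f, mid)
  expect_equal(unname(pmid[1, "lo"]), 0.5, tolerance = 1e-9)
  expect_identical(predict_lda(f, matrix(c(-1, 11), ncol = 1)),
                   c("lo", "hi"))
  expect_equal(rowSums(posterior(f, x)), rep(1, 120), tolerance = 1e-12)

  # duplicated feature column: ridge path taken, predictions still defined
  xd <- cbind(x, x)
  fd <- fit_lda(xd, y)
  expect_true(fd$ridge_used)
  expect_identical(predict_lda(fd, cbind(c(-1, 11), c(-1, 11))),
                   c("lo", "hi"))

  expect_error(fit_lda(x[1:3, , drop = FALSE], c("a", "a", "b")),
               "fewer than 2")
  expect_error(posterior(f, matrix(0, 1, 3)), "mismatch")
})

test_that("posteriors match the brute-force Gaussian density-ratio oracle
           and MASS::lda", {
  set.seed(2)
  mu <- rbind(c(0, 0), c(3, 1), c(1, 4))
  x <- do.call(rbind, lapply(1:3, function(c) {
    sweep(matrix(rnorm(40 * 2), 40, 2), 2, mu[c, ], "+")
  }))
  y <- rep(c("a", "b", "c"), each = 40)
  f <- fit_lda(x, y)
  xe <- matrix(rnorm(20, 1, 2), 10, 2)
  p <- posterior(f, xe)
  # oracle: explicit shared-covariance Gaussian densities
  Sg <- Reduce(`+`, lapply(split(as.data.frame(x), y), function(d) {
    crossprod(scale(as.matrix(d), scale = FALSE))
  })) / (120 - 3)
  Si <- solve(Sg)
  mh <- rowsum(x, y) / 40
  dens <- sapply(1:3, function(c) {
    apply(xe, 1, function(v) {
      exp(-0.5 * drop(t(v - mh[c, ]) %*% Si %*% (v - mh[c, ])))
    })
  })
  expect_equal(unname(p), dens / rowSums(dens), tolerance = 1e-9)
  if (requireNamespace("MASS", quietly = TRUE)) {
    pm <- predict(MASS::lda(x, grouping = y, prior = rep(1, 3) / 3), xe)
    expect_equal(unname(p), unname(pm$posterior), tolerance = 1e-9)
  }
})

test_that("Sherman-Morrison LOOCV equals brute-force refitting and MASS CV", {
  set.seed(3)
  x <- matrix(rnorm(60 * 5), 60, 5)
  x[, 1] <- x[, 1] + rep(c(0, 1, 2), each = 20)
  y <- rep(c("a", "b", "c"), each = 20)
  cv <- loocv_predict(x, y)
  # brute force: refit from scratch per held-out row
  for (i in seq_len(nrow(x))) {
    f <- fit_lda(x[-i, ], y[-i])
    expect_equal(cv$posterior[i, ], posterior(f, x[i, ])[1, ],
                 tolerance = 1e-8)
  }
  if (requireNamespace("MASS", quietly = TRUE)) {
    mcv <- MASS::lda(x, grouping = y, prior = rep(1, 3) / 3, CV = TRUE)
    expect_identical(cv$class, as.character(mcv$class))
    expect_equal(unname(cv$posterior), unname(mcv$posterior),
                 tolerance = 1e-8)
  }
})

test_that("LOOCV accuracies hit the separability extremes and the shuffled
           null sits at chance", {
  set.seed(4)
  xs <- rbind(matrix(rnorm(40, 0, 0.1), 20), matrix(rnorm(40, 9, 0.1), 20))
  ys <- rep(c("a", "b"), each = 20)
  acc <- loocv_accuracies(xs, ys)
  expect_equal(unname(acc$per_class), c(1, 1))
  expect_equal(acc$overall, 1)

  # shuffled labels on overlapping classes, k = 4: accuracy ~ 25%
  nd <- null_data(n_per_class = 60, k = 4, seed = 8)
  yshuf <- sample(nd$y)
  a <- loocv_accuracies(nd$x, yshuf)
  se <- sqrt(0.25 * 0.75 / length(yshuf))
  expect_lt(abs(a$overall - 0.25), 3 * se + 0.02)
})

test_that("balanced ensembles are reproducible, balanced, and detect the
           generator's group structure", {
  fx <- small_reference()
  lab <- cofactor_models()$geo(fx$meta_by_pip)
  e1 <- balanced_ensemble(fx$features, lab, n_perm = 15, seed = 11)
  e2 <- balanced_ensemble(fx$features, lab, n_perm = 15, seed = 11)
  expect_identical(e1$class_acc, e2$class_acc)
  expect_identical(e1$indices, e2$indices)
  expect_identical(e1$null_class_acc, e2$null_class_acc)

  # every permutation samples exactly the minimal group size per class
  ylab <- lab[!is.na(lab)]
  m <- min(table(ylab))
  expect_identical(e1$m, m)
  for (idx in e1$indices) {
    expect_identical(length(idx), m * length(unique(ylab)))
    expect_true(all(table(ylab[idx]) == m))
    expect_false(anyDuplicated(idx) > 0)
  }
  # balanced input: each permutation uses every row of the smallest config
  xb <- fx$features[!is.na(lab), ][1:40, ]
  yb <- rep(c("p", "q"), 20)
  eb <- balanced_ensemble(xb, yb, n_perm = 5, seed = 2)
  for (idx in eb$indices) expect_setequal(idx, 1:40)

  # structure detected: median class accuracies beat the null maxima
  cs <- confusion_summary(e1)
  expect_true(all(cs$significant))

  # ensemble medians invariant to row order of the input
  perm <- sample(nrow(fx$features))
  e3 <- balanced_ensemble(fx$features[perm, ], lab[perm], n_perm = 15,
                          seed = 11)
  expect_equal(apply(e3$class_acc, 2, median),
               apply(e1$class_acc, 2, median), tolerance = 0.15)

  expect_error(balanced_ensemble(fx$features[1:8, ], rep(c("a", "b"), 4),
                                 n_perm = 5), "below")
})

test_that("null LOOCV accuracy is calibrated at 1/k for the study's class
           counts", {
  for (k in c(2, 4, 5, 8, 10)) {
    nd <- null_data(n_per_class = 24, k = k, seed = 100 + k)
    ens <- balanced_ensemble(nd$x, nd$y, n_perm = 25, seed = k)
    mu <- mean(ens$null_overall_acc)
    se <- sd(ens$null_overall_acc) / sqrt(length(ens$null_overall_acc))
    expect_lt(abs(mu - 1 / k), 3 * se + 0.01)
  }
})

test_that("null accuracies are consistent with Binomial(n, 1/k)/n", {
  nd <- null_data(n_per_class = 90, k = 4, seed = 55)
  ens <- balanced_ensemble(nd$x, nd$y, n_perm = 40, seed = 7)
  n <- 4 * 90
  ks <- suppressWarnings(ks.test(ens$null_overall_acc,
                                 function(q) pbinom(q * n, n, 0.25)))
  expect_lt(unname(ks$statistic), 0.25)
  expect_lt(abs(mean(ens$null_overall_acc) - 0.25), 0.02)
})

test_that("node accuracy is high for separated splits, symmetric, and at
           chance for structureless data", {
  fx <- small_reference()
  lab <- cofactor_models()$status(fx$meta_by_pip)
  grp <- fx$pip_table$group
  # wild vs domesticated is strongly separated by construction
  acc <- node_accuracy(fx$features, grp, "wild", n_perm = 10, seed = 5)
  expect_gt(acc, 0.9)
  # complement split gives the same accuracy
  rest <- setdiff(unique(grp), "wild")
  acc2 <- node_accuracy(fx$features, grp, rest, n_perm = 10, seed = 5)
  expect_equal(acc, acc2, tolerance = 0.05)

  nd <- null_data(n_per_class = 40, k = 4, seed = 9)
  acc0 <- node_accuracy(nd$x, nd$y, c("c1", "c2"), n_perm = 10, seed = 6)
  expect_lt(abs(acc0 - 0.5), 0.1)
  expect_error(node_accuracy(nd$x, nd$y, paste0("c", 1:4), 5), "empty")
})

test_that("confusion summaries renormalise rows and flag chance-level
           classes as nonsignificant", {
  set.seed(10)
  xs <- rbind(matrix(rnorm(80, 0, 0.1), 40), matrix(rnorm(80, 5, 0.1), 40))
  ys <- rep(c("a", "b"), each = 40)
  cs <- confusion_summary(balanced_ensemble(xs, ys, n_perm = 10, seed = 1))
  expect_equal(unname(diag(cs$matrix)), c(100, 100))

  # unbalanced structureless classes, so every permutation draws a fresh
  # balanced subset and the medians concentrate near chance
  set.seed(12)
  n_c <- c(60, 70, 80, 90)
  x0 <- matrix(rnorm(sum(n_c) * 8), sum(n_c), 8)
  y0 <- rep(paste0("c", 1:4), times = n_c)
  ens <- balanced_ensemble(x0, y0, n_perm = 30, seed = 3)
  cs0 <- confusion_summary(ens)
  expect_true(all(abs(rowSums(cs0$matrix) - 100) < 0.5))
  # structureless: diagonal near 100/k, nothing significant
  expect_lt(max(abs(diag(cs0$matrix) - 25)), 15)
  expect_false(any(cs0$significant))
})
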