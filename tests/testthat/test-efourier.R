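# Independent numeric oracle: Fourier coefficients of the arc-length
# parameterised contour by dense Riemann integration, never via efourier().
oracle_coe <- function(pts, H, n_dense = 20000) {
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  sd_ <- total * (seq_len(n_dense) - 0.5) / n_dense
  xd <- approx(s, closed[, 1], xout = sd_)$y
  yd <- approx(s, closed[, 2], xout = sd_)$y
  res <- list(an = numeric(H), bn = numeric(H), cn = numeric(H),
              dn = numeric(H))
  for (h in seq_len(H)) {
    co <- cos(2 * pi * h * sd_ / total)
    si <- sin(2 * pi * h * sd_ / total)
    res$an[h] <- 2 * mean(xd * co)
    res$bn[h] <- 2 * mean(xd * si)
    res$cn[h] <- 2 * mean(yd * co)
    res$dn[h] <- 2 * mean(yd * si)
  }
  res
}

test_that("elliptical Fourier coefficients match the closed-form circle and
           the numeric-integration oracle on an ellipse", {
  circ <- circle_outline(256)
  co <- efourier(circ, H = 3)
  expect_equal(co$an[1], 1, tolerance = 1e-3)
  expect_equal(co$dn[1], 1, tolerance = 1e-3)
  expect_lt(max(abs(c(co$bn[1], co$cn[1]))), 1e-6)
  expect_lt(max(abs(c(co$an[2], co$bn[2], co$cn[2], co$dn[2]))), 1e-3)

  t <- 2 * pi * (0:399) / 400
  ell <- pip_outline(cbind(2 * cos(t), sin(t)), c(1L, 201L))
  ce <- efourier(ell, H = 4)
  orc <- oracle_coe(ell$points, 4)
  # arc-length parameterisation: first harmonic is (1.828, 1.073), not (2, 1)
  expect_equal(ce$an[1], orc$an[1], tolerance = 1e-3)
  expect_equal(ce$dn[1], orc$dn[1], tolerance = 1e-3)
  expect_equal(ce$an[1], 1.8283, tolerance = 1e-3)
  expect_equal(ce$dn[1], 1.0730, tolerance = 1e-3)
  expect_lt(max(abs(c(ce$bn[1], ce$cn[1]))), 1e-6)
  expect_equal(ce$an, orc$an, tolerance = 1e-3)
  expect_equal(ce$dn, orc$dn, tolerance = 1e-3)

  expect_error(efourier(circle_outline(32), H = 10), "at least")
})

test_that("forward/inverse round-trip stays within 1% of the perimeter at
           H = 25", {
  for (seed in 1:5) {
    o <- random_smooth_outline(n = 300, seed = seed)
    co <- efourier(o, H = 25)
    rec <- efourier_inverse(co, n_points = 1000)
    per <- pipmorph:::perimeter(o$points)
    # nearest-point deviation from the original polyline
    dev <- vapply(seq_len(nrow(rec$points)), function(i) {
      min(sqrt(rowSums(sweep(o$points, 2, rec$points[i, ])^2)))
    }, 0)
    expect_lt(max(dev), 0.01 * per)
  }
})

test_that("inverse reconstruction handles pure and degenerate series", {
  co <- pipmorph:::eft_coe(an = 1, bn = 0, cn = 0, dn = 1)
  circ <- efourier_inverse(co, 360)
  expect_lt(max(abs(sqrt(rowSums(circ$points^2)) - 1)), 1e-12)
  z <- pipmorph:::eft_coe(an = 0, bn = 0, cn = 0, dn = 0, a0 = 3, c0 = -2)
  flat <- efourier_inverse(z, 64, landmarks = c(1L, 33L))
  expect_true(all(abs(sweep(flat$points, 2, c(3, -2))) < 1e-12))
  expect_error(efourier_inverse(co, 4), ">= 8")
})

test_that("harmonic power follows the quadratic form and its cumulative
           ratio matches brute force", {
  circ <- pipmorph:::eft_coe(an = 1, bn = 0, cn = 0, dn = 1)
  hp <- harmonic_power(circ)
  expect_equal(hp$power, 1)
  expect_equal(hp$cumulative_ratio, 1)

  two <- pipmorph:::eft_coe(an = c(2, 1), bn = c(1, 0), cn = c(1, 1),
                            dn = c(0, 0))
  hp2 <- harmonic_power(two)
  expect_equal(hp2$power, c(3, 1))
  expect_equal(hp2$cumulative_ratio, c(0.75, 1))

  set.seed(3)
  amps <- 1 / (1:8)^2
  co <- pipmorph:::eft_coe(an = amps * rnorm(8), bn = amps * rnorm(8),
                           cn = amps * rnorm(8), dn = amps * rnorm(8))
  hp3 <- harmonic_power(co)
  brute <- (co$an^2 + co$bn^2 + co$cn^2 + co$dn^2) / 2
  expect_equal(hp3$power, brute)
  expect_equal(hp3$cumulative_ratio, cumsum(brute) / sum(brute))
})

test_that("harmonic calibration selects the smallest harmonic count
           reaching the power threshold", {
  t <- 2 * pi * (0:199) / 200
  ells <- lapply(c(1.5, 2, 3), function(a) {
    pip_outline(cbind(a * cos(t), sin(t)), c(1L, 101L))
  })
  cal <- calibrate_harmonics(ells, threshold = 0.95, H_max = 6)
  expect_identical(unname(cal$chosen_H["dorsal"]), 1L)
  expect_true(all(diff(cal$table$mean_cumulative_ratio) >= -1e-12))

  expect_warning(cal2 <- calibrate_harmonics(ells, threshold = 1,
                                             H_max = 4),
                 "H_max")
  expect_identical(unname(cal2$chosen_H["dorsal"]), 4L)
  expect_error(calibrate_harmonics(list()), "empty")

  # reproducible across generator seeds at equal configuration
  chosen <- vapply(c(5L, 6L), function(s) {
    cc <- collection_config(groups = data.frame(
      archetype = c("wild", "EAST_table"), n_cultivars = 2L),
      pips_per_cultivar = 3L, seed = s)
    ref <- generate_reference(cc)
    reg <- lapply(ref$outlines,
                  function(o) resample_outline(bookstein_register(o), 200))
    calibrate_harmonics(reg, 0.95, 8)$chosen_H[["dorsal"]]
  }, integer(1))
  expect_identical(chosen[1], chosen[2])
})

test_that("coefficients are stable under resampling density", {
  o <- random_smooth_outline(n = 1200, seed = 9)
  r300 <- resample_outline(o, 300)
  r1000 <- resample_outline(o, 1000)
  c300 <- efourier(r300, H = 5)
  c1000 <- efourier(r1000, H = 5)
  for (f in c("an", "bn", "cn", "dn")) {
    expect_lt(max(abs(c300[[f]] - c1000[[f]])), 1e-3)
  }
})

test_that("reconstruction error is nonincreasing in harmonic count", {
  set.seed(11)
  for (seed in c(21, 22, 23)) {
    o <- resample_outline(random_smooth_outline(n = 400, seed = seed), 256)
    errs <- vapply(1:15, function(H) {
      rec <- efourier_inverse(efourier(o, H = H), nrow(o$points))
      # equal-arc input, so reconstruction samples align with the vertices
      mean(sqrt(rowSums((rec$points - o$points)^2)))
    }, 0)
    expect_true(all(diff(errs) <= 1e-8))
  }
})

test_that("the feature matrix has the documented 41-column schema and drops
           pips missing a view", {
  fx <- small_reference()
  feats <- fx$features
  expect_identical(ncol(feats), 41L)
  expect_identical(colnames(feats)[1], "dorsal_a1")
  expect_identical(colnames(feats)[5], "dorsal_a2")
  expect_identical(colnames(feats)[21], "lateral_a1")
  expect_identical(colnames(feats)[41], "length_mm")
  expect_identical(nrow(feats), nrow(fx$pip_table))

  # drop a lateral view: its pip disappears and is reported
  reg <- fx$registered
  views <- vapply(reg, function(o) o$view, "")
  drop_id <- reg[[which(views == "lateral")[1]]]$pip_id
  reg2 <- reg[!(vapply(reg, function(o) o$pip_id, "") == drop_id &
                  views == "lateral")]
  expect_message(f2 <- build_feature_matrix(reg2, fx$lengths, H = 5L),
                 "missing view")
  expect_identical(attr(f2, "dropped"), drop_id)
  expect_identical(nrow(f2), nrow(feats) - 1L)
})
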