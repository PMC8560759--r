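#' Elliptical Fourier coefficients
#'
#' Internal constructor for the coefficient container: per harmonic n the
#' quadruple (a_n, b_n) for the x(t) series and (c_n, d_n) for y(t), plus the
#' series centres a0, c0.
#'
#' @keywords internal
eft_coe <- function(an, bn, cn, dn, a0 = 0, c0 = 0, view = "dorsal",
                    pip_id = "pip") {
  H <- length(an)
  stopifnot(length(bn) == H, length(cn) == H, length(dn) == H, H >= 1L,
            all(is.finite(c(an, bn, cn, dn, a0, c0))))
  structure(list(an = as.numeric(an), bn = as.numeric(bn),
                 cn = as.numeric(cn), dn = as.numeric(dn),
                 a0 = as.numeric(a0), c0 = as.numeric(c0), H = H,
                 view = view, pip_id = pip_id),
            class = "eft_coe")
}

#' @export
print.eft_coe <- function(x, ...) {
  cat(sprintf("<eft_coe> %s [%s] H=%d\n", x$pip_id, x$view, x$H))
  invisible(x)
}

#' Elliptical Fourier transform of a closed outline
#'
#' Kuhl-Giardina decomposition of the chord-length-parameterised contour into
#' truncated Fourier series x(t) = a0 + sum a_n cos(2 pi n t / T) +
#' b_n sin(2 pi n t / T) and analogously y(t). No ellipse-based normalisation
#' is applied: position, size, rotation and starting point are assumed fixed
#' by prior Bookstein registration, so all four coefficients of harmonic 1
#' are retained.
#'
#' @param outline a [pip_outline()] (normally registered and resampled).
#' @param H number of harmonics; the outline must have at least `4 * H + 2`
#'   points.
#' @return An `eft_coe` object.
#' @export
efourier <- function(outline, H = 5L) {
  stopifnot(inherits(outline, "pip_outline"))
  H <- as.integer(H)
  pts <- outline$points
  n <- nrow(pts)
  if (n < 4L * H + 2L) {
    stop("need at least ", 4L * H + 2L, " points for H = ", H, ", got ", n)
  }
  nxt <- c(2:n, 1L)
  dx <- pts[nxt, 1] - pts[, 1]
  dy <- pts[nxt, 2] - pts[, 2]
  dt <- sqrt(dx^2 + dy^2)
  zero <- dt <= 0
  if (any(zero)) { dx <- dx[!zero]; dy <- dy[!zero]; dt <- dt[!zero] }
  if (length(dt) < 3L) stop("degenerate contour")
  total <- sum(dt)
  t1 <- cumsum(dt)
  t0 <- c(0, t1[-length(t1)])
  phi1 <- 2 * pi * t1 / total
  phi0 <- 2 * pi * t0 / total
  an <- bn <- cn <- dn <- numeric(H)
  vx <- dx / dt
  vy <- dy / dt
  for (h in seq_len(H)) {
    k <- total / (2 * h^2 * pi^2)
    dcos <- cos(h * phi1) - cos(h * phi0)
    dsin <- sin(h * phi1) - sin(h * phi0)
    an[h] <- k * sum(vx * dcos)
    bn[h] <- k * sum(vx * dsin)
    cn[h] <- k * sum(vy * dcos)
    dn[h] <- k * sum(vy * dsin)
  }
  # DC terms: mean of the piecewise-linear series over one period
  x1 <- pts[!zero, 1]; y1 <- pts[!zero, 2]
  x2 <- pts[nxt, 1][!zero]; y2 <- pts[nxt, 2][!zero]
  a0 <- sum((x1 + x2) / 2 * dt) / total
  c0 <- sum((y1 + y2) / 2 * dt) / total
  eft_coe(an, bn, cn, dn, a0, c0, view = outline$view, pip_id = outline$pip_id)
}

#' Reconstruct an outline from elliptical Fourier coefficients
#'
#' Evaluates the truncated series at `n_points` equally spaced values of the
#' curvilinear parameter.
#'
#' @param coe an `eft_coe` object.
#' @param n_points number of points (>= 8).
#' @param view,pip_id,scale_mm_per_unit passed to the resulting outline;
#'   default to the coefficients' metadata.
#' @param landmarks optional landmark indices; by default the two extremes of
#'   the reconstruction along x (the registered baseline axis).
#' @return A [pip_outline()].
#' @export
efourier_inverse <- function(coe, n_points = 300L, view = coe$view,
                             pip_id = coe$pip_id, scale_mm_per_unit = 1,
                             landmarks = NULL) {
  stopifnot(inherits(coe, "eft_coe"))
  n_points <- as.integer(n_points)
  if (n_points < 8L) stop("`n_points` must be >= 8")
  t <- (seq_len(n_points) - 1L) / n_points
  x <- rep(coe$a0, n_points)
  y <- rep(coe$c0, n_points)
  for (h in seq_len(coe$H)) {
    co <- cos(2 * pi * h * t)
    si <- sin(2 * pi * h * t)
    x <- x + coe$an[h] * co + coe$bn[h] * si
    y <- y + coe$cn[h] * co + coe$dn[h] * si
  }
  if (is.null(landmarks)) landmarks <- c(which.max(x), which.min(x))
  if (landmarks[1] == landmarks[2]) landmarks <- c(1L, n_points %/% 2L + 1L)
  pip_outline(cbind(x, y), landmarks, view = view, pip_id = pip_id,
              scale_mm_per_unit = scale_mm_per_unit)
}

#' Per-harmonic power and cumulative power ratio
#'
#' Harmonic power is (a_n^2 + b_n^2 + c_n^2 + d_n^2) / 2; its cumulative
#' ratio over harmonics guides truncation of the series.
#'
#' @param coe an `eft_coe` object.
#' @return A data frame with columns `harmonic`, `power`, `cumulative_ratio`.
#' @export
harmonic_power <- function(coe) {
  stopifnot(inherits(coe, "eft_coe"))
  p <- (coe$an^2 + coe$bn^2 + coe$cn^2 + coe$dn^2) / 2
  data.frame(harmonic = seq_len(coe$H), power = p,
             cumulative_ratio = cumsum(p) / sum(p))
}

#' Choose the number of harmonics from cumulative harmonic power
#'
#' Computes, per view, the cumulative power ratio of each outline up to
#' `H_max` harmonics, averages the ratios across outlines, and retains the
#' smallest harmonic count whose mean cumulative ratio reaches `threshold`.
#'
#' @param outlines list of registered [pip_outline()] objects (any mix of
#'   views).
#' @param threshold cumulative power ratio to reach (default 0.95).
#' @param H_max largest harmonic count considered.
#' @return A list of class `harmonic_calibration` with elements `chosen_H`
#'   (named integer vector per view), `threshold` and `table` (data frame:
#'   view, harmonic, mean_cumulative_ratio).
#' @export
calibrate_harmonics <- function(outlines, threshold = 0.95, H_max = 10L) {
  if (length(outlines) == 0L) stop("empty outline collection")
  stopifnot(threshold > 0, threshold <= 1)
  views <- vapply(outlines, function(o) o$view, character(1))
  tabs <- list()
  chosen <- integer(0)
  for (v in sort(unique(views))) {
    ratios <- vapply(outlines[views == v], function(o) {
      harmonic_power(efourier(o, H = H_max))$cumulative_ratio
    }, numeric(H_max))
    m <- rowMeans(ratios)
    hit <- which(m >= threshold)
    if (threshold >= 1 || length(hit) == 0L) {
      warning("threshold ", threshold, " only reachable with the full ",
              "series for view ", v, "; using H_max = ", H_max)
      hv <- H_max
    } else hv <- min(hit)
    chosen[v] <- as.integer(hv)
    tabs[[v]] <- data.frame(view = v, harmonic = seq_len(H_max),
                            mean_cumulative_ratio = m)
  }
  structure(list(chosen_H = chosen, threshold = threshold,
                 table = do.call(rbind, tabs)),
            class = "harmonic_calibration")
}

#' @export
print.harmonic_calibration <- function(x, ...) {
  cat("<harmonic_calibration> threshold", x$threshold, "->",
      paste(names(x$chosen_H), x$chosen_H, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

coe_vector <- function(coe, H) {
  if (coe$H < H) stop("coefficients hold ", coe$H, " harmonics, need ", H)
  v <- as.vector(rbind(coe$an[1:H], coe$bn[1:H], coe$cn[1:H], coe$dn[1:H]))
  names(v) <- as.vector(vapply(seq_len(H), function(h) {
    paste0(c("a", "b", "c", "d"), h)
  }, character(4)))
  v
}

#' Assemble the per-pip feature matrix
#'
#' One row per pip: the dorsal-view coefficient quadruples (a1, b1, c1, d1,
#' a2, ...), then the lateral-view quadruples, then the pip length in mm.
#' With 5 harmonics per view this is the 40-coefficient + length = 41-column
#' form matrix. Pips missing either view are dropped with a message.
#'
#' @param outlines list of registered [pip_outline()] objects; each pip must
#'   appear once per view.
#' @param lengths_mm named numeric vector of pip lengths, names = pip ids.
#' @param H harmonics per view: a single integer or a vector named
#'   `c(dorsal = , lateral = )`.
#' @return Numeric matrix (pips x features) with column names like
#'   `dorsal_a1 ... lateral_d5, length_mm`; attribute `dropped` lists pip ids
#'   excluded for a missing view.
#' @export
build_feature_matrix <- function(outlines, lengths_mm, H = 5L) {
  if (length(H) == 1L) H <- c(dorsal = H, lateral = H)
  H <- as.integer(H[c("dorsal", "lateral")])
  names(H) <- c("dorsal", "lateral")
  ids <- vapply(outlines, function(o) o$pip_id, character(1))
  views <- vapply(outlines, function(o) o$view, character(1))
  pips <- unique(ids)
  have_both <- vapply(pips, function(p) {
    all(c("dorsal", "lateral") %in% views[ids == p])
  }, logical(1))
  dropped <- pips[!have_both]
  if (length(dropped)) {
    message(length(dropped), " pip(s) dropped for missing view: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  pips <- pips[have_both]
  missing_len <- setdiff(pips, names(lengths_mm))
  if (length(missing_len)) {
    stop("no length for pip(s): ", paste(utils::head(missing_len, 5), collapse = ", "))
  }
  p <- 4L * sum(H) + 1L
  out <- matrix(NA_real_, length(pips), p)
  for (i in seq_along(pips)) {
    row <- numeric(0)
    for (v in c("dorsal", "lateral")) {
      j <- which(ids == pips[i] & views == v)[1]
      row <- c(row, coe_vector(efourier(outlines[[j]], H = H[v]), H[v]))
    }
    out[i, ] <- c(row, lengths_mm[pips[i]])
  }
  colnames(out) <- c(
    paste0("dorsal_", names(coe_vector(eft_coe(rep(0.1, H["dorsal"]),
      rep(0.1, H["dorsal"]), rep(0.1, H["dorsal"]), rep(0.1, H["dorsal"])), H["dorsal"]))),
    paste0("lateral_", names(coe_vector(eft_coe(rep(0.1, H["lateral"]),
      rep(0.1, H["lateral"]), rep(0.1, H["lateral"]), rep(0.1, H["lateral"])), H["lateral"]))),
    "length_mm")
  rownames(out) <- pips
  attr(out, "dropped") <- dropped
  out
}
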