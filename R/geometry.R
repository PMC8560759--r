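#' Construct a pip outline
#'
#' An outline is an ordered closed contour of (x, y) coordinates with two tip
#' landmarks (stalk end and chalaza end), a view tag and a mm-per-unit scale.
#' The contour is treated as closed: the last point connects back to the
#' first.
#'
#' @param points numeric matrix with two columns (x, y), at least 32 rows.
#' @param landmarks integer vector of length 2: indices into `points` of the
#'   stalk-end tip (landmark a) and the opposite tip (landmark b).
#' @param view `"dorsal"` or `"lateral"`.
#' @param pip_id character identifier of the pip this view belongs to.
#' @param scale_mm_per_unit positive scale factor converting coordinate units
#'   to millimetres.
#' @return An object of class `pip_outline`.
#' @export
pip_outline <- function(points, landmarks, view = c("dorsal", "lateral"),
                        pip_id = "pip", scale_mm_per_unit = 1) {
  view <- match.arg(view)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L) stop("`points` must have two columns (x, y)")
  n <- nrow(points)
  if (n < 32L) stop("outline must have at least 32 points, got ", n)
  if (anyNA(points) || any(!is.finite(points))) {
    stop("outline coordinates must be finite")
  }
  landmarks <- as.integer(landmarks)
  if (length(landmarks) != 2L || anyNA(landmarks) ||
      any(landmarks < 1L | landmarks > n) || landmarks[1] == landmarks[2]) {
    stop("`landmarks` must be two distinct indices in 1..", n)
  }
  if (!is.numeric(scale_mm_per_unit) || length(scale_mm_per_unit) != 1L ||
      !is.finite(scale_mm_per_unit) || scale_mm_per_unit <= 0) {
    stop("`scale_mm_per_unit` must be a positive number")
  }
  structure(
    list(points = unname(points), landmarks = landmarks, view = view,
         pip_id = as.character(pip_id),
         scale_mm_per_unit = as.numeric(scale_mm_per_unit),
         registered = FALSE),
    class = "pip_outline")
}

#' @export
print.pip_outline <- function(x, ...) {
  cat(sprintf("<pip_outline> %s [%s] %d points, scale %g mm/unit%s\n",
              x$pip_id, x$view, nrow(x$points), x$scale_mm_per_unit,
              if (isTRUE(x$registered)) ", registered" else ""))
  invisible(x)
}

landmark_points <- function(outline) {
  outline$points[outline$landmarks, , drop = FALSE]
}

#' Read an outline coordinate file
#'
#' The plain-text dialect has four header lines (`id`, `view`,
#' `scale_mm_per_unit`, `landmark_indices` with two 1-based indices) followed
#' by one `x y` coordinate row per point. Blank lines and `#` comments are
#' ignored. Malformed files are rejected with the offending line number.
#'
#' @param path path to an outline file.
#' @return A [pip_outline()].
#' @export
read_outline <- function(path) {
  if (!file.exists(path)) stop("no such outline file: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (length(keep) < 5L) stop("outline file too short: ", path)
  hdr <- list()
  coord_start <- NA_integer_
  for (i in keep) {
    m <- regmatches(raw[i], regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*[: ]\\s*(.*\\S)\\s*$", raw[i]))[[1]]
    if (length(m) == 3L && m[2] %in% c("id", "view", "scale_mm_per_unit", "landmark_indices")) {
      hdr[[m[2]]] <- m[3]
    } else {
      coord_start <- i
      break
    }
  }
  for (field in c("id", "view", "scale_mm_per_unit", "landmark_indices")) {
    if (is.null(hdr[[field]])) {
      stop(sprintf("%s: missing header field `%s`", path, field))
    }
  }
  if (is.na(coord_start)) stop(path, ": no coordinate rows")
  rows <- keep[keep >= coord_start]
  xy <- matrix(NA_real_, length(rows), 2L)
  for (j in seq_along(rows)) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(raw[rows[j]]), "[,;[:space:]]+")[[1]]))
    if (length(vals) != 2L || anyNA(vals)) {
      stop(sprintf("%s: line %d is not a numeric x,y row", path, rows[j]))
    }
    xy[j, ] <- vals
  }
  lmk <- suppressWarnings(as.integer(strsplit(trimws(hdr$landmark_indices), "[,;[:space:]]+")[[1]]))
  if (length(lmk) != 2L || anyNA(lmk)) {
    stop(path, ": `landmark_indices` must hold two integers")
  }
  pip_outline(xy, lmk, view = hdr$view, pip_id = hdr$id,
              scale_mm_per_unit = as.numeric(hdr$scale_mm_per_unit))
}

#' Write an outline coordinate file
#'
#' @param outline a [pip_outline()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_outline <- function(outline, path) {
  stopifnot(inherits(outline, "pip_outline"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("id", outline$pip_id),
    paste("view", outline$view),
    paste("scale_mm_per_unit", format(outline$scale_mm_per_unit, digits = 17)),
    paste("landmark_indices", outline$landmarks[1], outline$landmarks[2]),
    paste(format(outline$points[, 1], digits = 17, trim = TRUE),
          format(outline$points[, 2], digits = 17, trim = TRUE))
  ), con)
  invisible(path)
}

signed_area <- function(points) {
  x <- points[, 1]; y <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

rotate_start <- function(points, start) {
  n <- nrow(points)
  if (start == 1L) return(points)
  points[c(start:n, seq_len(start - 1L)), , drop = FALSE]
}

#' Register an outline on Bookstein coordinates
#'
#' Applies the similarity transform (translation, rotation, uniform scaling)
#' that sends landmark a to (-0.5, 0) and landmark b to (0.5, 0), removing
#' position, size, rotation and starting point. The point sequence is rotated
#' so that landmark a is the first point, and orientation is normalised to
#' counterclockwise (the sequence is reversed if needed).
#'
#' @param outline a [pip_outline()].
#' @return A registered `pip_outline` (`registered = TRUE`), landmark a at
#'   index 1.
#' @export
bookstein_register <- function(outline) {
  stopifnot(inherits(outline, "pip_outline"))
  pts <- outline$points
  z <- complex(real = pts[, 1], imaginary = pts[, 2])
  a <- z[outline$landmarks[1]]
  b <- z[outline$landmarks[2]]
  base <- b - a
  if (Mod(base) < 1e-12 * max(1, max(abs(pts)))) {
    stop("coincident landmarks: zero baseline, cannot register")
  }
  w <- (z - a) / base - 0.5
  reg <- cbind(Re(w), Im(w))
  n <- nrow(reg)
  la <- outline$landmarks[1]
  reg <- rotate_start(reg, la)
  lb <- ((outline$landmarks[2] - la) %% n) + 1L
  if (signed_area(reg) < 0) {
    reg <- reg[c(1L, n:2L), , drop = FALSE]
    if (lb > 1L) lb <- n - lb + 2L
  }
  out <- outline
  out$points <- reg
  out$landmarks <- c(1L, lb)
  out$registered <- TRUE
  out
}

perimeter <- function(points) {
  d <- points - points[c(2:nrow(points), 1L), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

#' Resample an outline to equally spaced points
#'
#' Points are placed at equal intervals of cumulative chord length around the
#' closed contour, starting at landmark a. Landmarks are re-indexed to the
#' nearest resampled point.
#'
#' @param outline a [pip_outline()].
#' @param n_points number of points (>= 32).
#' @return A `pip_outline` with `n_points` points, landmark a at index 1.
#' @export
resample_outline <- function(outline, n_points = 300L) {
  stopifnot(inherits(outline, "pip_outline"))
  n_points <- as.integer(n_points)
  if (n_points < 32L) stop("`n_points` must be >= 32")
  pts <- rotate_start(outline$points, outline$landmarks[1])
  n <- nrow(pts)
  lb_old <- ((outline$landmarks[2] - outline$landmarks[1]) %% n) + 1L
  closed <- rbind(pts, pts[1L, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  total <- sum(seg)
  if (total <= 0) stop("degenerate outline: zero perimeter")
  s <- c(0, cumsum(seg))                       # arc position of each vertex
  target <- total * (seq_len(n_points) - 1L) / n_points
  x <- stats::approx(s, closed[, 1], xout = target, method = "linear",
                     ties = "ordered")$y
  y <- stats::approx(s, closed[, 2], xout = target, method = "linear",
                     ties = "ordered")$y
  # landmark b: nearest sample to its arc position
  sb <- s[lb_old]
  lb_new <- (round(sb / total * n_points) %% n_points) + 1L
  out <- outline
  out$points <- matrix(c(x, y), ncol = 2L)
  out$landmarks <- c(1L, as.integer(lb_new))
  if (out$landmarks[2] == 1L) out$landmarks[2] <- 2L
  out
}

#' Pip length in millimetres
#'
#' Tip-to-tip Euclidean distance between the two landmarks, multiplied by the
#' outline's mm-per-unit scale. Invariant to point order, resampling density
#' and registration when computed on the unregistered outline.
#'
#' @param outline a [pip_outline()] carrying a positive scale.
#' @return Length in mm.
#' @export
pip_length <- function(outline) {
  stopifnot(inherits(outline, "pip_outline"))
  lm <- landmark_points(outline)
  sqrt(sum((lm[1, ] - lm[2, ])^2)) * outline$scale_mm_per_unit
}
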