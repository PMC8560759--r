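# Shared fixtures, built in code and memoised across test files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

circle_outline <- function(n = 256, r = 1, phase = 0, ccw = TRUE,
                           pip_id = "circle") {
  t <- 2 * pi * (seq_len(n) - 1) / n + phase
  if (!ccw) t <- rev(t)
  pts <- cbind(r * cos(t), r * sin(t))
  pip_outline(pts, c(1L, n %/% 2L + 1L), pip_id = pip_id)
}

# random smooth simple closed contour (low-order Fourier perturbation of a
# circle), guaranteed simple by construction for small amplitude
random_smooth_outline <- function(n = 200, seed = 1, amp = 0.08) {
  set.seed(seed)
  t <- 2 * pi * (seq_len(n) - 1) / n
  r <- 1 + amp * (sin(2 * t + runif(1, 0, 2 * pi)) +
                  0.5 * cos(3 * t + runif(1, 0, 2 * pi)))
  pts <- cbind(r * cos(t), 0.7 * r * sin(t))
  pip_outline(pts, c(1L, which.min(pts[, 1])), pip_id = paste0("rnd", seed))
}

# small reference collection shared by the heavier tests
small_reference <- function() {
  memo("small_reference", {
    cc <- collection_config(n_cultivars = 4L, pips_per_cultivar = 8L,
                            seed = 42L)
    ref <- generate_reference(cc)
    reg <- lapply(ref$outlines,
                  function(o) resample_outline(bookstein_register(o), 300))
    lens <- vapply(ref$outlines, pip_length, 0)
    names(lens) <- vapply(ref$outlines, function(o) o$pip_id, "")
    lens <- lens[!duplicated(names(lens))]
    feats <- build_feature_matrix(reg, lens, H = 5L)
    pt <- ref$pips[match(rownames(feats), ref$pips$pip_id), ]
    meta_by_pip <- ref$metadata[match(pt$cultivar_id,
                                      ref$metadata$cultivar_id), ]
    list(config = cc, ref = ref, registered = reg, features = feats,
         lengths = lens, pip_table = pt, meta_by_pip = meta_by_pip)
  })
}

# structureless gaussian data with k balanced classes
null_data <- function(n_per_class, k, p = 8, seed = 1) {
  set.seed(seed)
  list(x = matrix(rnorm(n_per_class * k * p), n_per_class * k, p),
       y = rep(paste0("c", seq_len(k)), each = n_per_class))
}

# brute-force average-linkage clustering, independent of hclust
brute_upgma_merge_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n + (n - 1))
  heights <- numeric(n - 1)
  members <- c(as.list(seq_len(n)), vector("list", n - 1))
  avg_d <- function(a, b) {
    mean(d[members[[a]], members[[b]]])
  }
  ids <- seq_len(n)
  for (s in seq_len(n - 1)) {
    best <- c(NA, NA); bh <- Inf
    act <- which(active[seq_len(n + s - 1)])
    for (i in seq_along(act)) {
      for (j in seq_len(i - 1)) {
        h <- avg_d(act[i], act[j])
        if (h < bh - 1e-12) { bh <- h; best <- c(act[j], act[i]) }
      }
    }
    heights[s] <- bh
    members[[n + s]] <- sort(c(members[[best[1]]], members[[best[2]]]))
    active[best] <- FALSE
    active[n + s] <- TRUE
  }
  list(heights = heights,
       sets = members[(n + 1):(2 * n - 1)])
}
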