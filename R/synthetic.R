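## Synthetic reference collections and archaeological assemblages.
##
## Archetypes differ only in a few interpretable shape parameters: the
## first-harmonic axis ratio (elongation, length/width), second- and
## third-harmonic asymmetries (egg-shape and "stalk" prominence) and pip
## length. Wild pips are roundish with short stalks and shorter; domesticated
## pips are more elongated with longer stalks and longer, with use and
## geography variants at distinct offsets.

pip_base_coe <- function(elongation, stalk, asym, flatten = 0,
                         view = "dorsal") {
  a1 <- 0.5
  an <- c(a1, asym, stalk, 0, 0, 0)
  bn <- c(0, 0, 0, 0, 0, 0)
  cn <- c(0, 0.25 * stalk, 0, 0, 0, 0)
  dn <- c(a1 / elongation - flatten, 0, 0.35 * stalk, 0.01, 0, 0)
  eft_coe(an, bn, cn, dn, view = view)
}

#' Default shape archetypes for the synthetic collection
#'
#' Builds one wild archetype (axis ratio near 1, short stalk, shorter pips)
#' and ten domesticated archetypes crossing two destination uses (wine,
#' table) with five geographic groups (EAST, BALK, ITAL, WEUR, IBER), at
#' fixed elongation, asymmetry and stalk offsets. Genetic labels (a 4-level
#' SNP grouping and a 5-level SSR grouping) are attached to the subset of
#' use-by-geography cells they cover; the remaining cells carry NA, mirroring
#' reference collections in which genetic assignments exist only for some
#' cultivars. Table archetypes are longer than wine ones.
#'
#' @param seed integer seed (the construction is deterministic; the seed is
#'   accepted for interface symmetry and reserved for future stochastic
#'   variants).
#' @return Named list of archetypes; each has `label`, `status`, `use`,
#'   `geo`, `snp4`, `ssr5`, `axis_ratio`, `length_mean_mm`, `length_sd_mm`
#'   and `coe` (list with `dorsal` and `lateral` base coefficients).
#' @export
make_default_archetypes <- function(seed = 1L) {
  geo_levels <- c("EAST", "BALK", "ITAL", "WEUR", "IBER")
  stalk_geo <- c(EAST = 0.030, BALK = 0.048, ITAL = 0.066, WEUR = 0.084,
                 IBER = 0.102)
  asym_geo <- c(EAST = -0.040, BALK = -0.020, ITAL = 0.000, WEUR = 0.020,
                IBER = 0.040)
  elong_use <- c(wine = 1.80, table = 1.45)
  len_use <- c(wine = 6.0, table = 7.0)
  snp4_map <- c(EAST.table = "EAST_Table", BALK.wine = "BALK_Wine",
                IBER.wine = "IBER_Wine", WEUR.wine = "WCEUR_Wine",
                ITAL.wine = "WCEUR_Wine")
  ssr5_map <- c(EAST.table = "EAST_Table", ITAL.table = "ITACE_Table",
                WEUR.wine = "WCEUR_Wine", BALK.wine = "BALK_Wine",
                IBER.wine = "IBER_WT")
  arch <- list()
  arch[["wild"]] <- list(
    label = "wild", status = "wild", use = NA_character_,
    geo = NA_character_, snp4 = NA_character_, ssr5 = NA_character_,
    axis_ratio = 1.15, length_mean_mm = 5.2, length_sd_mm = 0.35,
    coe = list(
      dorsal = pip_base_coe(1.15, 0.015, 0.000, view = "dorsal"),
      lateral = pip_base_coe(1.15, 0.012, 0.000, flatten = 0.06,
                             view = "lateral")))
  for (use in c("wine", "table")) {
    for (geo in geo_levels) {
      elong <- elong_use[use] + 0.04 * (match(geo, geo_levels) - 3)
      lab <- paste(geo, use, sep = "_")
      key <- paste(geo, use, sep = ".")
      arch[[lab]] <- list(
        label = lab, status = "domesticated", use = use, geo = geo,
        snp4 = if (key %in% names(snp4_map)) snp4_map[[key]] else NA_character_,
        ssr5 = if (key %in% names(ssr5_map)) ssr5_map[[key]] else NA_character_,
        axis_ratio = unname(elong),
        length_mean_mm = unname(len_use[use]), length_sd_mm = 0.4,
        coe = list(
          dorsal = pip_base_coe(elong, stalk_geo[geo], asym_geo[geo],
                                view = "dorsal"),
          lateral = pip_base_coe(elong * 1.05, 0.8 * stalk_geo[geo],
                                 asym_geo[geo], flatten = 0.06,
                                 view = "lateral")))
    }
  }
  arch
}

## O(n) turning-number test: for a simple closed polygon the exterior angles
## sum to +-2*pi; coefficient noise that pinches the outline into a small
## loop adds a full extra turn. Fast proxy used for bulk rate checks; the
## quadratic segment-intersection test below is the exact check.
turning_number <- function(points) {
  d <- diff(rbind(points, points[1L, , drop = FALSE]))
  ang <- atan2(d[, 2], d[, 1])
  ext <- diff(c(ang, ang[1]))
  ext <- (ext + pi) %% (2 * pi) - pi
  sum(ext) / (2 * pi)
}

is_simple_outline <- function(points, method = c("turning", "segments")) {
  method <- match.arg(method)
  if (method == "turning") {
    return(abs(abs(turning_number(points)) - 1) < 1e-6)
  }
  n <- nrow(points)
  p1 <- points
  p2 <- points[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    # skip adjacent segments (shared endpoints)
    js <- if (i == 1L) 3:(n - 1L) else (i + 2L):n
    if (length(js) == 0L) next
    if (any(segments_cross(p1[i, ], p2[i, ], p1[js, , drop = FALSE],
                           p2[js, , drop = FALSE]))) {
      return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(a1, a2, b1, b2) {
  # proper intersection of segment a with each row-pair of b (vectorised)
  d <- a2 - a1
  s1 <- (b1[, 1] - a1[1]) * d[2] - (b1[, 2] - a1[2]) * d[1]
  s2 <- (b2[, 1] - a1[1]) * d[2] - (b2[, 2] - a1[2]) * d[1]
  e <- b2 - b1
  t1 <- (a1[1] - b1[, 1]) * e[, 2] - (a1[2] - b1[, 2]) * e[, 1]
  t2 <- (a2[1] - b1[, 1]) * e[, 2] - (a2[2] - b1[, 2]) * e[, 1]
  (s1 * s2 < 0) & (t1 * t2 < 0)
}

#' Configuration for a synthetic reference collection
#'
#' @param archetypes archetype list, e.g. [make_default_archetypes()].
#' @param groups data frame with columns `archetype` (label present in
#'   `archetypes`) and `n_cultivars`; defaults to every archetype with
#'   `n_cultivars` cultivars each.
#' @param n_cultivars default cultivars per group when `groups` is NULL.
#' @param pips_per_cultivar pips sampled per cultivar (default 30, the
#'   collection depth the generator emulates).
#' @param within_cultivar_sd,within_group_sd Gaussian sd of the pip-level and
#'   cultivar-level perturbations of the first-harmonic coefficients; higher
#'   harmonics are perturbed with sd decaying as 1/n. Must satisfy
#'   `within_cultivar_sd <= within_group_sd`.
#' @param berry_size_rule named numeric vector: pip-length shift in mm per
#'   berry size class; must be increasing small < medium < large.
#' @param berry_size_probs sampling probabilities of the size classes.
#' @param length_sd_pip_mm sd of pip length around its cultivar mean.
#' @param missing_rate fraction of cultivar labels (use, snp4, ssr5) set
#'   missing completely at random.
#' @param mixed_use_rate fraction of domesticated cultivars recorded as
#'   "mixed" use.
#' @param seed integer seed.
#' @return A list of class `collection_config`.
#' @export
collection_config <- function(archetypes = make_default_archetypes(),
                              groups = NULL,
                              n_cultivars = 4L,
                              pips_per_cultivar = 30L,
                              within_cultivar_sd = 0.004,
                              within_group_sd = 0.012,
                              berry_size_rule = c(small = -0.8, medium = 0,
                                                  large = 0.8),
                              berry_size_probs = c(small = 0.3, medium = 0.45,
                                                   large = 0.25),
                              length_sd_pip_mm = 0.15,
                              missing_rate = 0.05,
                              mixed_use_rate = 0.05,
                              seed = 1L) {
  if (is.null(groups)) {
    groups <- data.frame(archetype = names(archetypes),
                         n_cultivars = n_cultivars)
  }
  stopifnot(all(groups$archetype %in% names(archetypes)),
            pips_per_cultivar >= 1L,
            within_cultivar_sd >= 0, within_group_sd >= 0,
            within_cultivar_sd <= within_group_sd,
            identical(names(berry_size_rule), c("small", "medium", "large")),
            !is.unsorted(berry_size_rule, strictly = TRUE))
  structure(list(archetypes = archetypes, groups = groups,
                 pips_per_cultivar = as.integer(pips_per_cultivar),
                 within_cultivar_sd = within_cultivar_sd,
                 within_group_sd = within_group_sd,
                 berry_size_rule = berry_size_rule,
                 berry_size_probs = berry_size_probs / sum(berry_size_probs),
                 length_sd_pip_mm = length_sd_pip_mm,
                 missing_rate = missing_rate,
                 mixed_use_rate = mixed_use_rate,
                 seed = as.integer(seed)),
            class = "collection_config")
}

perturb_coe <- function(coe, sd1) {
  if (sd1 <= 0) return(coe)
  sds <- sd1 / seq_len(coe$H)
  coe$an <- coe$an + stats::rnorm(coe$H, 0, sds)
  coe$bn <- coe$bn + stats::rnorm(coe$H, 0, sds)
  coe$cn <- coe$cn + stats::rnorm(coe$H, 0, sds)
  coe$dn <- coe$dn + stats::rnorm(coe$H, 0, sds)
  coe
}

coe_add <- function(coe, offset) {
  coe$an <- coe$an + offset$an; coe$bn <- coe$bn + offset$bn
  coe$cn <- coe$cn + offset$cn; coe$dn <- coe$dn + offset$dn
  coe
}

draw_offset <- function(H, sd1) {
  sds <- if (sd1 > 0) sd1 / seq_len(H) else rep(0, H)
  list(an = stats::rnorm(H, 0, sds), bn = stats::rnorm(H, 0, sds),
       cn = stats::rnorm(H, 0, sds), dn = stats::rnorm(H, 0, sds))
}

synth_outline <- function(coe, length_mm, pip_id, n_points = 300L) {
  o <- efourier_inverse(coe, n_points = n_points, pip_id = pip_id)
  tip_dist <- sqrt(sum((o$points[o$landmarks[1], ] -
                        o$points[o$landmarks[2], ])^2))
  o$scale_mm_per_unit <- length_mm / tip_dist
  o
}

#' Generate a synthetic reference collection
#'
#' Per cultivar, a coefficient offset is drawn at the within-group sd; per
#' pip, noise at the within-cultivar sd; both decay as 1/n across harmonics.
#' Each pip is reconstructed at 300 points in both views, with tip landmarks
#' at the extremes of the first-harmonic major axis and the mm scale set so
#' the tip-to-tip distance equals the drawn pip length. Cultivar pip-length
#' means are the archetype mean shifted by the cultivar's berry size class.
#'
#' @param config a [collection_config()].
#' @return List with `outlines` (two [pip_outline()]s per pip), `metadata`
#'   (one row per cultivar: cultivar_id, use, geo_group, core_region_flag,
#'   berry_size, snp4, ssr5), `pips` (pip_id, cultivar_id, group,
#'   length_mm) and `truth` (per-cultivar generating archetype; never read
#'   by the analysis pipeline).
#' @export
generate_reference <- function(config = collection_config()) {
  stopifnot(inherits(config, "collection_config"))
  set.seed(config$seed)
  outlines <- list()
  meta <- list()
  pips <- list()
  n_bad <- 0L; n_tot <- 0L
  cidx <- 0L
  for (g in seq_len(nrow(config$groups))) {
    arch <- config$archetypes[[config$groups$archetype[g]]]
    for (ci in seq_len(config$groups$n_cultivars[g])) {
      cidx <- cidx + 1L
      cultivar_id <- sprintf("CV%03d", cidx)
      off <- list(dorsal = draw_offset(arch$coe$dorsal$H, config$within_group_sd),
                  lateral = draw_offset(arch$coe$lateral$H, config$within_group_sd))
      size <- sample(names(config$berry_size_rule), 1L,
                     prob = config$berry_size_probs)
      len_mean <- arch$length_mean_mm + config$berry_size_rule[[size]] +
        stats::rnorm(1, 0, arch$length_sd_mm)
      use_lab <- arch$use
      if (!is.na(use_lab) && stats::runif(1) < config$mixed_use_rate) {
        use_lab <- "mixed"
      }
      miss <- stats::runif(3) < config$missing_rate
      meta[[cidx]] <- data.frame(
        cultivar_id = cultivar_id,
        use = if (miss[1]) NA_character_ else use_lab,
        geo_group = arch$geo,
        core_region_flag = !is.na(arch$geo),
        berry_size = size,
        snp4 = if (miss[2]) NA_character_ else arch$snp4,
        ssr5 = if (miss[3]) NA_character_ else arch$ssr5,
        status = arch$status,
        stringsAsFactors = FALSE)
      for (pi in seq_len(config$pips_per_cultivar)) {
        pip_id <- sprintf("%s_P%02d", cultivar_id, pi)
        len <- max(1, stats::rnorm(1, len_mean, config$length_sd_pip_mm))
        for (v in c("dorsal", "lateral")) {
          coe <- coe_add(arch$coe[[v]], off[[v]])
          coe <- perturb_coe(coe, config$within_cultivar_sd)
          o <- synth_outline(coe, len, pip_id)
          o$view <- v
          n_tot <- n_tot + 1L
          if (!is_simple_outline(o$points)) n_bad <- n_bad + 1L
          outlines[[length(outlines) + 1L]] <- o
        }
        pips[[length(pips) + 1L]] <- data.frame(
          pip_id = pip_id, cultivar_id = cultivar_id,
          group = arch$label, length_mm = len, stringsAsFactors = FALSE)
      }
    }
  }
  if (n_bad / n_tot > 0.01) {
    stop(sprintf(paste0("noise configuration produces self-intersecting ",
                        "outlines at %.1f%% (> 1%%); reduce the sd settings"),
                 100 * n_bad / n_tot))
  }
  truth <- data.frame(cultivar_id = vapply(meta, `[[`, "", "cultivar_id"),
                      group = rep(config$groups$archetype,
                                  times = config$groups$n_cultivars),
                      stringsAsFactors = FALSE)
  list(outlines = outlines, metadata = do.call(rbind, meta),
       pips = do.call(rbind, pips), truth = truth)
}

#' Configuration for a synthetic archaeological assemblage
#'
#' @param n_pips number of pips in the assemblage.
#' @param wild_fraction probability that a pip is drawn from the wild
#'   archetype.
#' @param domesticated_mixture named probability vector over domesticated
#'   archetype labels (must sum to 1).
#' @param noise_sd first-harmonic sd of per-pip coefficient noise (1/n decay).
#' @param phase free-text phase label carried into reports.
#' @param seed integer seed.
#' @export
assemblage_config <- function(n_pips = 100L, wild_fraction = 0.5,
                              domesticated_mixture = NULL,
                              noise_sd = 0.012, phase = "phase1",
                              seed = 1L) {
  stopifnot(n_pips >= 1L, wild_fraction >= 0, wild_fraction <= 1,
            noise_sd >= 0)
  if (is.null(domesticated_mixture)) {
    domesticated_mixture <- c(EAST_table = 1)
  }
  if (abs(sum(domesticated_mixture) - 1) > 1e-8) {
    stop("`domesticated_mixture` must sum to 1")
  }
  structure(list(n_pips = as.integer(n_pips), wild_fraction = wild_fraction,
                 domesticated_mixture = domesticated_mixture,
                 noise_sd = noise_sd, phase = phase, seed = as.integer(seed)),
            class = "assemblage_config")
}

#' Generate a synthetic archaeological assemblage
#'
#' Draws the number of wild-type pips from a binomial at `wild_fraction`,
#' assigns the remaining pips to domesticated archetypes according to the
#' mixture, and synthesises noisy two-view outlines. Ground-truth labels are
#' returned separately and are never read by the inference pipeline.
#'
#' @param config an [assemblage_config()].
#' @param archetypes archetype list containing "wild" plus every mixture
#'   label.
#' @return List with `outlines`, `truth` (pip_id, group, status, length_mm)
#'   and `phase`.
#' @export
generate_assemblage <- function(config, archetypes = make_default_archetypes()) {
  stopifnot(inherits(config, "assemblage_config"))
  mix_labels <- names(config$domesticated_mixture)
  bad <- setdiff(mix_labels, names(archetypes))
  if (length(bad)) {
    stop("mixture labels not among archetypes: ", paste(bad, collapse = ", "))
  }
  set.seed(config$seed)
  n_wild <- stats::rbinom(1L, config$n_pips, config$wild_fraction)
  labels <- c(rep("wild", n_wild),
              if (config$n_pips > n_wild)
                sample(mix_labels, config$n_pips - n_wild, replace = TRUE,
                       prob = config$domesticated_mixture))
  labels <- sample(labels)
  outlines <- list()
  truth <- vector("list", config$n_pips)
  for (i in seq_len(config$n_pips)) {
    arch <- archetypes[[labels[i]]]
    pip_id <- sprintf("%s_A%03d", config$phase, i)
    len <- max(1, stats::rnorm(1, arch$length_mean_mm, arch$length_sd_mm))
    for (v in c("dorsal", "lateral")) {
      coe <- perturb_coe(arch$coe[[v]], config$noise_sd)
      o <- synth_outline(coe, len, pip_id)
      o$view <- v
      outlines[[length(outlines) + 1L]] <- o
    }
    truth[[i]] <- data.frame(pip_id = pip_id, group = labels[i],
                             status = arch$status, length_mm = len,
                             stringsAsFactors = FALSE)
  }
  list(outlines = outlines, truth = do.call(rbind, truth),
       phase = config$phase)
}

#' Write a collection to plain-text files
#'
#' Outlines are written one pip-view per file into `dir/outlines/`; cultivar
#' metadata to `dir/metadata.csv`; ground truth (if present) to
#' `dir/ground_truth.csv`, which the analysis pipeline never reads.
#'
#' @param collection result of [generate_reference()] or
#'   [generate_assemblage()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_collection <- function(collection, dir) {
  odir <- file.path(dir, "outlines")
  dir.create(odir, recursive = TRUE, showWarnings = FALSE)
  for (o in collection$outlines) {
    write_outline(o, file.path(odir, paste0(o$pip_id, "_", o$view, ".txt")))
  }
  if (!is.null(collection$metadata)) {
    utils::write.csv(collection$metadata, file.path(dir, "metadata.csv"),
                     row.names = FALSE)
  }
  if (!is.null(collection$truth)) {
    utils::write.csv(collection$truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
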