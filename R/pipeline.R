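#' Configuration for a full reference analysis run
#'
#' Defaults mirror the method's standard settings: 100 balanced
#' permutations, multiscale bootstrap over r = 0.5..1.4 step 0.1 with B =
#' 100, 95% harmonic-power threshold, and filtering cut-offs at a 0.8 median
#' posterior and a 0.5 vote fraction.
#'
#' @param synthetic a [collection_config()] to generate data, or NULL to
#'   read from `outlines_dir`/`metadata_csv`.
#' @param outlines_dir,metadata_csv input paths when `synthetic` is NULL.
#' @param models subset of `names(cofactor_models())`.
#' @param n_perm balanced permutations per model.
#' @param n_points resampled points per outline before the Fourier
#'   transform.
#' @param harmonic_threshold cumulative power threshold for harmonic
#'   calibration.
#' @param H harmonics per view (default 5, the standard configuration that
#'   yields the 40-coefficient + length feature matrix); NULL to use the
#'   calibrated value instead. The calibration table is computed and
#'   reported either way.
#' @param r_grid,B multiscale bootstrap settings.
#' @param cutoffs filter-curve cut-off grid.
#' @param node_n_perm permutations per node accuracy (defaults to `n_perm`).
#' @param out_dir output directory, or NULL to skip writing files.
#' @param seed master seed for every stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = collection_config(),
                            outlines_dir = NULL, metadata_csv = NULL,
                            models = c("use", "geo", "geo_use", "snp4",
                                       "ssr5", "status"),
                            n_perm = 100L, n_points = 300L,
                            harmonic_threshold = 0.95, H = 5L,
                            r_grid = seq(0.5, 1.4, by = 0.1), B = 100L,
                            cutoffs = seq(0, 1, by = 0.05),
                            node_n_perm = n_perm,
                            out_dir = NULL, seed = 1L) {
  known <- names(cofactor_models())
  bad <- setdiff(models, known)
  if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "))
  if (!length(models)) stop("model list is empty")
  if (is.null(synthetic) &&
      (is.null(outlines_dir) || is.null(metadata_csv))) {
    stop("either `synthetic` or both `outlines_dir` and `metadata_csv`")
  }
  structure(list(synthetic = synthetic, outlines_dir = outlines_dir,
                 metadata_csv = metadata_csv, models = models,
                 n_perm = as.integer(n_perm), n_points = as.integer(n_points),
                 harmonic_threshold = harmonic_threshold, H = H,
                 r_grid = r_grid, B = as.integer(B), cutoffs = cutoffs,
                 node_n_perm = as.integer(node_n_perm),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Scalar fields of [pipeline_config()] can be given in a YAML mapping;
#' unspecified fields keep their defaults. Synthetic-collection settings go
#' under a `synthetic:` mapping passed to [collection_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the `yaml` package is required to read YAML configurations")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synthetic)) {
    raw$synthetic <- do.call(collection_config, raw$synthetic)
  }
  do.call(pipeline_config, raw)
}

read_outline_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  if (!length(files)) stop("no outline files in ", dir)
  lapply(files, read_outline)
}

ingest_features <- function(outlines, config) {
  lengths_mm <- vapply(outlines, pip_length, 0)
  names(lengths_mm) <- vapply(outlines, function(o) o$pip_id, "")
  lengths_mm <- lengths_mm[!duplicated(names(lengths_mm))]
  reg <- lapply(outlines, function(o) {
    resample_outline(bookstein_register(o), config$n_points)
  })
  calib <- calibrate_harmonics(reg, threshold = config$harmonic_threshold)
  H <- if (is.null(config$H)) calib$chosen_H else {
    h <- config$H
    if (length(h) == 1L) c(dorsal = h, lateral = h) else h
  }
  feats <- build_feature_matrix(reg, lengths_mm, H = H)
  list(features = feats, calibration = calib, H = H, lengths_mm = lengths_mm)
}

write_csv_out <- function(df, dir, name, manifest) {
  if (is.null(dir)) return(manifest)
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  c(manifest, name)
}

#' Run the full reference analysis
#'
#' Executes the chain: ingest (or synthesise) outlines, Bookstein-register
#' and resample, calibrate harmonic count, build the coefficient + length
#' feature matrix, PCA with variety centroids, and, per cofactor model, the
#' group-mean correlation-distance UPGMA tree with multiscale-bootstrap AU
#' support and per-node cross-validated accuracies, the balanced LDA
#' ensemble with its shuffled-label null and median confusion matrix, and
#' posterior/vote filter curves. All artifacts are written under
#' `config$out_dir` (when set) along with a JSON manifest recording seeds
#' and counts.
#'
#' @param config a [pipeline_config()].
#' @return List of class `pipeline_run` with elements `features`,
#'   `calibration`, `pca`, `centroids`, `models` (per model: labels, tree,
#'   support, ensemble, confusion, curves), `metadata`, `pip_table`,
#'   `manifest`.
#' @export
run_reference_analysis <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  manifest_files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  # --- data ---
  if (!is.null(config$synthetic)) {
    coll <- stage("synthesise", generate_reference(config$synthetic))
    outlines <- coll$outlines
    meta <- coll$metadata
    pip_table <- coll$pips
  } else {
    outlines <- stage("ingest", read_outline_dir(config$outlines_dir))
    meta <- stage("ingest", utils::read.csv(config$metadata_csv,
                                            stringsAsFactors = FALSE))
    ids <- unique(vapply(outlines, function(o) o$pip_id, ""))
    pip_table <- data.frame(pip_id = ids,
                            cultivar_id = sub("_P[0-9]+$", "", ids),
                            stringsAsFactors = FALSE)
  }
  ing <- stage("features", ingest_features(outlines, config))
  feats <- ing$features
  pip_table <- pip_table[match(rownames(feats), pip_table$pip_id), ]
  meta_by_pip <- meta[match(pip_table$cultivar_id, meta$cultivar_id), ]
  # --- morphospace ---
  pca <- stage("pca", pip_pca(feats))
  centroids <- stage("pca", variety_centroids(pca, pip_table$cultivar_id))
  manifest_files <- write_csv_out(
    data.frame(pip_id = rownames(feats), pca$scores[, 1:2]),
    config$out_dir, "pca_scores.csv", manifest_files)
  manifest_files <- write_csv_out(centroids, config$out_dir,
                                  "variety_centroids.csv", manifest_files)
  manifest_files <- write_csv_out(
    data.frame(axis = seq_along(pca$variance_ratio),
               variance_ratio = pca$variance_ratio),
    config$out_dir, "pca_scree.csv", manifest_files)
  manifest_files <- write_csv_out(ing$calibration$table, config$out_dir,
                                  "harmonic_calibration.csv", manifest_files)
  # --- per-model trees + ensembles ---
  defs <- cofactor_models()[config$models]
  models <- list()
  for (mod in names(defs)) {
    labels <- defs[[mod]](meta_by_pip)
    if (length(unique(stats::na.omit(labels))) < 2L) {
      message("model `", mod, "` skipped: fewer than 2 classes present")
      next
    }
    entry <- list(labels = labels)
    k <- length(unique(stats::na.omit(labels)))
    if (k >= 4L) {
      gm <- stage(mod, group_mean_matrix(feats, labels))
      tree <- stage(mod, upgma(correlation_distance(gm)))
      support <- stage(mod, multiscale_bootstrap_au(
        gm, tree, r_grid = config$r_grid, B = config$B,
        seed = config$seed + 101L))
      sets <- hclust_leaf_sets(tree)
      cv <- rep(NA_real_, length(sets))
      for (i in seq_along(sets)) {
        if (length(sets[[i]]) >= length(tree$labels)) next  # root: no split
        cv[i] <- stage(mod, node_accuracy(
          feats, labels, sets[[i]], n_perm = config$node_n_perm,
          seed = config$seed + 202L + i))
      }
      support$nodes$cv_accuracy <- cv
      entry$tree <- tree
      entry$support <- support
      if (!is.null(config$out_dir)) {
        nw <- paste0("tree_", mod, ".nwk")
        export_newick(support, file.path(config$out_dir, nw))
        manifest_files <- c(manifest_files, nw)
        manifest_files <- write_csv_out(support$nodes, config$out_dir,
                                        paste0("nodes_", mod, ".csv"),
                                        manifest_files)
      }
    }
    ens <- stage(mod, balanced_ensemble(feats, labels,
                                        n_perm = config$n_perm,
                                        seed = config$seed + 303L))
    conf <- confusion_summary(ens)
    pcurve <- stage(mod, posterior_filter_curve(ens, feats, labels,
                                                config$cutoffs))
    vcurve <- stage(mod, vote_filter_curve(ens, feats, labels,
                                           config$cutoffs))
    entry$ensemble <- ens
    entry$confusion <- conf
    entry$posterior_curve <- pcurve
    entry$vote_curve <- vcurve
    manifest_files <- write_csv_out(
      as.data.frame(conf$matrix), config$out_dir,
      paste0("confusion_", mod, ".csv"), manifest_files)
    manifest_files <- write_csv_out(
      data.frame(class = ens$labels,
                 median_accuracy = conf$class_accuracy,
                 null_max = conf$null_max,
                 significant = conf$significant),
      config$out_dir, paste0("class_accuracy_", mod, ".csv"),
      manifest_files)
    manifest_files <- write_csv_out(pcurve, config$out_dir,
                                    paste0("filter_posterior_", mod, ".csv"),
                                    manifest_files)
    manifest_files <- write_csv_out(vcurve, config$out_dir,
                                    paste0("filter_vote_", mod, ".csv"),
                                    manifest_files)
    models[[mod]] <- entry
  }
  manifest <- list(
    seed = config$seed, n_perm = config$n_perm,
    n_pips = nrow(feats), n_cultivars = length(unique(pip_table$cultivar_id)),
    chosen_H = as.list(ing$H), models = names(models),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = manifest_files)
  if (!is.null(config$out_dir)) {
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(features = feats, calibration = ing$calibration,
                 H = ing$H, lengths_mm = ing$lengths_mm, pca = pca,
                 centroids = centroids, models = models, metadata = meta,
                 pip_table = pip_table, manifest = manifest,
                 config = config),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d pips x %d features; models: %s\n",
              nrow(x$features), ncol(x$features),
              paste(names(x$models), collapse = ", ")))
  invisible(x)
}

#' Two-stage inference on archaeological assemblages from a trained run
#'
#' Registers, resamples and transforms the assemblage outlines with the
#' harmonic counts of the trained run, then applies the wild/domesticated
#' status ensemble followed by every trained cofactor ensemble
#' ([archaeo_inference()]).
#'
#' @param trained_run a [run_reference_analysis()] result that includes the
#'   `status` model.
#' @param assemblages list of assemblage collections (as returned by
#'   [generate_assemblage()], or lists with `outlines` and `phase`).
#' @param out_dir optional output directory for the report CSV/JSON.
#' @return An `archaeo_report` (invisible file paths noted in attributes
#'   when written).
#' @export
run_archaeo_inference <- function(trained_run, assemblages, out_dir = NULL) {
  stopifnot(inherits(trained_run, "pipeline_run"))
  if (is.null(trained_run$models$status)) {
    stop("trained run lacks the `status` model")
  }
  phases <- list()
  cfg <- trained_run$config
  for (a in assemblages) {
    if (!length(a$outlines)) stop("assemblage `", a$phase, "` is empty")
    ing <- ingest_features(a$outlines,
                           list(n_points = cfg$n_points,
                                harmonic_threshold = cfg$harmonic_threshold,
                                H = trained_run$H))
    if (!identical(colnames(ing$features), colnames(trained_run$features))) {
      stop("assemblage feature schema does not match the trained run")
    }
    phases[[a$phase]] <- list(x = ing$features, lengths_mm = ing$lengths_mm)
  }
  cof <- trained_run$models[setdiff(names(trained_run$models), "status")]
  report <- archaeo_inference(
    trained_run$models$status$ensemble,
    lapply(cof, `[[`, "ensemble"),
    phases)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    props <- do.call(rbind, lapply(report, `[[`, "proportions"))
    utils::write.csv(props, file.path(out_dir, "archaeo_proportions.csv"),
                     row.names = FALSE)
    summ <- lapply(report, function(e) e[setdiff(names(e), "proportions")])
    jsonlite::write_json(summ, file.path(out_dir, "archaeo_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
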