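#' Pipeline run configuration
#'
#' Collects every stage parameter of the synth -> extract -> select ->
#' split -> train -> evaluate -> compile -> infer pipeline, materializing
#' all defaults so the resulting manifest records exactly what was run.
#'
#' @param out_dir Output directory for all artifacts.
#' @param n_classes 2 or 4 (used when `specs` is `NULL`).
#' @param specs List of [class_spec()]; defaults to
#'   `default_class_specs(n_classes)`.
#' @param n_per_class Blocks generated per class.
#' @param size Block side length in pixels.
#' @param data_seed Seed for the synthetic data stage.
#' @param glcm_levels Gray-level count for all co-occurrence matrices.
#' @param selection `"cfs"`, `"pca"` or `"none"`.
#' @param variance_kept PCA variance fraction (when `selection = "pca"`).
#' @param algorithm Tree algorithm: `"j48"`, `"rep"` or `"rt"`.
#' @param split_seed Seed of the stratified 60/20/20 split.
#' @param control [tree_control()] parameters.
#' @param band Fuzzy transition half-width fraction.
#' @param write_blocks Also write the generated blocks as PNGs?
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("fuzzyweed_run_"),
                       n_classes = 2, specs = NULL, n_per_class = 50,
                       size = 100, data_seed = 1, glcm_levels = 8,
                       selection = c("cfs", "pca", "none"),
                       variance_kept = 0.95,
                       algorithm = c("j48", "rep", "rt"), split_seed = 1,
                       control = tree_control(), band = 0.05,
                       write_blocks = FALSE) {
  structure(list(out_dir = out_dir, n_classes = n_classes,
                 specs = specs %||% default_class_specs(n_classes),
                 n_per_class = n_per_class, size = size,
                 data_seed = data_seed, glcm_levels = glcm_levels,
                 selection = match.arg(selection),
                 variance_kept = variance_kept,
                 algorithm = match.arg(algorithm), split_seed = split_seed,
                 control = control, band = band,
                 write_blocks = write_blocks),
            class = "run_config")
}

#' Run the full classification pipeline
#'
#' Executes every stage in order on synthetic data, writing `features.csv`,
#' `selected.csv`, `model.tree.json`, `model.fis.json`, `predictions.csv`,
#' `report.txt` and `manifest.json` into the configured output directory.
#' Each stage logs the parameters it actually used (including defaults) to
#' `run.log`; a stage failure aborts with the stage name while retaining
#' the artifacts already written.
#'
#' @param config A [run_config()].
#' @return Object of class `run_manifest` (invisibly written as
#'   `manifest.json`): the config snapshot, package version, per-file MD5
#'   checksums, and the evaluation metrics.
#' @export
#' @examples
#' \donttest{
#' man <- run_pipeline(run_config(n_per_class = 6, size = 32))
#' man$metrics$test_accuracy
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$out_dir, "run.log")
  log_line <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = logfile, append = TRUE, sep = "")
    message(msg)
  }
  stage <- function(name, expr) {
    log_line("[%s] start", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  metrics <- list()

  dataset <- stage("synth", {
    log_line("[synth] %d classes x %d blocks of %dx%d px, seed %d",
             length(config$specs), config$n_per_class, config$size,
             config$size, config$data_seed)
    d <- generate_dataset(config$specs, config$n_per_class, config$size,
                          config$data_seed)
    if (config$write_blocks)
      write_dataset(d, file.path(config$out_dir, "blocks"))
    d
  })

  features <- stage("extract", {
    log_line("[extract] glcm_levels = %d", config$glcm_levels)
    f <- extract_features(dataset, glcm_levels = config$glcm_levels)
    utils::write.csv(f, file.path(config$out_dir, "features.csv"),
                     row.names = FALSE)
    f
  })

  selected <- stage("select", {
    log_line("[select] method = %s", config$selection)
    out <- switch(config$selection,
      cfs = {
        sel <- cfs_select(features)
        log_line("[select] CFS kept %d feature(s), merit %.4f: %s",
                 length(sel$selected), sel$merit,
                 paste(sel$selected, collapse = ", "))
        features[c("class", sel$selected)]
      },
      pca = {
        red <- pca_reduce(features, variance_kept = config$variance_kept)
        log_line("[select] PCA kept %d component(s) (%.1f%% variance)",
                 red$n_components, 100 * red$cum_variance)
        red$scores[c("class", setdiff(names(red$scores), "class"))]
      },
      none = features)
    utils::write.csv(out, file.path(config$out_dir, "selected.csv"),
                     row.names = FALSE)
    out
  })

  split <- stage("split", {
    log_line("[split] stratified 60/20/20, seed %d", config$split_seed)
    split_data(selected, seed = config$split_seed)
  })

  tree <- stage("train", {
    log_line("[train] algorithm = %s, min_leaf = %d, cf = %s",
             config$algorithm, config$control$min_leaf,
             format(config$control$cf))
    t <- weed_tree(class ~ ., split$train, algorithm = config$algorithm,
                   validation = split$validation, seed = config$split_seed,
                   control = config$control)
    write_tree(t, file.path(config$out_dir, "model.tree.json"))
    t
  })

  stage("evaluate", {
    ev_tr <- evaluate(tree, split$train)
    ev_te <- evaluate(tree, split$test)
    metrics <- list(train_accuracy = ev_tr$accuracy,
                    train_kappa = ev_tr$kappa, train_rmse = ev_tr$rmse,
                    test_accuracy = ev_te$accuracy,
                    test_kappa = ev_te$kappa, test_rmse = ev_te$rmse,
                    n_leaves = n_leaves(tree), n_nodes = n_nodes(tree))
    rpt <- file.path(config$out_dir, "report.txt")
    writeLines(c(utils::capture.output(print(tree)), "", "Training set:",
                 utils::capture.output(print(ev_tr)), "", "Test set:",
                 utils::capture.output(print(ev_te))), rpt)
    log_line("[evaluate] test accuracy %.4f, kappa %.4f, rmse %.4f",
             ev_te$accuracy, ev_te$kappa, ev_te$rmse)
  })

  fis <- stage("compile-fis", {
    log_line("[compile-fis] band = %.3f", config$band)
    if (tree$root$type == "leaf") {
      log_line("[compile-fis] skipped: tree is a single leaf")
      NULL
    } else {
      f <- as_fis(tree, band = config$band)
      write_fis(f, file.path(config$out_dir, "model.fis.json"))
      f
    }
  })

  stage("infer", {
    if (is.null(fis)) {
      log_line("[infer] skipped: no fuzzy model")
    } else {
      pred <- predict(fis, split$test)
      out <- data.frame(crisp_output = pred$crisp, class = pred$class,
                        observed = split$test$class)
      utils::write.csv(out, file.path(config$out_dir, "predictions.csv"),
                       row.names = FALSE)
      agree <- mean(as.character(pred$class) ==
                      as.character(predict(tree, split$test)))
      metrics$fis_accuracy <- mean(as.character(pred$class) ==
                                     as.character(split$test$class))
      metrics$fis_tree_agreement <- agree
      log_line("[infer] fuzzy accuracy %.4f, tree agreement %.4f",
               metrics$fis_accuracy, agree)
    }
  })

  arts <- c("features.csv", "selected.csv", "model.tree.json",
            "model.fis.json", "predictions.csv", "report.txt")
  arts <- arts[file.exists(file.path(config$out_dir, arts))]
  checksums <- as.list(tools::md5sum(file.path(config$out_dir, arts)))
  names(checksums) <- arts

  manifest <- structure(list(
    config = serialize_config(config),
    package_version = as.character(utils::packageVersion("fuzzyweed")),
    checksums = checksums, metrics = metrics),
    class = "run_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' @noRd
serialize_config <- function(config) {
  c <- unclass(config)
  c$specs <- lapply(c$specs, unclass)
  c$control <- unclass(c$control)
  c
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run manifest\n")
  cat(sprintf("  algorithm: %s-%s | blocks: %d x %d classes\n",
              toupper(x$config$algorithm), toupper(x$config$selection),
              x$config$n_per_class, length(x$config$specs)))
  for (m in names(x$metrics))
    cat(sprintf("  %s: %s\n", m, format(x$metrics[[m]], digits = 4)))
  invisible(x)
}
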