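#' Train a deployable trophic-mode model bundle
#'
#' Fits the min-max scaler on the training profiles restricted to the selected
#' feature Pfams, trains the gradient-boosting classifier on the scaled (or
#' binarized) values, and packages everything needed to score new profiles:
#' the feature list, the scaler, the classifier, the hyperparameters, and a
#' training manifest (class counts, seed, mode).
#'
#' @param lp A [labeled_profiles()] object holding raw TPM values.
#' @param features Character vector of feature Pfam accessions (typically from
#'   [select_features()]); profiles are zero-filled to this list.
#' @param hyperparams Classifier hyperparameters.
#' @param binarize_input If `TRUE`, expression is converted to presence/
#'   absence instead of min-max scaled.
#' @param seed Seed recorded in the manifest (training itself is
#'   deterministic).
#' @return An object of class `trophic_model_bundle`.
#' @export
train_trophic_model <- function(lp, features, hyperparams = default_hyperparams(),
                                binarize_input = FALSE, seed = NA) {
  stopifnot(inherits(lp, "labeled_profiles"), length(features) > 0)
  x <- align_features(lp$x, features)
  scaler <- fit_scaler(x)
  x_in <- if (binarize_input) binarize(x) else apply_scaler(x, scaler)
  clf <- fit_trophic_classifier(x_in, lp$label, hyperparams)
  structure(
    list(
      features = features,
      scaler = scaler,
      classifier = clf,
      hyperparams = hyperparams,
      binarize_input = binarize_input,
      manifest = list(
        class_counts = as.list(table(lp$label)),
        n_features = length(features),
        seed = seed,
        package_version = as.character(utils::packageVersion("protroph"))
      )
    ),
    class = "trophic_model_bundle"
  )
}

#' @export
print.trophic_model_bundle <- function(x, ...) {
  cat("<trophic_model_bundle> ", length(x$features), " feature Pfams; input: ",
      if (x$binarize_input) "binary" else "min-max scaled TPM", "\n", sep = "")
  invisible(x)
}

# Zero-fill/reorder a matrix to a fixed feature list.
align_features <- function(x, features) {
  out <- matrix(0, nrow = nrow(x), ncol = length(features),
                dimnames = list(rownames(x), features))
  shared <- intersect(colnames(x), features)
  out[, shared] <- x[, shared, drop = FALSE]
  out
}

#' Save / load a model bundle as a directory of text artifacts
#'
#' The bundle directory contains `features.txt` (one accession per line),
#' `scaler.tsv`, `config.json` (hyperparameters, input mode, manifest), and
#' `classifier.json` (the boosted-tree model in xgboost's JSON format).
#'
#' @param bundle A `trophic_model_bundle`.
#' @param dir Directory to create/populate.
#' @return `save_model_bundle()` returns `dir` invisibly;
#'   `load_model_bundle()` returns the restored bundle.
#' @export
save_model_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "trophic_model_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(bundle$features, file.path(dir, "features.txt"))
  readr::write_tsv(bundle$scaler$params, file.path(dir, "scaler.tsv"))
  jsonlite::write_json(
    list(
      hyperparams = bundle$hyperparams,
      binarize_input = bundle$binarize_input,
      manifest = bundle$manifest
    ),
    file.path(dir, "config.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  xgboost::xgb.save(bundle$classifier$model, file.path(dir, "classifier.json"))
  invisible(dir)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(dir) {
  needed <- file.path(dir, c("features.txt", "scaler.tsv", "config.json",
                             "classifier.json"))
  if (!all(file.exists(needed))) {
    stop("not a model bundle directory (missing ",
         paste(basename(needed)[!file.exists(needed)], collapse = ", "),
         "): ", dir)
  }
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  scaler <- structure(
    list(params = readr::read_tsv(file.path(dir, "scaler.tsv"),
                                  show_col_types = FALSE)),
    class = "trophic_scaler"
  )
  model <- xgboost::xgb.load(file.path(dir, "classifier.json"))
  structure(
    list(
      features = readLines(file.path(dir, "features.txt")),
      scaler = scaler,
      classifier = list(model = model, classes = TROPHIC_MODES),
      hyperparams = as.list(cfg$hyperparams),
      binarize_input = isTRUE(cfg$binarize_input),
      manifest = cfg$manifest
    ),
    class = "trophic_model_bundle"
  )
}
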