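# R-side wrapper around the compiled gradient-boosted tree learner, plus
# bundle serialization. Bundles are plain JSON (numbers stored as %.17g
# strings) so a save/load round trip reproduces predictions bit for bit.

#' Gradient-boosting configuration
#'
#' @param nrounds Number of boosting rounds.
#' @param eta Learning rate.
#' @param max_depth Maximum tree depth.
#' @param lambda L2 regularisation on leaf weights.
#' @param min_child_weight Minimum hessian sum per child.
#' @param monotone Optional named integer vector (+1/-1 per feature name)
#'   of monotonicity constraints; unnamed features are unconstrained.
#' @return A `gbt_config` list.
#' @export
gbt_config <- function(nrounds = 50L, eta = 0.3, max_depth = 4L,
                       lambda = 1.0, min_child_weight = 1.0,
                       monotone = NULL) {
  structure(list(nrounds = as.integer(nrounds), eta = eta,
                 max_depth = as.integer(max_depth), lambda = lambda,
                 min_child_weight = min_child_weight,
                 monotone = monotone),
            class = "gbt_config")
}

# Fit the boosted-tree classifier on a numeric matrix with NAs allowed.
gbt_fit <- function(X, y, config = gbt_config()) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  mono <- integer(0)
  if (!is.null(config$monotone)) {
    mono <- integer(ncol(X))
    hit <- match(names(config$monotone), colnames(X))
    mono[hit[!is.na(hit)]] <- as.integer(
      config$monotone[!is.na(hit)])
  }
  forest <- gbt_fit_cpp(X, as.numeric(y), config$nrounds, config$eta,
                        config$max_depth, config$lambda,
                        config$min_child_weight, mono, 0.0)
  structure(list(forest = forest, feature_names = colnames(X),
                 config = config, base_margin = 0.0),
            class = "gbt_model")
}

# Predicted probabilities; columns of `X` must match the stored names.
gbt_predict <- function(model, X) {
  X <- align_features(X, model$feature_names)
  plogis(gbt_predict_cpp(model$forest, X, model$base_margin))
}

# Reorder matrix/data-frame columns to `features`; error on any mismatch.
align_features <- function(X, features) {
  if (is.data.frame(X)) X <- as.matrix(X[, , drop = FALSE])
  miss <- setdiff(features, colnames(X))
  if (length(miss)) {
    stop("feature missing from prediction input: ", miss[1L],
         call. = FALSE)
  }
  X[, features, drop = FALSE]
}

#' Save / load a trained model bundle
#'
#' The bundle is a self-describing JSON archive: tree structure, ordered
#' feature names, training configuration, seed, and the registry
#' fingerprint. Numeric values are stored with 17 significant digits so
#' that reloaded bundles give byte-identical predictions.
#'
#' @param bundle A model bundle from [train_ts()] or [train_tm()].
#' @param path Output JSON path.
#' @return `read_bundle` returns the bundle.
#' @export
write_bundle <- function(bundle, path) {
  enc_tree <- function(tr) {
    list(feature = tr$feature, threshold = num_encode(tr$threshold),
         default_left = tr$default_left, left = tr$left, right = tr$right,
         value = num_encode(tr$value))
  }
  cfg <- bundle$model$config
  payload <- list(
    package = "mirtarscan", bundle_version = 1L, stage = bundle$stage,
    feature_names = bundle$feature_names,
    registry_fingerprint = bundle$registry_fingerprint,
    seed = bundle$seed,
    config = list(nrounds = cfg$nrounds, eta = num_encode(cfg$eta),
                  max_depth = cfg$max_depth,
                  lambda = num_encode(cfg$lambda),
                  min_child_weight = num_encode(cfg$min_child_weight),
                  monotone = as.list(cfg$monotone %||% integer(0))),
    base_margin = num_encode(bundle$model$base_margin),
    trees = lapply(bundle$model$forest, enc_tree))
  jsonlite::write_json(payload, path, auto_unbox = FALSE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec_tree <- function(tr) {
    list(feature = as.integer(tr$feature),
         threshold = num_decode(tr$threshold),
         default_left = as.integer(tr$default_left),
         left = as.integer(tr$left), right = as.integer(tr$right),
         value = num_decode(tr$value))
  }
  mono <- unlist(p$config$monotone)
  cfg <- gbt_config(nrounds = p$config$nrounds,
                    eta = num_decode(p$config$eta),
                    max_depth = p$config$max_depth,
                    lambda = num_decode(p$config$lambda),
                    min_child_weight = num_decode(p$config$min_child_weight),
                    monotone = if (length(mono)) mono else NULL)
  trees <- if (is.data.frame(p$trees)) {
    lapply(seq_len(nrow(p$trees)), function(i)
      dec_tree(lapply(p$trees, function(col) col[[i]])))
  } else {
    lapply(p$trees, dec_tree)
  }
  model <- structure(list(forest = trees,
                          feature_names = p$feature_names,
                          config = cfg,
                          base_margin = num_decode(p$base_margin)),
                     class = "gbt_model")
  structure(list(model = model, feature_names = p$feature_names,
                 config = cfg, seed = p$seed, stage = p$stage,
                 registry_fingerprint = p$registry_fingerprint),
            class = "model_bundle")
}

#' Permutation feature importance
#'
#' Drop in predictive AUC when one feature column is shuffled; a generic
#' model-interpretation report.
#'
#' @param bundle A trained model bundle.
#' @param X Feature data (matrix or data frame with the bundle's columns).
#' @param y Binary labels.
#' @param n_perm Number of permutations per feature.
#' @param seed RNG seed.
#' @return Data frame `feature`, `importance` (mean AUC drop), sorted
#'   decreasing.
#' @export
permutation_importance <- function(bundle, X, y, n_perm = 5L, seed = 1L) {
  X <- align_features(X, bundle$feature_names)
  base <- compute_metrics(y, gbt_predict(bundle$model, X))$auc
  imp <- vapply(seq_along(bundle$feature_names), function(j) {
    drops <- vapply(seq_len(n_perm), function(r) {
      Xp <- X
      Xp[, j] <- with_rng(derive_seed(seed, j * 131L + r),
                          sample(Xp[, j]))
      base - compute_metrics(y, gbt_predict(bundle$model, Xp))$auc
    }, numeric(1L))
    mean(drops)
  }, numeric(1L))
  out <- data.frame(feature = bundle$feature_names, importance = imp,
                    stringsAsFactors = FALSE)
  out[order(-out$importance), , drop = FALSE]
}
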