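# Site-level (TS) classifier: cross-validation, MCC-driven forward
# stepwise greedy feature selection, training, and binding-confidence
# prediction.

#' Stratified k-fold cross-validation of the boosted-tree classifier
#'
#' Folds are stratified by label and deterministic given `seed`; every
#' sample is tested exactly once. The summary is the unweighted mean and
#' sd of each metric across folds.
#'
#' @param X Numeric feature matrix (named columns; NAs allowed).
#' @param y Binary labels.
#' @param k Number of folds (>= 2).
#' @param config A [gbt_config()].
#' @param seed Integer seed controlling fold assignment.
#' @param threshold Classification threshold for the threshold metrics.
#' @return List `per_fold` (list of `metrics_report`), `mean`, `sd`,
#'   `folds` (the fold assignment vector).
#' @export
cross_validate <- function(X, y, k = 10L, config = gbt_config(),
                           seed = 1L, threshold = 0.5) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  fold <- stratified_folds(y, k, seed)
  reports <- lapply(seq_len(k), function(f) {
    tr <- fold != f
    model <- gbt_fit(X[tr, , drop = FALSE], y[tr], config)
    p <- gbt_predict(model, X[!tr, , drop = FALSE])
    compute_metrics(y[!tr], p, threshold)
  })
  s <- summarise_metrics(reports)
  list(per_fold = reports, mean = s$mean, sd = s$sd, folds = fold)
}

#' MCC-driven forward stepwise greedy feature selection
#'
#' Starts from the empty set; at each iteration every remaining candidate
#' is added in turn to the current set, the model is scored by mean
#' cross-validated MCC, and the best feature is kept. Ties are broken by
#' candidate (registry) order. Selection stops at `max_features` or when
#' the best gain falls below `min_gain`.
#'
#' @param X Numeric feature matrix.
#' @param y Binary labels.
#' @param candidates Candidate feature names in registry order; defaults
#'   to all columns of `X`.
#' @param k Folds for the internal cross-validation (default 10).
#' @param seed Seed for the fold assignment (fixed across the whole
#'   selection run so feature scores are comparable).
#' @param config A [gbt_config()]; the default here uses fewer, shallower
#'   trees than [train_ts()] since thousands of fits are made.
#' @param max_features Cap on the number of selected features (default
#'   22).
#' @param min_gain Minimum CV-MCC improvement to keep adding features.
#' @return Data frame `feature`, `cv_mcc`: the selection trajectory in
#'   order of inclusion.
#' @export
greedy_forward_selection <- function(X, y, candidates = colnames(X),
                                     k = 10L, seed = 1L,
                                     config = gbt_config(nrounds = 20L,
                                                         max_depth = 3L),
                                     max_features = 22L,
                                     min_gain = 1e-4) {
  if (length(candidates) < 1L) stop("no candidate features", call. = FALSE)
  cols <- match(candidates, colnames(X))
  if (anyNA(cols)) {
    stop("unknown feature name: ", candidates[is.na(cols)][1L],
         call. = FALSE)
  }
  fold <- stratified_folds(y, k, seed)
  eval_sets <- function(sets) {
    gbt_cv_mcc_cpp(X, as.numeric(y), fold, k, sets, config$nrounds,
                   config$eta, config$max_depth, config$lambda,
                   config$min_child_weight)
  }
  selected <- integer(0)
  scores <- numeric(0)
  remaining <- cols
  last <- -Inf
  while (length(selected) < max_features && length(remaining) > 0L) {
    cand_scores <- eval_sets(lapply(remaining, function(j)
      c(selected, j)))
    best <- which(cand_scores >= max(cand_scores) - 1e-12)[1L]
    best_s <- cand_scores[best]
    if (length(selected) > 0L && best_s - last < min_gain) break
    selected <- c(selected, remaining[best])
    scores <- c(scores, best_s)
    remaining <- remaining[-best]
    last <- best_s
  }
  selected <- colnames(X)[selected]
  data.frame(feature = selected, cv_mcc = scores,
             stringsAsFactors = FALSE)
}

#' Train the site-level (TS) binding classifier
#'
#' @param X Numeric feature matrix (named columns; NAs handled
#'   internally by the learner).
#' @param y Binary labels (1 = interaction).
#' @param features Feature names to train on (order is stored in the
#'   bundle and enforced at prediction).
#' @param config A [gbt_config()].
#' @param seed Recorded in the bundle for provenance (the learner itself
#'   is deterministic).
#' @return A `model_bundle` with elements `model`, `feature_names`,
#'   `config`, `seed`, `registry_fingerprint`.
#' @export
train_ts <- function(X, y, features = colnames(X),
                     config = gbt_config(), seed = 1L) {
  miss <- setdiff(features, colnames(X))
  if (length(miss)) stop("unknown feature name: ", miss[1L], call. = FALSE)
  model <- gbt_fit(X[, features, drop = FALSE], y, config)
  structure(list(model = model, feature_names = features,
                 config = config, seed = seed, stage = "TS",
                 registry_fingerprint = text_fingerprint(features)),
            class = "model_bundle")
}

#' Score candidate sites with a trained TS bundle
#'
#' @param bundle A TS `model_bundle`.
#' @param sites_features Feature matrix or featurized data frame holding
#'   exactly the bundle's feature columns.
#' @return Numeric vector of binding confidences in \[0, 1\], input order
#'   preserved; empty input gives an empty vector.
#' @export
predict_sites <- function(bundle, sites_features) {
  if (is.data.frame(sites_features)) {
    miss <- setdiff(bundle$feature_names, names(sites_features))
    if (length(miss)) {
      stop("feature missing from prediction input: ", miss[1L],
           call. = FALSE)
    }
    sites_features <- as.matrix(
      sites_features[, bundle$feature_names, drop = FALSE])
  }
  if (nrow(sites_features) == 0L) return(numeric(0))
  X <- align_features(sites_features, bundle$feature_names)
  gbt_predict(bundle$model, X)
}
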