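# Transcript-level (TM) repression model: aggregation of per-site binding
# confidences into four features (sum, top-1/2/3) and the repression
# classifier emitting an interaction confidence.

#' Aggregate per-site binding probabilities
#'
#' @param probabilities Numeric vector of site probabilities in \[0, 1\].
#' @return Named numeric `sum_p`, `top1`, `top2`, `top3`. Fewer than three
#'   sites leave the corresponding top-k entries missing; zero sites give
#'   `(0, NA, NA, NA)`. Missing entries stay missing (the classifier
#'   handles them internally) — they are not imputed as 0, which would
#'   conflate "no site" with "a site of probability 0".
#' @export
aggregate_site_probs <- function(probabilities) {
  if (length(probabilities) &&
      (anyNA(probabilities) || any(probabilities < 0 | probabilities > 1))) {
    stop("site probabilities must be in [0, 1]", call. = FALSE)
  }
  s <- sort(probabilities, decreasing = TRUE)
  c(sum_p = sum(probabilities),
    top1 = if (length(s) >= 1L) s[1L] else NA_real_,
    top2 = if (length(s) >= 2L) s[2L] else NA_real_,
    top3 = if (length(s) >= 3L) s[3L] else NA_real_)
}

#' Build the transcript-level (TM) dataset
#'
#' For each labelled (miRNA, gene) pair: the gene is resolved to its
#' longest-UTR transcript, all canonical sites are scanned and scored with
#' the TS bundle, and the per-site probabilities aggregated. Pairs whose
#' gene cannot be resolved are reported and skipped.
#'
#' @param ts_bundle Trained TS `model_bundle`.
#' @param mirnas A `mirna_set`.
#' @param utrs A `utr_set` with gene ids.
#' @param tm_labels Data frame `mirna_id`, `gene_id`, `label`
#'   (`"repressed"`/`"unaffected"`), e.g. from
#'   [label_tm_from_expression()].
#' @param conservation,snps Optional resources passed to the featurizer.
#' @param registry Registry used to featurize (only the families needed by
#'   the bundle's features are computed).
#' @param flank Scanner flank.
#' @return Data frame `mirna_id`, `gene_id`, `transcript_id`, `n_sites`,
#'   `sum_p`, `top1`, `top2`, `top3`, `label`; attribute `"skipped"` lists
#'   unresolvable pairs.
#' @export
build_tm_dataset <- function(ts_bundle, mirnas, utrs, tm_labels,
                             conservation = NULL, snps = NULL,
                             registry = default_registry(), flank = 20L) {
  reg <- registry_subset(registry, ts_bundle$feature_names)
  # keep whole families so the featurizer contract (family membership)
  # stays intact
  fams <- unique(reg$features$family)
  reg_full <- default_registry(families = fams, config = registry$config)
  resolved <- lapply(seq_len(nrow(tm_labels)), function(i) {
    tryCatch({
      tr <- resolve_gene_to_longest_transcript(tm_labels$gene_id[i], utrs)
      data.frame(mirna_id = tm_labels$mirna_id[i],
                 gene_id = tm_labels$gene_id[i],
                 transcript_id = tr$transcript_id,
                 label = tm_labels$label[i], stringsAsFactors = FALSE)
    }, error = function(e) NULL)
  })
  skipped <- tm_labels[vapply(resolved, is.null, logical(1L)), ,
                       drop = FALSE]
  pairs <- do.call(rbind, resolved)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    stop("no resolvable (miRNA, gene) pairs", call. = FALSE)
  }
  sites <- scan_corpus(mirnas, utrs,
                       pairs = pairs[, c("mirna_id", "transcript_id")],
                       flank = flank)
  agg <- matrix(NA_real_, nrow = nrow(pairs), ncol = 4L,
                dimnames = list(NULL, c("sum_p", "top1", "top2", "top3")))
  n_sites <- integer(nrow(pairs))
  if (nrow(sites) > 0L) {
    feats <- featurize_sites(sites, mirnas, utrs,
                             conservation = conservation, snps = snps,
                             registry = reg_full)
    p <- predict_sites(ts_bundle, feats)
    skey <- paste(sites$mirna_id, sites$transcript_id, sep = "\r")
    pkey <- paste(pairs$mirna_id, pairs$transcript_id, sep = "\r")
    by_pair <- split(p, factor(skey, levels = unique(pkey)))
    for (i in seq_len(nrow(pairs))) {
      pp <- by_pair[[pkey[i]]] %||% numeric(0)
      agg[i, ] <- aggregate_site_probs(pp)
      n_sites[i] <- length(pp)
    }
  } else {
    for (i in seq_len(nrow(pairs))) agg[i, ] <- aggregate_site_probs(numeric(0))
  }
  out <- cbind(pairs[, c("mirna_id", "gene_id", "transcript_id")],
               n_sites = n_sites, as.data.frame(agg),
               label = pairs$label)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Train the transcript-level (TM) repression classifier
#'
#' @param tm_dataset Output of [build_tm_dataset()] (or any data frame
#'   with `sum_p`, `top1`, `top2`, `top3` and a `label` column).
#' @param config A [gbt_config()]; set
#'   `monotone = c(sum_p = 1, top1 = 1, top2 = 1, top3 = 1)` to enforce
#'   that higher site probabilities never lower the repression score
#'   (off by default).
#' @param seed Provenance seed stored in the bundle.
#' @param features Aggregation features to use.
#' @return A TM `model_bundle`.
#' @export
train_tm <- function(tm_dataset,
                     config = gbt_config(nrounds = 50L, max_depth = 3L),
                     seed = 1L,
                     features = c("sum_p", "top1", "top2", "top3")) {
  y <- as.integer(tm_dataset$label == "repressed")
  if (length(unique(y)) < 2L) stop("both TM labels required", call. = FALSE)
  X <- as.matrix(tm_dataset[, features, drop = FALSE])
  model <- gbt_fit(X, y, config)
  structure(list(model = model, feature_names = features,
                 config = config, seed = seed, stage = "TM",
                 registry_fingerprint = text_fingerprint(features)),
            class = "model_bundle")
}

#' Interaction confidence for (miRNA, transcript) examples
#'
#' @param bundle A TM `model_bundle`.
#' @param examples Data frame or matrix with the bundle's aggregation
#'   feature columns.
#' @return Numeric vector of interaction confidences in \[0, 1\].
#' @export
predict_tm <- function(bundle, examples) {
  if (is.data.frame(examples)) {
    examples <- as.matrix(examples[, bundle$feature_names, drop = FALSE])
  }
  if (nrow(examples) == 0L) return(numeric(0))
  gbt_predict(bundle$model, examples)
}

#' Full prediction report for miRNA / transcript-or-gene queries
#'
#' Mirrors the result-table layout of the web-facing tool: one row per
#' (miRNA, transcript) with the interaction confidence, plus a per-site
#' sub-table with 1-based inclusive coordinates, site type and binding
#' confidence. Gene ids are resolved to their longest-UTR transcript.
#'
#' @param ts_bundle,tm_bundle Trained TS and TM bundles.
#' @param mirnas A `mirna_set`.
#' @param utrs A `utr_set`.
#' @param targets Character vector of transcript or gene identifiers.
#' @param conservation,snps,registry,flank Passed to the featurizer.
#' @return List `interactions` (data frame with `mirna_id`,
#'   `transcript_id`, `gene_id`, `resolved_from_gene`, `n_sites`,
#'   `interaction_confidence`) and `sites` (data frame with
#'   `site_start`, `site_end` 1-based inclusive, `site_type`,
#'   `binding_confidence`).
#' @export
prediction_report <- function(ts_bundle, tm_bundle, mirnas, utrs, targets,
                              conservation = NULL, snps = NULL,
                              registry = default_registry(),
                              flank = 20L) {
  rows <- lapply(targets, function(tg) {
    if (tg %in% utrs$transcript_id) {
      i <- match(tg, utrs$transcript_id)
      data.frame(transcript_id = tg, gene_id = utrs$gene_id[i],
                 resolved_from_gene = FALSE, stringsAsFactors = FALSE)
    } else {
      tr <- resolve_gene_to_longest_transcript(tg, utrs)
      data.frame(transcript_id = tr$transcript_id, gene_id = tg,
                 resolved_from_gene = TRUE, stringsAsFactors = FALSE)
    }
  })
  tset <- unique(do.call(rbind, rows))
  pairs <- merge(data.frame(mirna_id = mirnas$id), tset)
  sites <- scan_corpus(mirnas, utrs,
                       pairs = pairs[, c("mirna_id", "transcript_id")],
                       flank = flank)
  reg <- registry_subset(registry, ts_bundle$feature_names)
  reg_full <- default_registry(unique(reg$features$family),
                               config = registry$config)
  site_tab <- data.frame(mirna_id = character(0),
                         transcript_id = character(0),
                         site_start = integer(0), site_end = integer(0),
                         site_type = character(0),
                         binding_confidence = numeric(0))
  agg <- matrix(NA_real_, nrow(pairs), 4L,
                dimnames = list(NULL, c("sum_p", "top1", "top2", "top3")))
  n_sites <- integer(nrow(pairs))
  if (nrow(sites) > 0L) {
    feats <- featurize_sites(sites, mirnas, utrs, conservation, snps,
                             reg_full)
    p <- predict_sites(ts_bundle, feats)
    site_tab <- data.frame(mirna_id = sites$mirna_id,
                           transcript_id = sites$transcript_id,
                           site_start = sites$start + 1L,   # 1-based incl.
                           site_end = sites$end,
                           site_type = sites$site_type,
                           binding_confidence = p,
                           stringsAsFactors = FALSE)
    skey <- paste(sites$mirna_id, sites$transcript_id, sep = "\r")
    pkey <- paste(pairs$mirna_id, pairs$transcript_id, sep = "\r")
    for (i in seq_len(nrow(pairs))) {
      pp <- p[skey == pkey[i]]
      agg[i, ] <- aggregate_site_probs(pp)
      n_sites[i] <- length(pp)
    }
  } else {
    for (i in seq_len(nrow(pairs))) agg[i, ] <- aggregate_site_probs(numeric(0))
  }
  conf <- predict_tm(tm_bundle, as.data.frame(agg))
  interactions <- data.frame(
    mirna_id = pairs$mirna_id, transcript_id = pairs$transcript_id,
    gene_id = pairs$gene_id, resolved_from_gene = pairs$resolved_from_gene,
    n_sites = n_sites, interaction_confidence = conf,
    stringsAsFactors = FALSE)
  list(interactions = interactions, sites = site_tab)
}
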