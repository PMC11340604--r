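# Assembly of labelled training sets: negative filtering against validated
# interaction lists, 1:1 under-sampling, expression-threshold labelling,
# and the blind / entity-held-out splits.

#' Filter candidate negatives against a validated-interaction list
#'
#' Any candidate whose (miRNA, gene) pair appears in the validated list is
#' considered a (possibly unobserved) interaction and removed from the
#' negative pool. Filtering keys on genes, not transcripts, because
#' validated databases report genes.
#'
#' @param candidates Data frame with columns `mirna_id` and `gene_id`
#'   (rows are candidate negative sites or pairs).
#' @param validated_pairs Data frame with columns `mirna_id`, `gene_id`.
#' @return The surviving candidates, order preserved, with attribute
#'   `"removed"` holding the removal count.
#' @export
filter_negatives <- function(candidates, validated_pairs) {
  key <- function(d) paste(d$mirna_id, d$gene_id, sep = "\r")
  drop <- key(candidates) %in% key(validated_pairs)
  out <- candidates[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- sum(drop)
  out
}

#' Random under-sampling to a 1:1 class balance
#'
#' A uniform random subset of the majority class of size equal to the
#' minority class is retained; the minority class is kept whole.
#' Deterministic given `seed`.
#'
#' @param positives,negatives Data frames (any columns).
#' @param seed Integer RNG seed.
#' @return List with elements `positives` and `negatives` of equal row
#'   count.
#' @export
undersample_balance <- function(positives, negatives, seed = 1L) {
  if (nrow(positives) == 0L || nrow(negatives) == 0L) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  if (nrow(negatives) >= nrow(positives)) {
    keep <- with_rng(seed, sort(sample.int(nrow(negatives),
                                           nrow(positives))))
    list(positives = positives,
         negatives = negatives[keep, , drop = FALSE])
  } else {
    keep <- with_rng(seed, sort(sample.int(nrow(positives),
                                           nrow(negatives))))
    list(positives = positives[keep, , drop = FALSE],
         negatives = negatives)
  }
}

#' Label miRNA-gene pairs from relative expression
#'
#' Records with relative expression at or below `repression_max` (default
#' 0.60, i.e. at least 40% reduction) are positive (repressed); records
#' inside `unaffected_range` (default \[1.00, 1.10\]) are negative
#' (unaffected); everything else is excluded. Boundaries are inclusive.
#'
#' @param records Data frame with columns `mirna_id`, `gene_id`,
#'   `relative_expression` (non-negative).
#' @param config List with `repression_max` and `unaffected_range`.
#' @return Data frame `mirna_id`, `gene_id`, `label` (`"repressed"` /
#'   `"unaffected"`); excluded records are dropped. Attribute
#'   `"n_excluded"` reports how many.
#' @export
label_tm_from_expression <- function(records,
                                     config = tm_label_config()) {
  if (any(records$relative_expression < 0)) {
    stop("negative relative expression value", call. = FALSE)
  }
  if (config$repression_max >= config$unaffected_range[1L]) {
    stop("repression_max must be below the unaffected range",
         call. = FALSE)
  }
  x <- records$relative_expression
  lab <- ifelse(x <= config$repression_max, "repressed",
                ifelse(x >= config$unaffected_range[1L] &
                         x <= config$unaffected_range[2L],
                       "unaffected", NA_character_))
  out <- data.frame(mirna_id = records$mirna_id,
                    gene_id = records$gene_id,
                    label = lab, stringsAsFactors = FALSE)
  n_excl <- sum(is.na(lab))
  out <- out[!is.na(out$label), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excl
  out
}

#' @rdname label_tm_from_expression
#' @param repression_max Upper bound of relative expression for the
#'   repressed class.
#' @param unaffected_range Inclusive range of relative expression for the
#'   unaffected class.
#' @export
tm_label_config <- function(repression_max = 0.60,
                            unaffected_range = c(1.00, 1.10)) {
  list(repression_max = repression_max,
       unaffected_range = unaffected_range)
}

#' Stratified blind-test split
#'
#' @param labels Binary label vector (0/1, logical, or two-level).
#' @param fraction Fraction of each class placed in the blind set,
#'   in (0, 1). Default 0.2.
#' @param seed Integer RNG seed.
#' @return List `train`, `blind` of integer row indices; disjoint and
#'   exhaustive, stratified by label, deterministic given `seed`.
#' @export
split_blind_test <- function(labels, fraction = 0.2, seed = 1L) {
  if (!(fraction > 0 && fraction < 1)) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  y <- as.integer(factor(labels))
  blind <- integer(0)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n_blind <- round(length(idx) * fraction)
    if (n_blind == 0L || n_blind == length(idx)) {
      stop("fraction leaves a class empty on one side", call. = FALSE)
    }
    take <- with_rng(derive_seed(seed, cls),
                     sample(idx, n_blind))
    blind <- c(blind, take)
  }
  blind <- sort(blind)
  list(train = setdiff(seq_along(y), blind), blind = blind)
}

#' Entity-held-out split (unseen miRNAs and/or transcripts)
#'
#' Holds out a fraction of miRNA and/or transcript identities; every
#' example involving a held-out entity goes to the test side, so the test
#' set shares no held-out entity with training.
#'
#' @param dataset Data frame carrying `mirna_id` and/or `transcript_id`.
#' @param entity `"mirna"`, `"transcript"`, or `"both"`.
#' @param fraction Fraction of entities held out (default 0.3).
#' @param seed Integer RNG seed.
#' @return List `train`, `test` of row indices, plus `held_mirnas` /
#'   `held_transcripts`.
#' @export
split_by_entity <- function(dataset, entity = c("mirna", "transcript",
                                                "both"),
                            fraction = 0.3, seed = 1L) {
  entity <- match.arg(entity)
  hold <- function(ids, k) {
    u <- sort(unique(ids))
    n <- max(1L, round(length(u) * fraction))
    if (length(u) < 2L) stop("too few entities to split", call. = FALSE)
    if (n >= length(u)) n <- length(u) - 1L
    with_rng(derive_seed(seed, k), sample(u, n))
  }
  held_m <- held_t <- character(0)
  in_test <- rep(FALSE, nrow(dataset))
  if (entity %in% c("mirna", "both")) {
    held_m <- hold(dataset$mirna_id, 1L)
    in_test <- in_test | dataset$mirna_id %in% held_m
  }
  if (entity %in% c("transcript", "both")) {
    held_t <- hold(dataset$transcript_id, 2L)
    in_test <- in_test | dataset$transcript_id %in% held_t
  }
  if (entity == "both") {
    # "unseen both": keep only test rows where *both* entities are unseen,
    # and drop from train any row touching a held-out entity.
    test <- which(dataset$mirna_id %in% held_m &
                    dataset$transcript_id %in% held_t)
    train <- which(!in_test)
  } else {
    test <- which(in_test)
    train <- which(!in_test)
  }
  list(train = train, test = test,
       held_mirnas = held_m, held_transcripts = held_t)
}

#' Build a labelled, balanced site-level (TS) dataset from a corpus
#'
#' Scans every miRNA-transcript pair of the corpus, labels scanned sites
#' against the ground-truth manifest (implanted and not withheld =>
#' positive; everything else is a candidate negative), removes candidate
#' negatives whose (miRNA, gene) pair is in the validated list, balances
#' classes 1:1 by random under-sampling, and featurizes the result.
#'
#' @param corpus A `syn_corpus` from [generate_corpus()] (or an equivalent
#'   list with `mirnas`, `utrs`, `conservation`, `snps`,
#'   `validated_pairs`, `manifest`).
#' @param registry Feature registry.
#' @param seed Seed for the under-sampling step.
#' @param flank Target-region flank passed to the scanner.
#' @return Featurized data frame (see [featurize_sites()]) with an extra
#'   `label` column (1 = interaction), attribute `"feature_names"`.
#' @export
build_ts_dataset <- function(corpus, registry = default_registry(),
                             seed = 1L, flank = 20L) {
  sites <- scan_corpus(corpus$mirnas, corpus$utrs, flank = flank)
  man <- corpus$manifest
  key <- function(d) paste(d$mirna_id, d$transcript_id, d$core_start,
                           sep = "\r")
  pos_key <- key(man[!man$withheld, , drop = FALSE])
  is_pos <- key(sites) %in% pos_key
  gid <- stats::setNames(corpus$utrs$gene_id, corpus$utrs$transcript_id)
  sites$gene_id <- gid[sites$transcript_id]
  positives <- sites[is_pos, , drop = FALSE]
  negatives <- filter_negatives(sites[!is_pos, , drop = FALSE],
                                corpus$validated_pairs)
  bal <- undersample_balance(positives, negatives, seed = seed)
  keep <- rbind(bal$positives, bal$negatives)
  lab <- c(rep(1L, nrow(bal$positives)), rep(0L, nrow(bal$negatives)))
  ord <- order(keep$mirna_id, keep$transcript_id, keep$start)
  keep <- keep[ord, , drop = FALSE]
  lab <- lab[ord]
  class(keep) <- c("candidate_sites", "data.frame")
  feat <- featurize_sites(keep, corpus$mirnas, corpus$utrs,
                          conservation = corpus$conservation,
                          snps = corpus$snps, registry = registry)
  feat$label <- lab
  attr(feat, "feature_names") <- registry$features$name
  feat
}
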