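# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (string building, pair counting,
# exhaustive enumeration) and share no code with the implementation paths
# they check.

COMP <- c(A = "U", C = "G", G = "C", U = "A")

random_rna_str <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Brute-force site scan: at every UTR offset, test the four canonical
# definitions by building the full site motif as a string and comparing.
oracle_scan <- function(mirna_seq, utr_seq) {
  m <- strsplit(mirna_seq, "")[[1L]]
  L <- nchar(utr_seq)
  m6 <- paste(rev(COMP[m[2:7]]), collapse = "")     # core motif on UTR
  m7 <- paste(c(COMP[m[8]], rev(COMP[m[2:7]])), collapse = "")
  res <- list()
  for (o in 0:(L - 6L)) {                            # 0-based core offset
    core <- substr(utr_seq, o + 1L, o + 6L)
    if (core != m6) next
    with_m8 <- o >= 1L &&
      substr(utr_seq, o, o + 6L) == m7
    with_a1 <- o + 7L <= L &&
      substr(utr_seq, o + 7L, o + 7L) == "A"
    if (with_m8 && with_a1) {
      type <- "8mer"; s <- o - 1L; e <- o + 7L
    } else if (with_m8) {
      type <- "7mer-m8"; s <- o - 1L; e <- o + 6L
    } else if (with_a1) {
      type <- "7mer-A1"; s <- o; e <- o + 7L
    } else {
      type <- "6mer"; s <- o; e <- o + 6L
    }
    res[[length(res) + 1L]] <- data.frame(
      start = s, end = e, core_start = o, site_type = type,
      stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    return(data.frame(start = integer(0), end = integer(0),
                      core_start = integer(0), site_type = character(0)))
  }
  out <- do.call(rbind, res)
  out[order(out$start, out$core_start), , drop = FALSE]
}

# Naive confusion-matrix metric recount from explicit counts.
oracle_metrics <- function(tp, fp, tn, fn) {
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  d1 <- tp + fp; d2 <- tp + fn; d3 <- tn + fp; d4 <- tn + fn
  mcc <- if (d1 > 0 && d2 > 0 && d3 > 0 && d4 > 0) {
    (tp * tn - fp * fn) / sqrt(d1) / sqrt(d2) / sqrt(d3) / sqrt(d4)
  } else 0
  list(precision = prec, recall = rec, specificity = spec, f1 = f1,
       mcc = mcc, bacc = (rec + spec) / 2)
}

# Label/score vectors realizing a confusion matrix at threshold 0.5.
confusion_vectors <- function(tp, fp, tn, fn) {
  list(labels = c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn)),
       scores = c(rep(0.9, tp), rep(0.9, fp), rep(0.1, tn), rep(0.1, fn)))
}

# AUC as the fraction of concordant positive-negative pairs (+ half ties).
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# Sort-and-sum aggregation oracle.
oracle_aggregate <- function(p) {
  s <- rev(sort(p))
  top <- rep(NA_real_, 3L)
  top[seq_len(min(3L, length(s)))] <- s[seq_len(min(3L, length(s)))]
  c(sum_p = sum(p), top1 = top[1L], top2 = top[2L], top3 = top[3L])
}

# Naive per-position k-mer recount.
oracle_kmer <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(NULL)
  words <- vapply(1:(n - k + 1L), function(i) substr(seq, i, i + k - 1L),
                  character(1L))
  table(words) / length(words)
}
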