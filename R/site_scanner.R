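#' Extract the seed of a miRNA
#'
#' The seed is miRNA positions 2-8 counted 1-based from the 5' end
#' (nucleotides 2-7 plus the position-8 base used by m8 site classes).
#'
#' @param sequence miRNA sequence, RNA alphabet, length >= 8.
#' @return Length-7 RNA string.
#' @export
mirna_seed <- function(sequence) {
  if (nchar(sequence) < 8L) {
    stop("miRNA shorter than 8 nt: seed positions 2-8 do not exist",
         call. = FALSE)
  }
  substr(sequence, 2L, 8L)
}

# Per-miRNA scanning constants: the UTR-strand motifs a canonical site is
# built from. M6 = revcomp(miRNA 2-7); the m8 context base is the
# complement of miRNA position 8; the A1 context base is always A.
seed_motifs <- function(sequence) {
  list(m6 = rna_revcomp(substr(sequence, 2L, 7L)),
       comp_m8 = rna_complement(substr(sequence, 8L, 8L)))
}

#' Classify the canonical site type at a 6mer-core offset
#'
#' Reading the UTR 5' to 3', a core match at 0-based offset `o` means
#' `utr[o..o+5]` equals the reverse complement of miRNA positions 2-7.
#' The class is then the maximal one supported by the two context bases:
#' the base 5'-adjacent to the core (offset `o-1`, pairing miRNA position
#' 8) and the base 3'-adjacent (offset `o+6`, opposite miRNA position 1,
#' which must be an adenine). Context bases truncated by the UTR boundary
#' cannot support their extension (conservative: an absent A1 base can
#' never yield 7mer-A1/8mer).
#'
#' @param mirna_seq miRNA sequence (RNA, length >= 8).
#' @param utr_seq UTR sequence (RNA).
#' @param core_start 0-based offset of the putative 6mer core.
#' @return One of `"6mer"`, `"7mer-A1"`, `"7mer-m8"`, `"8mer"`, or
#'   `NA_character_` when the core does not match.
#' @export
classify_site_type <- function(mirna_seq, utr_seq, core_start) {
  L <- nchar(utr_seq)
  if (core_start < 0L || core_start + 6L > L) {
    stop("core offset out of UTR bounds", call. = FALSE)
  }
  mot <- seed_motifs(mirna_seq)
  if (substr(utr_seq, core_start + 1L, core_start + 6L) != mot$m6) {
    return(NA_character_)
  }
  has_m8 <- core_start >= 1L &&
    substr(utr_seq, core_start, core_start) == mot$comp_m8
  has_a1 <- core_start + 6L < L &&
    substr(utr_seq, core_start + 7L, core_start + 7L) == "A"
  if (has_m8 && has_a1) "8mer"
  else if (has_m8) "7mer-m8"
  else if (has_a1) "7mer-A1"
  else "6mer"
}

#' Enumerate canonical seed-match sites in a 3'-UTR
#'
#' Finds every exact Watson-Crick match of the miRNA 6mer core
#' (reverse complement of positions 2-7) in the UTR and classifies each
#' occurrence as the maximal site class (see [classify_site_type()]).
#' Each core offset yields at most one site; overlapping sites from
#' distinct offsets are all reported. G:U wobbles do not count as seed
#' matches.
#'
#' @param mirna_seq,utr_seq RNA sequences.
#' @param mirna_id,transcript_id Identifiers copied into the output.
#' @param flank Number of UTR bases kept on each side of the site in
#'   `target_region` (clipped at UTR boundaries). Default 20.
#' @return Data frame (class `candidate_sites`), one row per site, sorted
#'   by `start`: `mirna_id`, `transcript_id`, `start`, `end` (0-based
#'   half-open site span), `core_start`, `site_type`, `target_region`,
#'   `region_start`, `region_end`, `clipped`.
#' @export
scan_sites <- function(mirna_seq, utr_seq, mirna_id = "mirna",
                       transcript_id = "utr", flank = 20L) {
  if (nchar(mirna_seq) < 8L) stop("miRNA shorter than 8 nt", call. = FALSE)
  mot <- seed_motifs(mirna_seq)
  L <- nchar(utr_seq)
  hits <- gregexpr(mot$m6, utr_seq, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(empty_sites())
  # gregexpr reports non-overlapping matches only; recover overlaps by
  # rescanning from every match + 1 (core is 6 nt so overlap is possible
  # for periodic motifs).
  starts <- integer(0)
  pos <- 1L
  repeat {
    m <- regexpr(mot$m6, substr(utr_seq, pos, L), fixed = TRUE)
    if (m == -1L) break
    starts <- c(starts, pos + m - 1L)
    pos <- pos + m
  }
  core0 <- starts - 1L  # 0-based core offsets
  rows <- lapply(core0, function(o) {
    type <- classify_site_type(mirna_seq, utr_seq, o)
    span <- site_span(o, type)
    rs <- max(0L, span[1L] - flank)
    re <- min(L, span[2L] + flank)
    data.frame(mirna_id = mirna_id, transcript_id = transcript_id,
               start = span[1L], end = span[2L], core_start = o,
               site_type = type,
               target_region = substr(utr_seq, rs + 1L, re),
               region_start = rs, region_end = re,
               clipped = (span[1L] - flank < 0L) || (span[2L] + flank > L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$core_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_sites", "data.frame")
  out
}

# 0-based half-open span of a site given its core offset and class.
site_span <- function(core_start, site_type) {
  switch(site_type,
         "8mer"    = c(core_start - 1L, core_start + 7L),
         "7mer-m8" = c(core_start - 1L, core_start + 6L),
         "7mer-A1" = c(core_start,      core_start + 7L),
         "6mer"    = c(core_start,      core_start + 6L),
         stop("unknown site type: ", site_type, call. = FALSE))
}

empty_sites <- function() {
  out <- data.frame(mirna_id = character(0), transcript_id = character(0),
                    start = integer(0), end = integer(0),
                    core_start = integer(0), site_type = character(0),
                    target_region = character(0), region_start = integer(0),
                    region_end = integer(0), clipped = logical(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("candidate_sites", "data.frame")
  out
}

#' Scan every miRNA against every UTR (or a given pair list)
#'
#' @param mirnas A `mirna_set`.
#' @param utrs A `utr_set`.
#' @param pairs Optional data frame with columns `mirna_id`,
#'   `transcript_id` restricting which combinations are scanned;
#'   by default all combinations.
#' @param flank Passed to [scan_sites()].
#' @return A `candidate_sites` data frame (possibly zero rows).
#' @export
scan_corpus <- function(mirnas, utrs, pairs = NULL, flank = 20L) {
  if (is.null(pairs)) {
    pairs <- expand.grid(mirna_id = mirnas$id,
                         transcript_id = utrs$transcript_id,
                         stringsAsFactors = FALSE)
  }
  mseq <- stats::setNames(mirnas$sequence, mirnas$id)
  useq <- stats::setNames(utrs$sequence, utrs$transcript_id)
  unknown_m <- setdiff(pairs$mirna_id, names(mseq))
  if (length(unknown_m)) stop("unknown miRNA id: ", unknown_m[1L],
                              call. = FALSE)
  unknown_t <- setdiff(pairs$transcript_id, names(useq))
  if (length(unknown_t)) stop("unknown transcript id: ", unknown_t[1L],
                              call. = FALSE)
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    res[[i]] <- scan_sites(mseq[[pairs$mirna_id[i]]],
                           useq[[pairs$transcript_id[i]]],
                           pairs$mirna_id[i], pairs$transcript_id[i],
                           flank = flank)
  }
  out <- data.table::rbindlist(res)
  out <- as.data.frame(out)
  class(out) <- c("candidate_sites", "data.frame")
  out
}
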