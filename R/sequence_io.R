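#' Read a miRNA or 3'-UTR FASTA file
#'
#' Sequences are normalized to the RNA alphabet (uppercase, `T` converted to
#' `U`); DNA input is therefore accepted. The record id is the first
#' whitespace-separated token of the header. Duplicate ids are rejected.
#'
#' @param path Path to a FASTA file.
#' @param role Either `"mirna"` or `"utr"`; controls validation and the
#'   returned columns.
#' @param gene_map Optional data frame (or TSV path) mapping
#'   `transcript_id` to `gene_id`; only used for `role = "utr"`.
#' @return For `role = "mirna"`, a data frame with columns `id`, `sequence`
#'   (class `mirna_set`). For `role = "utr"`, a data frame with columns
#'   `transcript_id`, `gene_id`, `sequence` (class `utr_set`).
#' @export
read_fasta <- function(path, role = c("mirna", "utr"), gene_map = NULL) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  seqs <- as.character(set)
  seqs <- vapply(seq_along(seqs), function(i) normalize_rna(seqs[i], ids[i]),
                 character(1L))
  if (role == "mirna") {
    short <- nchar(seqs) < 8L
    if (any(short)) {
      stop("miRNA '", ids[short][1L],
           "' is shorter than 8 nt; seed positions 2-8 must exist",
           call. = FALSE)
    }
    out <- data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
    class(out) <- c("mirna_set", "data.frame")
  } else {
    if (any(nchar(seqs) == 0L)) stop("empty UTR sequence", call. = FALSE)
    gid <- rep(NA_character_, length(ids))
    if (!is.null(gene_map)) {
      if (is.character(gene_map) && length(gene_map) == 1L) {
        gene_map <- data.table::fread(gene_map, header = TRUE,
                                      sep = "\t", data.table = FALSE)
      }
      m <- match(ids, gene_map[[1L]])
      gid <- as.character(gene_map[[2L]][m])
    }
    out <- data.frame(transcript_id = ids, gene_id = gid, sequence = seqs,
                      stringsAsFactors = FALSE)
    class(out) <- c("utr_set", "data.frame")
  }
  rownames(out) <- NULL
  out
}

#' Write sequences to FASTA
#'
#' Inverse of [read_fasta()]: the round trip reproduces ids and normalized
#' sequences byte-identically.
#'
#' @param x A `mirna_set` or `utr_set` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  ids <- if ("id" %in% names(x)) x$id else x$transcript_id
  writeLines(paste0(">", ids, "\n", x$sequence), path, sep = "\n")
  invisible(path)
}

#' Read a validated miRNA-gene interaction pair list
#'
#' Headerless TSV with at least two columns: miRNA id and gene id. Fields
#' are whitespace-trimmed and duplicate pairs collapsed.
#'
#' @param path Path to a TSV file.
#' @return Data frame with columns `mirna_id`, `gene_id`, one row per
#'   distinct pair. An empty file yields zero rows.
#' @export
read_pair_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(mirna_id = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    stop(sprintf("malformed pair list row at line %d: expected >= 2 columns",
                 which(nf < 2L)[1L]), call. = FALSE)
  }
  out <- data.frame(
    mirna_id = trimws(vapply(parts, `[`, character(1L), 1L)),
    gene_id = trimws(vapply(parts, `[`, character(1L), 2L)),
    stringsAsFactors = FALSE)
  unique(out)
}

#' Read a transcript-coordinate conservation track
#'
#' Headerless bedGraph-like TSV: `transcript_id`, `start`, `end` (0-based,
#' half-open) and `score`. Positions not covered by any interval are
#' treated as missing.
#'
#' @param path Path to a TSV file.
#' @return Data frame with columns `transcript_id`, `start`, `end`, `score`.
#' @export
read_conservation <- function(path) {
  tr <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE,
                          col.names = c("transcript_id", "start",
                                        "end", "score"))
  if (any(tr$end <= tr$start)) stop("conservation interval with end <= start",
                                    call. = FALSE)
  tr
}

# Expand a conservation track to one per-base score vector per transcript.
# `utr` supplies transcript lengths; uncovered positions are NA.
conservation_vectors <- function(track, utrs) {
  lens <- nchar(utrs$sequence)
  names(lens) <- utrs$transcript_id
  out <- lapply(utrs$transcript_id, function(tid) rep(NA_real_, lens[[tid]]))
  names(out) <- utrs$transcript_id
  for (i in seq_len(nrow(track))) {
    tid <- track$transcript_id[i]
    if (is.null(out[[tid]])) next
    a <- track$start[i]; b <- min(track$end[i], length(out[[tid]]))
    if (b > a) out[[tid]][(a + 1L):b] <- track$score[i]
  }
  out
}

#' Read a SNP annotation table
#'
#' TSV with header columns `transcript_id`, `position` (0-based UTR
#' coordinate) and `disease_related` (0/1).
#'
#' @param path Path to a TSV file.
#' @return Data frame with those three columns (`disease_related` logical).
#' @export
read_snp_table <- function(path) {
  sn <- data.table::fread(path, header = TRUE, sep = "\t",
                          data.table = FALSE)
  need <- c("transcript_id", "position", "disease_related")
  if (!all(need %in% names(sn))) {
    stop("SNP table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sn$disease_related <- as.logical(sn$disease_related)
  sn[need]
}

#' Read an expression table for repression labelling
#'
#' TSV with header columns `mirna_id`, `gene_id`, `relative_expression`
#' (fraction of the no-transfection control, non-negative).
#'
#' @param path Path to a TSV file.
#' @return Data frame with those three columns.
#' @export
read_expression <- function(path) {
  ex <- data.table::fread(path, header = TRUE, sep = "\t",
                          data.table = FALSE)
  need <- c("mirna_id", "gene_id", "relative_expression")
  if (!all(need %in% names(ex))) {
    stop("expression table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ex[need]
}

#' Resolve a gene to its longest-UTR transcript
#'
#' When a gene maps to several transcripts the transcript with the longest
#' 3'-UTR is used for prediction; ties are broken by the lexicographically
#' smallest transcript id.
#'
#' @param gene_id A single gene identifier.
#' @param utrs A `utr_set` with a populated `gene_id` column.
#' @return One-row `utr_set` data frame.
#' @export
resolve_gene_to_longest_transcript <- function(gene_id, utrs) {
  hit <- utrs[!is.na(utrs$gene_id) & utrs$gene_id == gene_id, , drop = FALSE]
  if (nrow(hit) == 0L) stop("unknown gene: ", gene_id, call. = FALSE)
  ord <- order(-nchar(hit$sequence), hit$transcript_id)
  out <- hit[ord[1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}
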