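#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Uppercases and converts `T` to `U`. The result must contain only
#' `A`, `C`, `G`, `U`; otherwise an error naming the first offending
#' position is raised. Idempotent.
#'
#' @param x Character vector of sequences.
#' @param what Label used in error messages (e.g. a record id).
#' @return Character vector of normalized RNA sequences.
#' @export
normalize_rna <- function(x, what = "sequence") {
  out <- chartr("t", "u", toupper(x))
  out <- chartr("T", "U", out)
  bad <- regexpr("[^ACGU]", out)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal character '%s' in %s '%s' at position %d",
                 substr(out[i], bad[i], bad[i]),
                 "record", what[min(i, length(what))], bad[i]),
         call. = FALSE)
  }
  out
}

# Complement of RNA bases (Watson-Crick), vectorised over characters.
rna_complement <- function(x) chartr("ACGU", "UGCA", x)

# Reverse complement of an RNA string.
rna_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(rna_complement(s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Split a string into a character vector of single bases.
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is untouched.
with_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and a stream index; stays < 2^31.
derive_seed <- function(seed, k) {
  (as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483629
}

# Polynomial rolling hash of a character vector, as a hex string. Used as
# a cheap registry fingerprint inside model bundles.
text_fingerprint <- function(x) {
  s <- paste(x, collapse = "|")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Encode/decode doubles as strings that round-trip exactly.
num_encode <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}
num_decode <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
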