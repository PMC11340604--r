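# Binding-stability features from a nearest-neighbor stacking model.
#
# The duplex alignment is the one fixed by the scanner register: with the
# 6mer core at 0-based UTR offset o, miRNA position p (1-based, 5'->3')
# sits opposite UTR position t(p) = o + 7 - p, with no bulges. A position
# is "paired" when the two bases are Watson-Crick complements. The energy
# is the sum of stacking terms over consecutive paired positions, using
# RNA/RNA dG37 nearest-neighbor parameters (Turner-style). Because every
# pair in the register is Watson-Crick, a stack is fully determined by the
# target-strand dinucleotide read 5'->3'.

.nn_stack <- c(
  AA = -0.93, UU = -0.93,
  AU = -1.10,
  UA = -1.33,
  CU = -2.08, AG = -2.08,
  CA = -2.11, UG = -2.11,
  GU = -2.24, AC = -2.24,
  GA = -2.35, UC = -2.35,
  CG = -2.36,
  GG = -3.26, CC = -3.26,
  GC = -3.42)

# Pairing mask over miRNA positions for the scanner register.
# Returns list(paired = logical over p = 1..n, tpos = 0-based UTR index or NA).
duplex_register <- function(mirna_chars, utr_chars, core_start) {
  n <- length(mirna_chars)
  p <- seq_len(n)
  tpos <- core_start + 7L - p
  ok <- tpos >= 0L & tpos < length(utr_chars)
  paired <- logical(n)
  paired[ok] <- utr_chars[tpos[ok] + 1L] ==
    rna_complement(mirna_chars[ok])
  list(paired = paired, tpos = ifelse(ok, tpos, NA_integer_))
}

# Sum NN stacking terms over consecutive paired miRNA positions within
# `positions` (1-based miRNA index vector, must be contiguous range).
stack_energy <- function(reg, utr_chars, positions) {
  e <- 0
  for (p in positions[-length(positions)]) {
    q <- p + 1L
    if (!(q %in% positions)) next
    if (reg$paired[p] && reg$paired[q]) {
      # target dinucleotide 5'->3' is (t(q), t(p)) since t decreases with p
      key <- paste0(utr_chars[reg$tpos[q] + 1L], utr_chars[reg$tpos[p] + 1L])
      e <- e + .nn_stack[[key]]
    }
  }
  e
}

#' Duplex stability features for a candidate site
#'
#' Four features from the built-in nearest-neighbor backend: total
#' hybridization energy over the scanner-register pairing (kcal/mol, lower
#' = more stable), the same restricted to seed positions 2-8, energy per
#' paired base, and the Watson-Crick paired-base count. An external-tool
#' backend is not bundled; requesting one raises an error instructing
#' fallback to the built-in backend.
#'
#' @param mirna_seq,utr_seq RNA sequences.
#' @param core_start 0-based offset of the site's 6mer core in the UTR.
#' @param backend `"builtin"` (default) or the name of an external tool.
#' @return Named numeric: `stab_dg_total`, `stab_dg_seed`,
#'   `stab_dg_per_pair`, `stab_paired_count`.
#' @export
duplex_energy <- function(mirna_seq, utr_seq, core_start,
                          backend = "builtin") {
  if (!identical(backend, "builtin")) {
    stop("duplex backend '", backend, "' is not available; ",
         "fall back to backend = \"builtin\"", call. = FALSE)
  }
  mc <- seq_chars(mirna_seq)
  uc <- seq_chars(utr_seq)
  reg <- duplex_register(mc, uc, core_start)
  npaired <- sum(reg$paired)
  total <- stack_energy(reg, uc, seq_along(mc))
  seed <- stack_energy(reg, uc, 2:8)
  c(stab_dg_total = total,
    stab_dg_seed = seed,
    stab_dg_per_pair = if (npaired > 0) total / npaired else 0,
    stab_paired_count = npaired)
}
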