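# Shared in-code fixtures: a reference miRNA with hand-checkable seed, and
# small corpora for pipeline tests.

MIR1 <- "UGGAAUGUAAAGAAGUAUGUAU"   # seed 2-8 = GGAAUGU; core motif CAUUCC

write_tmp_fasta <- function(records, ids = names(records)) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(paste0(">", ids, "\n", unname(records)), path)
  path
}

small_corpus <- function(seed = 42L, n_mirnas = 3L, n_transcripts = 40L,
                         ...) {
  generate_corpus(corpus_config(n_mirnas = n_mirnas,
                                n_transcripts = n_transcripts,
                                utr_length_range = c(200L, 400L),
                                seed = seed, ...))
}

# A cleanly separable classification fixture: one informative feature,
# the rest noise.
separable_xy <- function(n = 100L, p_noise = 5L, seed = 1L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- cbind(signal = y * 2 + stats::rnorm(n, sd = 0.1),
             matrix(stats::rnorm(n * p_noise), n, p_noise,
                    dimnames = list(NULL, paste0("noise", seq_len(p_noise)))))
  list(X = X, y = y)
}
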