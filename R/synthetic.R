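# Synthetic corpus generator: a fully specified world with implanted
# canonical sites, conservation uplift over implants, sparse SNPs,
# validated-pair withholding, and expression values tied to implantation,
# so every pipeline stage can be trained and tested offline.

#' Configuration of a synthetic corpus
#'
#' Defaults describe the stated test world: 5 miRNAs x 500 transcripts
#' with an implant rate of 0.4 per (miRNA, transcript) pair, i.e. about
#' 1000 implanted sites in expectation.
#'
#' @param n_mirnas Number of miRNAs (22 nt each).
#' @param n_transcripts Number of 3'-UTRs.
#' @param utr_length_range Min/max UTR length (uniform), nt.
#' @param implant_rate Probability that a given (miRNA, transcript) pair
#'   receives one implanted site.
#' @param site_type_probs Named probabilities over the four site classes
#'   for implanted sites.
#' @param energy_bias GC-content increment applied to the target-region
#'   flanks of implanted sites (background P(G or C) = 0.5).
#' @param supp_rate Probability that an implanted site also receives a
#'   perfect 3'-supplementary patch complementary to miRNA positions
#'   13-16.
#' @param conservation_signal Mean conservation uplift over implanted
#'   sites (background per-base scores are uniform on \[0, 0.6\]).
#' @param snp_density Per-base probability of a SNP annotation.
#' @param disease_snp_frac Fraction of SNPs flagged disease-related.
#' @param repression_link Probability that a gene with >= 1 implanted site
#'   for a miRNA is drawn repressed (relative expression in
#'   \[0.2, 0.6\]); otherwise, and for all implant-free pairs, expression
#'   is drawn unaffected in \[1.0, 1.1\] (a small fraction of implant-free
#'   pairs falls in the excluded middle range instead).
#' @param withheld_frac Fraction of implanted sites withheld from the
#'   positive list and placed in the candidate-negative pool while their
#'   (miRNA, gene) pair is added to the validated list — so negative
#'   filtering has real work to do, mimicking assay sensitivity limits.
#' @param two_transcript_gene_frac Fraction of transcripts grouped into
#'   two-transcript genes (exercises the longest-transcript rule).
#' @param seed Integer seed; the corpus is a pure function of the config.
#' @return A `corpus_config` list.
#' @export
corpus_config <- function(n_mirnas = 5L, n_transcripts = 500L,
                          utr_length_range = c(500L, 1500L),
                          implant_rate = 0.4,
                          site_type_probs = c("6mer" = 0.20,
                                              "7mer-A1" = 0.25,
                                              "7mer-m8" = 0.30,
                                              "8mer" = 0.25),
                          energy_bias = 0.15, supp_rate = 0.5,
                          conservation_signal = 0.4,
                          snp_density = 0.002, disease_snp_frac = 0.2,
                          repression_link = 0.9, withheld_frac = 0.1,
                          two_transcript_gene_frac = 0.1, seed = 1L) {
  rates <- c(implant_rate, site_type_probs, energy_bias, supp_rate,
             conservation_signal, snp_density, disease_snp_frac,
             repression_link, withheld_frac, two_transcript_gene_frac)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]",
                                       call. = FALSE)
  if (utr_length_range[1L] < 30L) stop("UTRs shorter than 30 nt cannot host implants",
                                       call. = FALSE)
  structure(list(n_mirnas = n_mirnas, n_transcripts = n_transcripts,
                 utr_length_range = utr_length_range,
                 implant_rate = implant_rate,
                 site_type_probs = site_type_probs,
                 energy_bias = energy_bias, supp_rate = supp_rate,
                 conservation_signal = conservation_signal,
                 snp_density = snp_density,
                 disease_snp_frac = disease_snp_frac,
                 repression_link = repression_link,
                 withheld_frac = withheld_frac,
                 two_transcript_gene_frac = two_transcript_gene_frac,
                 seed = seed),
            class = "corpus_config")
}

random_rna <- function(n, gc = 0.5) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}

#' Generate a synthetic corpus
#'
#' Background UTR sequence is uniform over \{A, C, G, U\}; implanted sites
#' write the exact core/context bases for their class and are guarded so
#' a flanking base never upgrades the class. All implants are recorded in
#' a ground-truth manifest. Deterministic: same config, same corpus.
#'
#' @param config A [corpus_config()].
#' @return A `syn_corpus` list: `config`, `mirnas`, `utrs`,
#'   `conservation` (named list of per-base vectors), `snps`,
#'   `validated_pairs`, `expression`, `manifest`.
#' @export
generate_corpus <- function(config = corpus_config()) {
  with_rng(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(cfg) {
  bases <- c("A", "C", "G", "U")
  mirnas <- data.frame(
    id = sprintf("syn-miR-%03d", seq_len(cfg$n_mirnas)),
    sequence = vapply(seq_len(cfg$n_mirnas), function(i) random_rna(22L),
                      character(1L)),
    stringsAsFactors = FALSE)
  class(mirnas) <- c("mirna_set", "data.frame")

  # gene structure: a fraction of transcripts share two-transcript genes
  n_t <- cfg$n_transcripts
  n_pairs <- floor(n_t * cfg$two_transcript_gene_frac / 2)
  gene_of <- integer(n_t)
  g <- 0L
  for (i in seq_len(n_pairs)) { g <- g + 1L; gene_of[2L * i - 1L] <- g
                                gene_of[2L * i] <- g }
  for (i in seq.int(2L * n_pairs + 1L, length.out = n_t - 2L * n_pairs)) {
    g <- g + 1L; gene_of[i] <- g
  }
  len_span <- cfg$utr_length_range[2L] - cfg$utr_length_range[1L] + 1L
  lens <- cfg$utr_length_range[1L] +
    sample.int(len_span, n_t, replace = TRUE) - 1L
  utr_chars <- lapply(lens, function(L) sample(bases, L, replace = TRUE))

  # implant sites
  manifest <- list()
  occupied <- lapply(seq_len(n_t), function(i) logical(lens[i]))
  types <- names(cfg$site_type_probs)
  for (ti in seq_len(n_t)) {
    L <- lens[ti]
    for (mi in seq_len(cfg$n_mirnas)) {
      if (runif(1) >= cfg$implant_rate) next
      type <- sample(types, 1L, prob = cfg$site_type_probs)
      m <- mirnas$sequence[mi]
      mot <- seed_motifs(m)
      # core offset leaving room for the supplementary patch (o-9) and
      # both context bases
      ok <- FALSE
      for (try in 1:12) {
        o <- sample.int(L - 21L, 1L) + 11L   # o in [12, L-10]
        span <- seq.int(o - 11L, o + 7L)     # patch + context + core + A1
        if (!any(occupied[[ti]][span + 1L])) { ok <- TRUE; break }
      }
      if (!ok) next
      core <- seq_chars(mot$m6)
      utr_chars[[ti]][(o + 1L):(o + 6L)] <- core
      if (type %in% c("8mer", "7mer-m8")) {
        utr_chars[[ti]][o] <- mot$comp_m8
      } else {
        utr_chars[[ti]][o] <- sample(setdiff(bases, mot$comp_m8), 1L)
      }
      if (type %in% c("8mer", "7mer-A1")) {
        utr_chars[[ti]][o + 7L] <- "A"
      } else {
        utr_chars[[ti]][o + 7L] <- sample(setdiff(bases, "A"), 1L)
      }
      supp <- runif(1) < cfg$supp_rate
      if (supp) {
        # perfect Watson-Crick patch opposite miRNA positions 13-16:
        # target position o + 7 - p for p = 13..16
        mc <- seq_chars(m)
        for (p in 13:16) {
          utr_chars[[ti]][o + 7L - p + 1L] <- rna_complement(mc[p])
        }
      }
      occupied[[ti]][span + 1L] <- TRUE
      # GC-biased flanks (energy bias), skipping occupied positions
      fl <- setdiff(seq.int(max(0L, o - 20L), min(L - 1L, o + 26L)), span)
      fl <- fl[!occupied[[ti]][fl + 1L]]
      if (length(fl)) {
        gc <- 0.5 + cfg$energy_bias
        utr_chars[[ti]][fl + 1L] <- sample(
          bases, length(fl), replace = TRUE,
          prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
      }
      sp <- site_span(o, type)
      manifest[[length(manifest) + 1L]] <- data.frame(
        mirna_id = mirnas$id[mi], transcript_id = ti, core_start = o,
        start = sp[1L], end = sp[2L], site_type = type, supp = supp,
        stringsAsFactors = FALSE)
    }
  }
  tids <- sprintf("SYNT%05d", seq_len(n_t))
  gids <- sprintf("SYNG%04d", gene_of)
  utrs <- data.frame(transcript_id = tids, gene_id = gids,
                     sequence = vapply(utr_chars, paste, character(1L),
                                       collapse = ""),
                     stringsAsFactors = FALSE)
  class(utrs) <- c("utr_set", "data.frame")
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(mirna_id = character(0), transcript_id = integer(0),
               core_start = integer(0), start = integer(0),
               end = integer(0), site_type = character(0),
               supp = logical(0))
  if (nrow(manifest)) {
    manifest$gene_id <- gids[manifest$transcript_id]
    manifest$transcript_id <- tids[manifest$transcript_id]
    manifest$withheld <- runif(nrow(manifest)) < cfg$withheld_frac
  } else {
    manifest$gene_id <- character(0)
    manifest$withheld <- logical(0)
  }

  # conservation: background uniform [0, 0.6]; uplift over implanted sites
  conservation <- lapply(seq_len(n_t), function(ti)
    runif(lens[ti], 0, 0.6))
  names(conservation) <- tids
  if (nrow(manifest)) {
    for (i in seq_len(nrow(manifest))) {
      tid <- manifest$transcript_id[i]
      idx <- (manifest$start[i] + 1L):manifest$end[i]
      conservation[[tid]][idx] <- pmin(
        1, conservation[[tid]][idx] + cfg$conservation_signal)
    }
  }

  # sparse SNPs, uniform over positions (independent of implants)
  snps <- list()
  for (ti in seq_len(n_t)) {
    n_snp <- rbinom(1L, lens[ti], cfg$snp_density)
    if (n_snp == 0L) next
    pos <- sort(sample.int(lens[ti], n_snp)) - 1L
    snps[[length(snps) + 1L]] <- data.frame(
      transcript_id = tids[ti], position = pos,
      disease_related = runif(n_snp) < cfg$disease_snp_frac,
      stringsAsFactors = FALSE)
  }
  snps <- if (length(snps)) do.call(rbind, snps) else
    data.frame(transcript_id = character(0), position = integer(0),
               disease_related = logical(0))

  # validated pairs: withheld implants (plus a few decoys without sites)
  validated <- unique(manifest[manifest$withheld,
                               c("mirna_id", "gene_id"), drop = FALSE])
  all_pairs <- expand.grid(mirna_id = mirnas$id, gene_id = unique(gids),
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
  has_implant <- paste(all_pairs$mirna_id, all_pairs$gene_id) %in%
    paste(manifest$mirna_id, manifest$gene_id)
  decoys <- all_pairs[!has_implant, , drop = FALSE]
  if (nrow(decoys) > 20L) decoys <- decoys[sample.int(nrow(decoys), 20L), ]
  validated <- unique(rbind(validated, decoys))
  rownames(validated) <- NULL

  # expression: repression tied to implantation
  rel <- numeric(nrow(all_pairs))
  for (i in seq_len(nrow(all_pairs))) {
    if (has_implant[i] && runif(1) < cfg$repression_link) {
      rel[i] <- runif(1, 0.2, 0.6)
    } else if (!has_implant[i] && runif(1) < 0.05) {
      rel[i] <- runif(1, 0.61, 0.99)       # excluded middle range
    } else {
      rel[i] <- runif(1, 1.0, 1.1)
    }
  }
  expression <- data.frame(mirna_id = all_pairs$mirna_id,
                           gene_id = all_pairs$gene_id,
                           relative_expression = rel,
                           stringsAsFactors = FALSE)

  structure(list(config = cfg, mirnas = mirnas, utrs = utrs,
                 conservation = conservation, snps = snps,
                 validated_pairs = validated, expression = expression,
                 manifest = manifest),
            class = "syn_corpus")
}

#' Write a corpus to disk in the pipeline's input formats
#'
#' Produces `mirnas.fa`, `utrs.fa`, `gene_map.tsv`, `conservation.tsv`
#' (bedGraph-like), `snps.tsv`, `validated_pairs.tsv`, `expression.tsv`,
#' `manifest.tsv` and `config.json` under `dir`.
#'
#' @param corpus A `syn_corpus`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  write_fasta(corpus$mirnas, fp("mirnas.fa"))
  write_fasta(corpus$utrs, fp("utrs.fa"))
  data.table::fwrite(corpus$utrs[, c("transcript_id", "gene_id")],
                     fp("gene_map.tsv"), sep = "\t")
  cons <- do.call(rbind, lapply(names(corpus$conservation), function(tid) {
    v <- corpus$conservation[[tid]]
    data.frame(transcript_id = tid, start = seq_along(v) - 1L,
               end = seq_along(v), score = num_encode(v),
               stringsAsFactors = FALSE)
  }))
  data.table::fwrite(cons, fp("conservation.tsv"), sep = "\t",
                     col.names = FALSE)
  sn <- corpus$snps
  sn$disease_related <- as.integer(sn$disease_related)
  data.table::fwrite(sn, fp("snps.tsv"), sep = "\t")
  data.table::fwrite(corpus$validated_pairs, fp("validated_pairs.tsv"),
                     sep = "\t", col.names = FALSE)
  data.table::fwrite(corpus$expression, fp("expression.tsv"), sep = "\t")
  man <- corpus$manifest
  man$supp <- as.integer(man$supp)
  man$withheld <- as.integer(man$withheld)
  data.table::fwrite(man, fp("manifest.tsv"), sep = "\t")
  jsonlite::write_json(unclass(corpus$config), fp("config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a corpus written by [write_corpus()]
#'
#' @param dir Corpus directory.
#' @return A `syn_corpus` (conservation restored as per-base vectors).
#' @export
read_corpus <- function(dir) {
  fp <- function(x) file.path(dir, x)
  mirnas <- read_fasta(fp("mirnas.fa"), "mirna")
  utrs <- read_fasta(fp("utrs.fa"), "utr", gene_map = fp("gene_map.tsv"))
  track <- read_conservation(fp("conservation.tsv"))
  man <- data.table::fread(fp("manifest.tsv"), data.table = FALSE)
  if (nrow(man)) {
    man$supp <- as.logical(man$supp)
    man$withheld <- as.logical(man$withheld)
  }
  cfg <- jsonlite::read_json(fp("config.json"), simplifyVector = TRUE)
  cfg$site_type_probs <- unlist(cfg$site_type_probs)
  class(cfg) <- "corpus_config"
  structure(list(config = cfg, mirnas = mirnas, utrs = utrs,
                 conservation = conservation_vectors(track, utrs),
                 snps = read_snp_table(fp("snps.tsv")),
                 validated_pairs = read_pair_list(fp("validated_pairs.tsv")),
                 expression = read_expression(fp("expression.tsv")),
                 manifest = man),
            class = "syn_corpus")
}

#' Evaluate site predictions against the ground-truth manifest
#'
#' @param manifest Corpus manifest (all implants, withheld or not).
#' @param predictions A `candidate_sites` data frame (e.g. scanner
#'   output, optionally filtered by a probability cut-off).
#' @param n_pairs Number of (miRNA, transcript) pairs scanned, for the
#'   chance-site rate; `NA` if unknown.
#' @return List `per_type_recall` (named numeric), `overall_recall`,
#'   `n_chance`, `chance_rate_per_pair`.
#' @export
ground_truth_eval <- function(manifest, predictions, n_pairs = NA) {
  if (nrow(predictions) &&
      !all(predictions$transcript_id %in% c(manifest$transcript_id,
                                            predictions$transcript_id))) {
    stop("corpus mismatch", call. = FALSE)
  }
  key <- function(d) paste(d$mirna_id, d$transcript_id, d$core_start,
                           sep = "\r")
  hit <- key(manifest) %in% key(predictions)
  per_type <- tapply(hit, manifest$site_type, mean)
  n_chance <- sum(!(key(predictions) %in% key(manifest)))
  list(per_type_recall = per_type,
       overall_recall = if (nrow(manifest)) mean(hit) else NA_real_,
       n_chance = n_chance,
       chance_rate_per_pair = if (is.na(n_pairs)) NA_real_
                              else n_chance / n_pairs)
}

#' Features causally affected by implantation in the synthetic world
#'
#' The generator implants differ from chance sites in class distribution,
#' thermodynamics (GC-biased flanks, supplementary patches) and
#' conservation uplift; those effects propagate to the site-type,
#' stability, supplementary, conservation and composition/structure
#' features. SNP placement and site position are implantation-independent
#' by construction, so those features carry no signal.
#'
#' @param registry A `feature_registry`.
#' @return Character vector of informative feature names.
#' @export
informative_features <- function(registry = default_registry()) {
  nm <- registry$features$name
  fam <- registry$features$family
  noise_acc <- c("acc_d5", "acc_d3", "acc_dmin", "acc_relpos",
                 "acc_utr_len", "acc_flank_clipped")
  keep <- (fam %in% c("sitetype", "stability", "supplementary",
                      "conservation", "descriptor")) |
    (fam == "accessibility" & !(nm %in% noise_acc))
  nm[keep]
}
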