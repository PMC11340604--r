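# The feature registry and the seven feature families.
#
# The default registry has exactly 154 named features:
#   4 site-type + 4 binding-stability + 13 accessibility +
#   7 3'-supplementary + 16 conservation + 18 SNP + 92 sequence descriptors.
# Family membership is config-driven so members can be swapped without code
# changes; absent resources (no conservation track, no SNP table) propagate
# as missing values, never silent zeros.

.BASES <- c("A", "C", "G", "U")

site_type_levels <- function() c("6mer", "7mer-A1", "7mer-m8", "8mer")

registry_feature_names <- function(family) {
  switch(family,
    sitetype = paste0("sitetype_",
                      c("6mer", "7mer_A1", "7mer_m8", "8mer")),
    stability = c("stab_dg_total", "stab_dg_seed", "stab_dg_per_pair",
                  "stab_paired_count"),
    accessibility = c("acc_d5", "acc_d3", "acc_dmin", "acc_relpos",
                      "acc_utr_len", "acc_au_flank5", "acc_au_flank3",
                      "acc_au_site", "acc_open_dg", "acc_punpaired_site",
                      "acc_punpaired_win10", "acc_gc_region",
                      "acc_flank_clipped"),
    supplementary = c("supp_count13_16", "supp_count12_17",
                      "supp_longest_run12_17", "supp_ge3_13_16",
                      "supp_pairs_3half", "supp_gu13_16",
                      "supp_best_offset"),
    conservation = as.vector(t(outer(
      c("cons_core", "cons_site", "cons_flank5", "cons_flank3"),
      c("mean", "min", "max", "frac"), paste, sep = "_"))),
    snp = c(paste0("snp_any_pos", 1:8), paste0("snp_dis_pos", 1:8),
            "snp_count", "snp_dis_count"),
    descriptor = c(
      paste0("desc_nc_", .BASES),
      paste0("desc_dnc_", as.vector(t(outer(.BASES, .BASES, paste0)))),
      paste0("desc_tnc_", as.vector(apply(
        expand.grid(.BASES, .BASES, .BASES)[, 3:1], 1, paste0,
        collapse = ""))),
      "desc_z_x", "desc_z_y", "desc_z_z",
      "desc_gc", "desc_au", "desc_purine", "desc_len",
      "desc_homopolymer"),
    stop("unknown feature family: ", family, call. = FALSE))
}

#' Build the default feature registry
#'
#' @param families Character vector of enabled families, a subset of
#'   `c("sitetype", "stability", "accessibility", "supplementary",
#'   "conservation", "snp", "descriptor")`.
#' @param config Named list of overrides for the registry configuration:
#'   `flank_width` (conservation/AU flank, nt, default 30),
#'   `cons_threshold` (default 0.5), `acc_window` (unpaired-propensity
#'   window, default 10), `fold_flank` (folding window flank, default 40),
#'   `fold_backend` (`"builtin"` or `"none"`), `duplex_backend`,
#'   `descriptor_input` (`"region"` or `"site"`).
#' @return A `feature_registry` list with elements `features`
#'   (data frame `name`, `family`) and `config`.
#' @export
default_registry <- function(families = c("sitetype", "stability",
                                          "accessibility", "supplementary",
                                          "conservation", "snp",
                                          "descriptor"),
                             config = list()) {
  feats <- do.call(rbind, lapply(families, function(f) {
    data.frame(name = registry_feature_names(f), family = f,
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(feats$name)) stop("duplicate feature names in registry",
                                      call. = FALSE)
  cfg <- modifyList(list(flank_width = 30L, cons_threshold = 0.5,
                         acc_window = 10L, fold_flank = 40L,
                         fold_backend = "builtin",
                         duplex_backend = "builtin",
                         descriptor_input = "region"), config)
  structure(list(features = feats, config = cfg),
            class = "feature_registry")
}

#' Restrict a registry to a subset of feature names
#'
#' @param registry A `feature_registry`.
#' @param names Feature names to keep (order follows the registry, not
#'   `names`).
#' @return A `feature_registry` containing only those features.
#' @export
registry_subset <- function(registry, names) {
  unknown <- setdiff(names, registry$features$name)
  if (length(unknown)) stop("unknown feature name: ", unknown[1L],
                            call. = FALSE)
  registry$features <- registry$features[
    registry$features$name %in% names, , drop = FALSE]
  rownames(registry$features) <- NULL
  registry
}

#' Serialize / restore a registry
#'
#' @param registry A `feature_registry`.
#' @param path JSON file path.
#' @return `read_registry` returns a `feature_registry`.
#' @export
write_registry <- function(registry, path) {
  jsonlite::write_json(list(features = registry$features,
                            config = registry$config),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- x$config
  structure(list(features = as.data.frame(x$features),
                 config = cfg),
            class = "feature_registry")
}

## ---- family computations ----------------------------------------------

site_type_features <- function(site_type) {
  v <- as.numeric(site_type_levels() == site_type)
  names(v) <- registry_feature_names("sitetype")
  v
}

frac_in <- function(chars, set) {
  if (length(chars) == 0L) return(NA_real_)
  mean(chars %in% set)
}

accessibility_features <- function(utr_chars, start, end, target_region,
                                   clipped, cfg, fold = NULL) {
  L <- length(utr_chars)
  len <- end - start
  d5 <- start
  d3 <- L - end
  relpos <- if (L - len > 0L) start / (L - len) else 0
  f5 <- if (start > 0L)
    utr_chars[seq.int(max(0L, start - cfg$flank_width), start - 1L) + 1L]
  else character(0)
  f3 <- if (end < L)
    utr_chars[seq.int(end, min(L, end + cfg$flank_width) - 1L) + 1L]
  else character(0)
  site_b <- utr_chars[seq.int(start, end - 1L) + 1L]
  reg_chars <- seq_chars(target_region)
  out <- c(acc_d5 = d5, acc_d3 = d3, acc_dmin = min(d5, d3),
           acc_relpos = relpos, acc_utr_len = L,
           acc_au_flank5 = frac_in(f5, c("A", "U")),
           acc_au_flank3 = frac_in(f3, c("A", "U")),
           acc_au_site = frac_in(site_b, c("A", "U")),
           acc_open_dg = NA_real_,
           acc_punpaired_site = NA_real_,
           acc_punpaired_win10 = NA_real_,
           acc_gc_region = frac_in(reg_chars, c("G", "C")),
           acc_flank_clipped = as.numeric(clipped))
  if (!is.null(fold)) {
    out[["acc_open_dg"]] <- fold$dg_open
    out[["acc_punpaired_site"]] <- fold$pu_site
    out[["acc_punpaired_win10"]] <- fold$pu_win
  }
  out
}

# Fold the site's local window and summarise unpaired propensities.
fold_site <- function(utr_seq, start, end, cfg) {
  if (identical(cfg$fold_backend, "none")) return(NULL)
  if (!identical(cfg$fold_backend, "builtin")) {
    stop("fold backend '", cfg$fold_backend, "' is not available; ",
         "fall back to fold_backend = \"builtin\"", call. = FALSE)
  }
  L <- nchar(utr_seq)
  ws <- max(0L, start - cfg$fold_flank)
  we <- min(L, end + cfg$fold_flank)
  window <- substr(utr_seq, ws + 1L, we)
  prof <- fold_profile_cpp(window, start - ws, end - ws)
  pu <- prof$p_unpaired
  site_idx <- seq.int(start - ws + 1L, end - ws)
  w10s <- max(0L, start - cfg$acc_window) - ws
  w10e <- min(L, end + cfg$acc_window) - ws
  list(dg_open = prof$dg_open,
       pu_site = mean(pu[site_idx]),
       pu_win = mean(pu[seq.int(w10s + 1L, w10e)]))
}

# Watson-Crick / wobble pair predicates for supplementary pairing.
is_wc <- function(a, b) b == rna_complement(a)
is_gu <- function(a, b) (a == "G" & b == "U") | (a == "U" & b == "G")

supplementary_pairing_features <- function(mirna_chars, utr_chars,
                                           core_start) {
  n <- length(mirna_chars)
  tpos <- function(p, shift = 0L) core_start + 7L - p + shift
  pair_at <- function(p, shift = 0L) {
    t <- tpos(p, shift)
    if (t < 0L || t >= length(utr_chars)) return(FALSE)
    is_wc(mirna_chars[p], utr_chars[t + 1L])
  }
  gu_at <- function(p) {
    t <- tpos(p)
    if (t < 0L || t >= length(utr_chars)) return(FALSE)
    is_gu(mirna_chars[p], utr_chars[t + 1L])
  }
  rng13 <- intersect(13:16, seq_len(n))
  rng12 <- intersect(12:17, seq_len(n))
  rng3p <- intersect(9:n, seq_len(n))
  c13 <- sum(vapply(rng13, pair_at, logical(1L)))
  c12 <- sum(vapply(rng12, pair_at, logical(1L)))
  runs <- rle(vapply(rng12, pair_at, logical(1L)))
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  total3p <- if (length(rng3p)) sum(vapply(rng3p, pair_at, logical(1L))) else 0L
  gu13 <- sum(vapply(rng13, gu_at, logical(1L)))
  # best target-window offset within +/- 2 nt; prefer smaller |shift|,
  # then the 5'-ward shift, requiring a strict improvement to move.
  shifts <- c(0L, -1L, 1L, -2L, 2L)
  counts <- vapply(shifts, function(s)
    sum(vapply(rng13, pair_at, logical(1L), shift = s)), numeric(1L))
  best <- abs(shifts[which.max(counts)])
  c(supp_count13_16 = c13, supp_count12_17 = c12,
    supp_longest_run12_17 = as.numeric(longest),
    supp_ge3_13_16 = as.numeric(c13 >= 3),
    supp_pairs_3half = total3p, supp_gu13_16 = gu13,
    supp_best_offset = as.numeric(best))
}

cons_stats <- function(v, thr) {
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    return(c(mean = NA_real_, min = NA_real_, max = NA_real_,
             frac = NA_real_))
  }
  c(mean = mean(v), min = min(v), max = max(v), frac = mean(v > thr))
}

conservation_features <- function(scores, start, end, core_start, cfg) {
  nm <- registry_feature_names("conservation")
  if (is.null(scores)) {
    return(stats::setNames(rep(NA_real_, 16L), nm))
  }
  L <- length(scores)
  slice <- function(a, b) {
    a <- max(0L, a); b <- min(L, b)
    if (b <= a) return(numeric(0))
    scores[(a + 1L):b]
  }
  out <- c(cons_stats(slice(core_start, core_start + 6L), cfg$cons_threshold),
           cons_stats(slice(start, end), cfg$cons_threshold),
           cons_stats(slice(start - cfg$flank_width, start),
                      cfg$cons_threshold),
           cons_stats(slice(end, end + cfg$flank_width), cfg$cons_threshold))
  stats::setNames(out, nm)
}

snp_features <- function(snp_rows, start, end) {
  nm <- registry_feature_names("snp")
  if (is.null(snp_rows)) return(stats::setNames(rep(NA_real_, 18L), nm))
  # the eight scored positions are the 3'-most eight bases of the site
  win <- seq.int(end - 8L, end - 1L)
  any_i <- dis_i <- numeric(8L)
  for (w in 1:8) {
    pos <- win[w]
    if (pos < start) { any_i[w] <- NA_real_; dis_i[w] <- NA_real_; next }
    hit <- snp_rows$position == pos
    any_i[w] <- as.numeric(any(hit))
    dis_i[w] <- as.numeric(any(hit & snp_rows$disease_related))
  }
  in_site <- snp_rows$position >= start & snp_rows$position < end
  stats::setNames(c(any_i, dis_i, sum(in_site),
                    sum(in_site & snp_rows$disease_related)), nm)
}

kmer_freqs <- function(chars, k) {
  n <- length(chars)
  if (n < k) return(NULL)
  idx <- seq_len(n - k + 1L)
  words <- vapply(idx, function(i) paste(chars[i:(i + k - 1L)],
                                         collapse = ""), character(1L))
  tab <- table(factor(words, levels = all_kmers(k)))
  as.numeric(tab) / length(idx)
}

all_kmers <- function(k) {
  if (k == 1L) return(.BASES)
  grids <- expand.grid(rep(list(.BASES), k))[, k:1, drop = FALSE]
  apply(grids, 1, paste0, collapse = "")
}

descriptor_features <- function(seq, cfg) {
  nm <- registry_feature_names("descriptor")
  chars <- seq_chars(seq)
  n <- length(chars)
  nc <- kmer_freqs(chars, 1L)
  dnc <- kmer_freqs(chars, 2L)
  tnc <- kmer_freqs(chars, 3L)
  count <- function(b) sum(chars == b)
  z <- if (n > 0L) {
    c((count("A") + count("G") - count("C") - count("U")) / n,
      (count("A") + count("C") - count("G") - count("U")) / n,
      (count("A") + count("U") - count("G") - count("C")) / n)
  } else rep(NA_real_, 3L)
  homop <- if (n > 0L) max(rle(chars)$lengths) else NA_real_
  vals <- c(nc %||% rep(NA_real_, 4L),
            dnc %||% rep(NA_real_, 16L),
            tnc %||% rep(NA_real_, 64L),
            z,
            frac_in(chars, c("G", "C")),
            frac_in(chars, c("A", "U")),
            frac_in(chars, c("A", "G")),
            n, homop)
  stats::setNames(vals, nm)
}

## ---- featurize ---------------------------------------------------------

#' Compute feature vectors for candidate sites
#'
#' Concatenates all families enabled in the registry, in registry order.
#' Families whose resources are absent (no conservation track, no SNP
#' table) are reported as missing (`NA`), never zero-filled.
#'
#' @param sites A `candidate_sites` data frame from [scan_sites()] /
#'   [scan_corpus()].
#' @param mirnas A `mirna_set` covering all `sites$mirna_id`.
#' @param utrs A `utr_set` covering all `sites$transcript_id`.
#' @param conservation Optional: either a track data frame (see
#'   [read_conservation()]) or a named list of per-base score vectors.
#' @param snps Optional SNP table (see [read_snp_table()]).
#' @param registry A `feature_registry`; default [default_registry()].
#' @return Data frame: the site meta columns (`mirna_id`, `transcript_id`,
#'   `start`, `end`, `core_start`, `site_type`) followed by one column per
#'   registry feature. Attribute `"feature_names"` carries the feature
#'   column names in registry order.
#' @export
featurize_sites <- function(sites, mirnas, utrs, conservation = NULL,
                            snps = NULL, registry = default_registry()) {
  feats <- registry$features
  cfg <- registry$config
  fam <- unique(feats$family)
  mseq <- stats::setNames(mirnas$sequence, mirnas$id)
  useq <- stats::setNames(utrs$sequence, utrs$transcript_id)
  if (!is.null(conservation) && is.data.frame(conservation)) {
    conservation <- conservation_vectors(conservation, utrs)
  }
  snp_by_t <- if (!is.null(snps)) split(snps, snps$transcript_id) else NULL
  uchars <- lapply(useq, seq_chars)
  mchars <- lapply(mseq, seq_chars)

  n <- nrow(sites)
  vals <- matrix(NA_real_, nrow = n, ncol = nrow(feats),
                 dimnames = list(NULL, feats$name))
  for (i in seq_len(n)) {
    s <- sites[i, ]
    uc <- uchars[[s$transcript_id]]
    mc <- mchars[[s$mirna_id]]
    if (is.null(uc)) stop("unknown transcript id: ", s$transcript_id,
                          call. = FALSE)
    if (is.null(mc)) stop("unknown miRNA id: ", s$mirna_id, call. = FALSE)
    row <- numeric(0)
    if ("sitetype" %in% fam) row <- c(row, site_type_features(s$site_type))
    if ("stability" %in% fam) {
      row <- c(row, duplex_energy(mseq[[s$mirna_id]], useq[[s$transcript_id]],
                                  s$core_start, cfg$duplex_backend))
    }
    if ("accessibility" %in% fam) {
      fold <- fold_site(useq[[s$transcript_id]], s$start, s$end, cfg)
      row <- c(row, accessibility_features(uc, s$start, s$end,
                                           s$target_region, s$clipped,
                                           cfg, fold))
    }
    if ("supplementary" %in% fam) {
      row <- c(row, supplementary_pairing_features(mc, uc, s$core_start))
    }
    if ("conservation" %in% fam) {
      row <- c(row, conservation_features(conservation[[s$transcript_id]],
                                          s$start, s$end, s$core_start, cfg))
    }
    if ("snp" %in% fam) {
      srows <- if (is.null(snp_by_t)) NULL
               else snp_by_t[[s$transcript_id]] %||%
                 snps[0, , drop = FALSE]
      row <- c(row, snp_features(srows, s$start, s$end))
    }
    if ("descriptor" %in% fam) {
      input <- if (identical(cfg$descriptor_input, "site"))
        substr(useq[[s$transcript_id]], s$start + 1L, s$end)
      else s$target_region
      row <- c(row, descriptor_features(input, cfg))
    }
    if (!all(feats$name %in% names(row))) {
      stop("registry/feature-name mismatch: ",
           setdiff(feats$name, names(row))[1L], call. = FALSE)
    }
    vals[i, ] <- row[feats$name]
  }
  meta <- sites[, c("mirna_id", "transcript_id", "start", "end",
                    "core_start", "site_type"), drop = FALSE]
  out <- cbind(meta, as.data.frame(vals))
  rownames(out) <- NULL
  attr(out, "feature_names") <- feats$name
  out
}

#' Extract the numeric feature matrix from a featurized data frame
#'
#' @param featurized Output of [featurize_sites()] (or a dataset carrying
#'   the same feature columns).
#' @param feature_names Which features to extract; defaults to the
#'   `"feature_names"` attribute.
#' @return Numeric matrix, one row per site.
#' @export
feature_matrix <- function(featurized,
                           feature_names = attr(featurized,
                                                "feature_names")) {
  missing_cols <- setdiff(feature_names, names(featurized))
  if (length(missing_cols)) stop("missing feature column: ",
                                 missing_cols[1L], call. = FALSE)
  as.matrix(featurized[, feature_names, drop = FALSE])
}

#' Per-feature association with the class label
#'
#' Continuous features are tested with the Wilcoxon rank-sum test;
#' indicator features (values in \{0, 1\}) with a 2x2 chi-square test.
#' Constant (zero-variance) features are flagged non-informative rather
#' than erroring.
#'
#' @param X Numeric feature matrix (columns named).
#' @param y Binary labels (0/1 or logical), length `nrow(X)`.
#' @return Data frame `feature`, `test`, `statistic`, `p_value`, `note`,
#'   sorted by p-value (non-informative features last).
#' @export
feature_class_association <- function(X, y) {
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2L) stop("both classes required", call. = FALSE)
  rows <- lapply(colnames(X), function(f) {
    v <- X[, f]
    ok <- !is.na(v)
    vv <- v[ok]; yy <- y[ok]
    if (length(vv) == 0L || length(unique(vv)) < 2L ||
        length(unique(yy)) < 2L) {
      return(data.frame(feature = f, test = "none", statistic = NA_real_,
                        p_value = NA_real_, note = "non-informative",
                        stringsAsFactors = FALSE))
    }
    if (all(vv %in% c(0, 1))) {
      tab <- table(factor(vv, levels = c(0, 1)),
                   factor(yy, levels = c(0, 1)))
      if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
        return(data.frame(feature = f, test = "chisq", statistic = NA_real_,
                          p_value = NA_real_, note = "non-informative",
                          stringsAsFactors = FALSE))
      }
      ts <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      data.frame(feature = f, test = "chisq",
                 statistic = unname(ts$statistic),
                 p_value = ts$p.value, note = "",
                 stringsAsFactors = FALSE)
    } else {
      ts <- suppressWarnings(stats::wilcox.test(vv[yy == 1], vv[yy == 0]))
      data.frame(feature = f, test = "wilcoxon",
                 statistic = unname(ts$statistic),
                 p_value = ts$p.value, note = "",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(is.na(out$p_value), out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
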