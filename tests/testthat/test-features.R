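test_that("default registry has 154 features with the stated family sizes", {
  reg <- default_registry()
  expect_equal(nrow(reg$features), 154L)
  expect_equal(as.vector(table(reg$features$family)[
    c("sitetype", "stability", "accessibility", "supplementary",
      "conservation", "snp", "descriptor")]),
    c(4L, 4L, 13L, 7L, 16L, 18L, 92L))
  expect_false(anyDuplicated(reg$features$name) > 0)
})

test_that("registry restriction and serialization round trip", {
  reg <- default_registry()
  sub <- registry_subset(reg, c("acc_d5", "sitetype_8mer"))
  expect_equal(sub$features$name, c("sitetype_8mer", "acc_d5"))  # reg order
  expect_error(registry_subset(reg, "nope"), "unknown feature")
  p <- withr::local_tempfile(fileext = ".json")
  write_registry(reg, p)
  reg2 <- read_registry(p)
  expect_equal(reg2$features$name, reg$features$name)
  expect_equal(reg2$config$cons_threshold, reg$config$cons_threshold)
})

test_that("site-type indicators are one-hot", {
  for (ty in c("6mer", "7mer-A1", "7mer-m8", "8mer")) {
    v <- mirtarscan:::site_type_features(ty)
    expect_equal(sum(v), 1)
    expect_true(all(v %in% c(0, 1)))
  }
  expect_equal(unname(mirtarscan:::site_type_features("8mer")),
               c(0, 0, 0, 1))
  expect_equal(unname(mirtarscan:::site_type_features("6mer")),
               c(1, 0, 0, 0))
})

test_that("accessibility features satisfy the distance identity", {
  set.seed(31)
  reg <- default_registry(config = list(fold_backend = "none"))
  n_sites <- 0L
  for (rep in 1:30) {
    m <- random_rna_str(22L)
    u <- random_rna_str(sample(80:300, 1L))
    # implant the core motif so at least one site always exists
    core <- mirtarscan:::seed_motifs(m)$m6
    o <- sample.int(nchar(u) - 20L, 1L) + 6L
    substr(u, o + 1L, o + 6L) <- core
    s <- scan_sites(m, u)
    expect_gte(nrow(s), 1L)
    n_sites <- n_sites + nrow(s)
    f <- featurize_sites(s, data.frame(id = "mirna", sequence = m),
                         data.frame(transcript_id = "utr", gene_id = NA,
                                    sequence = u),
                         registry = reg)
    expect_equal(f$acc_d5 + (s$end - s$start) + f$acc_d3,
                 rep(nchar(u), nrow(s)))
  }
  expect_gte(n_sites, 30L)
})

test_that("flank AU fractions match hand counts on a designed UTR", {
  # UTR: 30 A's | site ACAUUCCA | 15 G's then 15 U's
  u <- paste0(strrep("A", 30), "ACAUUCCA", strrep("G", 15), strrep("U", 15))
  s <- scan_sites(MIR1, u)
  expect_equal(s$site_type, "8mer")
  f <- featurize_sites(
    s, data.frame(id = s$mirna_id, sequence = MIR1),
    data.frame(transcript_id = s$transcript_id, gene_id = NA, sequence = u),
    registry = default_registry(config = list(fold_backend = "none")))
  expect_equal(f$acc_au_flank5, 1.0)           # 30 A's
  expect_equal(f$acc_au_flank3, 0.5)           # 15 G + 15 U
  expect_equal(f$acc_au_site, 5 / 8)           # ACAUUCCA: 5 of 8 A/U
  expect_equal(f$acc_d5, 30)
})

test_that("site at UTR position 0 has zero 5' distance", {
  u <- paste0("CAUUCC", "A", strrep("G", 20))
  s <- scan_sites(MIR1, u)
  f <- featurize_sites(
    s, data.frame(id = s$mirna_id, sequence = MIR1),
    data.frame(transcript_id = s$transcript_id, gene_id = NA, sequence = u),
    registry = default_registry(config = list(fold_backend = "none")))
  expect_equal(f$acc_d5, 0)
})

test_that("fold backend yields finite opening energies and propensities", {
  u <- paste0(strrep("G", 20), "ACAUUCCA", strrep("C", 20))
  s <- scan_sites(MIR1, u)
  f <- featurize_sites(
    s, data.frame(id = s$mirna_id, sequence = MIR1),
    data.frame(transcript_id = s$transcript_id, gene_id = NA, sequence = u))
  expect_gte(f$acc_open_dg, 0)
  expect_true(f$acc_punpaired_site >= 0 && f$acc_punpaired_site <= 1)
  expect_error(
    featurize_sites(s, data.frame(id = s$mirna_id, sequence = MIR1),
                    data.frame(transcript_id = s$transcript_id,
                               gene_id = NA, sequence = u),
                    registry = default_registry(
                      config = list(fold_backend = "rnaplfold"))),
    "fall back")
})

test_that("supplementary pairing counts match constructed geometries", {
  mc <- strsplit(MIR1, "")[[1L]]
  core <- "CAUUCC"                               # core at offset 9
  # perfect 13-16 patch at positions 0-3 (position o-9 pairs p=16)
  patch <- unname(COMP[mc[16:13]])
  utr <- paste(c(patch, rep("C", 5L), strsplit(core, "")[[1L]], "U", "C"),
               collapse = "")
  f <- mirtarscan:::supplementary_pairing_features(
    mc, strsplit(utr, "")[[1L]], 9L)
  expect_equal(f[["supp_count13_16"]], 4)
  expect_equal(f[["supp_ge3_13_16"]], 1)
  expect_equal(f[["supp_best_offset"]], 0)

  # pairs at miRNA 13 and 14 only -> longest run over 12-17 is 2
  # (position 4, opposite miRNA 12, is set to G so p12 does not pair)
  patch2 <- c("G", "G", unname(COMP[mc[14:13]]))
  stopifnot(!any(patch2[1:2] == COMP[mc[16:15]]))
  utr2 <- paste(c(patch2, "G", rep("C", 4L), strsplit(core, "")[[1L]],
                  "U", "C"), collapse = "")
  f2 <- mirtarscan:::supplementary_pairing_features(
    mc, strsplit(utr2, "")[[1L]], 9L)
  expect_equal(f2[["supp_count13_16"]], 2)
  expect_equal(f2[["supp_longest_run12_17"]], 2)

  # zero complementarity in the 13-16 window
  anti <- rep("G", 4L)
  stopifnot(!any(anti == COMP[mc[16:13]]))
  utr3 <- paste(c(anti, rep("C", 5L), strsplit(core, "")[[1L]], "U", "C"),
                collapse = "")
  f3 <- mirtarscan:::supplementary_pairing_features(
    mc, strsplit(utr3, "")[[1L]], 9L)
  expect_equal(f3[["supp_count13_16"]], 0)
})

test_that("conservation features summarise tracks per region", {
  u <- strrep("G", 100)
  s <- scan_sites(MIR1, paste0(strrep("G", 40), "ACAUUCCA",
                               strrep("G", 40)))
  cfg <- default_registry()$config
  # constant track
  f <- mirtarscan:::conservation_features(rep(0.8, 88), s$start, s$end,
                                          s$core_start, cfg)
  expect_equal(unname(f[c("cons_core_mean", "cons_site_mean",
                          "cons_flank5_mean", "cons_flank3_mean")]),
               rep(0.8, 4))
  expect_equal(unname(f["cons_site_frac"]), 1.0)
  # step track: 1.0 over the site, 0.0 elsewhere
  v <- rep(0, 88)
  v[(s$start + 1L):s$end] <- 1
  f2 <- mirtarscan:::conservation_features(v, s$start, s$end,
                                           s$core_start, cfg)
  expect_equal(unname(f2["cons_site_mean"]), 1.0)
  expect_equal(unname(f2["cons_flank5_mean"]), 0.0)
  expect_equal(unname(f2["cons_flank3_mean"]), 0.0)
  # flanks uncovered -> flank features missing, site present
  v3 <- rep(NA_real_, 88)
  v3[(s$start + 1L):s$end] <- 0.7
  f3 <- mirtarscan:::conservation_features(v3, s$start, s$end,
                                           s$core_start, cfg)
  expect_true(is.na(f3[["cons_flank5_mean"]]))
  expect_equal(f3[["cons_site_mean"]], 0.7)
  expect_true(all(is.na(mirtarscan:::conservation_features(
    NULL, s$start, s$end, s$core_start, cfg))))
})

test_that("SNP features index the 3'-most eight site positions", {
  # 8mer site spanning [start, end)
  start <- 40L; end <- 48L
  empty <- data.frame(transcript_id = character(0), position = integer(0),
                      disease_related = logical(0))
  f0 <- mirtarscan:::snp_features(empty, start, end)
  expect_equal(unname(f0[c("snp_count", "snp_dis_count")]), c(0, 0))
  expect_true(all(f0[paste0("snp_any_pos", 1:8)] == 0))

  # one disease SNP at site position 3 (the third of the eight positions)
  snp <- data.frame(transcript_id = "t", position = end - 8L + 2L,
                    disease_related = TRUE)
  f1 <- mirtarscan:::snp_features(snp, start, end)
  expect_equal(f1[["snp_any_pos3"]], 1)
  expect_equal(f1[["snp_dis_pos3"]], 1)
  expect_equal(unname(f1[c("snp_count", "snp_dis_count")]), c(1, 1))

  # two non-disease SNPs in the site
  snp2 <- data.frame(transcript_id = "t", position = c(start, start + 4L),
                     disease_related = FALSE)
  f2 <- mirtarscan:::snp_features(snp2, start, end)
  expect_equal(unname(f2[c("snp_count", "snp_dis_count")]), c(2, 0))

  # 6mer site: the two absent window positions are missing
  f3 <- mirtarscan:::snp_features(empty, 40L, 46L)
  expect_true(is.na(f3[["snp_any_pos1"]]) && is.na(f3[["snp_any_pos2"]]))
  expect_equal(f3[["snp_any_pos3"]], 0)

  # absent table entirely -> all missing
  f4 <- mirtarscan:::snp_features(NULL, start, end)
  expect_true(all(is.na(f4)))
})

test_that("descriptor features match hand-counted compositions", {
  cfg <- default_registry()$config
  f <- mirtarscan:::descriptor_features("AAAA", cfg)
  expect_equal(unname(f[paste0("desc_nc_", c("A", "C", "G", "U"))]),
               c(1, 0, 0, 0))
  expect_equal(f[["desc_homopolymer"]], 4)

  f2 <- mirtarscan:::descriptor_features("ACGU", cfg)
  expect_equal(unname(f2[c("desc_dnc_AC", "desc_dnc_CG", "desc_dnc_GU")]),
               rep(1 / 3, 3))
  expect_equal(sum(f2[grep("^desc_dnc_", names(f2))]), 1)
  expect_true(all(is.na(f2[grep("^desc_tnc_", names(f2))]) == FALSE))
  expect_equal(f2[["desc_gc"]], 0.5)
  expect_equal(f2[["desc_purine"]], 0.5)

  # k-mer families sum to 1 on random regions; counts match naive recount
  set.seed(9)
  for (rep in 1:20) {
    r <- random_rna_str(sample(10:60, 1L))
    fr <- mirtarscan:::descriptor_features(r, cfg)
    for (k in 1:3) {
      fam <- fr[grep(paste0("^desc_", c("nc", "dnc", "tnc")[k], "_"),
                     names(fr))]
      expect_equal(sum(fam), 1, tolerance = 1e-12)
      naive <- oracle_kmer(r, k)
      for (w in names(naive)) {
        expect_equal(fam[[paste0("desc_", c("nc", "dnc", "tnc")[k], "_",
                                 w)]],
                     unname(naive[w]), tolerance = 1e-12)
      }
    }
  }
  # region shorter than k -> family missing
  fs <- mirtarscan:::descriptor_features("AC", cfg)
  expect_true(all(is.na(fs[grep("^desc_tnc_", names(fs))])))
  expect_false(anyNA(fs[grep("^desc_dnc_", names(fs))]))
})

test_that("featurize honours the registry and missing resources", {
  corpus <- small_corpus(seed = 3L, n_transcripts = 10L)
  sites <- scan_corpus(corpus$mirnas, corpus$utrs)[1:5, ]
  class(sites) <- c("candidate_sites", "data.frame")
  full <- featurize_sites(sites, corpus$mirnas, corpus$utrs,
                          conservation = corpus$conservation,
                          snps = corpus$snps)
  expect_equal(length(attr(full, "feature_names")), 154L)
  expect_false(anyNA(full$cons_site_mean))

  nores <- featurize_sites(sites, corpus$mirnas, corpus$utrs)
  expect_true(all(is.na(nores[, grep("^cons_", names(nores))])))
  expect_true(all(is.na(nores[, grep("^snp_", names(nores))])))

  sub <- registry_subset(default_registry(),
                         c("stab_dg_total", "acc_d5", "desc_gc"))
  f22 <- featurize_sites(sites, corpus$mirnas, corpus$utrs, registry = sub)
  expect_equal(length(attr(f22, "feature_names")), 3L)
})

test_that("featurize is deterministic", {
  corpus <- small_corpus(seed = 8L, n_transcripts = 8L)
  sites <- scan_corpus(corpus$mirnas, corpus$utrs)[1:4, ]
  class(sites) <- c("candidate_sites", "data.frame")
  a <- featurize_sites(sites, corpus$mirnas, corpus$utrs,
                       conservation = corpus$conservation,
                       snps = corpus$snps)
  b <- featurize_sites(sites, corpus$mirnas, corpus$utrs,
                       conservation = corpus$conservation,
                       snps = corpus$snps)
  expect_identical(a, b)
})

test_that("feature/class association ranks separating features first", {
  set.seed(21)
  n <- 40L
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(sep = y * 10 + runif(n),          # perfectly separating
             same = rep(1:5, 8),               # identical across classes
             const = rep(2, n),                # constant
             ind = rbinom(n, 1, 0.5))          # indicator, uninformative
  tab <- feature_class_association(X, y)
  expect_equal(tab$feature[1L], "sep")
  # perfectly separated rank-sum statistic hits its extreme value
  expect_equal(tab$statistic[tab$feature == "sep"], (n / 2)^2)
  expect_gt(tab$p_value[tab$feature == "same"], 0.9)
  expect_equal(tab$note[tab$feature == "const"], "non-informative")
  expect_equal(tab$test[tab$feature == "ind"], "chisq")
  expect_error(feature_class_association(X, rep(1, n)), "both classes")
})
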