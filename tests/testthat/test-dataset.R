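test_that("negative filtering is a set difference keyed on (miRNA, gene)", {
  cand <- data.frame(mirna_id = paste0("m", c(1, 1, 2, 2, 3)),
                     gene_id = paste0("g", c(1, 2, 1, 2, 3)),
                     stringsAsFactors = FALSE)
  val <- data.frame(mirna_id = c("m1", "m2"), gene_id = c("g1", "g2"),
                    stringsAsFactors = FALSE)
  out <- filter_negatives(cand, val)
  expect_equal(nrow(out), 3L)
  expect_equal(attr(out, "removed"), 2L)

  none <- filter_negatives(cand, val[0, ])
  expect_equal(nrow(none), 5L)

  all_removed <- filter_negatives(cand, cand)
  expect_equal(nrow(all_removed), 0L)
  expect_equal(attr(all_removed, "removed"), 5L)
})

test_that("negative filtering equals brute-force set difference", {
  set.seed(17)
  for (rep in 1:100) {
    cand <- data.frame(
      mirna_id = sample(paste0("m", 1:5), 20, replace = TRUE),
      gene_id = sample(paste0("g", 1:5), 20, replace = TRUE),
      stringsAsFactors = FALSE)
    val <- unique(data.frame(
      mirna_id = sample(paste0("m", 1:5), 8, replace = TRUE),
      gene_id = sample(paste0("g", 1:5), 8, replace = TRUE),
      stringsAsFactors = FALSE))
    got <- filter_negatives(cand, val)
    keep <- !(paste(cand$mirna_id, cand$gene_id) %in%
                paste(val$mirna_id, val$gene_id))
    expect_equal(got$mirna_id, cand$mirna_id[keep])
    expect_equal(got$gene_id, cand$gene_id[keep])
  }
})

test_that("under-sampling yields exactly 1:1 for arbitrary sizes", {
  set.seed(23)
  for (np in c(1L, 7L, 30L)) for (nn in c(1L, 12L, 200L)) {
    pos <- data.frame(i = seq_len(np))
    neg <- data.frame(i = seq_len(nn) + 1000L)
    bal <- undersample_balance(pos, neg, seed = np * 100L + nn)
    expect_equal(nrow(bal$positives), nrow(bal$negatives))
    expect_equal(nrow(bal$positives), min(np, nn))
    expect_true(all(bal$negatives$i %in% neg$i))
    expect_true(all(bal$positives$i %in% pos$i))
  }
  b1 <- undersample_balance(data.frame(i = 1:10),
                            data.frame(i = 1:1000), seed = 4L)
  b2 <- undersample_balance(data.frame(i = 1:10),
                            data.frame(i = 1:1000), seed = 4L)
  expect_identical(b1, b2)
  expect_error(undersample_balance(data.frame(), data.frame(i = 1)),
               "non-empty")
})

test_that("expression labelling maps the stated thresholds inclusively", {
  rec <- data.frame(mirna_id = "m", gene_id = paste0("g", 1:7),
                    relative_expression = c(0.55, 0.60, 0.61, 0.80,
                                            1.00, 1.05, 1.10),
                    stringsAsFactors = FALSE)
  lab <- label_tm_from_expression(rec)
  lookup <- stats::setNames(lab$label, lab$gene_id)
  expect_equal(unname(lookup["g1"]), "repressed")
  expect_equal(unname(lookup["g2"]), "repressed")    # boundary inclusive
  expect_false("g3" %in% lab$gene_id)                # excluded
  expect_false("g4" %in% lab$gene_id)
  expect_equal(unname(lookup["g5"]), "unaffected")   # boundary inclusive
  expect_equal(unname(lookup["g6"]), "unaffected")
  expect_equal(unname(lookup["g7"]), "unaffected")   # boundary inclusive
  expect_equal(attr(lab, "n_excluded"), 2L)

  expect_error(label_tm_from_expression(
    data.frame(mirna_id = "m", gene_id = "g",
               relative_expression = -0.1)), "negative")
})

test_that("every expression record maps to exactly one label bucket", {
  set.seed(19)
  rec <- data.frame(mirna_id = "m", gene_id = paste0("g", 1:500),
                    relative_expression = runif(500, 0, 1.5),
                    stringsAsFactors = FALSE)
  lab <- label_tm_from_expression(rec)
  n_pos <- sum(rec$relative_expression <= 0.60)
  n_neg <- sum(rec$relative_expression >= 1.00 &
                 rec$relative_expression <= 1.10)
  expect_equal(sum(lab$label == "repressed"), n_pos)
  expect_equal(sum(lab$label == "unaffected"), n_neg)
  expect_equal(nrow(lab) + attr(lab, "n_excluded"), 500L)
})

test_that("blind split is stratified, exhaustive, and deterministic", {
  y <- rep(c(0, 1), each = 50)
  sp <- split_blind_test(y, fraction = 0.2, seed = 9L)
  expect_equal(length(sp$blind), 20L)
  expect_equal(sum(y[sp$blind]), 10)
  expect_setequal(c(sp$train, sp$blind), seq_along(y))
  sp2 <- split_blind_test(y, fraction = 0.2, seed = 9L)
  expect_identical(sp, sp2)
  expect_error(split_blind_test(y, fraction = 0), "fraction")
  expect_error(split_blind_test(c(0, 1, 1, 1), fraction = 0.1), "empty")
})

test_that("entity splits hold out whole miRNAs / transcripts", {
  set.seed(3)
  ds <- expand.grid(mirna_id = paste0("m", 1:10),
                    transcript_id = paste0("t", 1:8),
                    stringsAsFactors = FALSE)
  sp <- split_by_entity(ds, "mirna", fraction = 0.3, seed = 2L)
  expect_equal(length(sp$held_mirnas), 3L)
  expect_false(any(ds$mirna_id[sp$train] %in% sp$held_mirnas))
  expect_true(all(ds$mirna_id[sp$test] %in% sp$held_mirnas))

  sb <- split_by_entity(ds, "both", fraction = 0.3, seed = 2L)
  expect_false(any(ds$mirna_id[sb$train] %in% sb$held_mirnas))
  expect_false(any(ds$transcript_id[sb$train] %in% sb$held_transcripts))
  expect_true(all(ds$mirna_id[sb$test] %in% sb$held_mirnas &
                    ds$transcript_id[sb$test] %in% sb$held_transcripts))

  one <- data.frame(mirna_id = "m1", transcript_id = paste0("t", 1:5))
  expect_error(split_by_entity(one, "mirna"), "too few")
})

test_that("the corpus TS dataset is balanced and withheld sites excluded", {
  corpus <- small_corpus(seed = 12L, n_transcripts = 60L)
  ds <- build_ts_dataset(corpus, seed = 12L)
  expect_equal(sum(ds$label == 1L), sum(ds$label == 0L))
  # no positive row corresponds to a withheld implant
  withheld <- corpus$manifest[corpus$manifest$withheld, ]
  if (nrow(withheld)) {
    k_pos <- paste(ds$mirna_id[ds$label == 1L],
                   ds$transcript_id[ds$label == 1L],
                   ds$core_start[ds$label == 1L])
    expect_false(any(paste(withheld$mirna_id, withheld$transcript_id,
                           withheld$core_start) %in% k_pos))
  }
  # negatives never share a validated (miRNA, gene) pair
  neg <- ds[ds$label == 0L, ]
  gid <- stats::setNames(corpus$utrs$gene_id, corpus$utrs$transcript_id)
  expect_false(any(paste(neg$mirna_id, gid[neg$transcript_id]) %in%
                     paste(corpus$validated_pairs$mirna_id,
                           corpus$validated_pairs$gene_id)))
})
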