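test_that("promoters span 5 kb upstream to 0.5 kb downstream of the TSS", {
  g <- data.frame(id = c("G1", "G2", "G3"), chrom = "chr1",
                  tss = c(10000, 10000, 3000), strand = c("+", "-", "+"))
  p <- derive_promoter(g)
  expect_equal(p$promoter_start, c(5000, 9500, 0))   # third is clipped at 0
  expect_equal(p$promoter_end, c(10500, 15000, 3500))
})

test_that("candidate pairs respect the 1 Mbp window and midpoint distance", {
  enh <- make_enhancer_set("chr1", 20000, 20500, "E1",
                           cbind(A = 1, B = 2, C = 3))
  genes <- make_genes("chr1", 10000, 15000, "G1", "+")
  p <- build_candidate_pairs(enh, genes)
  expect_equal(nrow(p), 1)
  expect_equal(p$distance, 10250)   # midpoint 20250 to TSS 10000

  far <- make_genes("chr1", 2.5e6, 2.51e6, "Gfar", "+")
  expect_equal(nrow(build_candidate_pairs(enh, far)), 0)
})

test_that("pair enumeration matches brute force on a 3x4 fixture", {
  fx <- tiny_fixture()
  p <- build_candidate_pairs(fx$enhancers, fx$genes)
  # brute-force double loop
  el <- fx$enhancers$elements
  expected <- 0
  for (i in seq_len(nrow(el))) for (j in seq_len(nrow(fx$genes))) {
    d <- oracle_dis(el$start[i], el$end[i], fx$genes$tss[j])
    if (el$chrom[i] == fx$genes$chrom[j] && d <= 1e6) expected <- expected + 1
  }
  expect_equal(nrow(p), expected)
  expect_equal(expected, 12)                        # all in range: E x G
  expect_false(any(duplicated(p[c("enhancer_id", "gene_id")])))
  expect_true(all(p$distance >= 0 & p$distance <= 1e6))
})

test_that("labeling requires both anchors, either assignment", {
  fx <- tiny_fixture()
  pairs <- build_candidate_pairs(fx$enhancers, fx$genes)
  # one loop: anchor1 over E1, anchor2 over G1's promoter [25000, 30500)
  ints <- data.frame(chrom1 = "chr1", start1 = 9900, end1 = 10600,
                     chrom2 = "chr1", start2 = 29000, end2 = 31000,
                     cell_type = "A", source = "test",
                     stringsAsFactors = FALSE)
  lab <- label_pairs(pairs, ints, fx$enhancers, fx$genes, cell_type = "A")
  expect_equal(lab$label[lab$enhancer_id == "E1" & lab$gene_id == "G1"],
               "positive")
  expect_equal(sum(lab$label == "positive"), 1)

  # swapped anchor assignment still labels positive
  swapped <- ints[, c(4:6, 1:3, 7:8)]
  colnames(swapped) <- colnames(ints)
  lab2 <- label_pairs(pairs, swapped, fx$enhancers, fx$genes, cell_type = "A")
  expect_equal(sum(lab2$label == "positive"), 1)

  # enhancer hit but promoter missed on the other anchor -> negative
  ints$start2 <- 500000; ints$end2 <- 501000
  lab3 <- label_pairs(pairs, ints, fx$enhancers, fx$genes, cell_type = "A")
  expect_equal(sum(lab3$label == "positive"), 0)
  # ... unless the stricter rule downgrades the half-touching pair
  lab4 <- label_pairs(pairs, ints, fx$enhancers, fx$genes, cell_type = "A",
                      rule = "either_touch")
  expect_true(all(lab4$label[lab4$enhancer_id == "E1"] == "unlabeled"))

  # loops in another cell type never affect the focal labels
  ints2 <- data.frame(chrom1 = "chr1", start1 = 9900, end1 = 10600,
                      chrom2 = "chr1", start2 = 29000, end2 = 31000,
                      cell_type = "B", source = "test",
                      stringsAsFactors = FALSE)
  lab5 <- label_pairs(pairs, ints2, fx$enhancers, fx$genes, cell_type = "A")
  expect_equal(sum(lab5$label == "positive"), 0)
})

test_that("labeling agrees with the brute-force oracle on random fixtures", {
  for (seed in 1:3) {
    set.seed(seed)
    enh <- rand_enhancer_set(40, n_ct = 3, seed = seed)
    gstart <- sort(sample.int(9e5, 12))
    genes <- make_genes("chr1", gstart, gstart + 9000,
                        sprintf("G%02d", 1:12),
                        sample(c("+", "-"), 12, replace = TRUE))
    a1 <- sample.int(9e5, 25)
    a2 <- sample.int(9e5, 25)
    ints <- data.frame(chrom1 = "chr1", start1 = a1, end1 = a1 + 4000,
                       chrom2 = "chr1", start2 = a2, end2 = a2 + 4000,
                       cell_type = "CT", source = "test",
                       stringsAsFactors = FALSE)
    pairs <- build_candidate_pairs(enh, genes)
    got <- label_pairs(pairs, ints, enh, genes)
    want <- oracle_labels(pairs, ints, enh, genes)
    expect_equal(got$label, want)
    expect_true(all(got$label %in% c("positive", "negative")))
  }
})

test_that("training filters keep supported enhancers and expressed targets", {
  fx <- tiny_fixture()
  pairs <- build_candidate_pairs(fx$enhancers, fx$genes)
  pairs$label <- "negative"
  support <- c(E1 = 0.6, E2 = 0.4, E3 = 1.0)
  kept <- filter_training_pairs(pairs, support, fx$expression, "A")
  expect_false(any(kept$enhancer_id == "E2"))           # under-supported
  expect_false(any(kept$gene_id == "G3"))               # FPKM == 0 in A
  expect_true(all(kept$enhancer_id %in% c("E1", "E3")))

  expect_error(filter_training_pairs(pairs, support[-1], fx$expression, "A"),
               "absent from support")
})

test_that("balanced training draw is half the positives plus equal negatives", {
  set.seed(9)
  pairs <- data.frame(enhancer_id = sprintf("E%d", 1:1100),
                      gene_id = "G1", chrom = "chr1", distance = 1,
                      label = rep(c("positive", "negative"), c(100, 1000)),
                      stringsAsFactors = FALSE)
  sp <- balance_training_set(pairs, seed = 4)
  expect_equal(sum(sp$train$label == "positive"), 50)
  expect_equal(sum(sp$train$label == "negative"), 50)
  expect_equal(nrow(sp$holdout), 1000)
  expect_equal(sum(sp$holdout$label == "positive"), 50)

  sp2 <- balance_training_set(pairs, seed = 4)
  expect_identical(sp$train, sp2$train)                 # reproducible
  sp3 <- balance_training_set(pairs, seed = 5)
  expect_false(identical(sp$train$enhancer_id, sp3$train$enhancer_id))

  few <- pairs[c(1:10, 101:103), ]
  expect_error(balance_training_set(few, seed = 1), "insufficient negatives")
  expect_error(balance_training_set(pairs[1, ], seed = 1), "at least 2")
})

test_that("negative subsampling reaches the requested class ratio", {
  pairs <- data.frame(enhancer_id = sprintf("E%d", 1:660), gene_id = "G1",
                      chrom = "chr1", distance = 1,
                      label = rep(c("positive", "negative"), c(60, 600)),
                      stringsAsFactors = FALSE)
  ub <- subsample_negatives(pairs, ratio = 5, seed = 2)
  expect_equal(sum(ub$label == "positive"), 60)
  expect_equal(sum(ub$label == "negative"), 300)
  expect_identical(ub, subsample_negatives(pairs, ratio = 5, seed = 2))
})
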