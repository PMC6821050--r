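test_that("pearson correlation handles hand cases and degenerate input", {
  expect_equal(pearson_cor(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(pearson_cor(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8,
               tolerance = 1e-12)
  expect_equal(pearson_cor(c(5, 5, 5), c(1, 2, 3)), 0)   # zero variance -> 0
  expect_error(pearson_cor(1:3, 1:4), "length")
  expect_error(pearson_cor(1:2, 2:1), "at least 3")
})

test_that("pearson matches the deviation-product oracle on random vectors", {
  set.seed(7)
  for (i in 1:100) {
    m <- sample(3:30, 1)
    x <- rnorm(m); y <- rnorm(m)
    expect_equal(pearson_cor(x, y), oracle_pearson(x, y), tolerance = 1e-12)
  }
})

test_that("EGC correlates activity with expression over the whole panel", {
  set.seed(21)
  expr_vec <- rexp(10, 1 / 5)
  enh <- make_enhancer_set("chr1", 1000, 1500, "E1",
                           matrix(2 * expr_vec, nrow = 1,
                                  dimnames = list(NULL, sprintf("C%02d", 1:10))))
  expr <- matrix(expr_vec, nrow = 1,
                 dimnames = list("G1", sprintf("C%02d", 1:10)))
  expect_equal(compute_egc(enh, expr, "E1", "G1"), 1.0)   # proportional

  flat <- enh
  flat$activity[1, ] <- 3
  expect_equal(compute_egc(flat, expr, "E1", "G1"), 0)    # constant activity
  expect_error(compute_egc(enh, expr[, 1:5, drop = FALSE], "E1", "G1"),
               "missing")
})

test_that("planted co-regulated pairs reach the configured correlation", {
  ds <- simulate_eg_data(sim_config(), seed = 7)
  r <- mapply(function(e, g) {
    suppressWarnings(cor(ds$enhancers$activity[e, ], ds$expression[g, ]))
  }, ds$planted$enhancer_id, ds$planted$gene_id)
  expect_equal(mean(r), 0.8, tolerance = 0.15)
  # independent recomputation route
  r2 <- mapply(function(e, g) {
    oracle_pearson(ds$enhancers$activity[e, ], ds$expression[g, ])
  }, ds$planted$enhancer_id, ds$planted$gene_id)
  expect_equal(r, r2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("GS returns the FPKM value unchanged", {
  fx <- tiny_fixture()
  expect_equal(compute_gs(fx$expression, "G1", "A"), 4.743)
  expect_equal(compute_gs(fx$expression, "G3", "A"), 0.0)
  expect_error(compute_gs(fx$expression, "G1", "Z"), "cell type")
})

test_that("DIS is the midpoint-to-TSS distance and matches the oracle", {
  enh <- make_enhancer_set("chr1", 20000, 20500, "E1", cbind(A = 1, B = 1, C = 1))
  genes <- make_genes("chr1", 10000, 15000, "G1", "+")
  expect_equal(compute_dis(enh, genes, "E1", "G1"), 10250)

  centered <- make_enhancer_set("chr1", 9800, 10200, "E1", cbind(A = 1, B = 1, C = 1))
  expect_equal(compute_dis(centered, genes, "E1", "G1"), 0)

  g2 <- make_genes("chr2", 10000, 15000, "G1", "+")
  expect_error(compute_dis(enh, g2, "E1", "G1"), "different chromosomes")

  set.seed(13)
  for (i in 1:100) {
    s <- sample.int(1e6, 1); w <- sample(100:2000, 1); t <- sample.int(1e6, 1)
    e <- make_enhancer_set("chr1", s, s + w, "E1", cbind(A = 1, B = 1, C = 1))
    g <- make_genes("chr1", t, t + 1000, "G1", "+")
    expect_identical(compute_dis(e, g, "E1", "G1"), oracle_dis(s, s + w, t))
  }
})

test_that("window context spans inner edges and clips contained elements", {
  # enhancer upstream of a + strand gene; promoter [25000, 30500)
  enh <- make_enhancer_set("chr1",
                           start = c(10000, 12000, 24500),
                           end = c(10500, 12800, 26000),
                           id = c("E1", "E2", "E3"),
                           activity = cbind(A = c(1, 2, 4), B = c(1, 1, 1),
                                            C = c(1, 1, 1)))
  genes <- make_genes("chr1", 30000, 45000, "G1", "+")
  expr <- matrix(c(3, 1, 1), 1, dimnames = list("G1", c("A", "B", "C")))
  ctx <- build_window(enh, genes, expr, "E1", "G1", "A")
  expect_equal(ctx$window, c(10500, 25000))      # inner edge to inner edge
  expect_equal(ctx$L_window, 14500)
  # E2 fully inside; E3 straddles the window end and is clipped to 500 bp
  expect_setequal(ctx$enhancers$id, c("E2", "E3"))
  expect_equal(ctx$enhancers$length[ctx$enhancers$id == "E2"], 800)
  expect_equal(ctx$enhancers$length[ctx$enhancers$id == "E3"], 500)
  expect_equal(oracle_window_sum(c(12000, 24500), c(12800, 26000), c(2, 4),
                                 10500, 25000),
               sum(ctx$enhancers$signal * ctx$enhancers$length))

  # no intervening elements: empty lists, window = plain gap
  solo <- make_enhancer_set("chr1", 10000, 10500, "E1", cbind(A = 1, B = 1, C = 1))
  ctx2 <- build_window(solo, genes, expr, "E1", "G1", "A")
  expect_equal(nrow(ctx2$enhancers), 0)
  expect_equal(ctx2$L_window, 14500)

  # abutting enhancer/promoter: degenerate window floored at 1 bp
  abut <- make_enhancer_set("chr1", 24000, 25000, "E1", cbind(A = 1, B = 1, C = 1))
  ctx3 <- build_window(abut, genes, expr, "E1", "G1", "A")
  expect_equal(ctx3$L_window, 1)
  expect_equal(compute_ews(ctx3), 0)
})

test_that("EWS and GWS follow the signal-times-length over window formulas", {
  ctx <- list(window = c(0, 1000), L_window = 1000,
              enhancers = data.frame(id = c("a", "b"), signal = c(2.0, 1.0),
                                     length = c(100, 200)),
              genes = data.frame(id = "g", signal = 5.0, length = 2000))
  expect_equal(compute_ews(ctx), 0.4)          # (2*100 + 1*200) / 1000
  ctx$L_window <- 10000
  expect_equal(compute_gws(ctx), 1.0)          # 5 * 2000 / 10000
  empty <- list(window = NULL, L_window = 1,
                enhancers = data.frame(signal = numeric(), length = numeric()),
                genes = data.frame(signal = numeric(), length = numeric()))
  expect_equal(compute_ews(empty), 0)
  expect_equal(compute_gws(empty), 0)
  # normalization identity: one element spanning the whole window at signal 1
  full <- list(window = c(0, 500), L_window = 500,
               enhancers = data.frame(id = "a", signal = 1, length = 500))
  expect_equal(compute_ews(full), 1.0)
})

test_that("EWS is invariant to splitting a contained enhancer in halves", {
  ctx_whole <- list(L_window = 1000,
                    enhancers = data.frame(signal = 3, length = 400))
  ctx_split <- list(L_window = 1000,
                    enhancers = data.frame(signal = c(3, 3), length = c(150, 250)))
  expect_equal(compute_ews(ctx_whole), compute_ews(ctx_split))
})

test_that("WEEC equals the brute-force pairwise-correlation mean", {
  set.seed(31)
  enh <- rand_enhancer_set(5, n_ct = 8, chrom_len = 5e5, seed = 31)
  genes <- make_genes("chr1", 250000, 260000, "G1", "+")
  got <- compute_weec(enh, genes, enh$elements$id[2], "G1")
  want <- oracle_weec(enh$activity, 2, c(1, 3, 4, 5))
  expect_equal(got, want, tolerance = 1e-12)

  # identical profiles give WEEC 1
  same <- make_enhancer_set("chr1", c(1000, 3000, 5000), c(1500, 3500, 5500),
                            c("E1", "E2", "E3"),
                            matrix(rep(c(1, 5, 2, 4), each = 3), nrow = 3,
                                   dimnames = list(NULL, c("A", "B", "C", "D"))))
  expect_equal(compute_weec(same, genes, "E2", "G1"), 1.0)

  # no neighbors -> defined as 0
  solo <- make_enhancer_set("chr1", 251000, 251500, "E1",
                            cbind(A = 1, B = 2, C = 3))
  expect_equal(compute_weec(solo, genes, "E1", "G1"), 0)
})

test_that("feature table composes the per-feature operations exactly", {
  fx <- tiny_fixture()
  pairs <- build_candidate_pairs(fx$enhancers, fx$genes)
  tab <- compute_feature_table(pairs, fx$enhancers, fx$genes, fx$expression, "A")
  expect_equal(colnames(tab)[(ncol(tab) - 5):ncol(tab)], EG_FEATURES)
  for (i in seq_len(nrow(tab))) {
    e <- tab$enhancer_id[i]; g <- tab$gene_id[i]
    expect_equal(tab$egc[i],
                 compute_egc(fx$enhancers, fx$expression, e, g),
                 tolerance = 1e-12)
    expect_equal(tab$gs[i], compute_gs(fx$expression, g, "A"))
    expect_equal(tab$dis[i], compute_dis(fx$enhancers, fx$genes, e, g))
    ctx <- build_window(fx$enhancers, fx$genes, fx$expression, e, g, "A")
    expect_equal(tab$ews[i], compute_ews(ctx), tolerance = 1e-12)
    expect_equal(tab$gws[i], compute_gws(ctx), tolerance = 1e-12)
    expect_equal(tab$weec[i],
                 compute_weec(fx$enhancers, fx$genes, e, g),
                 tolerance = 1e-12)
  }
  expect_error(compute_feature_table(transform(pairs, enhancer_id = "nope"),
                                     fx$enhancers, fx$genes, fx$expression, "A"),
               "nope")
})

test_that("feature table is deterministic and in range on synthetic data", {
  ds <- default_sim()
  t1 <- sim_feature_table(ds)
  t2 <- sim_feature_table(ds)
  expect_identical(t1, t2)
  expect_true(all(abs(t1$egc) <= 1 + 1e-12))
  expect_true(all(abs(t1$weec) <= 1 + 1e-12))
  expect_true(all(t1$gs >= 0 & t1$dis >= 0 & t1$ews >= 0 & t1$gws >= 0))
  expect_true(all(is.finite(as.matrix(t1[EG_FEATURES]))))
})

test_that("vectorized features agree with scalar operations on random data", {
  enh <- rand_enhancer_set(30, n_ct = 6, chrom_len = 8e5, seed = 77)
  set.seed(78)
  gstart <- sort(sample.int(7e5, 8))
  genes <- make_genes("chr1", gstart, gstart + sample(4000:20000, 8, TRUE),
                      sprintf("G%02d", 1:8),
                      sample(c("+", "-"), 8, TRUE))
  expr <- matrix(rexp(8 * 6, 1 / 4), nrow = 8,
                 dimnames = list(genes$id, enh$cell_types))
  pairs <- build_candidate_pairs(enh, genes)
  tab <- compute_feature_table(pairs, enh, genes, expr, "CT01")
  idx <- seq(1, nrow(tab), by = 7)      # spot-check a spread of pairs
  for (i in idx) {
    e <- tab$enhancer_id[i]; g <- tab$gene_id[i]
    ctx <- build_window(enh, genes, expr, e, g, "CT01")
    expect_equal(tab$ews[i], compute_ews(ctx), tolerance = 1e-12)
    expect_equal(tab$gws[i], compute_gws(ctx), tolerance = 1e-12)
    expect_equal(tab$egc[i], compute_egc(enh, expr, e, g), tolerance = 1e-12)
    expect_equal(tab$weec[i], compute_weec(enh, genes, e, g), tolerance = 1e-12)
  }
})
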