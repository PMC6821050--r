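# Independent brute-force oracles and small fixture builders shared across
# the suite. The oracles deliberately use naive loop/enumeration formulations
# so they share no code path with the package implementations they check.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  if (dx == 0 || dy == 0) return(0)
  num / sqrt(dx * dy)
}

oracle_auroc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

oracle_dis <- function(start, end, tss) {
  mid <- start + floor((end - start) / 2)
  abs(mid - tss)
}

# sum of signal x clipped length over elements intersecting [ws, we)
oracle_window_sum <- function(starts, ends, signals, ws, we) {
  total <- 0
  for (i in seq_along(starts)) {
    lo <- max(starts[i], ws)
    hi <- min(ends[i], we)
    if (hi > lo) total <- total + signals[i] * (hi - lo)
  }
  total
}

oracle_weec <- function(activity, focal_row, other_rows) {
  if (!length(other_rows)) return(0)
  vals <- numeric(length(other_rows))
  for (i in seq_along(other_rows))
    vals[i] <- oracle_pearson(activity[focal_row, ], activity[other_rows[i], ])
  mean(vals)
}

# double loop over pairs x interactions: both-anchor rule, >= 1 bp each side
oracle_labels <- function(pairs, interactions, enhancers, genes) {
  el <- enhancers$elements
  out <- character(nrow(pairs))
  ov <- function(s1, e1, s2, e2) min(e1, e2) - max(s1, s2) >= 1
  for (i in seq_len(nrow(pairs))) {
    e <- el[el$id == pairs$enhancer_id[i], ]
    g <- genes[genes$id == pairs$gene_id[i], ]
    hit <- FALSE
    for (j in seq_len(nrow(interactions))) {
      a <- interactions[j, ]
      if (a$chrom1 != e$chrom) next
      if ((ov(e$start, e$end, a$start1, a$end1) &&
           ov(g$promoter_start, g$promoter_end, a$start2, a$end2)) ||
          (ov(e$start, e$end, a$start2, a$end2) &&
           ov(g$promoter_start, g$promoter_end, a$start1, a$end1))) {
        hit <- TRUE
        break
      }
    }
    out[i] <- if (hit) "positive" else "negative"
  }
  out
}

# ---- fixture builders ----------------------------------------------------

make_enhancer_set <- function(chrom, start, end, id, activity) {
  activity <- as.matrix(activity)
  rownames(activity) <- id
  structure(list(elements = data.frame(chrom = chrom, start = start, end = end,
                                       id = id, stringsAsFactors = FALSE),
                 activity = activity,
                 cell_types = colnames(activity)),
            class = "enhancer_set")
}

make_genes <- function(chrom, start, end, id, strand) {
  g <- data.frame(chrom = chrom, start = start, end = end, id = id,
                  strand = strand, stringsAsFactors = FALSE)
  g$tss <- ifelse(g$strand == "+", g$start, g$end)
  derive_promoter(g)
}

rand_enhancer_set <- function(n, n_ct = 5, chrom_len = 1e6, seed = 1) {
  set.seed(seed)
  start <- as.numeric(sort(sample.int(chrom_len - 2000, n)))
  width <- as.numeric(sample(200:1500, n, replace = TRUE))
  act <- matrix(round(stats::rexp(n * n_ct, 1 / 3), 4), nrow = n,
                dimnames = list(NULL, sprintf("CT%02d", seq_len(n_ct))))
  make_enhancer_set("chr1", start, start + width, sprintf("E%03d", seq_len(n)), act)
}

# a tiny fully in-range 3 enhancer x 4 gene single-chromosome fixture
tiny_fixture <- function() {
  enh <- make_enhancer_set("chr1",
                           start = c(10000, 52000, 90000),
                           end = c(10500, 52600, 90400),
                           id = c("E1", "E2", "E3"),
                           activity = cbind(A = c(2, 0, 1.5),
                                            B = c(1, 3, 0.5),
                                            C = c(4, 1, 2.5)))
  genes <- make_genes("chr1",
                      start = c(30000, 60000, 71000, 120000),
                      end = c(45000, 69000, 80000, 140000),
                      id = c("G1", "G2", "G3", "G4"),
                      strand = c("+", "-", "+", "-"))
  expr <- matrix(c(4.743, 0.289, 1.2,
                   2.0, 2.5, 3.0,
                   0.0, 1.0, 2.0,
                   5.0, 0.5, 0.25),
                 nrow = 4, byrow = TRUE,
                 dimnames = list(c("G1", "G2", "G3", "G4"), c("A", "B", "C")))
  list(enhancers = enh, genes = genes, expression = expr)
}

# ---- shared expensive objects (memoised per test session) ----------------

.eglink_cache <- new.env(parent = emptyenv())

cached_obj <- function(key, expr) {
  if (!exists(key, envir = .eglink_cache, inherits = FALSE))
    assign(key, force(expr), envir = .eglink_cache)
  get(key, envir = .eglink_cache, inherits = FALSE)
}

default_sim <- function() cached_obj("sim11", simulate_eg_data(sim_config(), seed = 11))

default_features <- function() cached_obj("ft11", sim_feature_table(default_sim()))
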