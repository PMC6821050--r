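#' Configuration for the synthetic enhancer-gene dataset generator
#'
#' The generator emulates the structure observed in loop-supported
#' enhancer-gene data: interacting pairs share a latent per-cell-type factor
#' (so enhancer activity correlates with target expression across the panel),
#' interacting enhancers come in spatially co-located co-regulating clusters
#' around their target (driving the window and enhancer-enhancer correlation
#' signals), interacting genes are more highly expressed, and planted loop
#' distances follow a short-scale exponential decay while non-interacting
#' candidates arise from geometry alone.
#'
#' @param n_cell_types Panel size (default 20).
#' @param n_genes Number of genes (default 200).
#' @param n_enhancers Number of enhancers (default 800).
#' @param chrom_length Length of the single simulated chromosome in bp
#'   (default 50 Mbp; all six features are intra-chromosomal).
#' @param frac_interacting Fraction of enhancers engaged in a true loop
#'   (default 0.1).
#' @param planted_correlation Target mean activity/expression Pearson
#'   correlation of interacting pairs (default 0.8). Individual pairs draw
#'   their correlation from a Beta-shaped spread around this mean, emulating
#'   heterogeneous regulatory strength.
#' @param distance_decay_scale Exponential scale of planted loop distances in
#'   bp (default 50 kb).
#' @param background_correlation Weight of a single shared factor among
#'   background (non-interacting) elements (default 0 = independent).
#' @param activity_noise_sd Marginal SD of enhancer activity around its
#'   baseline (default 1.5 signal units).
#' @param expression_noise_sd Marginal SD of gene FPKM around its baseline
#'   (default 4).
#' @param cluster_size Enhancers per co-regulating cluster (default 3).
#' @param bystanders_per_locus Highly expressed but non-interacting genes
#'   placed near each interacting locus (default 1); they provide realistic
#'   hard negatives and populate the windows of positive pairs.
#' @param frac_silent_enhancer Fraction of interacting enhancers whose
#'   *measured* activity is background noise (default 0.05), emulating
#'   annotation failures: the loop is real but the activity track missed the
#'   element, so its correlation features are blank and only its genomic
#'   context (distance, window signals) betrays the interaction.
#' @param frac_decoupled_loci Fraction of interacting loci whose measured
#'   expression profile is decoupled from the cluster's latent factor
#'   (default 0.05), emulating noisy RNA-seq: expression stays high but the
#'   activity/expression correlation vanishes while the enhancer-enhancer
#'   correlation within the cluster survives.
#' @param anchor_halfwidth Loop anchor half-width in bp (default 2500,
#'   the resolution of high-resolution Hi-C loop calls).
#' @param activity_baseline Named vector c(background=, interacting=) of mean
#'   activity levels (defaults 2 and 6).
#' @param expression_baseline Named vector c(background=, interacting=) of
#'   mean FPKM levels (defaults 3 and 20).
#' @param null_signal When TRUE, generate a signal-free control: loops are
#'   drawn geometrically at uniform distances, no latent factor is shared, and
#'   interacting elements keep background baselines. Labels then carry no
#'   feature information.
#' @param seed Default seed used by [simulate_eg_data()].
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_cell_types = 20, n_genes = 200, n_enhancers = 800,
                       chrom_length = 5e7, frac_interacting = 0.1,
                       planted_correlation = 0.8, distance_decay_scale = 5e4,
                       background_correlation = 0, activity_noise_sd = 1.5,
                       expression_noise_sd = 4, cluster_size = 3,
                       bystanders_per_locus = 1,
                       frac_silent_enhancer = 0.05,
                       frac_decoupled_loci = 0.05,
                       anchor_halfwidth = 2500,
                       activity_baseline = c(background = 2, interacting = 6),
                       expression_baseline = c(background = 3, interacting = 20),
                       null_signal = FALSE, seed = 11L) {
  cfg <- list(n_cell_types = as.integer(n_cell_types),
              n_genes = as.integer(n_genes),
              n_enhancers = as.integer(n_enhancers),
              chrom_length = chrom_length,
              frac_interacting = frac_interacting,
              planted_correlation = planted_correlation,
              distance_decay_scale = distance_decay_scale,
              background_correlation = background_correlation,
              activity_noise_sd = activity_noise_sd,
              expression_noise_sd = expression_noise_sd,
              cluster_size = as.integer(cluster_size),
              bystanders_per_locus = as.integer(bystanders_per_locus),
              frac_silent_enhancer = frac_silent_enhancer,
              frac_decoupled_loci = frac_decoupled_loci,
              anchor_halfwidth = anchor_halfwidth,
              activity_baseline = activity_baseline,
              expression_baseline = expression_baseline,
              null_signal = isTRUE(null_signal),
              seed = as.integer(seed))
  stopifnot(cfg$n_cell_types >= 3, cfg$n_genes >= 1, cfg$n_enhancers >= 1,
            cfg$cluster_size >= 1, cfg$bystanders_per_locus >= 0)
  if (cfg$frac_interacting < 0 || cfg$frac_interacting > 1)
    stop("frac_interacting must be in [0,1]", call. = FALSE)
  if (abs(cfg$planted_correlation) > 1)
    stop("planted_correlation must be in [-1,1]", call. = FALSE)
  if (cfg$background_correlation < 0 || cfg$background_correlation > 1)
    stop("background_correlation must be in [0,1]", call. = FALSE)
  if (cfg$frac_silent_enhancer < 0 || cfg$frac_silent_enhancer > 1 ||
      cfg$frac_decoupled_loci < 0 || cfg$frac_decoupled_loci > 1)
    stop("noise fractions must be in [0,1]", call. = FALSE)
  # geometric feasibility: elements must fit with room to spare
  if (cfg$n_enhancers * 1000 + cfg$n_genes * 30000 > 0.8 * cfg$chrom_length ||
      cfg$chrom_length < 2e5)
    stop("too many elements for chrom_length", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# latent-factor pair: both vectors = sqrt(rho)*z + sqrt(1-rho)*noise, so their
# Pearson correlation targets rho; affine rescaling downstream preserves it
mix_factor <- function(z, rho) {
  sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(length(z))
}

#' Generate a seeded synthetic multi-cell-type enhancer-gene dataset
#'
#' See [sim_config()] for the generative structure. Loops are emitted as BEDPE
#' anchors of half-width `anchor_halfwidth` around the planted enhancer
#' midpoint and the target TSS; truth labels for all candidate pairs are then
#' derived with [label_pairs()] against those anchors, so incidental overlaps
#' label exactly as they would on real data. Identical seeds give identical
#' datasets.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed (defaults to the config's).
#' @return Object of class `eg_sim`: list with enhancers (`enhancer_set`),
#'   genes (with promoters), expression matrix, interactions, support vector,
#'   labeled candidate `pairs`, the `planted` loop pairs (enhancer_id,
#'   gene_id), `focal_cell_type`, `cell_types`, config, seed.
#' @export
simulate_eg_data <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  rs <- local_rng(seed)
  on.exit(rs(), add = TRUE)
  L <- config$chrom_length
  n_ct <- config$n_cell_types
  cts <- sprintf("CT%02d", seq_len(n_ct))
  focal <- cts[1]
  chrom <- "chr1"
  null <- config$null_signal

  n_int_enh <- round(config$frac_interacting * config$n_enhancers)
  csize <- if (null) 1L else config$cluster_size
  n_loci <- n_int_enh %/% csize
  n_int_enh <- n_loci * csize

  # ---- gene placement ----------------------------------------------------
  margin <- 50000
  gene_len <- round(stats::runif(config$n_genes, 5000, 30000))
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  tss <- round(stats::runif(config$n_genes, margin, L - margin))
  roles <- rep("background", config$n_genes)
  locus_gene <- integer(0)
  if (n_loci > 0) {
    locus_gene <- sample.int(config$n_genes, n_loci)
    roles[locus_gene] <- "interacting"
    n_by <- if (null) 0L else config$bystanders_per_locus
    if (n_by > 0) {
      pool <- setdiff(seq_len(config$n_genes), locus_gene)
      n_take <- min(length(pool), n_loci * n_by)
      by_idx <- sample(pool, n_take)
      roles[by_idx] <- "bystander"
      host <- rep(locus_gene, each = n_by)[seq_len(n_take)]
      tss[by_idx] <- pmin(pmax(tss[host] + round(stats::runif(n_take, -1e5, 1e5)),
                               35000), L - 35000)
    }
  }
  gstart <- ifelse(strand == "+", tss, tss - gene_len)
  gend <- ifelse(strand == "+", tss + gene_len, tss)

  # ---- expression --------------------------------------------------------
  eb <- config$expression_baseline
  e_base <- ifelse(roles == "background" | null, eb[["background"]],
                   eb[["interacting"]])
  z_locus <- matrix(stats::rnorm(max(n_loci, 1) * n_ct), nrow = max(n_loci, 1))
  z_bg <- stats::rnorm(n_ct)     # shared background factor
  bc <- config$background_correlation
  rho_pair <- if (null || n_loci == 0) rep(0, max(n_loci, 1)) else {
    # per-locus regulatory strength: Beta-shaped spread with the configured mean
    mu <- abs(config$planted_correlation)
    if (mu >= 0.999 || mu <= 0.001) rep(config$planted_correlation, n_loci)
    else sign(config$planted_correlation) *
      stats::rbeta(n_loci, shape1 = 20 * mu, shape2 = 20 * (1 - mu))
  }
  decoupled <- rep(FALSE, max(n_loci, 1))
  if (!null && n_loci > 0) {
    n_dec <- round(config$frac_decoupled_loci * n_loci)
    if (n_dec > 0) decoupled[sample.int(n_loci, n_dec)] <- TRUE
  }
  expr <- matrix(0, config$n_genes, n_ct)
  for (i in seq_len(config$n_genes)) {
    l <- match(i, locus_gene)
    y <- if (!is.na(l) && !null && !decoupled[l])
      mix_factor(z_locus[l, ], abs(rho_pair[l]))
    else sqrt(bc) * z_bg + sqrt(1 - bc) * stats::rnorm(n_ct)
    expr[i, ] <- pmax(e_base[i] + config$expression_noise_sd * y, 0)
  }

  # ---- enhancer placement ------------------------------------------------
  ab <- config$activity_baseline
  n_bg_enh <- config$n_enhancers - n_int_enh
  e_mid <- numeric(config$n_enhancers)
  e_role <- rep("background", config$n_enhancers)
  e_locus <- rep(NA_integer_, config$n_enhancers)
  if (n_int_enh > 0) {
    li <- rep(seq_len(n_loci), each = csize)
    side <- sample(c(-1, 1), n_loci, replace = TRUE)[li]
    # member distances drawn iid from the decay law (uniform under the null),
    # all members of a locus on the same side: nearer members populate the
    # windows of the farther ones
    d_member <- if (null) stats::runif(n_int_enh, 2000, 9.5e5) else
      pmin(1000 + stats::rexp(n_int_enh, rate = 1 / config$distance_decay_scale),
           9.5e5)
    e_mid[seq_len(n_int_enh)] <-
      pmin(pmax(tss[locus_gene[li]] + side * d_member, 2000), L - 2000)
    e_role[seq_len(n_int_enh)] <- "interacting"
    e_locus[seq_len(n_int_enh)] <- li
  }
  if (n_bg_enh > 0)
    e_mid[n_int_enh + seq_len(n_bg_enh)] <- stats::runif(n_bg_enh, 5000, L - 5000)
  e_mid <- round(e_mid)                      # coordinates are integral bp
  e_width <- round(stats::runif(config$n_enhancers, 200, 1000))

  # ---- activity ----------------------------------------------------------
  rho_sign <- sign(config$planted_correlation + (config$planted_correlation == 0))
  silent <- rep(FALSE, config$n_enhancers)
  if (!null && n_int_enh > 0) {
    n_sil <- round(config$frac_silent_enhancer * n_int_enh)
    if (n_sil > 0) silent[sample.int(n_int_enh, n_sil)] <- TRUE
  }
  act <- matrix(0, config$n_enhancers, n_ct)
  for (i in seq_len(config$n_enhancers)) {
    if (e_role[i] == "interacting" && !null && !silent[i]) {
      a <- rho_sign * mix_factor(z_locus[e_locus[i], ], abs(rho_pair[e_locus[i]]))
      base <- ab[["interacting"]]
    } else {
      a <- sqrt(bc) * z_bg + sqrt(1 - bc) * stats::rnorm(n_ct)
      base <- ab[["background"]]
    }
    act[i, ] <- pmax(base + config$activity_noise_sd * a, 0)
  }

  # ---- assemble, position-sorted ids ------------------------------------
  g_ord <- order(tss)
  genes <- data.frame(chrom = chrom,
                      start = gstart[g_ord], end = gend[g_ord],
                      id = sprintf("G%04d", seq_len(config$n_genes)),
                      strand = strand[g_ord], tss = tss[g_ord],
                      role = roles[g_ord], stringsAsFactors = FALSE)
  genes <- derive_promoter(genes)
  expr <- expr[g_ord, , drop = FALSE]
  dimnames(expr) <- list(genes$id, cts)

  e_ord <- order(e_mid)
  e_start <- (e_mid - e_width %/% 2)[e_ord]
  elements <- data.frame(chrom = chrom, start = e_start,
                         end = e_start + e_width[e_ord],
                         id = sprintf("E%05d", seq_len(config$n_enhancers)),
                         stringsAsFactors = FALSE)
  act <- act[e_ord, , drop = FALSE]
  dimnames(act) <- list(elements$id, cts)
  enhancers <- structure(list(elements = elements, activity = act,
                              cell_types = cts), class = "enhancer_set")
  e_role <- e_role[e_ord]; e_locus <- e_locus[e_ord]

  # ---- true loops as BEDPE anchors --------------------------------------
  hw <- config$anchor_halfwidth
  idx <- which(e_role == "interacting")
  planted <- data.frame(enhancer_id = character(), gene_id = character(),
                        stringsAsFactors = FALSE)
  if (length(idx)) {
    gmatch <- match(locus_gene[e_locus[idx]],
                    order(tss))       # position of host gene after sorting
    g_tss <- genes$tss[gmatch]
    emid2 <- enhancer_midpoint(elements$start[idx], elements$end[idx])
    interactions <- data.frame(
      chrom1 = chrom, start1 = pmax(0, emid2 - hw), end1 = emid2 + hw,
      chrom2 = chrom, start2 = pmax(0, g_tss - hw), end2 = g_tss + hw,
      cell_type = focal, source = "synthetic", stringsAsFactors = FALSE)
    planted <- data.frame(enhancer_id = elements$id[idx],
                          gene_id = genes$id[gmatch],
                          stringsAsFactors = FALSE)
  } else {
    interactions <- data.frame(chrom1 = character(), start1 = numeric(),
                               end1 = numeric(), chrom2 = character(),
                               start2 = numeric(), end2 = numeric(),
                               cell_type = character(), source = character(),
                               stringsAsFactors = FALSE)
  }

  support <- stats::setNames(rep(1, config$n_enhancers), elements$id)
  pairs <- build_candidate_pairs(enhancers, genes, max_dist = 1e6)
  pairs <- label_pairs(pairs, interactions, enhancers, genes, cell_type = focal)

  structure(list(config = config, seed = as.integer(seed),
                 cell_types = cts, focal_cell_type = focal,
                 enhancers = enhancers, genes = genes, expression = expr,
                 interactions = interactions, support = support,
                 pairs = pairs, planted = planted),
            class = "eg_sim")
}

#' @export
print.eg_sim <- function(x, ...) {
  np <- sum(x$pairs$label == "positive")
  cat(sprintf(paste0("synthetic enhancer-gene dataset (seed %d)\n",
                     "  %d enhancers, %d genes, %d cell types on %s (%.1f Mbp)\n",
                     "  %d loops; %d candidate pairs: %d positive / %d negative\n"),
              x$seed, nrow(x$enhancers$elements), nrow(x$genes),
              length(x$cell_types), x$genes$chrom[1],
              x$config$chrom_length / 1e6, nrow(x$interactions),
              nrow(x$pairs), np, nrow(x$pairs) - np))
  invisible(x)
}

#' Compute the labeled six-feature table of a synthetic dataset
#'
#' Convenience wrapper around [compute_feature_table()] using the dataset's
#' focal cell type.
#'
#' @param dataset An `eg_sim`.
#' @param ... Passed to [compute_feature_table()].
#' @return Labeled feature table (data.frame).
#' @export
sim_feature_table <- function(dataset, ...) {
  compute_feature_table(dataset$pairs, dataset$enhancers, dataset$genes,
                        dataset$expression, dataset$focal_cell_type, ...)
}

#' Export a synthetic dataset in the on-disk formats the readers consume
#'
#' Writes `enhancers.bed` (scored BED), `expression.tsv`, `genes.bed` (BED6),
#' `loops.bedpe` and `truth_labels.tsv` into `directory`. Re-reading the files
#' reproduces the matrices exactly; re-deriving labels from the exported loops
#' reproduces the emitted truth labels.
#'
#' @param dataset An `eg_sim`.
#' @param directory Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
export_eg_data <- function(dataset, directory) {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create directory %s", directory), call. = FALSE)
  paths <- c(enhancers = file.path(directory, "enhancers.bed"),
             expression = file.path(directory, "expression.tsv"),
             genes = file.path(directory, "genes.bed"),
             loops = file.path(directory, "loops.bedpe"),
             truth = file.path(directory, "truth_labels.tsv"))
  write_enhancer_bed(dataset$enhancers, paths[["enhancers"]])
  write_expression_table(dataset$expression, paths[["expression"]])
  write_gene_annotation(dataset$genes, paths[["genes"]])
  write_bedpe(dataset$interactions, paths[["loops"]])
  truth <- dataset$pairs[, c("enhancer_id", "gene_id", "chrom", "distance", "label")]
  truth$cell_type <- dataset$focal_cell_type
  utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(paths)
}
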