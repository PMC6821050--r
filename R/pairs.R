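#' Derive promoter intervals from TSS and strand
#'
#' The promoter is the TSS-containing region 5 kbp upstream and 0.5 kbp
#' downstream of the TSS, relative to the strand: \[tss-5000, tss+500) on the
#' + strand, \[tss-500, tss+5000) on the - strand, clipped at position 0.
#'
#' @param genes data.frame with columns tss and strand (see
#'   [read_gene_annotation()]).
#' @param upstream,downstream Promoter extent in bp (defaults 5000 / 500).
#' @return `genes` with promoter_start and promoter_end columns added.
#' @export
derive_promoter <- function(genes, upstream = 5000, downstream = 500) {
  if (!all(c("tss", "strand") %in% colnames(genes)))
    stop("genes need tss and strand columns", call. = FALSE)
  plus <- genes$strand == "+"
  genes$promoter_start <- pmax(0, ifelse(plus, genes$tss - upstream,
                                         genes$tss - downstream))
  genes$promoter_end <- ifelse(plus, genes$tss + downstream,
                               genes$tss + upstream)
  genes
}

enhancer_midpoint <- function(start, end) start + floor((end - start) / 2)

#' Enumerate candidate enhancer-gene pairs within a distance bound
#'
#' One candidate per (enhancer, gene) on the same chromosome whose
#' enhancer-midpoint-to-TSS distance (the DIS feature) is at most `max_dist`
#' (default 1 Mbp — beyond which real interactions are vanishingly rare).
#'
#' @param enhancers An `enhancer_set`.
#' @param genes Gene annotation data.frame (promoters not required here).
#' @param max_dist Maximum DIS in bp.
#' @return data.frame with columns enhancer_id, gene_id, chrom, distance;
#'   no duplicates; distance in \[0, max_dist\].
#' @export
build_candidate_pairs <- function(enhancers, genes, max_dist = 1e6) {
  el <- enhancers$elements
  out <- vector("list", 0L)
  for (chr in intersect(unique(el$chrom), unique(genes$chrom))) {
    e <- el[el$chrom == chr, , drop = FALSE]
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (!nrow(e) || !nrow(g)) next
    mid <- enhancer_midpoint(e$start, e$end)
    # cross join via index expansion
    ei <- rep(seq_len(nrow(e)), times = nrow(g))
    gi <- rep(seq_len(nrow(g)), each = nrow(e))
    d <- abs(mid[ei] - g$tss[gi])
    keep <- d <= max_dist
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      enhancer_id = e$id[ei[keep]],
      gene_id = g$id[gi[keep]],
      chrom = chr,
      distance = d[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(enhancer_id = character(), gene_id = character(),
                      chrom = character(), distance = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

overlap_len <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

#' Label candidate pairs against interaction records
#'
#' A pair is positive iff some interaction on the same chromosome (and, when
#' `cell_type` is given, in that cell type) has one anchor overlapping the
#' enhancer interval and the other anchor overlapping the gene's promoter, by
#' at least `anchor_overlap_bp` each, under either anchor assignment.
#' Everything else — including pairs touching only one anchor — is negative.
#'
#' The alternative, stricter reading of "no overlap" (a pair is only negative
#' when neither element touches any anchor) is available as
#' `rule = "either_touch"`, which drops such half-touching pairs to label
#' `"unlabeled"` instead of negative.
#'
#' @param pairs Candidate pairs from [build_candidate_pairs()].
#' @param interactions Interaction data.frame (see [read_bedpe()]).
#' @param enhancers The `enhancer_set` the pairs refer to.
#' @param genes Gene annotation with promoters (see [derive_promoter()]).
#' @param cell_type Optional focal cell type; interactions in other cell types
#'   are ignored (labels are per cell type).
#' @param anchor_overlap_bp Minimum overlap on each anchor, default 1.
#' @param rule "both_anchor" (default) or "either_touch" (see above).
#' @return `pairs` with a `label` column in {"positive","negative","unlabeled"}.
#' @export
label_pairs <- function(pairs, interactions, enhancers, genes,
                        cell_type = NULL, anchor_overlap_bp = 1,
                        rule = c("both_anchor", "either_touch")) {
  rule <- match.arg(rule)
  if (!all(c("promoter_start", "promoter_end") %in% colnames(genes)))
    genes <- derive_promoter(genes)
  if (!is.null(cell_type) && nrow(interactions))
    interactions <- interactions[interactions$cell_type == cell_type, , drop = FALSE]
  el <- enhancers$elements
  ei <- match(pairs$enhancer_id, el$id)
  gi <- match(pairs$gene_id, genes$id)
  if (anyNA(ei)) stop("pair references unknown enhancer id", call. = FALSE)
  if (anyNA(gi)) stop("pair references unknown gene id", call. = FALSE)
  n <- nrow(pairs)
  pos <- logical(n)
  touched <- logical(n)

  if (nrow(interactions) && n) {
    # IRanges handles the interval joins; both anchor assignments are checked.
    for (chr in unique(pairs$chrom)) {
      pidx <- which(pairs$chrom == chr)
      iidx <- which(interactions$chrom1 == chr)
      if (!length(pidx) || !length(iidx)) next
      ints <- interactions[iidx, , drop = FALSE]
      er <- IRanges::IRanges(start = el$start[ei[pidx]] + 1L,
                             end = el$end[ei[pidx]])
      pr <- IRanges::IRanges(start = genes$promoter_start[gi[pidx]] + 1L,
                             end = genes$promoter_end[gi[pidx]])
      a1 <- IRanges::IRanges(start = ints$start1 + 1L, end = ints$end1)
      a2 <- IRanges::IRanges(start = ints$start2 + 1L, end = ints$end2)
      ov <- function(q, s) {
        h <- IRanges::findOverlaps(q, s, minoverlap = anchor_overlap_bp)
        cbind(S4Vectors::queryHits(h), S4Vectors::subjectHits(h))
      }
      e1 <- ov(er, a1); p2 <- ov(pr, a2)
      e2 <- ov(er, a2); p1 <- ov(pr, a1)
      hit_join <- function(eh, ph) {
        if (!nrow(eh) || !nrow(ph)) return(integer())
        ke <- paste(eh[, 1], eh[, 2]); kp <- paste(ph[, 1], ph[, 2])
        unique(eh[ke %in% kp, 1])
      }
      # same interaction must carry both the enhancer and the promoter, but a
      # positive may arise from different interactions under the two
      # assignments; hit keys are (pair-within-chr, interaction) index pairs
      hits <- unique(c(hit_join(e1, p2), hit_join(e2, p1)))
      pos[pidx[hits]] <- TRUE
      touched[pidx[unique(c(e1[, 1], e2[, 1], p1[, 1], p2[, 1]))]] <- TRUE
    }
  }
  pairs$label <- ifelse(pos, "positive", "negative")
  if (rule == "either_touch")
    pairs$label[!pos & touched] <- "unlabeled"
  pairs
}

#' Apply the training-set selection filters
#'
#' Keeps pairs whose enhancer is supported by at least `min_support` of the
#' high-throughput evidence tracks and whose target gene is expressed
#' (FPKM > `min_fpkm_exclusive`) in the focal cell type. Both criteria follow
#' the training-data selection rules: well-supported enhancers, expressed
#' targets.
#'
#' @param pairs Labeled candidate pairs.
#' @param enhancer_support Named numeric vector in \[0,1\]: per enhancer id,
#'   the fraction of evidence tracks supporting it.
#' @param expression Expression matrix (genes x cell types).
#' @param cell_type Focal cell type for the expression filter.
#' @param min_support Minimum evidence fraction (default 0.5).
#' @param min_fpkm_exclusive Pairs are kept when FPKM is strictly greater than
#'   this (default 0).
#' @return Filtered pairs.
#' @export
filter_training_pairs <- function(pairs, enhancer_support, expression,
                                  cell_type, min_support = 0.5,
                                  min_fpkm_exclusive = 0) {
  if (!nrow(pairs)) return(pairs)
  sup <- enhancer_support[pairs$enhancer_id]
  if (anyNA(sup))
    stop(sprintf("enhancer(s) absent from support map: %s",
                 paste(unique(pairs$enhancer_id[is.na(sup)]), collapse = ",")),
         call. = FALSE)
  gi <- match(pairs$gene_id, rownames(expression))
  if (anyNA(gi)) stop("gene missing from expression matrix", call. = FALSE)
  if (!cell_type %in% colnames(expression))
    stop(sprintf("cell type %s missing from expression matrix", cell_type),
         call. = FALSE)
  fpkm <- expression[gi, cell_type]
  keep <- sup >= min_support & fpkm > min_fpkm_exclusive
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Draw the balanced training sample
#'
#' Randomly selects half of the positive pairs and an equal number of
#' negatives for training; everything else goes to the holdout. Reproducible
#' under `seed`.
#'
#' @param pairs Labeled pairs (label in {"positive","negative"}).
#' @param seed Integer seed for the sampling.
#' @return list(train =, holdout =) of pair data.frames.
#' @export
balance_training_set <- function(pairs, seed) {
  pidx <- which(pairs$label == "positive")
  nidx <- which(pairs$label == "negative")
  n_pos_train <- floor(length(pidx) / 2)
  if (length(pidx) < 2)
    stop("need at least 2 positive pairs to balance", call. = FALSE)
  if (length(nidx) < n_pos_train)
    stop(sprintf("insufficient negatives: need %d, have %d",
                 n_pos_train, length(nidx)), call. = FALSE)
  rs <- local_rng(seed)
  on.exit(rs(), add = TRUE)
  tp <- sample(pidx, n_pos_train)
  tn <- sample(nidx, n_pos_train)
  train_idx <- sort(c(tp, tn))
  list(train = pairs[train_idx, , drop = FALSE],
       holdout = pairs[setdiff(seq_len(nrow(pairs)), train_idx), , drop = FALSE])
}

#' Subsample negatives to a fixed class ratio for unbalanced evaluation
#'
#' Keeps every positive and a seeded random sample of `ratio` times as many
#' negatives, emulating the 1:5 unbalanced evaluation design. Training is
#' never altered by this utility.
#'
#' @param pairs Labeled pairs.
#' @param ratio Negatives per positive (default 5).
#' @param seed Integer seed.
#' @return Subsampled pairs.
#' @export
subsample_negatives <- function(pairs, ratio = 5, seed = 1L) {
  pidx <- which(pairs$label == "positive")
  nidx <- which(pairs$label == "negative")
  n_neg <- min(length(nidx), round(ratio * length(pidx)))
  rs <- local_rng(seed)
  on.exit(rs(), add = TRUE)
  keep <- sort(c(pidx, sample(nidx, n_neg)))
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Seeded RNG scoped to one operation: returns a restore function so callers'
# RNG state is untouched and results depend only on the given seed.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}
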