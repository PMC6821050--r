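#' Pearson correlation with a zero-variance convention
#'
#' Standard Pearson r over two equal-length vectors of at least three values.
#' If either vector has zero variance the correlation is defined as 0 rather
#' than NaN: a flat activity or expression profile carries no correlation
#' signal and must not poison the feature table.
#'
#' @param x,y Numeric vectors of equal length m >= 3.
#' @return Pearson r in \[-1, 1\].
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y))
    stop("pearson_cor: length mismatch", call. = FALSE)
  if (length(x) < 3)
    stop("pearson_cor: need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("pearson_cor: missing values", call. = FALSE)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(0)
  stats::cor(x, y)
}

panel_vectors <- function(enhancers, expression, enhancer_id, gene_id,
                          cell_types = NULL) {
  if (is.null(cell_types)) cell_types <- enhancers$cell_types
  if (!enhancer_id %in% rownames(enhancers$activity))
    stop(sprintf("unknown enhancer id %s", enhancer_id), call. = FALSE)
  if (!gene_id %in% rownames(expression))
    stop(sprintf("unknown gene id %s", gene_id), call. = FALSE)
  miss_a <- setdiff(cell_types, colnames(enhancers$activity))
  miss_e <- setdiff(cell_types, colnames(expression))
  if (length(miss_a) || length(miss_e))
    stop(sprintf("cell type(s) missing: %s",
                 paste(unique(c(miss_a, miss_e)), collapse = ",")),
         call. = FALSE)
  list(activity = enhancers$activity[enhancer_id, cell_types],
       expr = expression[gene_id, cell_types])
}

#' EGC: enhancer-activity / gene-expression correlation across the panel
#'
#' Pearson correlation between an enhancer's activity profile and a gene's
#' FPKM profile over the full cell-type panel (not only the focal cell type);
#' tissue-specific co-activity across the panel is the signal.
#'
#' @param enhancers An `enhancer_set`.
#' @param expression Expression matrix (genes x cell types).
#' @param enhancer_id,gene_id Element identifiers.
#' @param cell_types Ordered panel; defaults to the enhancer set's cell types.
#' @param log_expression When TRUE, FPKM is log2(x+1)-transformed before the
#'   correlation (off by default; raw FPKM is the reference behaviour).
#' @return Pearson r in \[-1, 1\].
#' @export
compute_egc <- function(enhancers, expression, enhancer_id, gene_id,
                        cell_types = NULL, log_expression = FALSE) {
  v <- panel_vectors(enhancers, expression, enhancer_id, gene_id, cell_types)
  e <- v$expr
  if (log_expression) e <- log2(e + 1)
  pearson_cor(v$activity, e)
}

#' GS: target gene expression in the focal cell type
#'
#' @param expression Expression matrix (genes x cell types).
#' @param gene_id Gene identifier.
#' @param cell_type Focal cell type.
#' @return The FPKM value, unchanged.
#' @export
compute_gs <- function(expression, gene_id, cell_type) {
  if (!gene_id %in% rownames(expression))
    stop(sprintf("unknown gene id %s", gene_id), call. = FALSE)
  if (!cell_type %in% colnames(expression))
    stop(sprintf("unknown cell type %s", cell_type), call. = FALSE)
  unname(expression[gene_id, cell_type])
}

#' DIS: genomic distance between enhancer midpoint and gene TSS
#'
#' The enhancer is anchored at its midpoint, `start + floor(length/2)`;
#' the midpoint is symmetric and insensitive to enhancer length.
#'
#' @param enhancers An `enhancer_set`.
#' @param genes Gene annotation data.frame.
#' @param enhancer_id,gene_id Element identifiers.
#' @return Distance in bp (>= 0).
#' @export
compute_dis <- function(enhancers, genes, enhancer_id, gene_id) {
  e <- enhancers$elements[match(enhancer_id, enhancers$elements$id), ]
  g <- genes[match(gene_id, genes$id), ]
  if (anyNA(e$start) || is.na(g$tss))
    stop("unknown enhancer or gene id", call. = FALSE)
  if (e$chrom != g$chrom)
    stop("enhancer and gene on different chromosomes", call. = FALSE)
  abs(enhancer_midpoint(e$start, e$end) - g$tss)
}

#' Build the window context between an enhancer and a gene's promoter
#'
#' The window runs from the inner edge of the enhancer to the inner edge of
#' the promoter (the side of each facing the other). Elements intersecting
#' the window are collected with their lengths clipped to the window; the
#' focal enhancer and focal gene are excluded so a pair cannot inflate its own
#' window signal. When enhancer and promoter overlap or abut, the window is
#' degenerate: no contained elements, and the window length is floored at 1 bp
#' to keep the downstream division defined.
#'
#' @param enhancers An `enhancer_set` (provides candidate contained enhancers).
#' @param genes Gene annotation with promoters (provides contained genes).
#' @param expression Expression matrix for gene signals.
#' @param enhancer_id,gene_id The focal pair.
#' @param cell_type Focal cell type for element signals.
#' @return list with `window` (c(start, end) or NULL when degenerate),
#'   `L_window`, `enhancers` and `genes` (data.frames with signal and clipped
#'   length columns).
#' @export
build_window <- function(enhancers, genes, expression, enhancer_id, gene_id,
                         cell_type) {
  el <- enhancers$elements
  e <- el[match(enhancer_id, el$id), ]
  if (!all(c("promoter_start", "promoter_end") %in% colnames(genes)))
    genes <- derive_promoter(genes)
  g <- genes[match(gene_id, genes$id), ]
  if (anyNA(e$start) || anyNA(g$tss))
    stop("unknown enhancer or gene id", call. = FALSE)
  if (e$chrom != g$chrom)
    stop("enhancer and gene on different chromosomes", call. = FALSE)
  if (e$end <= g$promoter_start) {        # enhancer upstream of promoter
    ws <- e$end; we <- g$promoter_start
  } else if (g$promoter_end <= e$start) { # enhancer downstream
    ws <- g$promoter_end; we <- e$start
  } else {                                # overlapping/abutting: degenerate
    ws <- we <- e$end
  }
  empty <- data.frame(id = character(), signal = numeric(), length = numeric(),
                      stringsAsFactors = FALSE)
  if (we <= ws)
    return(list(window = NULL, L_window = 1, enhancers = empty, genes = empty))
  clip_elements <- function(ids, chrom, s0, e0, signal, drop_id) {
    same <- chrom == e$chrom & ids != drop_id
    len <- overlap_len(s0, e0, ws, we)
    keep <- same & len > 0
    data.frame(id = ids[keep], signal = signal[keep], length = len[keep],
               stringsAsFactors = FALSE)
  }
  ce <- clip_elements(el$id, el$chrom, el$start, el$end,
                      enhancers$activity[, cell_type], enhancer_id)
  gsig <- expression[match(genes$id, rownames(expression)), cell_type]
  cg <- clip_elements(genes$id, genes$chrom, genes$start, genes$end,
                      gsig, gene_id)
  list(window = c(ws, we), L_window = we - ws, enhancers = ce, genes = cg)
}

#' EWS: distance-normalized enhancer signal in the window
#'
#' EWS = sum over contained enhancers of (signal x clipped length) divided by
#' the window length; 0 when the window holds no other enhancer.
#'
#' @param ctx Window context from [build_window()].
#' @return Non-negative signal per bp.
#' @export
compute_ews <- function(ctx) {
  if (!nrow(ctx$enhancers)) return(0)
  sum(ctx$enhancers$signal * ctx$enhancers$length) / ctx$L_window
}

#' GWS: distance-normalized gene expression in the window
#'
#' Same contract as [compute_ews()] with gene FPKM as signal and the
#' (window-clipped) gene-body length as the element length.
#'
#' @param ctx Window context from [build_window()].
#' @return Non-negative signal per bp.
#' @export
compute_gws <- function(ctx) {
  if (!nrow(ctx$genes)) return(0)
  sum(ctx$genes$signal * ctx$genes$length) / ctx$L_window
}

#' WEEC: mean correlation of an enhancer with the gene's other enhancers
#'
#' For the m enhancers within `max_dist` (1 Mbp) of the gene's TSS — the
#' neighborhood is anchored on the gene — WEEC is the mean Pearson correlation
#' between the focal enhancer's activity profile and each of the other m-1
#' profiles across the full cell-type panel. With no neighbors (m = 1) the
#' value is defined as 0.
#'
#' @param enhancers An `enhancer_set`.
#' @param genes Gene annotation data.frame.
#' @param enhancer_id,gene_id The focal pair.
#' @param max_dist Neighborhood radius around the TSS in bp.
#' @return Mean r in \[-1, 1\].
#' @export
compute_weec <- function(enhancers, genes, enhancer_id, gene_id,
                         max_dist = 1e6) {
  el <- enhancers$elements
  g <- genes[match(gene_id, genes$id), ]
  if (is.na(g$tss)) stop("unknown gene id", call. = FALSE)
  mid <- enhancer_midpoint(el$start, el$end)
  nbr <- el$id[el$chrom == g$chrom & abs(mid - g$tss) <= max_dist]
  if (!enhancer_id %in% nbr)
    stop("focal enhancer not within max_dist of the gene TSS", call. = FALSE)
  others <- setdiff(nbr, enhancer_id)
  if (!length(others)) return(0)
  focal <- enhancers$activity[enhancer_id, ]
  mean(vapply(others, function(j) pearson_cor(focal, enhancers$activity[j, ]),
              numeric(1)))
}

# Rows standardized so tcrossprod gives Pearson correlations; zero-variance
# rows become all-zero (r = 0 convention).
standardize_rows <- function(m) {
  mu <- rowMeans(m)
  ctr <- m - mu
  ss <- sqrt(rowSums(ctr^2))
  ss[ss == 0] <- Inf
  ctr / ss
}

#' Compute the six-feature table for a set of candidate pairs
#'
#' Vectorized computation of EGC, GS, DIS, EWS, GWS and WEEC for every pair,
#' equivalent to calling the per-feature operations pair by pair. Output is
#' deterministic given the inputs. Coordinates of the focal elements are
#' carried along so predictions can be written directly.
#'
#' @param pairs Candidate pairs from [build_candidate_pairs()] (a `label`
#'   column, if present, is preserved).
#' @param enhancers An `enhancer_set`.
#' @param genes Gene annotation (promoters derived if absent).
#' @param expression Expression matrix (genes x cell types).
#' @param cell_type Focal cell type for GS/EWS/GWS.
#' @param max_dist WEEC neighborhood radius in bp (default 1 Mbp, matching the
#'   candidate window).
#' @param log_expression Log2(x+1)-transform FPKM before EGC (default FALSE).
#' @return `pairs` with columns enh_start, enh_end, tss, cell_type and the six
#'   [EG_FEATURES] appended.
#' @export
compute_feature_table <- function(pairs, enhancers, genes, expression,
                                  cell_type, max_dist = 1e6,
                                  log_expression = FALSE) {
  el <- enhancers$elements
  if (!all(c("promoter_start", "promoter_end") %in% colnames(genes)))
    genes <- derive_promoter(genes)
  ei <- match(pairs$enhancer_id, el$id)
  gi <- match(pairs$gene_id, genes$id)
  if (anyNA(ei))
    stop(sprintf("unresolvable enhancer id(s): %s",
                 paste(unique(pairs$enhancer_id[is.na(ei)]), collapse = ",")),
         call. = FALSE)
  if (anyNA(gi))
    stop(sprintf("unresolvable gene id(s): %s",
                 paste(unique(pairs$gene_id[is.na(gi)]), collapse = ",")),
         call. = FALSE)
  xi <- match(pairs$gene_id, rownames(expression))
  if (anyNA(xi))
    stop(sprintf("gene id(s) missing from expression matrix: %s",
                 paste(unique(pairs$gene_id[is.na(xi)]), collapse = ",")),
         call. = FALSE)
  if (!cell_type %in% colnames(expression) ||
      !cell_type %in% enhancers$cell_types)
    stop(sprintf("cell type %s absent from activity or expression", cell_type),
         call. = FALSE)
  panel <- enhancers$cell_types
  miss <- setdiff(panel, colnames(expression))
  if (length(miss))
    stop(sprintf("expression matrix lacks cell type(s): %s",
                 paste(miss, collapse = ",")), call. = FALSE)

  n <- nrow(pairs)
  act <- enhancers$activity[, panel, drop = FALSE]
  expr_p <- expression[, panel, drop = FALSE]
  expr_egc <- if (log_expression) log2(expr_p + 1) else expr_p
  Za <- standardize_rows(act)
  Ze <- standardize_rows(expr_egc)

  mid <- enhancer_midpoint(el$start, el$end)
  tss <- genes$tss[gi]

  pairs$enh_start <- el$start[ei]
  pairs$enh_end <- el$end[ei]
  pairs$tss <- tss
  pairs$cell_type <- cell_type

  pairs$egc <- if (n) rowSums(Za[ei, , drop = FALSE] * Ze[xi, , drop = FALSE]) else numeric(0)
  pairs$gs <- if (n) unname(expression[xi, cell_type]) else numeric(0)
  pairs$dis <- abs(mid[ei] - tss)

  # window signals: one batched overlap join per element class
  ws <- we <- numeric(n)
  ee <- el$end[ei]; es <- el$start[ei]
  ps <- genes$promoter_start[gi]; pe <- genes$promoter_end[gi]
  up <- ee <= ps          # enhancer upstream of promoter
  dn <- pe <= es          # enhancer downstream
  ws[up] <- ee[up]; we[up] <- ps[up]
  ws[dn] <- pe[dn]; we[dn] <- es[dn]
  ws[!up & !dn] <- 0; we[!up & !dn] <- 0   # degenerate
  valid <- we > ws
  L <- pmax(1, we - ws)

  window_sum <- function(sub_start, sub_end, sub_chrom, sub_signal, sub_id,
                         focal_id) {
    out <- numeric(n)
    if (!any(valid) || !length(sub_start)) return(out)
    qi <- which(valid)
    for (chr in unique(pairs$chrom[qi])) {
      q <- qi[pairs$chrom[qi] == chr]
      s <- which(sub_chrom == chr)
      if (!length(q) || !length(s)) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(start = ws[q] + 1L, end = we[q]),
        IRanges::IRanges(start = sub_start[s] + 1L, end = sub_end[s]))
      if (!length(hits)) next
      hq <- q[S4Vectors::queryHits(hits)]
      hs <- s[S4Vectors::subjectHits(hits)]
      keep <- sub_id[hs] != focal_id[hq]
      hq <- hq[keep]; hs <- hs[keep]
      if (!length(hq)) next
      clip <- pmin(sub_end[hs], we[hq]) - pmax(sub_start[hs], ws[hq])
      contrib <- rowsum(sub_signal[hs] * clip, group = hq)
      out[as.integer(rownames(contrib))] <- contrib[, 1]
    }
    out
  }
  pairs$ews <- window_sum(el$start, el$end, el$chrom, act[, cell_type],
                          el$id, pairs$enhancer_id) / L
  gsig <- expression[match(genes$id, rownames(expression)), cell_type]
  pairs$gws <- window_sum(genes$start, genes$end, genes$chrom, gsig,
                          genes$id, pairs$gene_id) / L

  # WEEC: gene-anchored neighborhoods over the enhancer correlation matrix
  pairs$weec <- 0
  if (n) {
    C <- tcrossprod(Za)   # r(i,j); zero-variance rows give r = 0
    for (g in unique(pairs$gene_id)) {
      rows <- which(pairs$gene_id == g)
      gg <- match(g, genes$id)
      nbr <- which(el$chrom == genes$chrom[gg] &
                     abs(mid - genes$tss[gg]) <= max_dist)
      if (length(nbr) < 2) next
      sums <- rowSums(C[, nbr, drop = FALSE])
      f <- ei[rows]
      pairs$weec[rows] <- (sums[f] - diag(C)[f]) / (length(nbr) - 1)
    }
  }
  rownames(pairs) <- NULL
  pairs
}
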