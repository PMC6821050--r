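#' @keywords internal
"_PACKAGE"

#' Canonical feature order used throughout the package
#'
#' All feature tables, trained models and prediction files order the six
#' features as EGC, GS, DIS, EWS, GWS, WEEC.
#' @export
EG_FEATURES <- c("egc", "gs", "dis", "ews", "gws", "weec")

# full-precision decimal rendering so numeric round-trips are bit-exact
num17 <- function(x) sprintf("%.17g", x)

# All coordinates are 0-based half-open (BED convention) internally.
# start >= 0, end > start, chrom non-empty.
validate_intervals <- function(chrom, start, end, what = "interval",
                               line = NULL) {
  where <- if (is.null(line)) "" else sprintf(" (line %s)", paste(line, collapse = ","))
  if (any(is.na(start)) || any(is.na(end)))
    stop(sprintf("non-numeric coordinates in %s%s", what, where), call. = FALSE)
  if (any(start < 0))
    stop(sprintf("negative start coordinate in %s%s", what, where), call. = FALSE)
  if (any(end <= start))
    stop(sprintf("end <= start in %s%s", what, where), call. = FALSE)
  if (any(!nzchar(chrom)) || any(is.na(chrom)))
    stop(sprintf("empty chromosome name in %s%s", what, where), call. = FALSE)
  invisible(TRUE)
}

#' Read an enhancer annotation file with per-cell-type activity scores
#'
#' The expected format is a header-bearing, tab-separated BED4 extended with
#' one numeric activity column per cell type: columns `chrom`, `start`, `end`,
#' `id`, then one column per cell type whose header names the cell type.
#' Coordinates follow the BED convention (0-based half-open). Activity scores
#' are synthesized signal intensities acting as a proxy for enhancer activity
#' and must be non-negative.
#'
#' @param path Path to the tab-separated file.
#' @param cell_types Optional character vector; when given, the file's header
#'   cell types must match it exactly (same set and order), otherwise an error
#'   is raised listing the difference.
#' @return An object of class `enhancer_set`: a list with `elements` (a
#'   data.frame with columns chrom, start, end, id), `activity` (numeric matrix,
#'   enhancers x cell types, rownames = enhancer ids) and `cell_types`.
#' @export
read_enhancer_bed <- function(path, cell_types = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = NA,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 4)
    stop("enhancer file needs at least 4 columns (chrom,start,end,id)", call. = FALSE)
  hdr <- colnames(tab)
  file_cells <- hdr[-(1:4)]
  if (!is.null(cell_types)) {
    if (!identical(as.character(cell_types), file_cells)) {
      miss <- setdiff(cell_types, file_cells)
      extra <- setdiff(file_cells, cell_types)
      stop(sprintf(
        "cell types in %s do not match the expected set (missing: %s; unexpected: %s)",
        path,
        if (length(miss)) paste(miss, collapse = ",") else "none",
        if (length(extra)) paste(extra, collapse = ",") else "none"),
        call. = FALSE)
    }
  }
  elements <- data.frame(chrom = as.character(tab[[1]]),
                         start = suppressWarnings(as.numeric(tab[[2]])),
                         end = suppressWarnings(as.numeric(tab[[3]])),
                         id = as.character(tab[[4]]),
                         stringsAsFactors = FALSE)
  if (nrow(elements)) {
    bad <- which(is.na(elements$start) | is.na(elements$end))
    if (length(bad))
      stop(sprintf("malformed enhancer line(s): %s", paste(bad + 1L, collapse = ",")),
           call. = FALSE)
    validate_intervals(elements$chrom, elements$start, elements$end,
                       "enhancer file", which(elements$end <= elements$start) + 1L)
    if (anyDuplicated(elements$id))
      stop("duplicate enhancer ids", call. = FALSE)
  }
  act <- as.matrix(tab[, -(1:4), drop = FALSE])
  if (nrow(act) && !is.numeric(act)) {
    act2 <- suppressWarnings(apply(act, 2, as.numeric))
    if (any(is.na(act2)))
      stop("non-numeric activity score in enhancer file", call. = FALSE)
    act <- matrix(act2, nrow = nrow(tab), dimnames = dimnames(act))
  }
  storage.mode(act) <- "double"
  if (nrow(act) && any(act < 0))
    stop("negative activity score in enhancer file", call. = FALSE)
  rownames(act) <- elements$id
  structure(list(elements = elements, activity = act, cell_types = file_cells),
            class = "enhancer_set")
}

#' @export
print.enhancer_set <- function(x, ...) {
  cat(sprintf("enhancer_set: %d enhancers x %d cell types\n",
              nrow(x$elements), length(x$cell_types)))
  invisible(x)
}

#' Write an enhancer set in the scored-BED dialect read by [read_enhancer_bed()]
#'
#' @param x An `enhancer_set`.
#' @param path Output path.
#' @export
write_enhancer_bed <- function(x, path) {
  out <- data.frame(chrom = x$elements$chrom,
                    start = format(x$elements$start, scientific = FALSE, trim = TRUE),
                    end = format(x$elements$end, scientific = FALSE, trim = TRUE),
                    id = x$elements$id, stringsAsFactors = FALSE)
  act <- as.data.frame(apply(x$activity, 2, num17), stringsAsFactors = FALSE)
  colnames(act) <- x$cell_types
  utils::write.table(cbind(out, act), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a gene expression matrix (FPKM)
#'
#' Tab-separated; genes in rows (first column = gene id), cell types in the
#' header. All values must be numeric and non-negative; missing cells and
#' duplicated gene ids are errors (silent zero-imputation would distort the
#' activity/expression correlations downstream).
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, genes x cell types, rownames = gene ids.
#' @export
read_expression_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    stop("expression table needs a gene id column plus one cell type", call. = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicate gene id(s) in expression table: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ",")), call. = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (nrow(m) && !is.numeric(m)) {
    m2 <- suppressWarnings(apply(m, 2, as.numeric))
    bad <- which(rowSums(matrix(is.na(m2), nrow = nrow(m))) > 0)
    if (length(bad))
      stop(sprintf("non-numeric expression value at row(s) %s",
                   paste(bad + 1L, collapse = ",")), call. = FALSE)
    m <- matrix(m2, nrow = nrow(tab), dimnames = dimnames(m))
  }
  storage.mode(m) <- "double"
  if (anyNA(m))
    stop("missing expression cells are not allowed", call. = FALSE)
  if (nrow(m) && any(m < 0))
    stop("negative FPKM in expression table", call. = FALSE)
  rownames(m) <- ids
  m
}

#' Write an expression matrix in the format read by [read_expression_table()]
#' @param expr Numeric matrix, genes x cell types.
#' @param path Output path.
#' @export
write_expression_table <- function(expr, path) {
  out <- data.frame(gene_id = rownames(expr), apply(expr, 2, num17),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("gene_id", colnames(expr))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read gene annotation from a BED6-like file
#'
#' Columns: chrom, txStart, txEnd, id, score, strand (no header). The TSS is
#' txStart on the + strand and txEnd on the - strand. Promoters are not set
#' here; call [derive_promoter()].
#'
#' @param path Path to the file.
#' @param one_based Set to TRUE when the source uses 1-based inclusive
#'   coordinates (GFF dialect); they are converted to 0-based half-open at this
#'   boundary.
#' @return data.frame with columns chrom, start, end, id, strand, tss.
#' @export
read_gene_annotation <- function(path, one_based = FALSE) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      id = character(), strand = character(), tss = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(readLines(path, n = 1))) return(empty)   # zero-line file
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (nrow(tab) && ncol(tab) < 6)
    stop("gene annotation needs 6 columns (chrom,start,end,id,score,strand)",
         call. = FALSE)
  if (!nrow(tab)) return(empty)
  g <- data.frame(chrom = as.character(tab[[1]]),
                  start = suppressWarnings(as.numeric(tab[[2]])),
                  end = suppressWarnings(as.numeric(tab[[3]])),
                  id = as.character(tab[[4]]),
                  strand = as.character(tab[[6]]),
                  stringsAsFactors = FALSE)
  if (one_based) g$start <- g$start - 1
  validate_intervals(g$chrom, g$start, g$end, "gene annotation")
  if (!all(g$strand %in% c("+", "-")))
    stop(sprintf("unknown strand symbol(s): %s",
                 paste(unique(setdiff(g$strand, c("+", "-"))), collapse = ",")),
         call. = FALSE)
  if (anyDuplicated(g$id)) stop("duplicate gene ids", call. = FALSE)
  g$tss <- ifelse(g$strand == "+", g$start, g$end)
  g
}

#' Write gene annotation as BED6
#' @param genes data.frame as returned by [read_gene_annotation()].
#' @param path Output path.
#' @export
write_gene_annotation <- function(genes, path) {
  out <- data.frame(genes$chrom,
                    format(genes$start, scientific = FALSE, trim = TRUE),
                    format(genes$end, scientific = FALSE, trim = TRUE),
                    genes$id, 0L, genes$strand, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read loop anchors from a BEDPE file
#'
#' Standard BEDPE columns chrom1,start1,end1,chrom2,start2,end2 with optional
#' name and score (no header). Inter-chromosomal records are dropped with a
#' warning reporting the count; all interaction-based labeling here is
#' intra-chromosomal.
#'
#' @param path Path to the BEDPE file.
#' @param cell_type Cell type the loops belong to (labels are per cell type).
#' @param source Provenance tag, e.g. "ChIA-PET", "Hi-C" or "synthetic".
#' @return data.frame with columns chrom1,start1,end1,chrom2,start2,end2,
#'   cell_type, source.
#' @export
read_bedpe <- function(path, cell_type, source = "ChIA-PET") {
  empty <- data.frame(chrom1 = character(), start1 = numeric(), end1 = numeric(),
                      chrom2 = character(), start2 = numeric(), end2 = numeric(),
                      cell_type = character(), source = character(),
                      stringsAsFactors = FALSE)
  if (!length(readLines(path, n = 1))) return(empty)   # zero-line file
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!nrow(tab)) return(empty)
  if (ncol(tab) < 6)
    stop("BEDPE needs at least 6 columns", call. = FALSE)
  x <- data.frame(chrom1 = as.character(tab[[1]]),
                  start1 = suppressWarnings(as.numeric(tab[[2]])),
                  end1 = suppressWarnings(as.numeric(tab[[3]])),
                  chrom2 = as.character(tab[[4]]),
                  start2 = suppressWarnings(as.numeric(tab[[5]])),
                  end2 = suppressWarnings(as.numeric(tab[[6]])),
                  stringsAsFactors = FALSE)
  validate_intervals(x$chrom1, x$start1, x$end1, "BEDPE anchor 1")
  validate_intervals(x$chrom2, x$start2, x$end2, "BEDPE anchor 2")
  inter <- x$chrom1 != x$chrom2
  if (any(inter)) {
    warning(sprintf("dropped %d inter-chromosomal BEDPE record(s)", sum(inter)),
            call. = FALSE)
    x <- x[!inter, , drop = FALSE]
  }
  if (!nrow(x)) return(empty)
  x$cell_type <- cell_type
  x$source <- source
  rownames(x) <- NULL
  x
}

#' Write interactions as BEDPE
#' @param interactions data.frame as returned by [read_bedpe()].
#' @param path Output path.
#' @export
write_bedpe <- function(interactions, path) {
  out <- data.frame(interactions$chrom1,
                    format(interactions$start1, scientific = FALSE, trim = TRUE),
                    format(interactions$end1, scientific = FALSE, trim = TRUE),
                    interactions$chrom2,
                    format(interactions$start2, scientific = FALSE, trim = TRUE),
                    format(interactions$end2, scientific = FALSE, trim = TRUE),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write scored candidate pairs as a prediction table
#'
#' Tab-separated with header: enhancer coordinates and id, gene id and TSS,
#' cell type, the six feature values in canonical order and the prediction
#' score. Rows are sorted by (chrom, enhancer start, gene id) so output is
#' deterministic. Every pair must carry a score in \[0, 1\].
#'
#' @param pairs data.frame with columns chrom, enh_start, enh_end, enhancer_id,
#'   gene_id, tss, cell_type, the six [EG_FEATURES] and score.
#' @param path Output path.
#' @export
write_predictions <- function(pairs, path) {
  need <- c("chrom", "enh_start", "enh_end", "enhancer_id", "gene_id", "tss",
            "cell_type", EG_FEATURES, "score")
  miss <- setdiff(need, colnames(pairs))
  if (length(miss))
    stop(sprintf("prediction table missing column(s): %s",
                 paste(miss, collapse = ",")), call. = FALSE)
  if (nrow(pairs)) {
    if (anyNA(pairs$score))
      stop("unscored pair in prediction output", call. = FALSE)
    if (any(pairs$score < 0 | pairs$score > 1))
      stop("prediction score outside [0,1]", call. = FALSE)
    o <- order(pairs$chrom, pairs$enh_start, pairs$gene_id)
    pairs <- pairs[o, , drop = FALSE]
  }
  out <- pairs[, need, drop = FALSE]
  out$enh_start <- format(out$enh_start, scientific = FALSE, trim = TRUE)
  out$enh_end <- format(out$enh_end, scientific = FALSE, trim = TRUE)
  out$tss <- format(out$tss, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a prediction table written by [write_predictions()]
#' @param path Path to the TSV file.
#' @return data.frame with the prediction columns.
#' @export
read_predictions <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
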