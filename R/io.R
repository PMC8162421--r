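#' Write / read a UMI matrix as MatrixMarket plus TSV sidecars
#'
#' Writes `matrix.mtx` (sparse counts), `genes.tsv` and `cells.tsv` (the
#' metadata tibbles) into a directory, or a single dense TSV for tiny
#' fixtures.
#'
#' @param umi a [umi_matrix()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_umi_mtx <- function(umi, dir) {
  stopifnot(inherits(umi, "umi_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(umi$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(umi$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(umi$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_umi_mtx
#' @export
read_umi_mtx <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  cells <- utils::read.delim(file.path(dir, "cells.tsv"),
                             stringsAsFactors = FALSE)
  dimnames(counts) <- list(genes$gene, cells$cell)
  umi_matrix(counts, cells = cells, genes = genes)
}

#' Write / read a dense UMI matrix TSV (tiny fixtures)
#'
#' @param umi a [umi_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_umi_tsv <- function(umi, path) {
  m <- as.matrix(umi$counts)
  utils::write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_umi_tsv
#' @export
read_umi_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  umi_matrix(m)
}

#' Write / read a footprint matrix as TSV with a JSON header line
#'
#' The first line is a `#`-prefixed JSON object recording `epsilon`, the
#' normalization flag and the grouping level; the rest is a plain TSV.
#'
#' @param fp a [compute_footprint()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_footprint <- function(fp, path) {
  stopifnot(inherits(fp, "footprint"))
  hdr <- jsonlite::toJSON(list(epsilon = attr(fp, "epsilon"),
                               normalized = attr(fp, "normalized"),
                               level = attr(fp, "level")),
                          auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  utils::write.table(data.frame(gene = rownames(fp), unclass(fp),
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_footprint
#' @export
read_footprint <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- jsonlite::fromJSON(sub("^#", "", hdr))
  df <- utils::read.delim(path, skip = 1, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  new_footprint(m, epsilon = meta$epsilon, normalized = meta$normalized,
                level = meta$level)
}

#' Write / read a cell-type tree as Newick with supports as node labels
#'
#' @param tree a `celltype_tree`.
#' @param path output file.
#' @return `path` invisibly; `read_celltype_tree()` returns the tree.
#' @export
write_celltype_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_celltype_tree
#' @export
read_celltype_tree <- function(path) {
  tree <- ape::read.tree(path)
  class(tree) <- c("celltype_tree", "phylo")
  tree
}

#' Write / read gene models as GFF3 and signal intervals as BED6
#'
#' Thin wrappers over `rtracklayer` (declared in Suggests); interval
#' tibbles use 1-based closed coordinates, matching GFF3 directly (BED's
#' 0-based half-open convention is handled by `rtracklayer`).
#'
#' @param x gene-model or peak tibble (see [validate_intervals()]).
#' @param path output file.
#' @return `path` invisibly; readers return interval tibbles.
#' @export
write_gene_models_gff3 <- function(x, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required for GFF3 I/O", call. = FALSE)
  }
  x <- validate_intervals(x, "gene")
  gr <- GenomicRanges::GRanges(
    seqnames = x$seqid,
    ranges = IRanges::IRanges(x$start, x$end),
    strand = x$strand, ID = x$gene, type = "gene",
    source = if ("source" %in% names(x)) x$source else "annotated")
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' @rdname write_gene_models_gff3
#' @export
read_gene_models_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required for GFF3 I/O", call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  tibble::tibble(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene = gr$ID,
    source = if (!is.null(gr$source)) as.character(gr$source) else "annotated")
}

#' @rdname write_gene_models_gff3
#' @export
write_peaks_bed <- function(x, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required for BED I/O", call. = FALSE)
  }
  x <- validate_intervals(x, "peak")
  gr <- GenomicRanges::GRanges(
    seqnames = x$seqid, ranges = IRanges::IRanges(x$start, x$end),
    strand = x$strand, name = x$peak, score = 0L)
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' @rdname write_gene_models_gff3
#' @export
read_peaks_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required for BED I/O", call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "bed")
  tibble::tibble(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    peak = gr$name)
}
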