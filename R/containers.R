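#' UMI count matrix with cell and gene metadata
#'
#' The atomic data container of the package: an integer genes x cells count
#' matrix (one UMI = one captured mRNA molecule) together with per-cell
#' metadata (stage/species, batch) and optional per-gene metadata (most
#' importantly an `organism` label for dual host--symbiont matrices).
#'
#' @param counts genes x cells matrix of non-negative integer counts. Dense
#'   matrices are converted to [Matrix::sparseMatrix()] storage. Row and
#'   column names are required and must be unique.
#' @param cells optional tibble of per-cell metadata with a `cell` column
#'   matching `colnames(counts)`. Extra columns (e.g. `stage`, `batch`) are
#'   carried along.
#' @param genes optional tibble of per-gene metadata with a `gene` column
#'   matching `rownames(counts)`. An `organism` column marks dual-species
#'   matrices.
#'
#' @return An object of class `umi_matrix`: a list with elements `counts`
#'   (a `dgCMatrix`), `cells` and `genes` (tibbles).
#' @export
umi_matrix <- function(counts, cells = NULL, genes = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have gene rownames and cell colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("gene and cell ids must be unique", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  if (is.null(cells)) {
    cells <- tibble::tibble(cell = colnames(counts))
  } else {
    cells <- tibble::as_tibble(cells)
    stopifnot("cell" %in% names(cells))
    if (!setequal(cells$cell, colnames(counts))) {
      stop("`cells$cell` must match colnames(counts)", call. = FALSE)
    }
    cells <- cells[match(colnames(counts), cells$cell), , drop = FALSE]
  }
  if (is.null(genes)) {
    genes <- tibble::tibble(gene = rownames(counts))
  } else {
    genes <- tibble::as_tibble(genes)
    stopifnot("gene" %in% names(genes))
    if (!setequal(genes$gene, rownames(counts))) {
      stop("`genes$gene` must match rownames(counts)", call. = FALSE)
    }
    genes <- genes[match(rownames(counts), genes$gene), , drop = FALSE]
  }
  structure(list(counts = counts, cells = cells, genes = genes),
            class = "umi_matrix")
}

#' @export
print.umi_matrix <- function(x, ...) {
  cat(sprintf("<umi_matrix> %d genes x %d cells, %s total UMIs\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  extra <- setdiff(names(x$cells), "cell")
  if (length(extra)) cat("  cell metadata:", paste(extra, collapse = ", "), "\n")
  if ("organism" %in% names(x$genes)) {
    cat("  organisms:", paste(unique(x$genes$organism), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.umi_matrix <- function(x) dim(x$counts)

#' Total UMI count per cell
#'
#' @param umi a [umi_matrix()].
#' @return Named numeric vector of column sums.
#' @export
cell_totals <- function(umi) {
  stopifnot(inherits(umi, "umi_matrix"))
  Matrix::colSums(umi$counts)
}

#' Subset a umi_matrix by genes and/or cells
#'
#' @param umi a [umi_matrix()].
#' @param genes,cells character vectors of ids to keep (default: all).
#' @return A [umi_matrix()] restricted to the requested ids, order preserved
#'   as given.
#' @export
umi_subset <- function(umi, genes = NULL, cells = NULL) {
  stopifnot(inherits(umi, "umi_matrix"))
  g <- if (is.null(genes)) rownames(umi$counts) else genes
  cc <- if (is.null(cells)) colnames(umi$counts) else cells
  missing_g <- setdiff(g, rownames(umi$counts))
  missing_c <- setdiff(cc, colnames(umi$counts))
  if (length(missing_g)) stop("unknown genes: ", paste(utils::head(missing_g, 5), collapse = ", "), call. = FALSE)
  if (length(missing_c)) stop("unknown cells: ", paste(utils::head(missing_c, 5), collapse = ", "), call. = FALSE)
  umi_matrix(umi$counts[g, cc, drop = FALSE],
             cells = umi$cells[match(cc, umi$cells$cell), , drop = FALSE],
             genes = umi$genes[match(g, umi$genes$gene), , drop = FALSE])
}

#' Metacell and cell-type assignment
#'
#' Maps each cell to a metacell (small transcriptionally coherent cluster,
#' here consumed as input rather than computed), each metacell to a cell
#' type, and optionally each cell type to a broad type. Cells absent from
#' `cells` (or with metacell `NA`) are outliers.
#'
#' @param cells tibble with columns `cell`, `metacell` (character; `NA` =
#'   outlier).
#' @param metacells tibble with columns `metacell`, `cell_type`.
#' @param cell_types optional tibble with columns `cell_type`, `broad_type`.
#' @return Object of class `metacell_map`.
#' @export
metacell_map <- function(cells, metacells, cell_types = NULL) {
  cells <- tibble::as_tibble(cells)
  metacells <- tibble::as_tibble(metacells)
  stopifnot(all(c("cell", "metacell") %in% names(cells)),
            all(c("metacell", "cell_type") %in% names(metacells)))
  if (anyDuplicated(cells$cell)) stop("duplicate cells in assignment", call. = FALSE)
  if (anyDuplicated(metacells$metacell)) stop("duplicate metacells", call. = FALSE)
  known <- stats::na.omit(unique(cells$metacell))
  if (!all(known %in% metacells$metacell)) {
    stop("cells reference metacells missing from `metacells`", call. = FALSE)
  }
  if (is.null(cell_types)) {
    cell_types <- tibble::tibble(cell_type = unique(metacells$cell_type),
                                 broad_type = unique(metacells$cell_type))
  } else {
    cell_types <- tibble::as_tibble(cell_types)
    stopifnot(all(c("cell_type", "broad_type") %in% names(cell_types)))
  }
  structure(list(cells = cells, metacells = metacells, cell_types = cell_types),
            class = "metacell_map")
}

#' @export
print.metacell_map <- function(x, ...) {
  cat(sprintf("<metacell_map> %d cells (%d outliers), %d metacells, %d cell types\n",
              nrow(x$cells), sum(is.na(x$cells$metacell)),
              nrow(x$metacells), nrow(x$cell_types)))
  invisible(x)
}

#' Group label per cell at a chosen resolution
#'
#' @param asg a [metacell_map()].
#' @param level `"metacell"` or `"celltype"`.
#' @return Named character vector keyed by cell id; `NA` for outliers.
#' @export
cell_groups <- function(asg, level = c("metacell", "celltype")) {
  level <- match.arg(level)
  mc <- stats::setNames(asg$cells$metacell, asg$cells$cell)
  if (level == "metacell") return(mc)
  ct <- stats::setNames(asg$metacells$cell_type, asg$metacells$metacell)
  stats::setNames(unname(ct[mc]), names(mc))
}
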