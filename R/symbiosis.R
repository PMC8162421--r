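#' Split a dual host--symbiont matrix by organism
#'
#' Dual-species matrices carry one `organism` label per gene (reads mapped
#' jointly to the host and symbiont genomes). This partitions the genes
#' into two matrices over the same cells; per-cell totals are conserved
#' exactly (host + symbiont = dual).
#'
#' @param dual a [umi_matrix()] whose `genes` tibble has an `organism`
#'   column with exactly two levels.
#' @param host,symbiont organism labels; defaults `"host"`, `"symbiont"`.
#' @return Named list with elements `host` and `symbiont`, each a
#'   [umi_matrix()].
#' @export
split_dual <- function(dual, host = "host", symbiont = "symbiont") {
  stopifnot(inherits(dual, "umi_matrix"))
  if (!("organism" %in% names(dual$genes))) {
    stop("genes carry no `organism` label", call. = FALSE)
  }
  if (anyNA(dual$genes$organism)) stop("unlabeled genes present", call. = FALSE)
  for (org in c(host, symbiont)) {
    if (!any(dual$genes$organism == org)) {
      stop("no genes labeled '", org, "'; both organisms required", call. = FALSE)
    }
  }
  pick <- function(org) {
    umi_subset(dual, genes = dual$genes$gene[dual$genes$organism == org])
  }
  list(host = pick(host), symbiont = pick(symbiont))
}

#' Symbiont occupancy per metacell
#'
#' A cell is symbiont-positive when its symbiont UMI count is strictly
#' greater than `threshold` (default 100). Reports, per metacell, the
#' fraction of positive cells and the median symbiont load among
#' positives.
#'
#' @param symb symbiont-gene [umi_matrix()] (e.g. from [split_dual()]).
#' @param asg a [metacell_map()]; metacells with no cells in `symb` are
#'   dropped with a warning.
#' @param threshold UMI threshold, strict `>` (default 100).
#' @return Tibble with columns `metacell`, `n_cells`, `n_positive`,
#'   `fraction`, `median_load`.
#' @export
occupancy <- function(symb, asg, threshold = 100) {
  stopifnot(inherits(symb, "umi_matrix"), threshold >= 0)
  grp <- cell_groups(asg, "metacell")
  tot <- cell_totals(symb)
  mcs <- asg$metacells$metacell
  out <- purrr::map_dfr(mcs, function(m) {
    cells_m <- intersect(names(grp)[!is.na(grp) & grp == m], names(tot))
    if (!length(cells_m)) {
      return(tibble::tibble(metacell = m, n_cells = 0L, n_positive = 0L,
                            fraction = NA_real_, median_load = NA_real_))
    }
    pos <- tot[cells_m] > threshold
    tibble::tibble(metacell = m, n_cells = length(cells_m),
                   n_positive = sum(pos),
                   fraction = mean(pos),
                   median_load = if (any(pos)) stats::median(tot[cells_m][pos])
                     else NA_real_)
  })
  empty <- out$metacell[out$n_cells == 0L]
  if (length(empty)) {
    warning("metacells with no cells dropped: ",
            paste(empty, collapse = ", "), call. = FALSE)
    out <- out[out$n_cells > 0L, , drop = FALSE]
  }
  out
}

#' Aggregate single-cell expression versus bulk
#'
#' Sums single-cell counts per gene, quantile-normalizes the aggregate and
#' the bulk vector jointly (two-column quantile normalization), and flags
#' genes whose absolute log2 fold-change exceeds `fc_thr`.
#'
#' @param sc single-cell [umi_matrix()].
#' @param bulk named numeric vector of bulk expression (e.g. mean CPM over
#'   replicates); names are gene ids.
#' @param fc_thr absolute log2 fold-change threshold, strict (default 2).
#' @param pseudo pseudocount for the log ratio (default 1).
#' @return Tibble with columns `gene`, `sc_value`, `bulk_value` (both
#'   quantile-normalized), `log2_fc`, `flagged`, over the shared gene
#'   universe.
#' @export
aggregate_vs_bulk <- function(sc, bulk, fc_thr = 2, pseudo = 1) {
  stopifnot(inherits(sc, "umi_matrix"), !is.null(names(bulk)))
  agg <- Matrix::rowSums(sc$counts)
  shared <- intersect(names(agg), names(bulk))
  if (!length(shared)) stop("disjoint gene sets", call. = FALSE)
  m <- cbind(sc = agg[shared], bulk = bulk[shared])
  qn <- quantile_normalize(m)
  lfc <- log2((qn[, "sc"] + pseudo) / (qn[, "bulk"] + pseudo))
  tibble::tibble(gene = shared, sc_value = qn[, "sc"],
                 bulk_value = qn[, "bulk"], log2_fc = lfc,
                 flagged = abs(lfc) > fc_thr)
}

#' Screen a symbiont matrix for transcriptional heterogeneity
#'
#' Runs the same feature-gene selection applied to the host (see
#' [select_feature_genes()]) on the symbiont cells. An empty result is the
#' documented "transcriptionally homogeneous" verdict -- the expected
#' outcome when every symbiont gene's expression merely tracks cell size.
#'
#' @param symb symbiont [umi_matrix()].
#' @param ... passed to [select_feature_genes()].
#' @return Character vector of variable genes (possibly empty); when empty
#'   a `message()` records the homogeneous verdict.
#' @export
heterogeneity_screen <- function(symb, ...) {
  stopifnot(inherits(symb, "umi_matrix"), ncol(symb$counts) > 0)
  genes <- suppressWarnings(select_feature_genes(symb, ...))
  if (!length(genes)) {
    message("heterogeneity_screen: no variable genes; verdict homogeneous")
  }
  genes
}

#' Counts-per-million with replicate averaging
#'
#' Scales each column of a bulk count matrix to counts per million and
#' averages across replicate columns.
#'
#' @param counts genes x replicates numeric matrix.
#' @return Named numeric vector of mean CPM per gene.
#' @export
bulk_cpm <- function(counts) {
  counts <- as.matrix(counts)
  cpm <- sweep(counts, 2L, colSums(counts), "/") * 1e6
  rowMeans(cpm)
}
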