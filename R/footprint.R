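#' Filter cells by total UMI count
#'
#' Removes cells whose library size falls outside `[min_umi, max_umi]`.
#' Whole-organism MARS-seq atlases typically use a lower bound of 100--200
#' UMIs (stage-dependent) and an upper bound of 8,000 UMIs; boundary values
#' are retained (`min_umi <= total <= max_umi`).
#'
#' @param umi a [umi_matrix()].
#' @param min_umi,max_umi inclusive bounds on per-cell total UMIs.
#' @return A [umi_matrix()] with failing cells dropped, cell order preserved.
#'   The number of removed cells is reported via `message()` and stored in
#'   attribute `"n_removed"`.
#' @export
filter_cells <- function(umi, min_umi = 100, max_umi = 8000) {
  stopifnot(inherits(umi, "umi_matrix"), min_umi < max_umi)
  tot <- cell_totals(umi)
  keep <- tot >= min_umi & tot <= max_umi
  if (!any(keep)) {
    stop(sprintf("all %d cells removed by UMI filter [%g, %g]",
                 length(keep), min_umi, max_umi), call. = FALSE)
  }
  n_removed <- sum(!keep)
  message(sprintf("filter_cells: removed %d of %d cells", n_removed, length(keep)))
  out <- umi_subset(umi, cells = colnames(umi$counts)[keep])
  attr(out, "n_removed") <- n_removed
  out
}

# Normalized size correlation: observed Pearson correlation between a gene's
# raw per-cell counts and cell total UMIs, centered by the mean correlation of
# count-matched size-proportional null genes (multinomial draws with
# probabilities proportional to cell totals and the same gene total). Genes
# tracking cell size score ~0; bursty/type-restricted genes score negative.
size_correlation <- function(counts, n_null = 30, seed = 1L) {
  tot <- Matrix::colSums(counts)
  dense <- as.matrix(counts)
  obs <- suppressWarnings(apply(dense, 1L, stats::cor, y = tot))
  p <- tot / sum(tot)
  gene_tot <- rowSums(dense)
  withr::with_seed(seed, {
    null_mean <- vapply(gene_tot, function(tg) {
      if (tg < 2) return(0)
      sims <- stats::rmultinom(n_null, size = tg, prob = p)
      mean(suppressWarnings(apply(sims, 2L, stats::cor, y = tot)), na.rm = TRUE)
    }, numeric(1))
  })
  out <- obs - null_mean
  out[is.na(out)] <- 0
  out
}

#' Select feature (marker candidate) genes
#'
#' Applies the count filters used for marker selection in whole-organism
#' atlases -- detected (> 1 UMI) in at least `min_cells` cells and total UMI
#' count strictly greater than `min_gene_umi` -- plus a normalized
#' size-correlation filter that removes genes whose expression merely tracks
#' cell size, and a user-supplied exclusion list (typically ribosomal
#' proteins and histones).
#'
#' The size-correlation statistic is the Pearson correlation between a
#' gene's per-cell counts and the per-cell total UMIs, centered by the mean
#' correlation of count-matched size-proportional null genes; genes are kept
#' only when the statistic is below `size_corr_thr`. A population whose
#' every gene is expressed proportionally to cell size therefore yields an
#' empty list -- the "transcriptionally homogeneous" verdict.
#'
#' @param umi a [umi_matrix()].
#' @param size_corr_thr keep genes with normalized size correlation strictly
#'   below this (default -0.05).
#' @param min_cells minimum number of cells with > 1 UMI (default 3).
#' @param min_gene_umi total-count threshold, strict (default 30: a gene at
#'   exactly 30 UMIs is excluded).
#' @param exclude character vector of gene ids to drop regardless.
#' @param n_null number of null genes per gene for the size-correlation
#'   centering.
#' @return Character vector of selected gene ids (possibly empty, with a
#'   warning).
#' @export
select_feature_genes <- function(umi, size_corr_thr = -0.05, min_cells = 3,
                                 min_gene_umi = 30, exclude = character(),
                                 n_null = 30) {
  stopifnot(inherits(umi, "umi_matrix"), ncol(umi$counts) > 0)
  counts <- umi$counts
  detected <- Matrix::rowSums(counts > 1) >= min_cells
  total_ok <- Matrix::rowSums(counts) > min_gene_umi
  cand <- detected & total_ok & !(rownames(counts) %in% exclude)
  genes <- rownames(counts)[cand]
  if (!length(genes)) {
    warning("no gene passes the count filters", call. = FALSE)
    return(character())
  }
  sc <- size_correlation(counts[genes, , drop = FALSE], n_null = n_null)
  out <- genes[sc < size_corr_thr]
  if (!length(out)) warning("no variable genes detected", call. = FALSE)
  out
}

#' Regularized geometric-mean expression footprint (fold-change matrix)
#'
#' For each group (metacell or cell type) and gene, computes the regularized
#' geometric mean of depth-scaled per-cell expression and divides by the
#' median across groups. The resulting values are the "fold-change" (FC)
#' representation of expression used throughout downstream analysis.
#'
#' Per cell, counts are converted to fractions and scaled to a common depth
#' (the median cell total). Per group g and gene i,
#' `geo = exp(mean(log(f + epsilon))) - epsilon` over cells in g; then
#' `FC = (geo + epsilon) / max(median_g(geo + epsilon), epsilon)`.
#'
#' @param umi a [umi_matrix()].
#' @param asg a [metacell_map()]; outlier cells are ignored.
#' @param epsilon regularization, on the depth-scaled fraction level
#'   (default 0.1).
#' @param level `"metacell"` or `"celltype"` -- the grouping of columns.
#' @param normalize divide by the cross-group median (default `TRUE`).
#' @return A numeric genes x groups matrix of class `footprint` with
#'   attributes `epsilon`, `normalized` and `level`. All values positive.
#' @export
compute_footprint <- function(umi, asg, epsilon = 0.1,
                              level = c("metacell", "celltype"),
                              normalize = TRUE) {
  level <- match.arg(level)
  stopifnot(inherits(umi, "umi_matrix"), epsilon > 0)
  grp <- cell_groups(asg, level)
  grp <- grp[intersect(names(grp), colnames(umi$counts))]
  grp <- grp[!is.na(grp)]
  if (!length(grp)) stop("no assigned cells overlap the matrix", call. = FALSE)
  groups <- sort(unique(grp))
  tot <- cell_totals(umi)[names(grp)]
  if (any(tot == 0)) stop("cells with zero total UMIs present", call. = FALSE)
  depth <- stats::median(tot)
  geo <- matrix(NA_real_, nrow(umi$counts), length(groups),
                dimnames = list(rownames(umi$counts), groups))
  for (g in groups) {
    cells_g <- names(grp)[grp == g]
    if (!length(cells_g)) stop("empty group: ", g, call. = FALSE)
    f <- as.matrix(umi$counts[, cells_g, drop = FALSE])
    f <- sweep(f, 2L, tot[cells_g] / depth, "/")
    geo[, g] <- exp(rowMeans(log(f + epsilon))) - epsilon
  }
  vals <- geo + epsilon
  if (normalize && length(groups) > 1) {
    med <- apply(vals, 1L, stats::median)
    vals <- vals / pmax(med, epsilon)
  } else if (normalize) {
    vals[] <- 1
  }
  new_footprint(vals, epsilon = epsilon, normalized = normalize, level = level)
}

new_footprint <- function(values, epsilon, normalized, level = "metacell") {
  stopifnot(all(values > 0))
  structure(values, class = c("footprint", "matrix"),
            epsilon = epsilon, normalized = normalized, level = level)
}

#' @export
print.footprint <- function(x, ...) {
  cat(sprintf("<footprint> %d genes x %d %ss (epsilon = %g, %s)\n",
              nrow(x), ncol(x), attr(x, "level"), attr(x, "epsilon"),
              if (isTRUE(attr(x, "normalized"))) "median-normalized" else "raw"))
  invisible(x)
}

#' @rdname tidy.footprint
#' @method tidy footprint
#' @export
tidy.footprint <- function(x, ...) {
  tibble::as_tibble(as.table(unclass(x)), .name_repair = "minimal") |>
    stats::setNames(c("gene", "group", "fc"))
}

#' Tidy a footprint into a long tibble
#'
#' @param x a `footprint` matrix.
#' @param ... unused.
#' @return Tibble with columns `gene`, `group`, `fc`.
#' @name tidy.footprint
NULL

#' Quality-control rules for metacell filtering
#'
#' Bundles the thresholds of the semi-supervised metacell filter: a metacell
#' must express at least `min_markers` marker genes and have a mean cell
#' total at or above the peak (mode) of the per-cell UMI distribution,
#' unless one of three exceptions fires: (i) it specifically expresses more
#' than `n_tfs` transcription-factor genes at FC > `tf_fc`; (ii) it carries
#' a strong symbiont signal (> `min_symb_umi` symbiont UMIs); (iii) it
#' expresses any gene from a rescue marker list (e.g. cnidocyte markers) at
#' FC > `marker_fc`.
#'
#' @param min_markers minimum expressed markers (FC > 1), default 10.
#' @param n_tfs exception (i): more than this many TFs, default 2.
#' @param tf_fc exception (i) FC threshold, default 2.
#' @param min_symb_umi exception (ii) symbiont UMI threshold, default 10000.
#' @param rescue_markers exception (iii) gene list, default none.
#' @param marker_fc exception (iii) FC threshold, default 1.5.
#' @param umi_peak optional explicit per-cell UMI mode; when `NULL` it is
#'   estimated as the midpoint of the tallest Freedman--Diaconis histogram
#'   bin of per-cell totals.
#' @return A list of class `qc_rules`.
#' @export
qc_rules <- function(min_markers = 10, n_tfs = 2, tf_fc = 2,
                     min_symb_umi = 10000, rescue_markers = character(),
                     marker_fc = 1.5, umi_peak = NULL) {
  stopifnot(min_markers >= 0, n_tfs >= 0, tf_fc > 0, min_symb_umi >= 0,
            marker_fc > 0)
  structure(list(min_markers = min_markers, n_tfs = n_tfs, tf_fc = tf_fc,
                 min_symb_umi = min_symb_umi, rescue_markers = rescue_markers,
                 marker_fc = marker_fc, umi_peak = umi_peak),
            class = "qc_rules")
}

umi_distribution_peak <- function(totals) {
  h <- graphics::hist(totals, breaks = "FD", plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Semi-supervised metacell filtering
#'
#' Retains a metacell iff it expresses at least `rules$min_markers` marker
#' genes (FC > 1) AND its mean cell total UMI is at or above the mode of the
#' per-cell UMI distribution, OR any of the three exceptions in
#' [qc_rules()] fires. Cells of removed metacells become outliers
#' (`metacell = NA`).
#'
#' @param fp metacell-level [compute_footprint()] output.
#' @param umi the [umi_matrix()] the footprint was computed from. For the
#'   symbiont exception the matrix must carry a per-gene `organism` label;
#'   without one the exception never fires.
#' @param asg a [metacell_map()].
#' @param markers character vector of marker genes (must be rows of `fp`).
#' @param rules a [qc_rules()].
#' @param tf_list character vector of transcription-factor gene ids;
#'   required when the TF exception is enabled (`rules$n_tfs` finite and
#'   `tf_fc` set).
#' @return A [metacell_map()] with failing metacells removed and their cells
#'   marked outliers; attribute `"qc_table"` holds a per-metacell tibble of
#'   the rule outcomes.
#' @export
filter_metacells <- function(fp, umi, asg, markers, rules = qc_rules(),
                             tf_list = character()) {
  stopifnot(inherits(fp, "footprint"), inherits(umi, "umi_matrix"),
            inherits(rules, "qc_rules"))
  if (!all(markers %in% rownames(fp))) {
    stop("`markers` must be a subset of footprint genes", call. = FALSE)
  }
  if (rules$n_tfs > 0 && !length(tf_list)) {
    stop("TF exception enabled but `tf_list` is empty", call. = FALSE)
  }
  grp <- cell_groups(asg, "metacell")
  grp <- grp[intersect(names(grp), colnames(umi$counts))]
  grp <- grp[!is.na(grp)]
  mcs <- colnames(fp)
  tot <- cell_totals(umi)
  peak <- rules$umi_peak %||% umi_distribution_peak(tot[names(grp)])
  # symbiont genes = any organism label other than the majority (host) label
  symb_genes <- character()
  if ("organism" %in% names(umi$genes)) {
    org_tab <- table(umi$genes$organism)
    host_org <- names(org_tab)[which.max(org_tab)]
    symb_genes <- umi$genes$gene[umi$genes$organism != host_org]
  }
  tf_in <- intersect(tf_list, rownames(fp))
  qc <- purrr::map_dfr(mcs, function(m) {
    cells_m <- names(grp)[grp == m]
    n_markers <- sum(fp[markers, m] > 1)
    mean_tot <- if (length(cells_m)) mean(tot[cells_m]) else NA_real_
    symb_umi <- if (length(symb_genes) && length(cells_m)) {
      sum(umi$counts[symb_genes, cells_m, drop = FALSE])
    } else 0
    n_tf <- if (length(tf_in)) sum(fp[tf_in, m] > rules$tf_fc) else 0L
    rescue_in <- intersect(rules$rescue_markers, rownames(fp))
    rescue_hit <- length(rescue_in) > 0 && any(fp[rescue_in, m] > rules$marker_fc)
    base_pass <- n_markers >= rules$min_markers &&
      !is.na(mean_tot) && mean_tot >= peak
    tibble::tibble(metacell = m, n_markers = n_markers, mean_total = mean_tot,
                   symbiont_umi = symb_umi, n_tf = n_tf,
                   base_pass = base_pass,
                   tf_exception = n_tf > rules$n_tfs,
                   symbiont_exception = symb_umi > rules$min_symb_umi,
                   marker_exception = rescue_hit,
                   retained = base_pass || n_tf > rules$n_tfs ||
                     symb_umi > rules$min_symb_umi || rescue_hit)
  })
  keep <- qc$metacell[qc$retained]
  cells <- asg$cells
  cells$metacell[!(cells$metacell %in% keep)] <- NA_character_
  out <- metacell_map(cells,
                      asg$metacells[asg$metacells$metacell %in% keep, , drop = FALSE],
                      asg$cell_types)
  attr(out, "qc_table") <- qc
  out
}

#' Top marker genes per group
#'
#' For each footprint column, genes with FC at or above `fc_thr` are ranked
#' by FC (descending, ties broken by gene id ascending) and truncated to
#' `max_per_group`. The union over groups is returned with each gene
#' attributed to its argmax group.
#'
#' @param fp a [compute_footprint()] result.
#' @param fc_thr minimum fold-change (inclusive), default 2.
#' @param max_per_group cap per group, default 10.
#' @return Tibble with columns `gene`, `group`, `fc` where `group` is the
#'   column of maximal FC for that gene; sorted by group then FC descending.
#' @export
top_markers <- function(fp, fc_thr = 2, max_per_group = 10) {
  stopifnot(inherits(fp, "footprint"), fc_thr > 1, max_per_group >= 1)
  per_group <- purrr::map(colnames(fp), function(g) {
    fc <- fp[, g]
    sel <- names(fc)[fc >= fc_thr]
    sel <- sel[order(-fc[sel], sel)]
    utils::head(sel, max_per_group)
  })
  genes <- sort(unique(unlist(per_group)))
  if (!length(genes)) {
    return(tibble::tibble(gene = character(), group = character(),
                          fc = numeric()))
  }
  sub <- unclass(fp)[genes, , drop = FALSE]
  argmax <- colnames(sub)[apply(sub, 1L, which.max)]
  tibble::tibble(gene = genes, group = argmax,
                 fc = sub[cbind(genes, argmax)]) |>
    dplyr::arrange(.data$group, dplyr::desc(.data$fc), .data$gene)
}
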