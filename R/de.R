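# Two-sided Fisher exact p-value for 2x2 tables [a, b; c, d], vectorized.
# Method of small p-values: sum of hypergeometric point probabilities not
# exceeding the observed one (the convention of stats::fisher.test).
fisher_p2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n); d <- rep_len(d, n)
  vapply(seq_len(n), function(i) {
    m <- a[i] + c[i]         # margin of column 1
    nn <- b[i] + d[i]        # margin of column 2
    k <- a[i] + b[i]         # row-1 draws
    support <- max(0, k - nn):min(k, m)
    probs <- stats::dhyper(support, m, nn, k)
    obs <- stats::dhyper(a[i], m, nn, k)
    min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  }, numeric(1))
}

# One-sided (enrichment) hypergeometric tail P(X >= a)
fisher_p1 <- function(a, b, c, d) {
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Fisher exact differential expression between two cell groups
#'
#' Pooled-UMI gene-versus-rest construction: for each gene g the 2x2 table
#' is \[n_gA, N_A - n_gA; n_gB, N_B - n_gB\], where n_gX is the summed UMI
#' count of g in group X and N_X the group's total UMI count. Two-sided
#' Fisher exact p-values are BH-adjusted across genes. An alternative
#' construction counting cells expressing the gene (rather than pooled
#' UMIs) is available via `method = "cells"`.
#'
#' @param umi a [umi_matrix()].
#' @param cells_a,cells_b disjoint, non-empty character vectors of cell
#'   ids.
#' @param alpha_adj adjusted-p significance threshold (default 1e-5).
#' @param rho regularization for the displayed log2 enrichment only
#'   (default 1); p-values always use raw counts.
#' @param method `"umi"` (pooled UMIs, default) or `"cells"` (cells
#'   detecting the gene with at least 1 UMI).
#' @return Tibble of class `de_result` with columns `gene`, `count_a`,
#'   `count_b`, `total_a`, `total_b`, `log2_enrichment`, `p`, `p_adj`,
#'   `significant`, sorted by `p`.
#' @export
fisher_de <- function(umi, cells_a, cells_b, alpha_adj = 1e-5, rho = 1,
                      method = c("umi", "cells")) {
  method <- match.arg(method)
  stopifnot(inherits(umi, "umi_matrix"),
            length(cells_a) > 0, length(cells_b) > 0)
  if (length(intersect(cells_a, cells_b))) {
    stop("cell groups must be disjoint", call. = FALSE)
  }
  ma <- umi$counts[, cells_a, drop = FALSE]
  mb <- umi$counts[, cells_b, drop = FALSE]
  if (method == "cells") {
    na <- Matrix::rowSums(ma > 0); nb <- Matrix::rowSums(mb > 0)
    total_a <- length(cells_a); total_b <- length(cells_b)
  } else {
    na <- Matrix::rowSums(ma); nb <- Matrix::rowSums(mb)
    total_a <- sum(na); total_b <- sum(nb)
  }
  if (total_a == 0 || total_b == 0) {
    stop("a group has zero total counts", call. = FALSE)
  }
  p <- fisher_p2(na, total_a - na, nb, total_b - nb)
  p_adj <- stats::p.adjust(p, method = "BH")
  out <- tibble::tibble(
    gene = rownames(umi$counts),
    count_a = as.numeric(na), count_b = as.numeric(nb),
    total_a = total_a, total_b = total_b,
    log2_enrichment = log2((na + rho) / total_a) - log2((nb + rho) / total_b),
    p = p, p_adj = p_adj, significant = p_adj < alpha_adj
  ) |> dplyr::arrange(.data$p, .data$gene)
  class(out) <- c("de_result", class(out))
  attr(out, "alpha_adj") <- alpha_adj
  out
}

#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x), n_significant = sum(x$significant),
                 alpha_adj = attr(x, "alpha_adj"))
}

#' Fisher term enrichment
#'
#' Generic one-sided (enrichment) Fisher exact test of a gene set against
#' annotation terms, BH-adjusted across terms. All annotated genes of the
#' organism typically serve as background.
#'
#' @param set character vector of genes (subset of `background`).
#' @param background character vector; the test universe.
#' @param term_map tibble with columns `gene`, `term` (a gene may carry
#'   many terms). Genes outside the background are ignored.
#' @param two_sided use the two-sided small-p-values method instead of the
#'   enrichment tail (default `FALSE`).
#' @return Tibble with columns `term`, `n_term`, `overlap`, `p`, `p_adj`,
#'   sorted by `p`.
#' @export
term_enrichment <- function(set, background, term_map, two_sided = FALSE) {
  if (!all(set %in% background)) {
    stop("`set` must be a subset of `background`", call. = FALSE)
  }
  term_map <- tibble::as_tibble(term_map)
  stopifnot(all(c("gene", "term") %in% names(term_map)))
  term_map <- term_map[term_map$gene %in% background, , drop = FALSE]
  if (!nrow(term_map)) stop("empty term universe", call. = FALSE)
  n_bg <- length(background)
  n_set <- length(set)
  res <- term_map |>
    dplyr::group_by(term = .data$term) |>
    dplyr::summarise(n_term = dplyr::n_distinct(.data$gene),
                     overlap = dplyr::n_distinct(intersect(.data$gene, set)),
                     .groups = "drop")
  a <- res$overlap
  b <- n_set - a
  c_ <- res$n_term - a
  d <- n_bg - n_set - c_
  res$p <- if (two_sided) fisher_p2(a, b, c_, d) else fisher_p1(a, b, c_, d)
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  dplyr::arrange(res, .data$p, .data$term)
}
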