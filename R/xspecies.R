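#' Ortholog-expanded joint cell-type expression matrix for two species
#'
#' Joins two cell-type footprints over an ortholog pair table, allowing
#' one-to-many orthology by duplicating a gene's expression row once per
#' expressed counterpart, up to `max_copies` counterparts; genes with more
#' expressed counterparts than `max_copies` are dropped. A counterpart is
#' "expressed" when its maximum FC exceeds `expressed_floor`. A pair whose
#' counterpart is unexpressed is retained only when the gene has no
#' expressed counterpart at all (so strictly one-to-one tables survive
#' unchanged).
#'
#' @param fp_a,fp_b cell-type [compute_footprint()] results for species A
#'   and B.
#' @param pairs tibble with columns `gene_a`, `gene_b` and optionally
#'   `orthogroup`; no duplicated (gene_a, gene_b) rows.
#' @param species names for the two species used to tag columns
#'   (`"species:celltype"`); default `c("A", "B")`.
#' @param max_copies maximum expressed counterparts (default 3).
#' @param expressed_floor FC floor defining "expressed" (default 1).
#' @return A `joint_expression` object: numeric matrix, rows = retained
#'   ortholog pairs (rownames `"gene_a|gene_b"`), columns tagged by species;
#'   attributes `row_info` (tibble) and `quantile_normalized = FALSE`.
#' @export
expand_orthologs <- function(fp_a, fp_b, pairs, species = c("A", "B"),
                             max_copies = 3, expressed_floor = 1) {
  stopifnot(max_copies >= 1, length(species) == 2)
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  if (anyDuplicated(pairs[c("gene_a", "gene_b")])) {
    stop("duplicate (gene_a, gene_b) rows in pair table", call. = FALSE)
  }
  bad_a <- setdiff(pairs$gene_a, rownames(fp_a))
  bad_b <- setdiff(pairs$gene_b, rownames(fp_b))
  if (length(bad_a) || length(bad_b)) {
    stop("pairs reference unknown genes: ",
         paste(utils::head(c(bad_a, bad_b), 5), collapse = ", "), call. = FALSE)
  }
  expr_a <- apply(unclass(fp_a), 1L, max) > expressed_floor
  expr_b <- apply(unclass(fp_b), 1L, max) > expressed_floor
  pairs <- pairs |>
    dplyr::mutate(e_a = expr_a[.data$gene_a], e_b = expr_b[.data$gene_b]) |>
    dplyr::group_by(.data$gene_a) |>
    dplyr::mutate(k_a = sum(.data$e_b)) |>
    dplyr::group_by(.data$gene_b) |>
    dplyr::mutate(k_b = sum(.data$e_a)) |>
    dplyr::ungroup()
  keep <- pairs$k_a <= max_copies & pairs$k_b <= max_copies &
    (pairs$e_b | pairs$k_a == 0) & (pairs$e_a | pairs$k_b == 0)
  kept <- pairs[keep, , drop = FALSE]
  mat <- cbind(unclass(fp_a)[kept$gene_a, , drop = FALSE],
               unclass(fp_b)[kept$gene_b, , drop = FALSE])
  colnames(mat) <- c(paste0(species[1], ":", colnames(fp_a)),
                     paste0(species[2], ":", colnames(fp_b)))
  rownames(mat) <- paste0(kept$gene_a, "|", kept$gene_b)
  new_joint(mat, row_info = kept[intersect(c("gene_a", "gene_b", "orthogroup"),
                                           names(kept))],
            species = stats::setNames(
              list(colnames(fp_a), colnames(fp_b)), species))
}

new_joint <- function(mat, row_info, species, quantile_normalized = FALSE) {
  structure(mat, class = c("joint_expression", "matrix"),
            row_info = tibble::as_tibble(row_info), species = species,
            quantile_normalized = quantile_normalized)
}

#' @export
print.joint_expression <- function(x, ...) {
  cat(sprintf("<joint_expression> %d ortholog rows x %d cell types (%s)%s\n",
              nrow(x), ncol(x),
              paste(names(attr(x, "species")), collapse = " + "),
              if (isTRUE(attr(x, "quantile_normalized")))
                ", quantile-normalized" else ""))
  invisible(x)
}

#' Quantile normalization
#'
#' Replaces each column's values by the mean across columns of the order
#' statistics at matching ranks, so that after normalization every column
#' has an identical sorted value vector. Ties within a column receive the
#' mean of the reference values over their rank span (the `ties = TRUE`
#' dialect).
#'
#' @param x a `joint_expression` object or plain numeric matrix with no
#'   missing values.
#' @return Same shape as the input; for `joint_expression` the
#'   `quantile_normalized` flag is set.
#' @export
quantile_normalize <- function(x) {
  m <- unclass(x)
  if (anyNA(m)) stop("missing values not allowed", call. = FALSE)
  ref <- rowMeans(apply(m, 2L, sort, method = "radix"))
  out <- apply(m, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    stats::approx(seq_along(ref), ref, xout = r)$y
  })
  dimnames(out) <- dimnames(m)
  if (inherits(x, "joint_expression")) {
    out <- new_joint(out, attr(x, "row_info"), attr(x, "species"),
                     quantile_normalized = TRUE)
  }
  out
}

# KLD(p || q) in bits for probability vectors (columns already normalized)
kld_bits <- function(p, q) sum(p * log2(p / q))

#' Pairwise Kullback--Leibler divergence between cell-type profiles
#'
#' Treats each cell-type column (over ortholog rows) as a probability
#' distribution after adding a pseudocount and renormalizing, and computes
#' the divergence for every cross-species cell-type pair. By default the
#' symmetrized mean of both directions is returned (cross-species cell-type
#' links are undirected).
#'
#' @param joint a quantile-normalized `joint_expression` (two species), or a
#'   plain matrix (all column pairs compared; useful for hand checks).
#' @param pseudo pseudocount as a fraction of column mass: each entry gets
#'   `pseudo * sum(col) / nrow` before renormalization (default 1e-4).
#' @param symmetrize `"mean"` (default) or `"none"` (directed
#'   KLD(A-type || B-type)).
#' @return Numeric matrix, species-A cell types x species-B cell types (or
#'   all columns x all columns for a plain matrix). Entries are >= 0 and
#'   zero iff the two columns are identical.
#' @export
kld_matrix <- function(joint, pseudo = 1e-4, symmetrize = c("mean", "none")) {
  symmetrize <- match.arg(symmetrize)
  stopifnot(pseudo >= 0)
  m <- unclass(joint)
  if (inherits(joint, "joint_expression") &&
      !isTRUE(attr(joint, "quantile_normalized"))) {
    stop("joint matrix must be quantile-normalized first", call. = FALSE)
  }
  if (any(m < 0)) stop("negative expression values", call. = FALSE)
  p <- apply(m, 2L, function(col) {
    col <- col + pseudo * sum(col) / length(col)
    col / sum(col)
  })
  if (inherits(joint, "joint_expression")) {
    sp <- attr(joint, "species")
    cols_a <- paste0(names(sp)[1], ":", sp[[1]])
    cols_b <- paste0(names(sp)[2], ":", sp[[2]])
  } else {
    cols_a <- cols_b <- colnames(m) %||% as.character(seq_len(ncol(m)))
    colnames(p) <- cols_a
  }
  out <- matrix(NA_real_, length(cols_a), length(cols_b),
                dimnames = list(cols_a, cols_b))
  for (a in cols_a) {
    for (b in cols_b) {
      d <- kld_bits(p[, a], p[, b])
      if (symmetrize == "mean") d <- (d + kld_bits(p[, b], p[, a])) / 2
      out[a, b] <- d
    }
  }
  if (!all(is.finite(out))) {
    stop("non-finite divergence; use pseudo > 0 with zero-containing columns",
         call. = FALSE)
  }
  # clamp tiny negative rounding noise
  out[out < 0 & out > -1e-12] <- 0
  out
}

#' Top cross-species cell-type links by lowest divergence
#'
#' Ranks all cell-type pairs by divergence and returns those in the lowest
#' `1 - quantile` tail (e.g. `quantile = 0.98` keeps the most similar 2%).
#' Ties at the cutoff are all included.
#'
#' @param kld a [kld_matrix()] result.
#' @param quantile similarity quantile in (0, 1\]; pairs whose similarity
#'   (negative divergence) is at or above this quantile are linked. A value
#'   of 0 returns all pairs.
#' @return Tibble with columns `celltype_a`, `celltype_b`, `divergence`,
#'   `rank_quantile`, sorted by divergence ascending.
#' @export
top_links <- function(kld, quantile = 0.98) {
  stopifnot(is.matrix(kld), quantile >= 0, quantile < 1)
  long <- tibble::as_tibble(as.table(kld), .name_repair = "minimal") |>
    stats::setNames(c("celltype_a", "celltype_b", "divergence"))
  sim <- -long$divergence
  cutoff <- stats::quantile(sim, probs = quantile, type = 7, names = FALSE)
  long |>
    dplyr::mutate(rank_quantile = (rank(sim) - 1) / max(length(sim) - 1, 1)) |>
    dplyr::filter(-(.data$divergence) >= cutoff) |>
    dplyr::arrange(.data$divergence)
}

#' Shared-ortholog expression test for matched cell types
#'
#' For each queried group of columns (a putative homologous cell-type set),
#' finds the shared genes -- rows with FC above `fc_thr` in every group
#' member -- and runs a paired two-sided Wilcoxon signed-rank test between
#' each shared gene's in-group mean and out-group mean expression. P-values
#' are BH-adjusted across all queried groups in the call.
#'
#' @param joint a (typically quantile-normalized) `joint_expression` or
#'   plain matrix.
#' @param groups a named list of character vectors of column names, or a
#'   single character vector (treated as one group).
#' @param fc_thr shared-gene threshold, strict `>` (default 1.3).
#' @return Tibble with one row per group: `group`, `n_genes`, `statistic`,
#'   `p`, `p_adj`, and a list-column `genes`.
#' @export
shared_ortholog_test <- function(joint, groups, fc_thr = 1.3) {
  m <- unclass(joint)
  if (!is.list(groups)) groups <- list(group1 = groups)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  res <- purrr::imap_dfr(groups, function(cols, nm) {
    if (!length(cols) || !all(cols %in% colnames(m))) {
      stop("group '", nm, "' has unknown columns", call. = FALSE)
    }
    if (length(cols) >= ncol(m)) {
      stop("group '", nm, "' must be a proper subset of columns", call. = FALSE)
    }
    ing <- m[, cols, drop = FALSE]
    outg <- m[, setdiff(colnames(m), cols), drop = FALSE]
    shared <- rownames(m)[rowSums(ing > fc_thr) == length(cols)]
    if (length(shared) < 2) {
      stop("group '", nm, "': fewer than 2 shared genes", call. = FALSE)
    }
    x <- rowMeans(ing[shared, , drop = FALSE])
    y <- rowMeans(outg[shared, , drop = FALSE])
    d <- x - y
    if (all(d == 0)) {
      warning("group '", nm, "': all paired differences zero; p = 1",
              call. = FALSE)
      return(tibble::tibble(group = nm, n_genes = length(shared),
                            statistic = NA_real_, p = 1,
                            genes = list(shared)))
    }
    use_exact <- sum(d != 0) <= 25 && !any(duplicated(abs(d[d != 0])))
    wt <- suppressWarnings(stats::wilcox.test(
      x, y, paired = TRUE, exact = use_exact, correct = TRUE))
    tibble::tibble(group = nm, n_genes = length(shared),
                   statistic = unname(wt$statistic), p = wt$p.value,
                   genes = list(shared))
  })
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res[c("group", "n_genes", "statistic", "p", "p_adj", "genes")]
}

#' Multi-species joint matrix over strict one-to-one orthologs
#'
#' Combines cell-type footprints of several species over orthogroups that
#' have exactly one member in every species, and quantile-normalizes the
#' result. Orthogroups missing a species or with multiple members in any
#' species are dropped (counts reported via `message()`).
#'
#' @param fps named list of [compute_footprint()] results, one per species.
#' @param members tibble with columns `orthogroup`, `species`, `gene`
#'   (long-format orthogroup membership).
#' @return A quantile-normalized `joint_expression` whose rows are
#'   orthogroups and whose columns span all species' cell types.
#' @export
one_to_one_joint <- function(fps, members) {
  stopifnot(is.list(fps), !is.null(names(fps)))
  members <- tibble::as_tibble(members)
  stopifnot(all(c("orthogroup", "species", "gene") %in% names(members)))
  members <- members[members$species %in% names(fps), , drop = FALSE]
  present <- purrr::imap_dfr(fps, function(fp, sp) {
    tibble::tibble(species = sp, gene = rownames(fp))
  })
  members <- dplyr::semi_join(members, present, by = c("species", "gene"))
  tab <- members |>
    dplyr::count(.data$orthogroup, .data$species) |>
    tidyr::pivot_wider(names_from = "species", values_from = "n",
                       values_fill = 0L)
  sp_cols <- names(fps)
  ok <- tab$orthogroup[rowSums(as.matrix(tab[sp_cols]) == 1L) == length(sp_cols)]
  n_drop <- length(unique(members$orthogroup)) - length(ok)
  if (n_drop > 0) {
    message(sprintf("one_to_one_joint: dropped %d orthogroups not strictly one-to-one",
                    n_drop))
  }
  if (!length(ok)) stop("no strict one-to-one orthogroups", call. = FALSE)
  keep <- members[members$orthogroup %in% ok, , drop = FALSE]
  wide <- keep |>
    dplyr::arrange(.data$orthogroup) |>
    tidyr::pivot_wider(names_from = "species", values_from = "gene")
  blocks <- lapply(sp_cols, function(sp) {
    b <- unclass(fps[[sp]])[wide[[sp]], , drop = FALSE]
    colnames(b) <- paste0(sp, ":", colnames(fps[[sp]]))
    b
  })
  mat <- do.call(cbind, blocks)
  rownames(mat) <- wide$orthogroup
  joint <- new_joint(mat, row_info = wide,
                     species = stats::setNames(
                       lapply(fps, colnames), names(fps)))
  quantile_normalize(joint)
}
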