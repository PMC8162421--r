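#' Variably expressed genes
#'
#' Genes whose maximum fold-change over any footprint column strictly
#' exceeds `fc_thr` (default 1.8, the conventional cut for cross-stage
#' cell-type trees).
#'
#' @param fp a median-normalized [compute_footprint()] result.
#' @param fc_thr strict threshold on the per-gene maximum FC.
#' @return Character vector of gene ids.
#' @export
variable_genes <- function(fp, fc_thr = 1.8) {
  stopifnot(inherits(fp, "footprint"))
  if (!isTRUE(attr(fp, "normalized"))) {
    stop("`fp` must be median-normalized", call. = FALSE)
  }
  mx <- apply(unclass(fp), 1L, max)
  rownames(fp)[mx > fc_thr]
}

# distance between cell-type columns: 1 - Pearson r on (optionally log2) FC
celltype_distance <- function(fp_sub, log_transform = TRUE) {
  m <- if (log_transform) log2(fp_sub) else fp_sub
  r <- suppressWarnings(stats::cor(m))
  r[is.na(r)] <- 0
  stats::as.dist(1 - r)
}

#' Cell-type co-occurrence matrix from downsampled correlation clustering
#'
#' Repeatedly (i) jackknife-samples a fraction of the variable genes without
#' replacement, (ii) computes Pearson correlation between cell-type columns
#' on log2 fold-changes, (iii) average-linkage clusters the distance
#' `1 - r`, (iv) cuts the dendrogram at the iteration's height, and (v)
#' increments the co-occurrence count of every pair of cell types falling
#' in the same cluster. Iterations are split across the requested cut
#' heights (e.g. 500 at h = 0.75 and 500 at h = 0.95).
#'
#' @param fp a [compute_footprint()] result (typically cell-type level).
#' @param genes variable genes to sample from (subset of `rownames(fp)`).
#' @param n_iter total iterations (default 1000).
#' @param downsample fraction of genes kept each iteration (default 0.75).
#' @param cut_heights data frame with columns `height` and `n` giving the
#'   number of iterations run at each cophenetic cut height on `1 - r`;
#'   `sum(n)` must equal `n_iter`. Default: half at 0.75, half at 0.95.
#' @param seed integer seed; iteration i uses substream seed `seed + i`.
#' @param log_transform correlate on `log2(FC)` (default) or linear FC.
#' @return Integer cell-type x cell-type matrix of class `cooc_matrix` with
#'   attributes `n_iter` and `params`; symmetric, diagonal `n_iter`.
#' @export
cooccurrence <- function(fp, genes, n_iter = 1000, downsample = 0.75,
                         cut_heights = NULL, seed = 1L,
                         log_transform = TRUE) {
  stopifnot(inherits(fp, "footprint"), n_iter >= 1,
            downsample > 0, downsample <= 1)
  if (ncol(fp) < 2) stop("need at least 2 cell types", call. = FALSE)
  if (!all(genes %in% rownames(fp))) {
    stop("`genes` must be a subset of footprint genes", call. = FALSE)
  }
  if (is.null(cut_heights)) {
    cut_heights <- data.frame(height = c(0.75, 0.95),
                              n = c(floor(n_iter / 2), ceiling(n_iter / 2)))
  }
  if (sum(cut_heights$n) != n_iter) {
    stop("cut-height iteration shares must sum to n_iter", call. = FALSE)
  }
  types <- colnames(fp)
  k <- length(types)
  cooc <- matrix(0L, k, k, dimnames = list(types, types))
  n_keep <- max(1L, floor(downsample * length(genes)))
  hs <- rep(cut_heights$height, cut_heights$n)
  for (i in seq_len(n_iter)) {
    gi <- withr::with_seed(seed + i, sample(genes, n_keep))
    d <- celltype_distance(unclass(fp)[gi, , drop = FALSE], log_transform)
    cl <- stats::cutree(stats::hclust(d, method = "average"), h = hs[i])
    same <- outer(cl, cl, "==")
    cooc <- cooc + same
  }
  diag(cooc) <- n_iter
  structure(cooc, class = c("cooc_matrix", "matrix"), n_iter = n_iter,
            params = list(downsample = downsample, cut_heights = cut_heights,
                          seed = seed, log_transform = log_transform))
}

#' @export
print.cooc_matrix <- function(x, ...) {
  cat(sprintf("<cooc_matrix> %d cell types, %d iterations\n",
              ncol(x), attr(x, "n_iter")))
  invisible(x)
}

#' @method tidy cooc_matrix
#' @export
tidy.cooc_matrix <- function(x, ...) {
  tibble::as_tibble(as.table(unclass(x)), .name_repair = "minimal") |>
    stats::setNames(c("type_a", "type_b", "count"))
}

# average-linkage tree from a distance, lexicographic tip order for
# deterministic tie-breaking; returns ape::phylo with node heights as
# branch lengths
hclust_phylo <- function(d) {
  labs <- attr(d, "Labels")
  ord <- order(labs)
  m <- as.matrix(d)[ord, ord]
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  phy <- ape::as.phylo(hc)
  phy
}

#' Build a cell-type tree from a co-occurrence matrix
#'
#' Average-linkage (UPGMA) hierarchical clustering on the distance
#' `1 - counts / n_iter`, agglomerated with Lance--Williams updates. Ties
#' in the minimum inter-cluster distance are broken deterministically in
#' favor of the lexicographically smallest merged tip set, so equal-count
#' matrices always yield the same tree.
#'
#' @param cooc a [cooccurrence()] result, or a plain symmetric distance-like
#'   matrix with dimnames (interpreted directly as distances when it is not
#'   a `cooc_matrix`).
#' @return A rooted binary tree of class `c("celltype_tree", "phylo")`;
#'   node supports unset (see [node_support()]).
#' @export
build_tree <- function(cooc) {
  if (inherits(cooc, "cooc_matrix")) {
    d <- 1 - unclass(cooc) / attr(cooc, "n_iter")
  } else {
    stopifnot(is.matrix(cooc), isSymmetric(unname(cooc)))
    d <- unclass(cooc)
  }
  tips <- colnames(d)
  k <- length(tips)
  if (k < 2) stop("need at least 2 cell types", call. = FALSE)
  # active clusters: index -> tip set / size / merge code (-i tip, +j step)
  sets <- lapply(tips, identity)
  sizes <- rep(1, k)
  codes <- -seq_len(k)
  dm <- d; diag(dm) <- Inf
  merge <- matrix(0L, k - 1, 2)
  height <- numeric(k - 1)
  active <- rep(TRUE, k)
  key <- function(s) paste(s, collapse = "\r")
  for (step in seq_len(k - 1)) {
    best_d <- Inf; best <- c(NA_integer_, NA_integer_); best_key <- NULL
    for (i in which(active)) {
      for (j in which(active)) {
        if (j <= i) next
        dij <- dm[i, j]
        if (dij < best_d - 1e-12) {
          best_d <- dij; best <- c(i, j)
          best_key <- key(sort(c(sets[[i]], sets[[j]])))
        } else if (dij <= best_d + 1e-12) {
          cand <- key(sort(c(sets[[i]], sets[[j]])))
          if (cand < best_key) {
            best_d <- min(best_d, dij); best <- c(i, j); best_key <- cand
          }
        }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- c(codes[i], codes[j])
    height[step] <- best_d
    # Lance-Williams average-linkage update into slot i
    for (m in which(active)) {
      if (m == i || m == j) next
      dm[i, m] <- dm[m, i] <- (sizes[i] * dm[i, m] + sizes[j] * dm[j, m]) /
        (sizes[i] + sizes[j])
    }
    sets[[i]] <- sort(c(sets[[i]], sets[[j]]))
    sizes[i] <- sizes[i] + sizes[j]
    codes[i] <- step
    active[j] <- FALSE
  }
  leaf_order <- integer(0)
  walk <- function(code) {
    if (code < 0) leaf_order <<- c(leaf_order, -code)
    else { walk(merge[code, 1]); walk(merge[code, 2]) }
  }
  walk(k - 1)
  hc <- structure(list(merge = merge, height = height, order = leaf_order,
                       labels = tips, method = "average"),
                  class = "hclust")
  phy <- ape::as.phylo(hc)
  class(phy) <- c("celltype_tree", "phylo")
  phy
}

# rooted clades of a phylo as a list of sorted tip-label character vectors,
# one per internal node (named by node number); postorder accumulation so it
# is robust to any internal node numbering
tree_clades <- function(phy) {
  n_tip <- length(phy$tip.label)
  nn <- n_tip + phy$Nnode
  acc <- vector("list", nn)
  for (i in seq_len(n_tip)) acc[[i]] <- phy$tip.label[i]
  po <- ape::reorder.phylo(phy, "postorder")$edge
  for (r in seq_len(nrow(po))) {
    acc[[po[r, 1]]] <- c(acc[[po[r, 1]]], acc[[po[r, 2]]])
  }
  nodes <- (n_tip + 1L):nn
  out <- lapply(acc[nodes], sort)
  names(out) <- nodes
  out
}

#' Jackknife node support for a cell-type tree
#'
#' Re-clusters the cell types `n_iter` times on jackknife-downsampled gene
#' sets (single-pass average linkage, same distance as [cooccurrence()])
#' and reports, per internal node of `tree`, the percentage of replicate
#' trees containing a clade with exactly the same tip set. Root and tips
#' are 100 by convention.
#'
#' @param tree a [build_tree()] result (tips must match `colnames(fp)`).
#' @param fp,genes,downsample,seed,log_transform as in [cooccurrence()].
#' @param n_iter number of jackknife replicates (default 1000).
#' @return The tree with `node.label` set to support percentages (numeric,
#'   0--100).
#' @export
node_support <- function(tree, fp, genes, n_iter = 1000, downsample = 0.75,
                         seed = 1L, log_transform = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (!setequal(tree$tip.label, colnames(fp))) {
    stop("tree tips must match footprint columns", call. = FALSE)
  }
  if (!all(genes %in% rownames(fp))) {
    stop("`genes` must be a subset of footprint genes", call. = FALSE)
  }
  clades <- tree_clades(tree)
  keys <- vapply(clades, paste, character(1), collapse = "\r")
  hits <- stats::setNames(integer(length(keys)), keys)
  n_keep <- max(1L, floor(downsample * length(genes)))
  for (i in seq_len(n_iter)) {
    gi <- withr::with_seed(seed + i, sample(genes, n_keep))
    d <- celltype_distance(unclass(fp)[gi, , drop = FALSE], log_transform)
    rep_phy <- hclust_phylo(d)
    rep_keys <- vapply(tree_clades(rep_phy), paste, character(1),
                       collapse = "\r")
    found <- keys %in% rep_keys
    hits[found] <- hits[found] + 1L
  }
  supp <- 100 * hits / n_iter
  # root clade (all tips) always present
  n_tip <- length(tree$tip.label)
  root_key <- paste(sort(tree$tip.label), collapse = "\r")
  supp[keys == root_key] <- 100
  tree$node.label <- unname(supp)
  class(tree) <- c("celltype_tree", "phylo")
  tree
}

#' Collapse weakly supported nodes to polytomies
#'
#' Deletes every internal node (root excepted) whose jackknife support is
#' strictly below `min_support`, attaching its children to its parent. Tip
#' set, surviving clades, their heights and supports are unchanged.
#'
#' @param tree a [node_support()]-annotated tree.
#' @param min_support support percentage below which a node is collapsed
#'   (default 10).
#' @return A `celltype_tree`, possibly multifurcating.
#' @export
collapse_low_support <- function(tree, min_support = 10) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$node.label)) stop("supports unset; run node_support()", call. = FALSE)
  supp <- as.numeric(tree$node.label)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  node_ids <- (n_tip + 1L):(n_tip + tree$Nnode)
  # clade heights from the original tree (for edge-length restoration)
  heights <- ape::node.depth.edgelength(tree)
  heights <- max(heights) - heights # 0 at tips of an ultrametric dendrogram
  clades <- tree_clades(tree)
  keys <- vapply(clades, paste, character(1), collapse = "\r")
  info <- stats::setNames(
    lapply(seq_along(node_ids), function(j) {
      list(support = supp[j], height = heights[node_ids[j]])
    }), keys)
  drop_nodes <- node_ids[supp < min_support & node_ids != root]
  work <- tree
  work$edge.length <- rep(1, nrow(work$edge))
  work$edge.length[work$edge[, 2] %in% drop_nodes] <- 0
  out <- ape::di2multi(work, tol = 0.5)
  # restore heights and supports for surviving clades
  out_clades <- tree_clades(out)
  out_keys <- vapply(out_clades, paste, character(1), collapse = "\r")
  out_nodes <- as.integer(names(out_clades))
  n_tip_out <- length(out$tip.label)
  h_out <- numeric(n_tip_out + out$Nnode)
  for (j in seq_along(out_nodes)) {
    h_out[out_nodes[j]] <- info[[out_keys[j]]]$height
  }
  out$edge.length <- h_out[out$edge[, 1]] - h_out[out$edge[, 2]]
  out$node.label <- vapply(out_keys, function(k) info[[k]]$support, numeric(1),
                           USE.NAMES = FALSE)
  class(out) <- c("celltype_tree", "phylo")
  out
}

#' @export
print.celltype_tree <- function(x, ...) {
  cat(sprintf("<celltype_tree> %d tips, %d internal nodes%s\n",
              length(x$tip.label), x$Nnode,
              if (!is.null(x$node.label)) " (supports set)" else ""))
  invisible(x)
}

#' @method tidy celltype_tree
#' @export
tidy.celltype_tree <- function(x, ...) {
  clades <- tree_clades(x)
  tibble::tibble(
    node = as.integer(names(clades)),
    n_tips = lengths(clades),
    tips = unname(lapply(clades, identity)),
    support = if (!is.null(x$node.label)) as.numeric(x$node.label) else NA_real_
  )
}

#' @method glance celltype_tree
#' @export
glance.celltype_tree <- function(x, ...) {
  tibble::tibble(
    n_tips = length(x$tip.label), n_nodes = x$Nnode,
    min_support = if (!is.null(x$node.label))
      min(as.numeric(x$node.label)) else NA_real_,
    resolved = ape::is.binary(x)
  )
}

#' Node-supporting gene selection with leakiness
#'
#' Finds genes characteristically shared by the cell types under a tree
#' node: expressed (FC > `fg_thr`) in (nearly) all foreground tips and not
#' expressed (FC < `bg_thr`) in (nearly) all background tips. `leak_fg` and
#' `leak_bg` give the tolerated fraction of violating tips on each side.
#'
#' Modes: `"node"` compares the node's descendant tips against all other
#' tips; `"vs_sister"` restricts the background to the sister clade's tips;
#' `"features_out"` swaps foreground and background relative to `"node"`
#' (genes differentially expressed in all the *other* tips).
#'
#' @param tree a `celltype_tree`.
#' @param fp cell-type footprint whose columns cover the tree tips.
#' @param node internal node id (ape numbering; see `tidy()` on the tree).
#' @param fg_thr foreground FC threshold, strict `>` (default 1.7).
#' @param bg_thr background FC threshold; a background tip with FC `>=
#'   bg_thr` counts as a violation (default 1.8).
#' @param leak_fg,leak_bg tolerated violating fractions in \[0, 1\]
#'   (default 0).
#' @param mode `"node"`, `"vs_sister"` or `"features_out"`.
#' @return Tibble with columns `gene`, `min_fg_fc`, `max_bg_fc`.
#' @export
node_supporting_genes <- function(tree, fp, node, fg_thr = 1.7, bg_thr = 1.8,
                                  leak_fg = 0, leak_bg = 0,
                                  mode = c("node", "vs_sister", "features_out")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"), fg_thr > 0, bg_thr > 0,
            leak_fg >= 0, leak_fg <= 1, leak_bg >= 0, leak_bg <= 1)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  if (!(node %in% seq_len(n_tip + tree$Nnode))) stop("unknown node", call. = FALSE)
  tips_under <- function(nd) {
    if (nd <= n_tip) return(tree$tip.label[nd])
    ape::extract.clade(tree, nd)$tip.label
  }
  fg_tips <- tips_under(node)
  if (mode == "vs_sister") {
    if (node == root) stop("root has no sister", call. = FALSE)
    parent <- tree$edge[tree$edge[, 2] == node, 1]
    sibs <- tree$edge[tree$edge[, 1] == parent, 2]
    sibs <- setdiff(sibs, node)
    bg_tips <- unlist(lapply(sibs, tips_under))
  } else {
    bg_tips <- setdiff(tree$tip.label, fg_tips)
  }
  if (mode == "features_out") {
    tmp <- fg_tips; fg_tips <- bg_tips; bg_tips <- tmp
  }
  if (!length(bg_tips)) stop("background is empty for this node/mode", call. = FALSE)
  m <- unclass(fp)[, c(fg_tips, bg_tips), drop = FALSE]
  fg <- m[, fg_tips, drop = FALSE]
  bg <- m[, bg_tips, drop = FALSE]
  n_fg_ok <- rowSums(fg > fg_thr)
  n_bg_bad <- rowSums(bg >= bg_thr)
  sel <- n_fg_ok >= (1 - leak_fg) * length(fg_tips) &
    n_bg_bad <= leak_bg * length(bg_tips)
  tibble::tibble(gene = rownames(m)[sel],
                 min_fg_fc = apply(fg[sel, , drop = FALSE], 1L, min),
                 max_bg_fc = apply(bg[sel, , drop = FALSE], 1L, max)) |>
    dplyr::arrange(dplyr::desc(.data$min_fg_fc), .data$gene)
}
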