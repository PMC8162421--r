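# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by the most naive route available (pair-merge loops,
# exhaustive enumeration) and never call the implementation they check.

# naive average-linkage agglomeration: returns list of merge steps, each a
# sorted character vector of the merged cluster's members, from a distance
# matrix with dimnames
naive_average_linkage <- function(dm) {
  clusters <- lapply(rownames(dm), identity)
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        d_ij <- mean(dm[clusters[[i]], clusters[[j]]])
        # tie-break: prefer lexicographically smallest merged member set
        if (d_ij < best_d - 1e-12) {
          best <- c(j, i); best_d <- d_ij
        } else if (abs(d_ij - best_d) <= 1e-12) {
          cand <- sort(c(clusters[[i]], clusters[[j]]))
          cur <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
          if (paste(cand, collapse = "|") < paste(cur, collapse = "|")) {
            best <- c(j, i)
          }
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- merged
    clusters[[best[2]]] <- NULL
    clusters[[best[1]]] <- merged
  }
  merges
}

# clades of a celltype_tree as sorted "a|b|c" strings (internal nodes)
clade_strings <- function(tree) {
  n_tip <- length(tree$tip.label)
  out <- character(0)
  for (node in (n_tip + 1):(n_tip + tree$Nnode)) {
    tips <- sort(ape::extract.clade(tree, node)$tip.label)
    out <- c(out, paste(tips, collapse = "|"))
  }
  sort(out)
}

# exhaustive Dollo oracle: most recent node whose clade contains the focal
# species and every present species (enumerates all nodes)
dollo_oracle <- function(present_species, tree, focal) {
  n_tip <- length(tree$tip.label)
  need <- union(focal, present_species)
  best_rank <- -Inf; best <- NA
  strata <- polypatlas::phylostrata(tree, focal)
  for (i in seq_len(nrow(strata))) {
    node <- strata$node[i]
    clade <- if (node <= n_tip) tree$tip.label[node]
    else ape::extract.clade(tree, node)$tip.label
    if (all(need %in% clade) && strata$age_rank[i] > best_rank) {
      best_rank <- strata$age_rank[i]
      best <- strata$stratum[i]
    }
  }
  best
}

# direct enumeration of the two-sided Fisher p (small-p-values method)
fisher_enum_p2 <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# brute-force node-supporting genes at leak = 0: set intersection/complement
node_genes_brute <- function(fp, fg_tips, bg_tips, fg_thr, bg_thr) {
  m <- unclass(fp)
  sel <- vapply(rownames(m), function(g) {
    all(m[g, fg_tips] > fg_thr) && all(m[g, bg_tips] < bg_thr)
  }, logical(1))
  sort(rownames(m)[sel])
}

# tiny deterministic umi_matrix from a dense matrix literal
umi_fix <- function(m, stage = NULL, organism = NULL) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  cells <- tibble::tibble(cell = colnames(m))
  if (!is.null(stage)) cells$stage <- stage
  genes <- tibble::tibble(gene = rownames(m))
  if (!is.null(organism)) genes$organism <- organism
  umi_matrix(m, cells = cells, genes = genes)
}

# assignment mapping each cell to its own metacell group label
asg_fix <- function(cells, metacell, cell_type = NULL) {
  mc <- tibble::tibble(cell = cells, metacell = metacell)
  mtab <- tibble::tibble(metacell = unique(metacell),
                         cell_type = if (is.null(cell_type))
                           unique(metacell) else cell_type)
  metacell_map(mc, mtab)
}

# species tree used throughout the ages tests: 8 tips, named strata on the
# root-to-focal path (focal = "sp1")
make_species_tree <- function() {
  txt <- "(((((sp1,sp2)N5,sp3)N4,(sp4,sp5)X1)N3,(sp6,sp7)X2)N2,sp8)N1;"
  ape::read.tree(text = txt)
}
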