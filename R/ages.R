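#' Phylostrata on the root-to-focal path of a species tree
#'
#' @param tree rooted `ape::phylo` species tree with unique labels on the
#'   nodes of the root-to-focal path (e.g. Metazoa, Cnidaria, ...).
#' @param focal focal species tip label.
#' @return Tibble with columns `stratum` (node/tip label), `node` (ape node
#'   id) and `age_rank` (1 = root/oldest, increasing toward the focal tip).
#' @export
phylostrata <- function(tree, focal) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("species tree must be rooted", call. = FALSE)
  if (!(focal %in% tree$tip.label)) stop("focal species not a tip", call. = FALSE)
  n_tip <- length(tree$tip.label)
  focal_id <- match(focal, tree$tip.label)
  path <- focal_id
  repeat {
    parent <- tree$edge[tree$edge[, 2] == path[1], 1]
    if (!length(parent)) break
    path <- c(parent, path)
  }
  labs <- c(tree$node.label %||% paste0("node", seq_len(tree$Nnode)))
  node_label <- function(id) {
    if (id <= n_tip) tree$tip.label[id] else labs[id - n_tip]
  }
  strata <- vapply(path, node_label, character(1))
  if (anyDuplicated(strata)) {
    stop("node names on the root-to-focal path must be unique", call. = FALSE)
  }
  tibble::tibble(stratum = strata, node = path,
                 age_rank = seq_along(path))
}

#' Gene ages by strict Dollo parsimony
#'
#' Assigns each focal-species gene the phylostratum of its orthogroup's
#' single-gain origin under Dollo parsimony: the most recent common
#' ancestor of the focal species and every species sharing the orthogroup
#' (one gain, unlimited losses). Genes with no orthogroup, or whose
#' orthogroup is present only in the focal species, receive the youngest
#' (focal-species) stratum.
#'
#' @param presence logical/0-1 orthogroup x species incidence matrix; row
#'   names are orthogroup ids, column names species (all must be tree
#'   tips).
#' @param tree rooted species tree (see [phylostrata()]).
#' @param focal focal species tip label.
#' @param gene_map tibble with columns `gene`, `orthogroup` (`NA` orthogroup
#'   = focal-specific gene). When `NULL`, one gene per orthogroup is
#'   assumed (`gene` = orthogroup id).
#' @return Tibble with columns `gene`, `orthogroup`, `stratum`, `age_rank`
#'   (1 = oldest); `stratum` is an ordered factor from root to focal.
#' @export
dollo_age <- function(presence, tree, focal, gene_map = NULL) {
  presence <- as.matrix(presence)
  strata <- phylostrata(tree, focal)
  unknown <- setdiff(colnames(presence), tree$tip.label)
  if (length(unknown)) {
    stop("presence names species absent from the tree: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(rownames(presence))) {
    stop("presence must have orthogroup rownames", call. = FALSE)
  }
  if (any(rowSums(presence > 0) == 0)) {
    stop("every orthogroup must be present in at least one species", call. = FALSE)
  }
  if (is.null(gene_map)) {
    gene_map <- tibble::tibble(gene = rownames(presence),
                               orthogroup = rownames(presence))
  }
  gene_map <- tibble::as_tibble(gene_map)
  focal_id <- match(focal, tree$tip.label)
  # orthogroup -> origin node (MRCA of focal + present species)
  og_rank <- vapply(rownames(presence), function(og) {
    sp <- colnames(presence)[presence[og, ] > 0]
    ids <- unique(c(focal_id, match(sp, tree$tip.label)))
    if (length(ids) == 1L) {
      return(strata$age_rank[strata$node == focal_id])
    }
    mrca <- ape::getMRCA(tree, ids)
    strata$age_rank[strata$node == mrca]
  }, numeric(1))
  youngest <- max(strata$age_rank)
  rank_of <- ifelse(is.na(gene_map$orthogroup), youngest,
                    og_rank[gene_map$orthogroup])
  rank_of[is.na(rank_of)] <- youngest # orthogroup absent from presence table
  n_unassigned <- sum(is.na(gene_map$orthogroup))
  if (n_unassigned > 0) {
    message(sprintf("dollo_age: %d genes without orthogroup assigned the youngest stratum",
                    n_unassigned))
  }
  tibble::tibble(
    gene = gene_map$gene,
    orthogroup = gene_map$orthogroup,
    stratum = factor(strata$stratum[rank_of], levels = strata$stratum,
                     ordered = TRUE),
    age_rank = rank_of
  )
}

#' Gene-age enrichment and depletion in gene sets
#'
#' For each (gene set, phylostratum) cell, tests the 2x2 table
#' \[set & stratum, set & !stratum; bg-not-set & stratum, rest\] with a
#' two-sided Fisher exact test. Odds ratios are sample ORs with a Haldane
#' (+0.5) correction when any cell is zero; p-values are BH-adjusted
#' across all (set, stratum) cells.
#'
#' @param ages a [dollo_age()] table covering the background.
#' @param gene_sets named list of character vectors (subsets of
#'   `background`).
#' @param background character vector of genes forming the test universe
#'   (e.g. all variable genes).
#' @return Tibble with columns `set`, `stratum`, `n_set`, `n_stratum`,
#'   `overlap`, `odds_ratio`, `p`, `p_adj`.
#' @export
age_enrichment <- function(ages, gene_sets, background) {
  stopifnot(is.list(gene_sets), length(background) > 0)
  if (!all(unlist(gene_sets) %in% background)) {
    stop("gene sets must be subsets of the background", call. = FALSE)
  }
  ages_bg <- ages[ages$gene %in% background, , drop = FALSE]
  strata <- levels(ages_bg$stratum)
  stratum_of <- stats::setNames(as.character(ages_bg$stratum), ages_bg$gene)
  res <- purrr::imap_dfr(gene_sets, function(set, nm) {
    purrr::map_dfr(strata, function(st) {
      in_st <- names(stratum_of)[stratum_of == st]
      a <- length(intersect(set, in_st))
      b <- length(set) - a
      c_ <- length(setdiff(in_st, set))
      d <- length(setdiff(background, union(set, in_st)))
      p <- fisher_p2(a, b, c_, d)
      or <- if (min(a, b, c_, d) == 0) {
        ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
      } else {
        (a * d) / (b * c_)
      }
      tibble::tibble(set = nm, stratum = st, n_set = length(set),
                     n_stratum = length(in_st), overlap = a,
                     odds_ratio = or, p = p)
    })
  })
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res$stratum <- factor(res$stratum, levels = strata, ordered = TRUE)
  res
}

#' Remove genes with within-species paralogs
#'
#' Paralog-control filter: drops focal genes whose orthogroup contains more
#' than one focal gene (inparalogs).
#'
#' @param gene_map tibble with columns `gene`, `orthogroup`.
#' @return Filtered tibble.
#' @export
drop_inparalogs <- function(gene_map) {
  gene_map <- tibble::as_tibble(gene_map)
  gene_map |>
    dplyr::group_by(.data$orthogroup) |>
    dplyr::filter(is.na(.data$orthogroup[1]) | dplyr::n() == 1L) |>
    dplyr::ungroup()
}
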