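#' Configuration for the synthetic atlas generator
#'
#' Defines planted study conditions for a multi-stage, whole-organism UMI
#' atlas: cell types organized in a planted two-level hierarchy (blocks of
#' related types under a root), each type defined by a program of marker
#' genes expressed `program_fc`-fold over a uniform baseline, cells drawn
#' multinomially from their type's program with log-normal library sizes.
#'
#' @param n_stages number of life stages (default 1).
#' @param celltypes_per_stage integer vector (recycled to `n_stages`) of
#'   planted types per stage; with `shared_type_map` unset, every planted
#'   type occurs in every stage and `celltypes_per_stage[1]` is the total
#'   number of types.
#' @param shared_type_map optional named list mapping planted type name
#'   (`"t1"`, `"t2"`, ...) to the integer stages it occurs in; types left
#'   out occur in every stage.
#' @param n_blocks number of blocks in the planted hierarchy (types are
#'   assigned to blocks round-robin); blocks share `block_markers_per_block`
#'   extra markers so the hierarchy is recoverable. Default 1 (flat).
#' @param n_genes total genes (default 500).
#' @param n_cells_per_type cells per (stage, type) (default 60).
#' @param program_fc expression multiplier of a type's markers over the
#'   uniform baseline; must be > 1 except for the no-signal control value 1
#'   (default 10).
#' @param markers_per_type private markers per type (default 10).
#' @param block_markers_per_block markers shared by all types of a block
#'   (default 5; ignored with `n_blocks = 1`).
#' @param libsize_log_mean,libsize_log_sd natural-log mean and sd of the
#'   log-normal library size (defaults `log(1000)` and 0.4, giving a median
#'   of 1,000 UMIs -- typical MARS-seq depth).
#' @param metacells_per_type metacells each (stage, type) is split into
#'   (default 2, the minimum).
#' @param seed integer seed; identical config + seed reproduces identical
#'   output bit for bit.
#' @return A list of class `atlas_sim_config`.
#' @export
atlas_sim_config <- function(n_stages = 1, celltypes_per_stage = 6,
                             shared_type_map = NULL, n_blocks = 1,
                             n_genes = 500, n_cells_per_type = 60,
                             program_fc = 10, markers_per_type = 10,
                             block_markers_per_block = 5,
                             libsize_log_mean = log(1000),
                             libsize_log_sd = 0.4,
                             metacells_per_type = 2, seed = 1L) {
  stopifnot(n_stages >= 1, all(celltypes_per_stage >= 1), n_genes >= 1,
            n_cells_per_type >= 1, markers_per_type >= 1, n_blocks >= 1,
            metacells_per_type >= 2, libsize_log_sd >= 0)
  if (program_fc < 1) stop("program_fc must be >= 1", call. = FALSE)
  n_types <- max(celltypes_per_stage)
  need <- n_types * markers_per_type +
    (if (n_blocks > 1) n_blocks * block_markers_per_block else 0)
  if (n_genes < need) {
    stop(sprintf("n_genes (%d) < genes needed for marker programs (%d)",
                 n_genes, need), call. = FALSE)
  }
  structure(list(
    n_stages = n_stages, celltypes_per_stage = celltypes_per_stage,
    shared_type_map = shared_type_map, n_blocks = n_blocks,
    n_genes = n_genes, n_cells_per_type = n_cells_per_type,
    program_fc = program_fc, markers_per_type = markers_per_type,
    block_markers_per_block = block_markers_per_block,
    libsize_log_mean = libsize_log_mean, libsize_log_sd = libsize_log_sd,
    metacells_per_type = metacells_per_type, seed = as.integer(seed)
  ), class = "atlas_sim_config")
}

# planted marker table + per-type expression programs (probability vectors)
plant_programs <- function(config) {
  n_types <- max(config$celltypes_per_stage)
  types <- paste0("t", seq_len(n_types))
  blocks <- paste0("b", rep_len(seq_len(config$n_blocks), n_types))
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  idx <- 0L
  marker_rows <- list()
  type_markers <- stats::setNames(vector("list", n_types), types)
  for (ti in seq_len(n_types)) {
    mk <- genes[idx + seq_len(config$markers_per_type)]
    idx <- idx + config$markers_per_type
    type_markers[[ti]] <- mk
    marker_rows[[length(marker_rows) + 1]] <-
      tibble::tibble(gene = mk, unit = types[ti], level = "type")
  }
  block_markers <- stats::setNames(
    vector("list", config$n_blocks), paste0("b", seq_len(config$n_blocks)))
  if (config$n_blocks > 1) {
    for (bi in seq_len(config$n_blocks)) {
      mk <- genes[idx + seq_len(config$block_markers_per_block)]
      idx <- idx + config$block_markers_per_block
      block_markers[[bi]] <- mk
      marker_rows[[length(marker_rows) + 1]] <-
        tibble::tibble(gene = mk, unit = names(block_markers)[bi],
                       level = "block")
    }
  }
  programs <- sapply(seq_len(n_types), function(ti) {
    rate <- rep(1, config$n_genes)
    names(rate) <- genes
    mk <- c(type_markers[[ti]], block_markers[[blocks[ti]]])
    rate[mk] <- config$program_fc
    rate / sum(rate)
  })
  colnames(programs) <- types
  rownames(programs) <- genes
  list(types = types, blocks = stats::setNames(blocks, types), genes = genes,
       programs = programs, markers = dplyr::bind_rows(marker_rows))
}

# planted hierarchy as an ape::phylo over the types (root -> blocks -> types)
plant_hierarchy <- function(types, blocks) {
  if (length(unique(blocks)) == 1L || length(types) <= 2L) {
    txt <- paste0("(", paste(types, collapse = ","), ");")
  } else {
    grp <- split(types, blocks)
    clades <- vapply(grp, function(ts) {
      if (length(ts) == 1L) ts else paste0("(", paste(ts, collapse = ","), ")")
    }, character(1))
    txt <- paste0("(", paste(clades, collapse = ","), ");")
  }
  ape::read.tree(text = txt)
}

#' Simulate a whole-organism UMI atlas with planted structure
#'
#' Each cell draws its counts multinomially from its planted type's
#' expression program (uniform baseline, markers multiplied by
#' `program_fc`, renormalized), with library size drawn log-normal. The
#' metacell assignment partitions each (stage, type)'s cells into at least
#' two metacells; cell-type and broad-type labels follow the planted
#' hierarchy.
#'
#' @param config an [atlas_sim_config()].
#' @return List with elements `umi` (a [umi_matrix()]; cell metadata
#'   carries `stage`), `assignment` (a [metacell_map()]) and `truth` (list:
#'   `cell_types` tibble, `hierarchy` ape::phylo over planted types,
#'   `markers` tibble, `programs` matrix, `config`).
#' @export
simulate_atlas <- function(config) {
  stopifnot(inherits(config, "atlas_sim_config"))
  pl <- plant_programs(config)
  n_types <- length(pl$types)
  stage_of_type <- lapply(pl$types, function(tp) {
    if (!is.null(config$shared_type_map) && tp %in% names(config$shared_type_map)) {
      config$shared_type_map[[tp]]
    } else {
      seq_len(config$n_stages)
    }
  })
  names(stage_of_type) <- pl$types
  withr::with_seed(config$seed, {
    cells <- list(); counts_cols <- list()
    for (si in seq_len(config$n_stages)) {
      types_here <- pl$types[vapply(stage_of_type, function(s) si %in% s,
                                    logical(1))]
      types_here <- utils::head(types_here, config$celltypes_per_stage[
        min(si, length(config$celltypes_per_stage))])
      for (tp in types_here) {
        n <- config$n_cells_per_type
        lib <- pmax(1, round(stats::rlnorm(n, config$libsize_log_mean,
                                           config$libsize_log_sd)))
        cnt <- sapply(lib, function(L) {
          stats::rmultinom(1, size = L, prob = pl$programs[, tp])[, 1]
        })
        ids <- sprintf("s%d_%s_c%03d", si, tp, seq_len(n))
        colnames(cnt) <- ids
        counts_cols[[length(counts_cols) + 1]] <- cnt
        cells[[length(cells) + 1]] <- tibble::tibble(
          cell = ids, stage = paste0("stage", si), type = tp)
      }
    }
    cells <- dplyr::bind_rows(cells)
    counts <- do.call(cbind, counts_cols)
    rownames(counts) <- pl$genes
  })
  # metacells: planted-type split within stage, round-robin
  cells <- cells |>
    dplyr::group_by(.data$stage, .data$type) |>
    dplyr::mutate(metacell = sprintf(
      "mc_%s_%s_%d", .data$stage, .data$type,
      (dplyr::row_number() - 1L) %% config$metacells_per_type + 1L)) |>
    dplyr::ungroup()
  mc_tab <- cells |>
    dplyr::distinct(.data$metacell, .data$type) |>
    dplyr::rename(cell_type = "type")
  ct_tab <- tibble::tibble(cell_type = pl$types,
                           broad_type = unname(pl$blocks))
  umi <- umi_matrix(counts,
                    cells = cells[c("cell", "stage")],
                    genes = tibble::tibble(gene = pl$genes))
  asg <- metacell_map(cells[c("cell", "metacell")], mc_tab, ct_tab)
  truth <- list(
    cell_types = cells[c("cell", "stage", "type", "metacell")],
    hierarchy = plant_hierarchy(pl$types, pl$blocks),
    markers = pl$markers,
    programs = pl$programs,
    config = config
  )
  list(umi = umi, assignment = asg, truth = truth)
}

#' Simulate orthology with planted gene ages on a species tree
#'
#' For each focal-species gene, samples an origin node uniformly on the
#' root-to-focal path of the species tree; the orthogroup is present in
#' every species of the origin clade minus independent losses (the focal
#' species never loses). Single-gain histories make strict Dollo parsimony
#' exact: the most recent common ancestor of the observed presence equals
#' the planted origin whenever at least one species of each side branch
#' survives loss; with `loss_prob = 0` it always does.
#'
#' A pairwise ortholog table against `partner` species is also produced:
#' one-to-one by default, with a fraction `one_to_many_fraction` of genes
#' given 2--4 partner copies.
#'
#' @param config an [atlas_sim_config()] (supplies `n_genes` and `seed`).
#' @param species_tree rooted `ape::phylo` with named internal nodes on the
#'   root-to-focal path.
#' @param focal focal species tip label.
#' @param partner partner species tip label for the pair table (default:
#'   first non-focal tip).
#' @param loss_prob per-species independent loss probability (default 0.1).
#' @param one_to_many_fraction fraction of paired genes with 2--4 partner
#'   copies (default 0.2).
#' @return List of class `orthology_set`: `pairs` (tibble `gene_a`,
#'   `gene_b`, `orthogroup`), `members` (long tibble `orthogroup`,
#'   `species`, `gene`), `presence` (orthogroup x species 0/1 matrix),
#'   `gene_map` (focal `gene` -> `orthogroup`), `species_tree`, `focal`,
#'   and `truth` (tibble `gene`, `orthogroup`, `origin_stratum`,
#'   `origin_rank`, `n_copies`).
#' @export
simulate_orthology <- function(config, species_tree, focal,
                               partner = NULL, loss_prob = 0.1,
                               one_to_many_fraction = 0.2) {
  stopifnot(inherits(config, "atlas_sim_config"))
  if (!ape::is.rooted(species_tree)) stop("species tree must be rooted", call. = FALSE)
  strata <- phylostrata(species_tree, focal)
  tips <- species_tree$tip.label
  if (is.null(partner)) partner <- setdiff(tips, focal)[1]
  n_tip <- length(tips)
  clade_tips <- function(node) {
    if (node <= n_tip) return(tips[node])
    ape::extract.clade(species_tree, node)$tip.label
  }
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  withr::with_seed(config$seed + 10000L, {
    origin_idx <- sample(nrow(strata), length(genes), replace = TRUE)
    ogs <- sprintf("OG%04d", seq_along(genes))
    presence <- matrix(0L, length(ogs), n_tip, dimnames = list(ogs, tips))
    for (i in seq_along(genes)) {
      clade <- clade_tips(strata$node[origin_idx[i]])
      lost <- clade[clade != focal][
        stats::runif(sum(clade != focal)) < loss_prob]
      presence[i, setdiff(clade, lost)] <- 1L
    }
    # pair table against partner (only for orthogroups containing partner)
    has_partner <- presence[, partner] == 1L
    n_copies <- integer(length(genes))
    pair_rows <- list()
    for (i in seq_along(genes)) {
      if (!has_partner[i]) next
      k <- if (stats::runif(1) < one_to_many_fraction) sample(2:4, 1) else 1L
      n_copies[i] <- k
      pair_rows[[length(pair_rows) + 1]] <- tibble::tibble(
        gene_a = genes[i],
        gene_b = if (k == 1L) paste0("p_", genes[i]) else
          paste0("p_", genes[i], "_", seq_len(k)),
        orthogroup = ogs[i])
    }
  })
  pairs <- dplyr::bind_rows(pair_rows)
  members <- dplyr::bind_rows(
    tibble::tibble(orthogroup = ogs, species = focal, gene = genes),
    pairs |>
      dplyr::transmute(.data$orthogroup, species = partner,
                       gene = .data$gene_b)
  )
  structure(list(
    pairs = pairs, members = members, presence = presence,
    gene_map = tibble::tibble(gene = genes, orthogroup = ogs),
    species_tree = species_tree, focal = focal, partner = partner,
    truth = tibble::tibble(gene = genes, orthogroup = ogs,
                           origin_stratum = strata$stratum[origin_idx],
                           origin_rank = strata$age_rank[origin_idx],
                           n_copies = n_copies)
  ), class = "orthology_set")
}

#' Simulate a dual host--symbiont UMI matrix
#'
#' Host counts are generated as in [simulate_atlas()]; each cell then
#' carries symbiont counts with its planted type's occupancy probability:
#' occupied cells receive a log-normal symbiont load distributed uniformly
#' (size-proportionally) across symbiont genes, so the symbiont fraction
#' shows no transcriptional heterogeneity by construction.
#'
#' @param config an [atlas_sim_config()].
#' @param occupancy_by_type named numeric vector in \[0, 1\], one entry per
#'   planted type (`"t1"`, ...); types left out default to 0.
#' @param load_log_mean natural-log mean of the symbiont load (default
#'   `log(400)`; well above the conventional 100-UMI occupancy threshold).
#' @param load_log_sd log sd of the load (default 0.5).
#' @param n_symb_genes number of symbiont genes (default 50).
#' @return List: `umi` (dual [umi_matrix()] with per-gene `organism`
#'   labels), `assignment`, `truth` (as in [simulate_atlas()], plus
#'   `occupied` logical per cell and `occupancy_by_type`).
#' @export
simulate_host_symbiont <- function(config, occupancy_by_type,
                                   load_log_mean = log(400),
                                   load_log_sd = 0.5, n_symb_genes = 50) {
  stopifnot(all(occupancy_by_type >= 0), all(occupancy_by_type <= 1))
  atlas <- simulate_atlas(config)
  host <- atlas$umi
  type_of <- stats::setNames(atlas$truth$cell_types$type,
                             atlas$truth$cell_types$cell)
  occ_p <- vapply(type_of, function(tp) {
    if (tp %in% names(occupancy_by_type)) occupancy_by_type[[tp]] else 0
  }, numeric(1))
  symb_genes <- sprintf("symb_g%03d", seq_len(n_symb_genes))
  withr::with_seed(config$seed + 20000L, {
    occupied <- stats::runif(length(occ_p)) < occ_p
    loads <- ifelse(occupied,
                    pmax(1, round(stats::rlnorm(length(occ_p), load_log_mean,
                                                load_log_sd))), 0)
    symb_counts <- sapply(loads, function(L) {
      if (L == 0) integer(n_symb_genes)
      else stats::rmultinom(1, L, rep(1 / n_symb_genes, n_symb_genes))[, 1]
    })
  })
  rownames(symb_counts) <- symb_genes
  colnames(symb_counts) <- colnames(host$counts)
  counts <- rbind(as.matrix(host$counts), symb_counts)
  genes <- tibble::tibble(
    gene = rownames(counts),
    organism = c(rep("host", nrow(host$counts)),
                 rep("symbiont", n_symb_genes)))
  umi <- umi_matrix(counts, cells = host$cells, genes = genes)
  truth <- atlas$truth
  truth$occupied <- stats::setNames(occupied, colnames(host$counts))
  truth$occupancy_by_type <- occupancy_by_type
  list(umi = umi, assignment = atlas$assignment, truth = truth)
}

#' Simulate a toy genome exercising every 3'-extension rule branch
#'
#' Builds stranded gene models on two toy scaffolds, each gene with a
#' downstream signal peak at a known gap, covering: plus- and minus-strand
#' genes with in-range peaks, a peak beyond the 2 kb limit, a peak
#' overlapping the downstream gene (blocked), orphan peaks straddling the
#' 100 bp length filter, and an orphan chain fused transitively within the
#' 4.5 kb fusion gap. Truth records the correct post-extension 3' ends.
#'
#' @param n_extra_genes additional plain plus-strand genes with in-range
#'   peaks (default 2).
#' @param peak_offset gap in bp between each truncated annotated gene end
#'   and its downstream peak (default 200; must be >= 0; 0 makes the peaks
#'   abut their genes).
#' @param peak_len signal peak length in bp (default 150).
#' @return List: `genes`, `peaks` (interval tibbles), `truth` (tibble
#'   `gene`, `true_end3` = correct 3' coordinate after extension,
#'   `extendable`), `orphan_truth` (tibble of surviving fused orphan
#'   intervals under the default 100 bp / 4.5 kb rules).
#' @export
simulate_toy_genome <- function(n_extra_genes = 2, peak_offset = 200,
                                peak_len = 150) {
  stopifnot(peak_offset >= 0, peak_len >= 1, n_extra_genes >= 0)
  g <- list(); p <- list(); tr <- list()
  add_gene <- function(gene, seqid, start, end, strand) {
    g[[length(g) + 1]] <<- tibble::tibble(
      seqid = seqid, start = start, end = end, strand = strand, gene = gene,
      source = "annotated")
  }
  add_peak <- function(peak, seqid, start, end, strand) {
    p[[length(p) + 1]] <<- tibble::tibble(
      seqid = seqid, start = start, end = end, strand = strand, peak = peak)
  }
  add_truth <- function(gene, true_end3, extendable) {
    tr[[length(tr) + 1]] <<- tibble::tibble(
      gene = gene, true_end3 = true_end3, extendable = extendable)
  }
  # plus-strand extendable gene(s), peak at gap `peak_offset`
  pos <- 1000
  for (i in seq_len(1 + n_extra_genes)) {
    id <- paste0("plusA", i)
    add_gene(id, "scafA", pos, pos + 999, "+")
    ps <- pos + 999 + peak_offset + 1
    add_peak(paste0("pk_", id), "scafA", ps, ps + peak_len - 1, "+")
    add_truth(id, ps + peak_len - 1, TRUE)
    pos <- ps + peak_len + 9000
  }
  # minus-strand extendable gene: 3' end is `start`, peak upstream-left
  ms <- pos + 2000
  add_gene("minusA1", "scafA", ms, ms + 999, "-")
  pe <- ms - peak_offset - 1
  add_peak("pk_minusA1", "scafA", pe - peak_len + 1, pe, "-")
  add_truth("minusA1", pe - peak_len + 1, TRUE)
  # gene whose peak lies beyond 2 kb (gap 2500): not extended
  far <- ms + 12000
  add_gene("plusFar", "scafA", far, far + 999, "+")
  add_peak("pk_far", "scafA", far + 999 + 2501, far + 999 + 2500 + peak_len,
           "+")
  add_truth("plusFar", far + 999, FALSE)
  # peak overlapping the downstream same-strand gene: blocked
  blk <- far + 20000
  add_gene("plusBlocked", "scafB", blk, blk + 999, "+")
  add_peak("pk_blocked", "scafB", blk + 1500, blk + 1500 + peak_len - 1, "+")
  add_gene("plusDownstream", "scafB", blk + 1550, blk + 3999, "+")
  dps <- blk + 3999 + peak_offset + 1
  add_peak("pk_downstream", "scafB", dps, dps + peak_len - 1, "+")
  add_truth("plusBlocked", blk + 999, FALSE)
  add_truth("plusDownstream", dps + peak_len - 1, TRUE)
  # orphan peaks: 90 bp (dropped) and 150 bp (kept), far from genes
  orb <- dps + 30000
  add_peak("orphan_short", "scafB", orb, orb + 89, "+")
  add_peak("orphan_long", "scafB", orb + 5000, orb + 5149, "+")
  # orphan chain a-b-c with gaps 4000 and 4000: fused transitively
  cha <- orb + 40000
  add_peak("chain_a", "scafB", cha, cha + 199, "+")
  add_peak("chain_b", "scafB", cha + 200 + 4000, cha + 200 + 4000 + 199, "+")
  add_peak("chain_c", "scafB", cha + 2 * (200 + 4000),
           cha + 2 * (200 + 4000) + 199, "+")
  genes <- dplyr::bind_rows(g)
  truth <- dplyr::bind_rows(tr)
  # surviving orphans under the default rules: the beyond-2kb peak (never
  # absorbed), the 150 bp orphan, and the transitively fused chain
  list(genes = genes, peaks = dplyr::bind_rows(p), truth = truth,
       orphan_truth = tibble::tibble(
         peaks = list("pk_far", "orphan_long",
                      c("chain_a", "chain_b", "chain_c")),
         start = c(far + 999 + 2501, orb + 5000, cha),
         end = c(far + 999 + 2500 + peak_len, orb + 5149,
                 cha + 2 * (200 + 4000) + 199)))
}

#' Simulate a matched pair of species atlases over planted orthologs
#'
#' Species A is a [simulate_atlas()] draw; species B re-uses A's planted
#' type programs mapped through the ortholog pair table (one-to-many
#' partners share their A counterpart's program rate), so each planted
#' type exists in both species and is the ground-truth cross-species
#' match.
#'
#' @param config an [atlas_sim_config()] (used for both species; species B
#'   uses `seed + 1` for its cell draws).
#' @param one_to_many_fraction fraction of A genes with multiple B copies
#'   (default 0.2).
#' @param copies candidate copy numbers for one-to-many genes (default
#'   `2:4`; use `2:3` to stay within a 3-copy expansion limit).
#' @return List: `atlas_a`, `atlas_b` (each as [simulate_atlas()]),
#'   `pairs` (tibble `gene_a`, `gene_b`, `orthogroup`), `matches` (tibble
#'   `type_a`, `type_b` of planted homologous types).
#' @export
simulate_species_pair <- function(config, one_to_many_fraction = 0.2,
                                  copies = 2:4) {
  stopifnot(inherits(config, "atlas_sim_config"), all(copies >= 2))
  atlas_a <- simulate_atlas(config)
  genes_a <- rownames(atlas_a$umi$counts)
  withr::with_seed(config$seed + 30000L, {
    k <- ifelse(stats::runif(length(genes_a)) < one_to_many_fraction,
                sample(copies, length(genes_a), replace = TRUE), 1L)
  })
  pairs <- tibble::tibble(
    gene_a = rep(genes_a, k),
    copy = unlist(lapply(k, seq_len)),
    orthogroup = rep(sprintf("OG%04d", seq_along(genes_a)), k)
  ) |>
    dplyr::mutate(gene_b = ifelse(rep(k, k) == 1L, paste0("q_", .data$gene_a),
                                  paste0("q_", .data$gene_a, "_", .data$copy))) |>
    dplyr::select("gene_a", "gene_b", "orthogroup")
  # species B programs: each B gene inherits its A ortholog's rate; B cells
  # drawn with an independent seed
  prog_a <- atlas_a$truth$programs
  rate_b <- prog_a[pairs$gene_a, , drop = FALSE]
  rownames(rate_b) <- pairs$gene_b
  prog_b <- sweep(rate_b, 2L, colSums(rate_b), "/")
  config_b <- config
  config_b$seed <- config$seed + 1L
  atlas_b <- simulate_from_programs(config_b, prog_b)
  list(atlas_a = atlas_a, atlas_b = atlas_b, pairs = pairs,
       matches = tibble::tibble(type_a = colnames(prog_a),
                                type_b = colnames(prog_b)))
}

# draw an atlas from explicit per-type programs (genes x types), one stage
simulate_from_programs <- function(config, programs) {
  types <- colnames(programs)
  genes <- rownames(programs)
  withr::with_seed(config$seed, {
    cols <- list(); cells <- list()
    for (tp in types) {
      n <- config$n_cells_per_type
      lib <- pmax(1, round(stats::rlnorm(n, config$libsize_log_mean,
                                         config$libsize_log_sd)))
      cnt <- sapply(lib, function(L) {
        stats::rmultinom(1, size = L, prob = programs[, tp])[, 1]
      })
      ids <- sprintf("s1_%s_c%03d", tp, seq_len(n))
      colnames(cnt) <- ids
      cols[[length(cols) + 1]] <- cnt
      cells[[length(cells) + 1]] <- tibble::tibble(
        cell = ids, stage = "stage1", type = tp)
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- genes
    cells <- dplyr::bind_rows(cells)
  })
  cells <- cells |>
    dplyr::group_by(.data$type) |>
    dplyr::mutate(metacell = sprintf(
      "mc_%s_%d", .data$type,
      (dplyr::row_number() - 1L) %% config$metacells_per_type + 1L)) |>
    dplyr::ungroup()
  mc_tab <- cells |> dplyr::distinct(.data$metacell, .data$type) |>
    dplyr::rename(cell_type = "type")
  umi <- umi_matrix(counts, cells = cells[c("cell", "stage")])
  asg <- metacell_map(cells[c("cell", "metacell")], mc_tab)
  list(umi = umi, assignment = asg,
       truth = list(cell_types = cells[c("cell", "type", "metacell")],
                    programs = programs, config = config))
}
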