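fp_from_matrix <- function(m) {
  polypatlas:::new_footprint(m, epsilon = 0.1, normalized = TRUE,
                             level = "celltype")
}

# planted two-block footprint: types a1..a3 share markers 1:10, b1..b3 share
# markers 11:20, plus per-type jitter
two_block_fp <- function(jitter = 0.05, seed = 1) {
  set.seed(seed)
  types <- c("a1", "a2", "a3", "b1", "b2", "b3")
  m <- matrix(1, 40, 6, dimnames = list(sprintf("g%02d", 1:40), types))
  m[1:10, 1:3] <- 8
  m[11:20, 4:6] <- 8
  m * exp(matrix(rnorm(length(m), 0, jitter), nrow(m)))
}

test_that("variable gene selection is strict and matches planted truth", {
  m <- matrix(1, 3, 4, dimnames = list(c("flat", "edge", "hot"),
                                       paste0("t", 1:4)))
  m["edge", 1] <- 1.8
  m["hot", 2] <- 1.81
  fp <- fp_from_matrix(m)
  expect_equal(variable_genes(fp, 1.8), "hot")  # 1.8 exactly is excluded
  expect_length(variable_genes(fp_from_matrix(matrix(
    1, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z")))), 1.8), 0)
  # planted markers recovered across seeds
  for (s in c(1, 2, 3)) {
    cfg <- atlas_sim_config(n_genes = 150, celltypes_per_stage = 3,
                            n_cells_per_type = 50, program_fc = 8,
                            markers_per_type = 6, seed = s)
    sim <- simulate_atlas(cfg)
    fp_s <- compute_footprint(sim$umi, sim$assignment, level = "celltype")
    vg <- variable_genes(fp_s, 1.8)
    expect_setequal(vg, sim$truth$markers$gene)
  }
})

test_that("co-occurrence counts respect symmetry, diagonal and degeneracy", {
  fp <- fp_from_matrix(two_block_fp())
  genes <- rownames(fp)
  co <- cooccurrence(fp, genes, n_iter = 50, downsample = 0.75, seed = 4,
                     cut_heights = data.frame(height = c(0.75, 0.95),
                                              n = c(25, 25)))
  expect_true(isSymmetric(unclass(co)))
  expect_true(all(diag(unclass(co)) == 50))
  expect_true(all(unclass(co) >= 0 & unclass(co) <= 50))
  # identical columns always co-occur
  m2 <- two_block_fp(jitter = 0)
  m2 <- cbind(m2, dup = m2[, "a1"])
  colnames(m2)[7] <- "a1_dup"
  co2 <- cooccurrence(fp_from_matrix(m2), rownames(m2), n_iter = 20,
                      downsample = 0.5, seed = 1,
                      cut_heights = data.frame(height = 0.75, n = 20))
  expect_equal(unname(unclass(co2)["a1", "a1_dup"]), 20)
  # no gene randomness: counts are all-or-nothing
  co3 <- cooccurrence(fp, genes, n_iter = 10, downsample = 1, seed = 9,
                      cut_heights = data.frame(height = 0.75, n = 10))
  expect_true(all(unclass(co3) %in% c(0L, 10L)))
})

test_that("planted blocks dominate the co-occurrence matrix", {
  fp <- fp_from_matrix(two_block_fp())
  co <- cooccurrence(fp, rownames(fp), n_iter = 100, downsample = 0.75,
                     seed = 11)
  cm <- unclass(co)
  within <- c(cm["a1", "a2"], cm["a1", "a3"], cm["a2", "a3"],
              cm["b1", "b2"], cm["b1", "b3"], cm["b2", "b3"])
  between <- cm[c("a1", "a2", "a3"), c("b1", "b2", "b3")]
  expect_true(all(within >= 90))
  expect_true(all(between <= 10))
})

test_that("build_tree agrees with naive pair-merge average linkage", {
  set.seed(13)
  for (rep in 1:25) {
    k <- sample(6:8, 1)
    tips <- sort(replicate(k, paste(sample(letters, 4), collapse = "")))
    n_iter <- 100L
    cm <- matrix(sample(0:100, k * k, replace = TRUE), k,
                 dimnames = list(tips, tips))
    cm <- pmax(cm, t(cm)); diag(cm) <- n_iter
    co <- structure(cm, class = c("cooc_matrix", "matrix"), n_iter = n_iter,
                    params = list())
    tree <- build_tree(co)
    dm <- 1 - cm / n_iter
    expected <- sort(vapply(naive_average_linkage(dm), paste, character(1),
                            collapse = "|"))
    expect_equal(clade_strings(tree), expected)
  }
})

test_that("build_tree is deterministic under total ties", {
  k <- 5; tips <- paste0("t", 1:5)
  cm <- matrix(50L, k, k, dimnames = list(tips, tips)); diag(cm) <- 100L
  co <- structure(cm, class = c("cooc_matrix", "matrix"), n_iter = 100L,
                  params = list())
  t1 <- ape::write.tree(build_tree(co))
  t2 <- ape::write.tree(build_tree(co))
  expect_identical(t1, t2)
})

test_that("ultrametric distances are reproduced exactly", {
  # counts derived from an ultrametric tree: cooc = n_iter * (1 - d)
  set.seed(17)
  for (rep in 1:10) {
    k <- sample(5:8, 1)
    phy <- ape::rcoal(k, tip.label = paste0("s", 1:k))
    d <- cophenetic(phy); d <- d / max(d) * 0.8
    cm <- round(1000 * (1 - d)); diag(cm) <- 1000L
    storage.mode(cm) <- "integer"
    co <- structure(cm, class = c("cooc_matrix", "matrix"), n_iter = 1000L,
                    params = list())
    tree <- build_tree(co)
    expect_setequal(clade_strings(tree), clade_strings(phy))
  }
})

test_that("node support is exact in the no-randomness limit", {
  fp <- fp_from_matrix(two_block_fp())
  co <- cooccurrence(fp, rownames(fp), n_iter = 20, downsample = 1, seed = 2,
                     cut_heights = data.frame(height = 0.75, n = 20))
  tree <- build_tree(co)
  tree <- node_support(tree, fp, rownames(fp), n_iter = 20, downsample = 1,
                       seed = 3)
  expect_true(all(as.numeric(tree$node.label) %in% c(0, 100)))
  expect_true(all(as.numeric(tree$node.label) == 100))
})

test_that("strong planted blocks earn high jackknife support", {
  fp <- fp_from_matrix(two_block_fp())
  co <- cooccurrence(fp, rownames(fp), n_iter = 100, seed = 5)
  tree <- build_tree(co)
  tree <- node_support(tree, fp, rownames(fp), n_iter = 100, seed = 6)
  td <- tidy(tree)
  block_rows <- vapply(td$tips, function(t)
    setequal(t, c("a1", "a2", "a3")) || setequal(t, c("b1", "b2", "b3")),
    logical(1))
  expect_equal(sum(block_rows), 2)
  expect_true(all(td$support[block_rows] >= 90))
})

test_that("collapsing low support produces polytomies but keeps strong clades", {
  fp <- fp_from_matrix(two_block_fp())
  co <- cooccurrence(fp, rownames(fp), n_iter = 100, seed = 7)
  tree <- node_support(build_tree(co), fp, rownames(fp), n_iter = 100,
                       seed = 8)
  col <- collapse_low_support(tree, min_support = 10)
  expect_setequal(col$tip.label, tree$tip.label)
  expect_true(all(as.numeric(col$node.label)[-1] >= 10 |
                    seq_len(col$Nnode)[-1] == 0))
  # identity when everything is strong
  keep <- tree; keep$node.label <- rep(100, keep$Nnode)
  expect_equal(clade_strings(collapse_low_support(keep, 10)),
               clade_strings(keep))
  # all-zero internal supports give a star tree
  star <- tree
  star$node.label <- c(100, rep(0, star$Nnode - 1))
  st <- collapse_low_support(star, 10)
  expect_equal(st$Nnode, 1L)
  # one weak node in a binary 4-tip tree yields one trifurcation
  t4 <- ape::read.tree(text = "((a,b),(c,d));")
  t4$node.label <- c(100, 9, 95)
  t4$edge.length <- rep(1, nrow(t4$edge))
  c4 <- collapse_low_support(t4, 10)
  expect_equal(c4$Nnode, 2L)
  kids_per_node <- table(c4$edge[, 1])
  expect_true(3 %in% kids_per_node)
})

test_that("node-supporting genes honor thresholds and leakiness", {
  types <- c("f1", "f2", "f3", "f4", "o1", "o2", "o3")
  m <- matrix(1, 6, 7, dimnames = list(paste0("g", 1:6), types))
  m["g1", 1:4] <- 2.0                      # clean foreground gene
  m["g2", 1:4] <- c(2, 2, 2, 1.6)          # fails one fg tip
  m["g3", ] <- c(2, 2, 2, 2, 1.9, 1, 1)    # leaks into one bg tip
  fp <- fp_from_matrix(m)
  tree <- ape::read.tree(text = "(((f1,f2),(f3,f4)),(o1,(o2,o3)));")
  tree$edge.length <- rep(1, nrow(tree$edge))
  class(tree) <- c("celltype_tree", "phylo")
  td <- tidy(tree)
  node_f <- td$node[vapply(td$tips, setequal, logical(1),
                           y = c("f1", "f2", "f3", "f4"))]
  # leak 0: brute-force intersection/complement equivalence
  res0 <- node_supporting_genes(tree, fp, node_f, fg_thr = 1.7,
                                bg_thr = 1.8, leak_fg = 0, leak_bg = 0)
  brute <- node_genes_brute(fp, c("f1", "f2", "f3", "f4"),
                            c("o1", "o2", "o3"), 1.7, 1.8)
  expect_setequal(res0$gene, brute)
  expect_equal(sort(res0$gene), c("g1"))
  # 10% leakiness on both sides: g1 only still (leak floor < 1 tip)
  res10 <- node_supporting_genes(tree, fp, node_f, 1.7, 1.8, 0.1, 0.1)
  expect_setequal(res10$gene, "g1")
  # leak_fg = 0.25 tolerates one failing fg tip of four
  res_fg <- node_supporting_genes(tree, fp, node_f, 1.7, 1.8,
                                  leak_fg = 0.25, leak_bg = 0)
  expect_true("g2" %in% res_fg$gene)
  # leak_bg = 0.34 tolerates one leaking bg tip of three
  res_bg <- node_supporting_genes(tree, fp, node_f, 1.7, 1.8,
                                  leak_fg = 0, leak_bg = 0.34)
  expect_true("g3" %in% res_bg$gene)
  # root with mode=node has empty background
  root <- length(tree$tip.label) + 1L
  expect_error(node_supporting_genes(tree, fp, root), "background")
})

test_that("leak and threshold monotonicity hold on random fixtures", {
  set.seed(23)
  tree <- ape::read.tree(text = "(((f1,f2),(f3,f4)),(o1,(o2,o3)));")
  tree$edge.length <- rep(1, nrow(tree$edge))
  class(tree) <- c("celltype_tree", "phylo")
  td <- tidy(tree)
  node_f <- td$node[vapply(td$tips, setequal, logical(1),
                           y = c("f1", "f2", "f3", "f4"))]
  for (rep in 1:10) {
    m <- matrix(exp(rnorm(20 * 7, 0, 0.7)), 20, 7,
                dimnames = list(sprintf("g%02d", 1:20),
                                c("f1", "f2", "f3", "f4", "o1", "o2", "o3")))
    fp <- fp_from_matrix(m)
    base <- node_supporting_genes(tree, fp, node_f, 1.3, 1.4, 0.1, 0.1)$gene
    wider_bg <- node_supporting_genes(tree, fp, node_f, 1.3, 1.4, 0.1,
                                      0.4)$gene
    expect_true(all(base %in% wider_bg))
    stricter_fg <- node_supporting_genes(tree, fp, node_f, 1.8, 1.4, 0.1,
                                         0.1)$gene
    expect_true(all(stricter_fg %in% base))
  }
})

test_that("vs_sister and features_out modes pick the stated backgrounds", {
  types <- c("f1", "f2", "s1", "s2", "o1", "o2")
  m <- matrix(1, 3, 6, dimnames = list(c("gf", "gs", "go"), types))
  m["gf", c("f1", "f2")] <- 3
  m["gf", c("o1", "o2")] <- 2.5   # hot outside the parent clade
  m["gs", c("s1", "s2")] <- 3
  m["go", c("o1", "o2", "s1", "s2")] <- 3  # expressed everywhere but f*
  fp <- fp_from_matrix(m)
  tree <- ape::read.tree(text = "(((f1,f2),(s1,s2)),(o1,o2));")
  tree$edge.length <- rep(1, nrow(tree$edge))
  class(tree) <- c("celltype_tree", "phylo")
  td <- tidy(tree)
  node_f <- td$node[vapply(td$tips, setequal, logical(1),
                           y = c("f1", "f2"))]
  # vs_sister ignores o1/o2, so gf qualifies despite their high FC
  vs <- node_supporting_genes(tree, fp, node_f, 1.7, 1.8,
                              mode = "vs_sister")
  expect_true("gf" %in% vs$gene)
  plain <- node_supporting_genes(tree, fp, node_f, 1.7, 1.8, mode = "node")
  expect_false("gf" %in% plain$gene)
  # features_out: genes expressed in all the *other* tips
  fo <- node_supporting_genes(tree, fp, node_f, 1.7, 1.8,
                              mode = "features_out")
  expect_true("go" %in% fo$gene)
  expect_false("gf" %in% fo$gene)
})
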