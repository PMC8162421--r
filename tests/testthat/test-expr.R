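test_that("cell filtering keeps boundary totals and is idempotent", {
  m <- matrix(0, 2, 4, dimnames = list(c("g1", "g2"), paste0("c", 1:4)))
  m[1, ] <- c(50, 100, 8000, 8001)
  umi <- umi_fix(m)
  kept <- suppressMessages(filter_cells(umi, 100, 8000))
  expect_equal(colnames(kept$counts), c("c2", "c3"))
  twice <- suppressMessages(filter_cells(kept, 100, 8000))
  expect_identical(as.matrix(twice$counts), as.matrix(kept$counts))
  # permissive bounds = identity
  all4 <- suppressMessages(filter_cells(umi, 0.5, Inf))
  expect_equal(ncol(all4$counts), 4)
  # all removed: explicit error
  m99 <- matrix(99, 1, 3, dimnames = list("g", paste0("c", 1:3)))
  expect_error(suppressMessages(filter_cells(umi_fix(m99), 100, 8000)),
               "all .* removed")
})

test_that("feature selection applies strict count thresholds and exclusions", {
  set.seed(1)
  n_cells <- 300
  size_f <- rlnorm(n_cells, 0, 0.5)  # cell size factors
  # 30 background genes proportional to size; g_marker bimodal (on in half
  # the cells at 20x), size-decorrelated; g_low exactly 30 total UMIs
  bg <- sapply(size_f, function(f) rpois(30, 1 * f))
  on <- seq_len(n_cells) %% 2 == 0
  g_marker <- rpois(n_cells, ifelse(on, 20, 0) * size_f)
  counts <- rbind(bg, g_marker = g_marker)
  rownames(counts)[1:30] <- paste0("bg", 1:30)
  g_low <- rep(0L, n_cells); g_low[1:15] <- 2L  # 30 total, detected in 15
  counts <- rbind(counts, g_low = g_low)
  colnames(counts) <- paste0("c", seq_len(n_cells))
  umi <- umi_fix(counts)
  sel <- suppressWarnings(select_feature_genes(umi, size_corr_thr = -0.05))
  expect_false("g_low" %in% sel)      # total 30 is not > 30
  expect_true("g_marker" %in% sel)    # bimodal, size-decorrelated
  sel2 <- suppressWarnings(
    select_feature_genes(umi, exclude = "g_marker"))
  expect_false("g_marker" %in% sel2)
})

test_that("size-proportional populations yield no variable genes", {
  # every gene's expression tracks cell size exactly (multinomial with
  # constant rates): the symbiont-like homogeneous case
  set.seed(7)
  n_genes <- 40; n_cells <- 300
  lib <- round(rlnorm(n_cells, log(400), 0.6))
  rates <- rep(1 / n_genes, n_genes)
  counts <- sapply(lib, function(L) rmultinom(1, L, rates)[, 1])
  rownames(counts) <- paste0("g", seq_len(n_genes))
  colnames(counts) <- paste0("c", seq_len(n_cells))
  expect_warning(sel <- select_feature_genes(umi_fix(counts)),
                 "no variable genes")
  expect_length(sel, 0)
})

test_that("footprint matches the hand-computed two-gene oracle", {
  # 2 genes x 4 cells, 2 metacells of 2 cells; depth = median total = 10
  m <- matrix(c(6, 4,    # c1 (total 10)
                8, 2,    # c2 (total 10)
                2, 8,    # c3 (total 10)
                1, 9),   # c4 (total 10)
              nrow = 2, dimnames = list(c("g1", "g2"), paste0("c", 1:4)))
  umi <- umi_fix(m)
  asg <- asg_fix(paste0("c", 1:4), c("m1", "m1", "m2", "m2"))
  eps <- 0.1
  fp <- compute_footprint(umi, asg, epsilon = eps, level = "metacell")
  # hand computation (fractions scaled to depth 10 equal raw counts here)
  geo <- function(x) exp(mean(log(x + eps))) - eps
  g <- matrix(c(geo(c(6, 8)), geo(c(4, 2)), geo(c(2, 1)), geo(c(8, 9))), 2)
  gp <- g + eps
  expected <- gp / pmax(apply(gp, 1, median), eps)
  expect_equal(unname(unclass(fp)), unname(expected), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("degenerate footprints are exactly flat", {
  m <- matrix(c(5, 5, 5, 5, 2, 2, 2, 2), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("c", 1:4)))
  umi <- umi_fix(m)
  # a single metacell: all FC = 1
  one <- compute_footprint(umi, asg_fix(paste0("c", 1:4), rep("m1", 4)))
  expect_true(all(unclass(one) == 1))
  # identical expression in all cells: FC = 1 everywhere
  two <- compute_footprint(umi, asg_fix(paste0("c", 1:4),
                                        c("m1", "m1", "m2", "m2")))
  expect_equal(max(abs(unclass(two) - 1)), 0, tolerance = 1e-12)
})

test_that("median-normalization invariant holds on random matrices", {
  set.seed(42)
  for (rep in 1:20) {
    n_g <- sample(5:30, 1); n_c <- sample(6:24, 1)
    m <- matrix(rpois(n_g * n_c, lambda = runif(1, 1, 20)), n_g, n_c,
                dimnames = list(paste0("g", 1:n_g), paste0("c", 1:n_c)))
    m[1, ] <- m[1, ] + 1  # keep totals positive
    k <- sample(2:4, 1)
    asg <- asg_fix(colnames(m), paste0("m", rep_len(seq_len(k), n_c)))
    fp <- compute_footprint(umi_fix(m), asg)
    meds <- apply(unclass(fp), 1L, median)
    expect_true(all(abs(meds - 1) < 1e-9 | meds < 1))
  }
})

test_that("footprint is equivariant to cell order within groups", {
  set.seed(3)
  m <- matrix(rpois(60, 5) + 1, 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
  grp <- rep(c("m1", "m2"), each = 5)
  fp1 <- compute_footprint(umi_fix(m), asg_fix(colnames(m), grp))
  perm <- c(5:1, 10:6)  # permute cells within each group
  m2 <- m[, perm]
  fp2 <- compute_footprint(umi_fix(m2), asg_fix(colnames(m2), grp[perm]))
  expect_equal(unclass(fp1), unclass(fp2)[rownames(fp1), colnames(fp1)],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("metacell QC retains exceptions and outliers failing metacells", {
  # three metacells: mc_good passes the base rule; mc_tf passes only via
  # the TF exception; mc_bad fails everything
  set.seed(9)
  n_per <- 20
  genes <- c(paste0("mk", 1:12), paste0("tf", 1:4), paste0("bg", 1:20))
  mk_cells <- function(active, n, depth) {
    rates <- setNames(rep(1, length(genes)), genes)
    rates[active] <- 40
    sapply(seq_len(n), function(i) rmultinom(1, depth, rates / sum(rates))[, 1])
  }
  cg <- mk_cells(paste0("mk", 1:12), n_per, 600)
  ct <- mk_cells(paste0("tf", 1:4), n_per, 600)
  cb <- mk_cells(character(), n_per, 100)
  counts <- cbind(cg, ct, cb)
  rownames(counts) <- genes
  colnames(counts) <- paste0("c", seq_len(3 * n_per))
  umi <- umi_fix(counts)
  asg <- asg_fix(colnames(counts),
                 rep(c("mc_good", "mc_tf", "mc_bad"), each = n_per))
  fp <- compute_footprint(umi, asg, level = "metacell")
  rules <- qc_rules(min_markers = 10, n_tfs = 2, tf_fc = 2,
                    umi_peak = 400)
  out <- filter_metacells(fp, umi, asg, markers = paste0("mk", 1:12),
                          rules = rules, tf_list = paste0("tf", 1:4))
  expect_setequal(out$metacells$metacell, c("mc_good", "mc_tf"))
  qc <- attr(out, "qc_table")
  expect_true(qc$tf_exception[qc$metacell == "mc_tf"])
  expect_false(qc$base_pass[qc$metacell == "mc_tf"])
  # cells of mc_bad are outliers now
  bad_cells <- colnames(counts)[41:60]
  expect_true(all(is.na(out$cells$metacell[out$cells$cell %in% bad_cells])))
  # empty TF list with TF exception enabled is a config error
  expect_error(filter_metacells(fp, umi, asg, markers = paste0("mk", 1:12),
                                rules = rules, tf_list = character()),
               "tf_list")
})

test_that("symbiont-laden metacells survive QC via the symbiont exception", {
  set.seed(10)
  host <- matrix(rpois(5 * 20, 3), 5, 20)
  symb <- matrix(0, 2, 20)
  symb[, 1:10] <- 700  # metacell mc1 carries 14,000 symbiont UMIs
  counts <- rbind(host, symb)
  rownames(counts) <- c(paste0("h", 1:5), paste0("s", 1:2))
  colnames(counts) <- paste0("c", 1:20)
  umi <- umi_fix(counts, organism = c(rep("host", 5), rep("symbiont", 2)))
  asg <- asg_fix(colnames(counts), rep(c("mc1", "mc2"), each = 10))
  fp <- compute_footprint(umi, asg)
  rules <- qc_rules(min_markers = 10, n_tfs = 0, min_symb_umi = 10000,
                    umi_peak = 1e6)  # base rule unreachable
  out <- filter_metacells(fp, umi, asg, markers = paste0("h", 1:5),
                          rules = rules, tf_list = character())
  expect_equal(out$metacells$metacell, "mc1")
})

test_that("top markers cap per group and break FC ties by gene id", {
  vals <- matrix(1, 14, 2, dimnames = list(sprintf("g%02d", 1:14),
                                           c("m1", "m2")))
  vals[1:14, 1] <- seq(3.4, 2.1, by = -0.1)  # 14 genes above 2 in m1
  fp <- polypatlas:::new_footprint(vals, epsilon = 0.1, normalized = TRUE)
  tm <- top_markers(fp, fc_thr = 2, max_per_group = 10)
  expect_equal(sum(tm$group == "m1"), 10)
  expect_equal(tm$gene[tm$group == "m1"][1], "g01")
  # tie at the cutoff: lexicographically smaller id retained
  tie <- matrix(c(2.5, 2.5, 2.5, 1, 1, 1), 3, 2,
                dimnames = list(c("gb", "ga", "gc"), c("m1", "m2")))
  fpt <- polypatlas:::new_footprint(tie, 0.1, TRUE)
  tmt <- top_markers(fpt, fc_thr = 2, max_per_group = 2)
  expect_setequal(tmt$gene, c("ga", "gb"))
  # all-flat matrix: empty table
  flat <- polypatlas:::new_footprint(matrix(1, 3, 2,
    dimnames = list(paste0("g", 1:3), c("a", "b"))), 0.1, TRUE)
  expect_equal(nrow(top_markers(flat)), 0)
})

test_that("planted markers surface in top_markers under strong signal", {
  for (s in c(101, 202)) {
    cfg <- atlas_sim_config(n_genes = 200, celltypes_per_stage = 4,
                            n_cells_per_type = 40, program_fc = 10,
                            markers_per_type = 5, seed = s)
    sim <- simulate_atlas(cfg)
    fp <- compute_footprint(sim$umi, sim$assignment, level = "celltype")
    tm <- top_markers(fp, fc_thr = 2, max_per_group = 10)
    planted <- sim$truth$markers[sim$truth$markers$level == "type", ]
    for (tp in unique(planted$unit)) {
      expect_true(all(planted$gene[planted$unit == tp] %in%
                        tm$gene[tm$group == tp]))
    }
  }
})
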