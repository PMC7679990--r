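test_that("regulon construction enforces its invariants", {
  expect_error(regulon("TF1", "x", "G1"), "sign")
  expect_error(regulon("TF1", "+", character(0)), "non-empty")
  expect_error(regulon("TF1", "+", c("TF1", "G2")), "own targets")
  r <- regulon("TF1", "-", c("G1", "G2"), npred = c(3L, 1L))
  expect_equal(r$npred, c(3L, 1L))
})

test_that("balanced sampling caps at the smallest type and is seeded", {
  labels <- rep(c("a", "b", "c"), times = c(500, 400, 300))
  idx <- balanced_sample(labels, 100, seed = 1)
  expect_equal(length(idx), 300)
  expect_true(all(table(labels[idx]) == 100))
  idx2 <- balanced_sample(labels, 350, seed = 1)
  expect_equal(length(idx2), 900)
  expect_true(all(table(labels[idx2]) == 300))
  expect_identical(balanced_sample(labels, 100, seed = 7),
                   balanced_sample(labels, 100, seed = 7))
})

test_that("zero-noise injection touches exactly the zero entries", {
  set.seed(1)
  m <- matrix(rpois(200, 1), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
  z <- m == 0
  out <- inject_zero_noise(m, 0.01, seed = 2)
  expect_identical(out[!z], m[!z] + 0)
  expect_true(all(abs(out[z]) <= 0.01))
  expect_equal(sum(out != m), sum(z))
  nonzero <- matrix(1:12, 3, 4)
  expect_identical(inject_zero_noise(nonzero, 0.01, 1), nonzero)
})

test_that("link inference signs copies and anti-copies correctly", {
  set.seed(2)
  n <- 100
  tf <- rnorm(n, 5, 1)
  m <- rbind(TFX = tf, copy = tf, anti = 10 - tf,
             noise = rnorm(n))
  colnames(m) <- paste0("c", 1:n)
  e <- infer_links(m, "TFX", top_n_targets = 3, sign_threshold = 0.03)
  expect_equal(e$sign[e$gene == "copy"], "+")
  expect_equal(e$r[e$gene == "copy"], 1, tolerance = 1e-12)
  expect_equal(e$sign[e$gene == "anti"], "-")
  expect_false("TFX" %in% e$gene)
  expect_warning(infer_links(rbind(m, FLAT = 1), c("TFX", "FLAT"), 3),
                 "constant TF")
})

test_that("motif pruning keeps supported edges and drops small regulons", {
  edges <- data.frame(
    tf = rep(c("T1", "T2"), each = 3),
    gene = c("a", "b", "c", "d", "e", "f"),
    r = c(0.5, 0.4, -0.3, 0.2, 0.2, 0.2),
    sign = c("+", "+", "-", "+", "+", "+"))
  motifs <- data.frame(tf = c("T1", "T1", "T1"), gene = c("a", "b", "c"))
  regs <- prune_by_motif(edges, motifs, min_targets = 1)
  ids <- vapply(regs, reg_id, character(1))
  expect_setequal(ids, c("T1(+)", "T1(-)"))
  expect_setequal(regs[[which(ids == "T1(+)")]]$targets, c("a", "b"))
  expect_equal(attr(regs, "dropped_tfs"), "T2")
  expect_length(prune_by_motif(edges, motifs, min_targets = 3), 0)
  expect_length(prune_by_motif(edges, motifs[0, ], 1), 0)
})

test_that("AUC scores hit the exact extremes", {
  # 100 genes, one cell; expression decreasing in gene index
  m <- matrix(100:1, 100, 1, dimnames = list(paste0("g", 1:100), "c1"))
  top <- regulon("TFX", "+", paste0("g", 1:3))
  expect_equal(unname(auc_score(m, top, top_fraction = 0.05, seed = 1)), 1)
  bottom <- regulon("TFX", "+", paste0("g", 96:100))
  expect_equal(unname(auc_score(m, bottom, 0.05, seed = 1)), 0)
  expect_error(auc_score(m, regulon("TFX", "+", "absent")), "no regulon gene")
})

test_that("AUC scoring matches the brute-force recovery-curve oracle", {
  set.seed(3)
  for (i in 1:20) {
    n_genes <- sample(10:50, 1)
    n_cells <- sample(2:20, 1)
    m <- matrix(rpois(n_genes * n_cells, 3), n_genes, n_cells,
                dimnames = list(paste0("g", seq_len(n_genes)),
                                paste0("c", seq_len(n_cells))))
    targets <- sample(rownames(m), sample(2:5, 1))
    tf_frac <- runif(1, 0.1, 0.5)
    seed <- i
    got <- auc_score(m, regulon("TFX", "+", targets), tf_frac, seed)
    tie <- withr::with_seed(scregulon:::derive_seed(seed, 53L),
                            sample.int(n_genes))
    want <- brute_auc(m, targets, tf_frac, tie)
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("AUC score is invariant to monotone transforms of a cell", {
  set.seed(4)
  m <- matrix(rnorm(50 * 5, 5), 50, 5,
              dimnames = list(paste0("g", 1:50), paste0("c", 1:5)))
  targets <- paste0("g", sample(50, 8))
  s1 <- auc_score(m, regulon("T", "+", targets), 0.2, seed = 6)
  m2 <- m; m2[, 3] <- exp(m[, 3] / 2) # strictly monotone on cell 3
  s2 <- auc_score(m2, regulon("T", "+", targets), 0.2, seed = 6)
  expect_equal(s1[3], s2[3])
})

test_that("the reproducibility gate retains perfect and rejects degenerate", {
  tm <- matrix(seq_len(12), 12, 2,
               dimnames = list(NULL, c("r1", "r2")))
  tm[, 2] <- 5 # constant score vector
  gate <- cv_gate(tm, tm, p_cutoff = 0.001)
  expect_true(gate$retained[1])   # r = 1, p ~ 0
  expect_lt(gate$p[1], 1e-10)
  expect_false(gate$retained[2])  # undefined r -> discarded
  expect_error(cv_gate(tm[1:2, ], tm[1:2, ]), "3 cell types")
})

test_that("crossvalidation needs three cell types and stratifies", {
  sim <- small_sim()
  norm <- small_norm()
  expect_error(
    crossvalidate(norm[, 1:160], rep(c("a", "b"), each = 80), sim$motifs),
    "3 cell types")
})

test_that("merged discovery accumulates Npred across iterations", {
  sim <- small_sim()
  norm <- small_norm()
  p1 <- cv_params(n_iter = 1, balanced_n = 60, seed = 2)
  d1 <- run_discovery(norm, sim$sce$state, sim$motifs, p1)
  if (length(d1$regulons) > 0) {
    expect_true(all(vapply(d1$regulons, function(r) all(r$npred == 1L),
                           logical(1))))
    expect_true(all(vapply(d1$regulons,
                           function(r) r$n_iterations_found == 1L,
                           logical(1))))
  }
  p4 <- cv_params(n_iter = 4, balanced_n = 60, seed = 2)
  d4 <- run_discovery(norm, sim$sce$state, sim$motifs, p4)
  expect_gt(length(d4$regulons), 0)
  npreds <- unlist(lapply(d4$regulons, function(r) r$npred))
  iters <- vapply(d4$regulons, function(r) r$n_iterations_found, integer(1))
  expect_true(all(npreds >= 1 & npreds <= 4))
  expect_true(all(npreds <= rep(iters, vapply(d4$regulons, function(r)
    length(r$targets), integer(1)))))
  # a stable regulon supported in every iteration exists at this effect size
  expect_true(any(iters == 4))
  expect_true(any(npreds == 4))
  # activity bounds and dimensions
  expect_true(all(d4$activity >= 0 & d4$activity <= 1))
  expect_equal(nrow(d4$activity), ncol(norm))

  # full determinism given the master seed
  d4b <- run_discovery(norm, sim$sce$state, sim$motifs, p4)
  expect_identical(d4$activity, d4b$activity)
  expect_identical(vapply(d4$regulons, reg_id, character(1)),
                   vapply(d4b$regulons, reg_id, character(1)))
})

test_that("the linear-model filter separates structured from flat scores", {
  labels <- rep(paste0("t", 1:4), each = 100)
  type_effect <- c(t1 = 0.2, t2 = 0.4, t3 = 0.6, t4 = 0.8)
  act <- cbind(exact = type_effect[labels],
               flat = rep(0.5, 400))
  p <- cv_params(n_fits_lm = 10, n_cells_lm = 50)
  res <- filter_linear_model(act, labels, p, seed = 1)
  expect_equal(res$mean_r2[res$regulon == "exact"], 1, tolerance = 1e-12)
  expect_true(res$retained[res$regulon == "exact"])
  expect_equal(res$mean_r2[res$regulon == "flat"], 0)
  expect_false(res$retained[res$regulon == "flat"])
})

test_that("expression support removes only unexpressed-TF regulons", {
  set.seed(5)
  n <- 300
  labels <- rep(c("a", "b", "c"), each = 100)
  score <- c(rnorm(100, 0.9, 0.02), rnorm(200, 0.1, 0.02)) # type a dominant
  act <- cbind(`T1(+)` = score, `T2(+)` = score, `T3(+)` = score)
  norm <- rbind(T1 = rbinom(n, 1, 0.5) * 2,     # expressed half the time
                T2 = c(rep(0, 297), 1, 1, 1),   # 99% zeros
                T3 = c(rep(0, 288), rep(1, 12))) # exactly 96% zeros
  colnames(norm) <- paste0("c", 1:n)
  regs <- list(regulon("T1", "+", "x"), regulon("T2", "+", "x"),
               regulon("T3", "+", "x"))
  res <- filter_expression_support(act, regs, norm, labels)
  expect_true(res$retained[1])
  expect_false(res$retained[2])
  expect_true(res$retained[3]) # boundary 0.96 kept under strict >
  # a missing TF removes the regulon
  res2 <- filter_expression_support(act[, 1, drop = FALSE],
                                    list(regulon("GONE", "+", "x")),
                                    norm, labels)
  expect_false(res2$retained[1])
})

test_that("the TF-correlation filter uses a strict -0.8 boundary", {
  set.seed(6)
  n <- 200
  tf <- rnorm(n, 2)
  norm <- rbind(TFP = tf, TFN = tf, TFB = tf)
  colnames(norm) <- paste0("c", 1:n)
  # build a score with correlation exactly -0.8 to tf
  noise <- rnorm(n)
  noise <- residuals(lm(noise ~ tf))
  z_tf <- scale(tf)[, 1]; z_no <- scale(noise)[, 1]
  s_exact <- -0.8 * z_tf + sqrt(1 - 0.64) * z_no
  act <- cbind(`TFP(+)` = tf, `TFN(-)` = -tf, `TFB(-)` = s_exact)
  regs <- list(regulon("TFP", "+", "x"), regulon("TFN", "-", "x"),
               regulon("TFB", "-", "x"))
  res <- filter_tf_correlation(act, regs, norm)
  expect_true(res$retained[1])
  expect_false(res$retained[2])
  expect_equal(res$tf_cor[3], -0.8, tolerance = 1e-12)
  expect_true(res$retained[3])
  # undefined correlation (constant score) is kept
  res2 <- filter_tf_correlation(cbind(`TFP(+)` = rep(1, n)),
                                list(regulon("TFP", "+", "x")), norm)
  expect_true(res2$retained[1])
})
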