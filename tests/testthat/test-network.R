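make_net <- function(a) {
  diag(a) <- 1
  structure(list(cor = NULL, adjacency = a, connectivity = colSums(a) - 1,
                 beta = 1, mode = "signed"), class = "network_matrices")
}

test_that("adjacency follows the signed and unsigned power forms", {
  x <- rbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10),  # cor +1
             c = c(5, 4, 3, 2, 1))                         # cor -1 with a
  colnames(x) <- sprintf("s%d", 1:5)
  clr <- feature_table(x, "clr")
  s <- adjacency_matrix(clr, beta = 6, mode = "signed")
  expect_equal(s$adjacency["a", "b"], 1)
  expect_equal(s$adjacency["a", "c"], 0)
  u <- adjacency_matrix(clr, beta = 6, mode = "unsigned")
  expect_equal(u$adjacency["a", "c"], 1)     # |cor| = 1
  # cor 0.5 unsigned beta 6 -> 0.5^6
  x2 <- rbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1), d = c(1, 0, 0, -1))
  colnames(x2) <- sprintf("s%d", 1:4)
  u2 <- adjacency_matrix(feature_table(x2, "clr"), beta = 6, "unsigned")
  expect_equal(u2$adjacency["a", "d"], cor(x2["a", ], x2["d", ])^6)
  expect_error(adjacency_matrix(clr, beta = 0.5), ">= 1")
})

test_that("TOM matches closed forms for 2 nodes, complete and empty graphs", {
  for (a12 in c(0.2, 0.5, 0.9)) {
    net <- make_net(matrix(c(1, a12, a12, 1), 2, 2))
    expect_equal(tom_similarity(net)[1, 2], a12)
  }
  for (n in c(4, 7)) {
    full <- make_net(matrix(1, n, n))
    expect_equal(max(abs(tom_similarity(full) - 1)), 0)
    empty <- make_net(diag(n))
    tomE <- tom_similarity(empty)
    expect_equal(unique(tomE[upper.tri(tomE)]), 0)
  }
  # symmetry and range on a random adjacency
  set.seed(21)
  r <- matrix(runif(49), 7, 7); r <- (r + t(r)) / 2
  tom <- tom_similarity(make_net(r))
  expect_equal(tom, t(tom))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
})

test_that("duplicated lipids are indiscernible under 1 - TOM", {
  set.seed(22)
  x <- matrix(rnorm(50), 5, 10,
              dimnames = list(sprintf("L%d", 1:5), sprintf("s%d", 1:10)))
  x[2, ] <- x[1, ]
  net <- adjacency_matrix(feature_table(x, "clr"), beta = 6)
  tom <- tom_similarity(net)
  # the duplicate pair shares every neighbourhood value and is mutually
  # closer than either is to any third lipid
  expect_equal(tom["L1", c("L3", "L4", "L5")],
               tom["L2", c("L3", "L4", "L5")])
  expect_equal(tom["L1", "L2"], max(tom["L1", c("L2", "L3", "L4", "L5")]))
})

test_that("scale-free fit flags power-law and anti-scale-free regimes", {
  set.seed(23)
  k <- round(stats::qexp(runif(500)) * 10) + 1   # heavy-ish tail
  k_pl <- round(2 / sqrt(runif(2000)))           # p(k) ~ k^-3
  fit <- suppressWarnings(scale_free_fit(k_pl))
  expect_lt(fit$slope, 0)
  expect_gt(fit$fit, 0.8)
  # increasing p(k): fit must be sign-flipped negative
  k_up <- rep(1:10, times = 1:10)
  fit_up <- scale_free_fit(k_up)
  expect_lt(fit_up$fit, 0)
})

test_that("soft-threshold choice is deterministic and validates input", {
  sim <- simulate_ocean(recovery_config(seed = 31L))
  clr <- clr_transform(normalize_total(sim$features))
  a <- suppressWarnings(pick_soft_threshold(clr, powers = c(2, 4, 6)))
  b <- suppressWarnings(pick_soft_threshold(clr, powers = c(2, 4, 6)))
  expect_identical(a$power, b$power)
  bad <- unclass(clr); bad[3, ] <- 1
  expect_error(pick_soft_threshold(feature_table(bad, "clr"),
                                   powers = c(2, 4)), "degenerate")
  expect_error(pick_soft_threshold(clr, powers = 6), "two candidate")
})

test_that("module detection recovers separated blocks exactly", {
  bl <- block_clr(k = 2L, per_block = 50L, n_samples = 40L, noise_sd = 0.02,
                  seed = 24L)
  tom <- tom_similarity(adjacency_matrix(bl$clr, beta = 6))
  det <- detect_modules(tom, min_module_size = 10L)
  expect_equal(sort(unname(det$sizes)), c(50L, 50L))
  expect_equal(adjusted_rand_index(det$labels, bl$labels), 1)
})

test_that("pure noise with a large size threshold yields only EL0", {
  set.seed(25)
  x <- matrix(rnorm(100 * 40), 100, 40,
              dimnames = list(sprintf("L%03d", 1:100),
                              sprintf("s%02d", 1:40)))
  tom <- tom_similarity(adjacency_matrix(feature_table(x, "clr"), beta = 6))
  det <- detect_modules(tom, min_module_size = 51L)
  expect_true(all(det$labels == 0L))
  expect_error(detect_modules(tom, min_module_size = 1L), ">= 2")
})

test_that("module labels are ordered by decreasing size", {
  bl1 <- block_clr(k = 3L, per_block = 12L, n_samples = 30L, seed = 26L)
  # unbalance the blocks: drop members from blocks 1 and 2
  keep <- !(rownames(bl1$clr) %in% c(sprintf("B1_%02d", 1:6),
                                     sprintf("B2_%02d", 1:3)))
  clr <- feature_table(unclass(bl1$clr)[keep, ], "clr")
  tom <- tom_similarity(adjacency_matrix(clr, beta = 6))
  det <- detect_modules(tom, min_module_size = 3L)
  expect_equal(unname(det$sizes), sort(unname(det$sizes),
                                       decreasing = TRUE))
  expect_equal(unname(det$sizes[1L]), 12L)
})

test_that("eigenlipids capture planted latents and orient with the mean", {
  bl <- block_clr(k = 2L, per_block = 25L, n_samples = 40L, noise_sd = 0,
                  seed = 27L)
  els <- compute_eigenlipids(bl$clr, bl$labels)
  for (j in 1:2) {
    expect_gte(abs(cor(els$profiles[, j], bl$latents[, j])), 0.999)
  }
  # orientation: positive correlation with the member mean profile
  x <- unclass(bl$clr)
  for (j in 1:2) {
    mem <- names(bl$labels)[bl$labels == j]
    expect_gt(cor(els$profiles[, j], colMeans(x[mem, ])), 0)
  }
  # flipping every member leaves the orientation rule intact
  flipped <- feature_table(-x, "clr")
  els2 <- compute_eigenlipids(flipped, bl$labels)
  for (j in 1:2) {
    mem <- names(bl$labels)[bl$labels == j]
    expect_gt(cor(els2$profiles[, j], colMeans(-x[mem, ])), 0)
  }
  expect_true(all(els$explained_variance > 0.99))
})

test_that("the eigenlipid explains at least as much variance as any member", {
  bl <- block_clr(k = 1L, per_block = 15L, n_samples = 30L, noise_sd = 0.8,
                  seed = 28L)
  els <- compute_eigenlipids(bl$clr, bl$labels)
  xs <- scale(t(unclass(bl$clr)))       # samples x lipids, standardised
  tot <- sum(xs^2)
  ev_eigen <- sum((t(xs) %*% els$profiles[, 1])^2) / tot
  for (i in seq_len(ncol(xs))) {
    u <- xs[, i] / sqrt(sum(xs[, i]^2))
    expect_gte(ev_eigen + 1e-10, sum((t(xs) %*% u)^2) / tot)
  }
})

test_that("membership scores behave like Spearman correlations", {
  bl <- block_clr(k = 2L, per_block = 20L, n_samples = 100L, noise_sd = 0,
                  seed = 29L)
  els <- compute_eigenlipids(bl$clr, bl$labels)
  x <- unclass(bl$clr)
  extra <- rbind(same = els$profiles[, 1],
                 mono = -exp(2 * els$profiles[, 1]),   # decreasing transform
                 flat = rep(1, ncol(x)))
  colnames(extra) <- colnames(x)
  ms <- membership_scores(feature_table(rbind(x, extra), "clr"), els)
  expect_equal(unname(ms$scores["same", 1]), 1)
  expect_equal(unname(ms$scores["mono", 1]), -1)
  expect_true(is.na(ms$scores["flat", 1]))
  # null behaviour: independent lipids rarely exceed |rho| = 0.3
  set.seed(30)
  nulls <- matrix(rnorm(200 * 100), 200, 100, dimnames =
                    list(sprintf("N%03d", 1:200), colnames(x)))
  msn <- membership_scores(feature_table(nulls, "clr"), els)
  expect_gt(mean(abs(msn$scores) < 0.3), 0.99)
})

test_that("projection reproduces training eigenlipids and survives dropout", {
  bl <- block_clr(k = 3L, per_block = 30L, n_samples = 50L, noise_sd = 0,
                  seed = 31L)
  els <- compute_eigenlipids(bl$clr, bl$labels)
  self <- project_region(bl$clr, els)
  expect_equal(self$profiles, els$profiles, tolerance = 1e-10)
  expect_equal(unname(self$overlap), rep(1, 3))

  set.seed(32)
  keep <- sort(sample(nrow(bl$clr), round(0.9 * nrow(bl$clr))))
  sub <- feature_table(unclass(bl$clr)[keep, ], "clr")
  pr <- project_region(sub, els)
  for (j in 1:3) expect_gte(cor(pr$profiles[, j], els$profiles[, j]), 0.99)

  disjoint <- feature_table(matrix(rnorm(20), 2, 10,
                                   dimnames = list(c("zz1", "zz2"),
                                                   sprintf("v%d", 1:10))),
                            "clr")
  expect_warning(pd <- project_region(disjoint, els), "no overlapping")
  expect_true(all(is.na(pd$profiles)))
})

test_that("IGP is perfect when validation equals training on clean blocks", {
  bl <- block_clr(k = 3L, per_block = 15L, n_samples = 30L, noise_sd = 0.05,
                  seed = 33L)
  els <- compute_eigenlipids(bl$clr, bl$labels)
  igp <- igp_reproducibility(bl$clr, els, n_perm = 99L, seed = 5L)
  expect_equal(igp$igp, rep(1, 3))
  expect_equal(igp$p, rep(1 / 100, 3))   # permutation lower bound
  expect_error(igp_reproducibility(bl$clr, els, n_perm = 50L), "99")
})
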