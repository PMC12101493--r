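# small eigenlipid_set stub with given profiles (samples x EL)
stub_els <- function(profiles) {
  structure(list(profiles = profiles), class = "eigenlipid_set")
}

toy_view_inputs <- function(n_el = 4L, n_samples = 24L, seed = 51L) {
  set.seed(seed)
  prof <- matrix(rnorm(n_samples * n_el), n_samples, n_el,
                 dimnames = list(sprintf("s%02d", 1:n_samples),
                                 paste0("EL", 1:n_el)))
  md <- data.frame(sample_id = rownames(prof),
                   station = rep(sprintf("S%d", 1:4), each = 6),
                   province = rep(c("WTRA", "APLR"), each = 12),
                   depth_m = rep(c(5, 25, 50, 100, 200, 400), 4),
                   mld_m = 30)
  el_tab <- matrix(runif(n_samples * n_el), n_samples, n_el,
                   dimnames = dimnames(prof))
  list(prof = prof, md = md, el_tab = el_tab)
}

test_that("distance views are normalised, symmetric and integrate by weights", {
  ti <- toy_view_inputs()
  ti$prof[, 2] <- ti$prof[, 1]           # duplicated EL profile
  ti$el_tab[, 2] <- ti$el_tab[, 1]
  d <- build_el_distances(stub_els(ti$prof), ti$el_tab, ti$md)
  for (v in c("distributional", "province", "depth", "integrated")) {
    m <- d[[v]]
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0 & m <= 1 + 1e-12))
    expect_equal(m["EL1", "EL2"], 0)     # duplicates at zero distance
  }
  d1 <- build_el_distances(stub_els(ti$prof), ti$el_tab, ti$md,
                           weights = c(1, 0, 0))
  expect_equal(d1$integrated, d1$distributional)
  # integrated bounded by the component views under equal weights
  lo <- pmin(d$distributional, d$province, d$depth)
  hi <- pmax(d$distributional, d$province, d$depth)
  expect_true(all(d$integrated >= lo - 1e-12 & d$integrated <= hi + 1e-12))
})

test_that("anti-correlated profiles span the normalised distance range", {
  ti <- toy_view_inputs(n_el = 3L)
  ti$prof[, 2] <- -ti$prof[, 1]
  d <- build_el_distances(stub_els(ti$prof), ti$el_tab, ti$md)
  expect_equal(d$distributional["EL1", "EL2"], 1)  # 1-(-1)=2 -> max -> 1
})

test_that("meta-dendrogram recovers planted distance blocks at k = 3", {
  n <- 9
  truth <- rep(1:3, each = 3)
  m <- matrix(0.9, n, n)
  for (b in 1:3) m[truth == b, truth == b] <- 0.05
  diag(m) <- 0
  dimnames(m) <- list(paste0("EL", 1:n), paste0("EL", 1:n))
  md <- meta_dendrogram(m, k = 3L)
  expect_equal(adjusted_rand_index(md$clusters, truth), 1)
  expect_equal(md$k, 3L)
  singl <- meta_dendrogram(m, k = n - 1L)
  expect_equal(length(unique(singl$clusters)), n - 1L)
  expect_error(meta_dendrogram(m, k = 1L), "k must be")
  expect_error(meta_dendrogram(m, k = n), "k must be")
  # permutation equivariance
  perm <- sample(n)
  md2 <- meta_dendrogram(m[perm, perm], k = 3L)
  expect_equal(adjusted_rand_index(md2$clusters[paste0("EL", 1:n)],
                                   md$clusters), 1)
})

test_that("cophenetic correlation is exact on ultrametric input", {
  set.seed(52)
  base <- matrix(runif(36), 6, 6); base <- (base + t(base)) / 2
  diag(base) <- 0
  tree0 <- stats::hclust(stats::as.dist(base), method = "average")
  ultra <- as.matrix(stats::cophenetic(tree0))
  tree <- stats::hclust(stats::as.dist(ultra), method = "average")
  expect_equal(cophenetic_correlation(tree, ultra), 1, tolerance = 1e-12)
  # small perturbations keep the correlation high
  noisy <- ultra + matrix(runif(36, 0, 0.02 * max(ultra)), 6, 6)
  noisy <- (noisy + t(noisy)) / 2; diag(noisy) <- 0
  treeN <- stats::hclust(stats::as.dist(noisy), method = "average")
  cc <- cophenetic_correlation(treeN, noisy)
  expect_gt(cc, 0.9)
  expect_lte(abs(cc), 1)
})

test_that("node significance separates planted groups and bounds p", {
  set.seed(53)
  x <- rbind(matrix(rnorm(8 * 6, 0), 8, 6),
             matrix(rnorm(8 * 6, 6), 8, 6))
  rownames(x) <- paste0("EL", 1:16)
  tree <- stats::hclust(stats::dist(x), method = "average")
  ns <- node_significance(x, tree, n_sim = 199L, seed = 3L)
  root <- ns[ns$node == nrow(tree$merge), ]
  expect_true(root$tested)
  expect_lte(root$p, 0.01)
  expect_gte(root$p, 1 / 200)
  expect_error(node_significance(x, tree, n_sim = 10L), "99")
})

test_that("tiny nodes are skipped and descent stops at insignificant nodes", {
  set.seed(54)
  x <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(paste0("EL", 1:6), NULL))
  tree <- stats::hclust(stats::dist(x), method = "average")
  ns <- node_significance(x, tree, n_sim = 99L, seed = 4L)
  expect_true(all(is.na(ns$p[ns$n_leaves < 3L])))
  # nodes below an untested/insignificant parent stay untested
  for (nd in which(!ns$tested & ns$n_leaves >= 3L)) {
    parent <- which(apply(tree$merge, 1, function(r) nd %in% r))
    expect_false(isTRUE(ns$significant[parent]))
  }
})
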