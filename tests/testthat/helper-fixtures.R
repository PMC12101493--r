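# shared in-code fixtures for the test suite

# feature table from a plain matrix, auto-naming rows/columns
ft <- function(m, view = "raw", lipids = NULL, samples = NULL) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 1L)
  rownames(m) <- if (is.null(lipids)) sprintf("L%03d", seq_len(nrow(m))) else
    lipids
  colnames(m) <- if (is.null(samples)) sprintf("s%03d", seq_len(ncol(m))) else
    samples
  feature_table(m, view)
}

# clr-view table of `k` perfectly planted blocks: block latents are
# orthogonal-ish Gaussian draws; members = latent + noise_sd * N(0,1)
block_clr <- function(k = 2L, per_block = 20L, n_samples = 30L,
                      noise_sd = 0, seed = 1L) {
  set.seed(seed)
  latents <- matrix(rnorm(n_samples * k), n_samples, k)
  latents <- scale(latents)
  x <- do.call(rbind, lapply(seq_len(k), function(b) {
    t(replicate(per_block,
                latents[, b] + rnorm(n_samples, 0, noise_sd)))
  }))
  rownames(x) <- sprintf("B%d_%02d", rep(seq_len(k), each = per_block),
                         sequence(rep(per_block, k)))
  colnames(x) <- sprintf("s%03d", seq_len(n_samples))
  list(clr = feature_table(x, "clr"),
       labels = stats::setNames(rep(seq_len(k), each = per_block),
                                rownames(x)),
       latents = latents)
}

# caterpillar hclust over `labels` with the given leaf order
caterpillar_tree <- function(labels) {
  n <- length(labels)
  merge <- matrix(0L, n - 1L, 2L)
  merge[1L, ] <- c(-1L, -2L)
  if (n > 2L) for (i in 2:(n - 1L)) merge[i, ] <- c(i - 1L, -(i + 1L))
  structure(list(merge = merge, height = seq_len(n - 1L),
                 order = seq_len(n), labels = labels,
                 method = "average", call = NULL,
                 dist.method = "euclidean"),
            class = "hclust")
}

# brute-force Cliff's Delta over all cross pairs (independent oracle)
delta_brute <- function(x, y) {
  s <- 0
  for (xi in x) for (yi in y) s <- s + sign(xi - yi)
  s / (length(x) * length(y))
}

# recovery-benchmark configuration: one region, 5 x 60 planted lipids, 40
# unassigned, 90 samples, noise_sd 0.15
recovery_config <- function(seed = 1L, ...) {
  ocean_config(n_regions = 1L, provinces_per_region = 3L,
               stations_per_province = 5L, seed = seed, ...)
}
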