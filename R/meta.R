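#' Distance views over modules and their integration
#'
#' Builds three EL x EL distance matrices and their integrated combination:
#' \itemize{
#' \item distributional: 1 - Pearson correlation between eigenlipid sample
#'   profiles;
#' \item province: correlation distance between per-province mean EL
#'   relative intensities (mixed-layer samples);
#' \item depth: Euclidean distance between standardised per-depth-bin mean
#'   EL intensity profiles.
#' }
#' Each view is min-max normalised to [0, 1] over its off-diagonal entries;
#' the integrated matrix is their weighted mean (equal weights by default).
#'
#' @param els \code{eigenlipid_set} (for the distributional view).
#' @param el_table samples x EL relative intensity matrix.
#' @param metadata sample metadata (province, depth_m, mld_m).
#' @param weights numeric length-3 weights (distributional, province,
#'   depth); normalised internally.
#' @param depth_bins bin edges in metres for the depth profile view.
#' @return list of class \code{el_distance_set} with \code{distributional},
#'   \code{province}, \code{depth}, \code{integrated} (matrices) and
#'   \code{weights}.
#' @export
build_el_distances <- function(els, el_table, metadata,
                               weights = c(1, 1, 1),
                               depth_bins = c(0, 25, 50, 100, 200, 400)) {
  el_names <- colnames(els$profiles)
  if (length(el_names) < 3L) stop("need >= 3 ELs for meta-clustering")
  missing_cols <- setdiff(el_names, colnames(el_table))
  if (length(missing_cols) > 0L) {
    stop("ELs missing from the intensity table: ",
         paste(missing_cols, collapse = ", "))
  }
  if (length(weights) != 3L || any(weights < 0) || sum(weights) == 0) {
    stop("weights must be three non-negative numbers, not all zero")
  }
  w <- weights / sum(weights)
  md <- metadata[match(rownames(el_table), metadata$sample_id), ]

  d_dist <- 1 - stats::cor(els$profiles)

  ml <- in_mixed_layer(md)
  prov_mean <- apply(el_table[ml, el_names, drop = FALSE], 2L, function(v) {
    tapply(v, md$province[ml], mean)
  })
  d_prov <- 1 - stats::cor(prov_mean)

  bins <- cut(md$depth_m, breaks = depth_bins, include.lowest = TRUE)
  depth_mean <- apply(el_table[, el_names, drop = FALSE], 2L, function(v) {
    tapply(v, bins, mean, na.rm = TRUE)
  })
  depth_std <- apply(depth_mean, 2L, function(v) {
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) v * 0 else (v - mean(v, na.rm = TRUE)) / s
  })
  d_depth <- as.matrix(stats::dist(t(depth_std)))

  norm01 <- function(m) {
    off <- m[upper.tri(m) | lower.tri(m)]
    rng <- range(off, na.rm = TRUE)
    out <- if (diff(rng) == 0) m * 0 else (m - rng[1L]) / diff(rng)
    diag(out) <- 0
    pmin(pmax(out, 0), 1)
  }
  dd <- norm01(d_dist[el_names, el_names])
  dp <- norm01(d_prov[el_names, el_names])
  dz <- norm01(d_depth[el_names, el_names])
  integrated <- w[1L] * dd + w[2L] * dp + w[3L] * dz
  structure(list(distributional = dd, province = dp, depth = dz,
                 integrated = integrated, weights = w),
            class = "el_distance_set")
}

#' Meta-dendrogram over modules
#'
#' Average-linkage hierarchical clustering of the integrated EL distance,
#' cut into \code{k} meta-clusters (labels MC1..MCk, numbered by first EL
#' index so relabelling ELs leaves memberships invariant).
#'
#' @param distances \code{el_distance_set} (or a symmetric distance
#'   matrix).
#' @param k number of meta-clusters, 2 <= k <= n-1.
#' @return list with \code{tree} (hclust), \code{clusters} (named MC
#'   labels per EL), \code{k}, \code{cophenetic} (cophenetic correlation
#'   with the input distance).
#' @export
meta_dendrogram <- function(distances, k = 3L) {
  m <- if (inherits(distances, "el_distance_set")) {
    distances$integrated
  } else as.matrix(distances)
  n <- nrow(m)
  if (k < 2L || k > n - 1L) stop("k must be in [2, n-1]")
  tree <- stats::hclust(stats::as.dist(m), method = "average")
  cl <- stats::cutree(tree, k = k)
  # stable numbering: MC index by order of first appearance over EL order
  first <- tapply(seq_along(cl), cl, min)
  remap <- stats::setNames(rank(first, ties.method = "first"), names(first))
  mc <- paste0("MC", remap[as.character(cl)])
  list(tree = tree,
       clusters = stats::setNames(mc, rownames(m)),
       k = k,
       cophenetic = cophenetic_correlation(tree, m))
}

#' Cophenetic correlation of a dendrogram
#'
#' Pearson correlation between the original pairwise distances and the
#' merge-height (cophenetic) distances implied by the tree.
#'
#' @param tree an \code{hclust}.
#' @param original symmetric distance matrix or \code{dist} over the same
#'   leaves.
#' @return numeric scalar in [-1, 1]; NA for < 3 leaves.
#' @export
cophenetic_correlation <- function(tree, original) {
  if (length(tree$order) < 3L) return(NA_real_)
  d0 <- stats::as.dist(as.matrix(original)[tree$labels, tree$labels])
  dc <- stats::cophenetic(tree)
  stats::cor(as.numeric(d0), as.numeric(dc))
}

# simulate from a Gaussian fitted to rows of x: mean + eigen-floored
# covariance (sigclust-style background floor keeps the fit full-rank)
fit_gaussian_sampler <- function(x) {
  n <- nrow(x); p <- ncol(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sv <- svd(xc, nu = 0)
  lambda <- rep(0, p)
  lambda[seq_along(sv$d)] <- sv$d^2 / max(n - 1L, 1L)
  sigma_b <- (stats::mad(xc))^2
  if (!is.finite(sigma_b) || sigma_b == 0) sigma_b <- stats::var(as.numeric(xc))
  if (!is.finite(sigma_b) || sigma_b == 0) sigma_b <- 1e-8
  # covariance model: sigma_b * I + V diag((lambda - sigma_b)_+) V'
  vr <- sv$v
  extra <- sqrt(pmax(lambda[seq_len(ncol(vr))] - sigma_b, 0))
  function(m) {
    z_iso <- matrix(stats::rnorm(m * p, sd = sqrt(sigma_b)), m, p)
    z_dir <- matrix(stats::rnorm(m * ncol(vr)), m, ncol(vr))
    sweep(z_iso + z_dir %*% (t(vr) * extra), 2L, mu, "+")
  }
}

# two-group cluster index: within-group SS after an average-linkage 2-split
# divided by total SS
cluster_index_2 <- function(x) {
  tot <- sum(sweep(x, 2L, colMeans(x))^2)
  if (tot == 0) return(1)
  cl <- stats::cutree(stats::hclust(stats::dist(x), method = "average"),
                      k = 2L)
  wss <- sum(vapply(split(seq_len(nrow(x)), cl), function(i) {
    xi <- x[i, , drop = FALSE]
    sum(sweep(xi, 2L, colMeans(xi))^2)
  }, numeric(1)))
  wss / tot
}

#' Monte Carlo significance of dendrogram nodes
#'
#' For each internal node, starting at the root and descending only
#' through significant nodes (sequential family-wise rule): fit a single
#' multivariate Gaussian to the node's EL feature vectors (mean plus
#' eigenvalue-floored covariance), simulate \code{n_sim} datasets of the
#' same size, and compare the node's observed two-group cluster index
#' (within-group sum of squares after an average-linkage 2-split, as a
#' fraction of total SS) to the simulated ones:
#' \eqn{p = (1 + \#\{index_{sim} \le index_{obs}\})/(n_{sim}+1)}. Nodes
#' with fewer than 3 leaves are not testable.
#'
#' @param x numeric matrix, one row per EL (leaves of the tree), columns
#'   are feature dimensions (e.g. eigenlipid sample profiles).
#' @param tree \code{hclust} over the rows of \code{x}.
#' @param n_sim Monte Carlo replicates per node (>= 99).
#' @param seed integer seed.
#' @param alpha significance level for descending (default 0.05).
#' @return data.frame per internal node: node (hclust merge index),
#'   n_leaves, index, p (NA if untested), tested, significant.
#' @export
node_significance <- function(x, tree, n_sim = 499L, seed = 1L,
                              alpha = 0.05) {
  if (n_sim < 99L) stop("n_sim must be >= 99")
  n <- nrow(x)
  if (!is.null(tree$labels) && !is.null(rownames(x))) {
    x <- x[tree$labels, , drop = FALSE]
  }
  leaves_of <- node_leaves(tree)
  res <- data.frame(node = seq_len(nrow(tree$merge)),
                    n_leaves = vapply(leaves_of, length, integer(1)),
                    index = NA_real_, p = NA_real_,
                    tested = FALSE, significant = FALSE)
  with_seed(seed, 4L, {
    # walk top-down: root is the last merge
    queue <- nrow(tree$merge)
    while (length(queue) > 0L) {
      nd <- queue[1L]; queue <- queue[-1L]
      lv <- leaves_of[[nd]]
      if (length(lv) < 3L) next
      xi <- x[lv, , drop = FALSE]
      obs <- cluster_index_2(xi)
      sampler <- fit_gaussian_sampler(xi)
      sims <- vapply(seq_len(n_sim), function(b) {
        cluster_index_2(sampler(length(lv)))
      }, numeric(1))
      p <- (1 + sum(sims <= obs + 1e-12)) / (n_sim + 1)
      res$index[nd] <- obs
      res$p[nd] <- p
      res$tested[nd] <- TRUE
      if (p <= alpha) {
        res$significant[nd] <- TRUE
        kids <- tree$merge[nd, ]
        queue <- c(queue, kids[kids > 0L])
      }
    }
  })
  res
}

# list of leaf index sets per internal node of an hclust
node_leaves <- function(tree) {
  out <- vector("list", nrow(tree$merge))
  for (i in seq_len(nrow(tree$merge))) {
    kids <- tree$merge[i, ]
    lv <- integer(0)
    for (kd in kids) {
      lv <- c(lv, if (kd < 0L) -kd else out[[kd]])
    }
    out[[i]] <- sort(lv)
  }
  out
}
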