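#' Scale-free topology fit of a connectivity vector
#'
#' Regresses log10 of the binned connectivity density on log10 of the mean
#' binned connectivity; returns the R-squared, signed negative when the
#' slope is positive (scale-free topology requires a decreasing p(k)).
#'
#' @param k vector of node connectivities (>= 0).
#' @param n_bins number of equal-width connectivity bins.
#' @return list with \code{fit} (signed R-squared) and \code{slope}.
#' @export
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[is.finite(k)]
  if (length(unique(k)) < 3L) return(list(fit = NA_real_, slope = NA_real_))
  cuts <- cut(k, breaks = n_bins)
  dk <- tapply(k, cuts, mean)
  pk <- tapply(k, cuts, length) / length(k)
  ok <- !is.na(dk) & dk > 0 & !is.na(pk) & pk > 0
  if (sum(ok) < 3L) return(list(fit = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2L])
  list(fit = if (slope > 0) -r2 else r2, slope = slope)
}

#' Choose the soft-threshold power
#'
#' Evaluates candidate powers and returns the smallest whose signed
#' scale-free fit reaches \code{target}; if none does, the power with the
#' maximal fit is returned with a warning.
#'
#' @param clr \code{feature_table} in clr view (lipids x samples).
#' @param powers candidate powers (>= 2 values).
#' @param target required signed R-squared (default 0.8).
#' @param mode \code{"signed"} or \code{"unsigned"} adjacency.
#' @return list with \code{power}, \code{fit_table} (power, fit, slope,
#'   mean_k) and \code{reached_target}.
#' @export
pick_soft_threshold <- function(clr, powers = c(1:10, seq(12, 20, 2)),
                                target = 0.8,
                                mode = c("signed", "unsigned")) {
  mode <- match.arg(mode)
  stopifnot_view(clr, "clr")
  if (length(powers) < 2L) stop("need at least two candidate powers")
  x <- as_ft_matrix(clr)
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate features (constant across samples): ",
         paste(utils::head(rownames(x)[sds == 0], 5L), collapse = ", "))
  }
  cr <- stats::cor(t(x))
  rows <- lapply(powers, function(b) {
    a <- raw_adjacency(cr, b, mode)
    k <- colSums(a) - 1
    sf <- scale_free_fit(k)
    data.frame(power = b, fit = sf$fit, slope = sf$slope, mean_k = mean(k))
  })
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$fit) & tab$fit >= target)
  if (length(ok) > 0L) {
    power <- tab$power[min(ok)]
    reached <- TRUE
  } else {
    power <- tab$power[which.max(tab$fit)]
    reached <- FALSE
    warning("no candidate power reached the scale-free fit target ",
            target, "; using power ", power, " (max fit)")
  }
  list(power = power, fit_table = tab, reached_target = reached)
}

raw_adjacency <- function(cr, beta, mode) {
  a <- if (mode == "signed") ((1 + cr) / 2)^beta else abs(cr)^beta
  diag(a) <- 1
  a
}

#' Weighted network adjacency
#'
#' Signed: \eqn{a_{ij} = ((1 + cor_{ij})/2)^\beta}; unsigned:
#' \eqn{a_{ij} = |cor_{ij}|^\beta}. Correlation is Pearson on the CLR
#' values.
#'
#' @param clr \code{feature_table} in clr view.
#' @param beta soft-threshold power (>= 1).
#' @param mode \code{"signed"} (default) or \code{"unsigned"}.
#' @return list of class \code{network_matrices} with \code{cor},
#'   \code{adjacency}, \code{connectivity}, \code{beta}, \code{mode}.
#' @export
adjacency_matrix <- function(clr, beta = 6, mode = c("signed", "unsigned")) {
  mode <- match.arg(mode)
  stopifnot_view(clr, "clr")
  if (beta < 1) stop("soft-threshold power must be >= 1")
  x <- as_ft_matrix(clr)
  cr <- stats::cor(t(x))
  a <- raw_adjacency(cr, beta, mode)
  structure(list(cor = cr, adjacency = a,
                 connectivity = colSums(a) - 1,
                 beta = beta, mode = mode),
            class = "network_matrices")
}

#' Topological overlap matrix
#'
#' \eqn{TOM_{ij} = (L_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})} with
#' \eqn{L_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and \eqn{k_i = \sum_{j \ne
#' i} a_{ij}}; \eqn{TOM_{ii} = 1}.
#'
#' @param net \code{network_matrices} from \code{\link{adjacency_matrix}}.
#' @return symmetric TOM matrix in [0, 1] with unit diagonal.
#' @export
tom_similarity <- function(net) {
  a <- net$adjacency
  diag(a) <- 0
  k <- colSums(a)
  L <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (L + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(net$adjacency)
  tom
}

#' Detect co-occurring lipid modules
#'
#' Average-linkage hierarchical clustering of the dissimilarity 1 - TOM,
#' followed by an adaptive branch cut: candidate cut heights (midpoints
#' between consecutive merge heights, restricted to at most
#' \code{cut_frac} times the maximum merge height so that incoherent
#' near-root branches never qualify) are scanned, and the lowest height
#' maximising the number of branches of size >= \code{min_module_size} is
#' used. Everything outside a qualifying branch is sent to EL0; surviving
#' modules are relabelled EL1..ELn by decreasing size (ties by first
#' appearance). The tight (lowest) cut keeps module cores clean and leaves
#' loosely attached lipids unassigned rather than absorbing them.
#'
#' @param tom TOM matrix from \code{\link{tom_similarity}}.
#' @param min_module_size smallest branch kept as a module (>= 2).
#' @param cut_frac coherence ceiling: branches must fully form below this
#'   fraction of the maximum merge height (default 0.9).
#' @return list with \code{labels} (named integer vector, 0 = unassigned),
#'   \code{sizes} (named, EL1..), \code{tree} (hclust), \code{cut_height}.
#' @export
detect_modules <- function(tom, min_module_size = 10L, cut_frac = 0.9) {
  if (min_module_size < 2L) stop("min_module_size must be >= 2")
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  hmax <- max(tree$height)
  ceiling_h <- cut_frac * hmax
  hs <- sort(unique(c(tree$height[tree$height <= ceiling_h], ceiling_h)))
  # intervals of constant branch configuration: [h_i, h_{i+1})
  lo <- c(0, hs[-length(hs)])
  hi <- hs
  mids <- (lo + hi) / 2
  lens <- hi - lo
  counts <- vapply(mids, function(h) {
    sum(table(stats::cutree(tree, h = h)) >= min_module_size)
  }, numeric(1))
  if (all(counts == 0)) {
    labels <- rep(0L, nrow(tom))
    best_h <- ceiling_h
  } else {
    # most persistent positive branch count, then its longest stable run
    persist <- tapply(lens[counts > 0], counts[counts > 0], sum)
    best_count <- as.numeric(names(persist)[which.max(persist)])
    in_run <- counts == best_count
    run_id <- cumsum(c(TRUE, diff(in_run) != 0))
    run_len <- tapply(lens[in_run], run_id[in_run], sum)
    best_run <- names(run_len)[which.max(run_len)]
    idx <- which(in_run & run_id == as.integer(best_run))
    best_h <- (lo[idx[1L]] + hi[idx[length(idx)]]) / 2
    labels <- relabel_by_size(stats::cutree(tree, h = best_h),
                              min_module_size)
  }
  sizes <- table(labels[labels > 0L])
  list(labels = stats::setNames(labels, rownames(tom)),
       sizes = if (length(sizes)) {
         stats::setNames(as.integer(sizes), paste0("EL", names(sizes)))
       } else integer(0),
       tree = tree, cut_height = best_h)
}

# relabel branches: too-small ones -> 0; others 1..n by decreasing size
relabel_by_size <- function(raw, min_size) {
  tab <- table(raw)
  keep <- names(tab)[tab >= min_size]
  ord <- keep[order(-tab[keep], as.integer(keep))]
  new <- integer(length(raw))
  for (i in seq_along(ord)) new[raw == as.integer(ord[i])] <- i
  new
}

#' Eigenlipid profiles of detected modules
#'
#' Per module, the first principal component over samples of the member
#' CLR submatrix (members standardised per lipid), unit-norm and
#' sign-oriented to correlate positively with the module's mean member
#' profile. A size-1 module's eigenlipid is that lipid's standardised
#' profile (unit-norm).
#'
#' @param clr \code{feature_table} in clr view.
#' @param labels module labels from \code{\link{detect_modules}} (named, 0
#'   = unassigned).
#' @return object of class \code{eigenlipid_set}: list with
#'   \code{profiles} (samples x EL matrix), \code{loadings} (per EL, named
#'   lipid weights), \code{singular_values}, \code{explained_variance},
#'   \code{scaling} (per-lipid mean/sd used), \code{labels}, \code{sizes}.
#' @export
compute_eigenlipids <- function(clr, labels) {
  stopifnot_view(clr, "clr")
  x <- as_ft_matrix(clr)
  labels <- labels[rownames(x)]
  mods <- sort(unique(labels[labels > 0L]))
  if (length(mods) == 0L) stop("no modules to summarise")
  profiles <- matrix(NA_real_, ncol(x), length(mods),
                     dimnames = list(colnames(x), paste0("EL", mods)))
  loadings <- list(); dvals <- numeric(length(mods))
  expl <- numeric(length(mods))
  mu <- rowMeans(x); sdv <- apply(x, 1L, stats::sd)
  for (j in seq_along(mods)) {
    mem <- names(labels)[labels == mods[j]]
    xs <- t((x[mem, , drop = FALSE] - mu[mem]) / pmax(sdv[mem], 1e-12))
    sv <- svd(xs)
    e <- sv$u[, 1L]
    mean_prof <- rowMeans(xs)
    if (stats::cor(e, mean_prof) < 0) {
      e <- -e
      sv$v[, 1L] <- -sv$v[, 1L]
    }
    profiles[, j] <- e
    loadings[[j]] <- stats::setNames(sv$v[, 1L], mem)
    dvals[j] <- sv$d[1L]
    expl[j] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  names(loadings) <- colnames(profiles)
  structure(list(profiles = profiles, loadings = loadings,
                 singular_values = stats::setNames(dvals,
                                                   colnames(profiles)),
                 explained_variance = stats::setNames(expl,
                                                      colnames(profiles)),
                 scaling = list(mean = mu, sd = sdv),
                 labels = labels,
                 sizes = stats::setNames(
                   as.integer(table(labels[labels > 0L])),
                   paste0("EL", mods))),
            class = "eigenlipid_set")
}

#' @export
print.eigenlipid_set <- function(x, ...) {
  cat(sprintf("<eigenlipid_set> %d modules over %d samples; sizes: %s\n",
              ncol(x$profiles), nrow(x$profiles),
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Module membership scores
#'
#' Spearman rank correlation over samples between each lipid's CLR profile
#' and each eigenlipid profile. Constant profiles yield NA.
#'
#' @param clr \code{feature_table} in clr view.
#' @param els \code{eigenlipid_set}.
#' @return list with \code{scores} (lipid x EL matrix of Spearman rho) and
#'   \code{own_module_median} (per EL, median |rho| of its members).
#' @export
membership_scores <- function(clr, els) {
  stopifnot_view(clr, "clr")
  x <- as_ft_matrix(clr)[, rownames(els$profiles), drop = FALSE]
  rho <- suppressWarnings(
    stats::cor(t(x), els$profiles, method = "spearman"))
  sds <- apply(x, 1L, stats::sd)
  rho[sds == 0, ] <- NA_real_
  own <- vapply(colnames(rho), function(el) {
    m <- as.integer(sub("^EL", "", el))
    mem <- intersect(names(els$labels)[els$labels == m], rownames(rho))
    if (length(mem) == 0L) return(NA_real_)
    stats::median(abs(rho[mem, el]), na.rm = TRUE)
  }, numeric(1))
  list(scores = rho, own_module_median = own)
}

#' Project reference eigenlipids into new samples
#'
#' New-sample eigenlipid values are the projection of the new CLR data
#' (standardised with the reference per-lipid scaling) onto the reference
#' first-PC loadings, divided by the reference singular value so that
#' projecting the training data reproduces \code{compute_eigenlipids}
#' exactly. Lipids absent from the new data are dropped and the loadings
#' renormalised; the retained-loading fraction is reported per EL.
#'
#' @param clr_new \code{feature_table} (clr) for the new samples.
#' @param els reference \code{eigenlipid_set}.
#' @return list with \code{profiles} (new samples x EL; NA where no lipid
#'   overlaps) and \code{overlap} (per EL fraction of loading norm
#'   retained).
#' @export
project_region <- function(clr_new, els) {
  stopifnot_view(clr_new, "clr")
  x <- as_ft_matrix(clr_new)
  out <- matrix(NA_real_, ncol(x), ncol(els$profiles),
                dimnames = list(colnames(x), colnames(els$profiles)))
  overlap <- stats::setNames(numeric(ncol(out)), colnames(out))
  for (el in colnames(out)) {
    v <- els$loadings[[el]]
    present <- intersect(names(v), rownames(x))
    overlap[el] <- if (length(v)) {
      sqrt(sum(v[present]^2)) / sqrt(sum(v^2))
    } else 0
    if (length(present) == 0L) {
      warning("no overlapping lipids for ", el, "; projection missing")
      next
    }
    vp <- v[present] / sqrt(sum(v[present]^2))
    xs <- t((x[present, , drop = FALSE] - els$scaling$mean[present]) /
              pmax(els$scaling$sd[present], 1e-12))
    out[, el] <- as.numeric(xs %*% vp) / els$singular_values[el]
  }
  list(profiles = out, overlap = overlap)
}

#' In-group proportion reproducibility test
#'
#' In validation data, each reference-module member lipid is assigned to
#' the nearest module centroid (mean member CLR profile over validation
#' samples) by Pearson correlation distance, leaving the lipid itself out
#' of its own centroid. The in-group proportion (IGP) of a module is the
#' fraction of its members whose nearest centroid is their own. The null
#' distribution is built by relabelling lipids at random (preserving module
#' sizes) and recomputing centroids and IGP; \eqn{p = (1 + \#\{IGP_{null}
#' \ge IGP_{obs}\}) / (n_{perm} + 1)}.
#'
#' @param clr_val \code{feature_table} (clr) of validation samples (>= 3).
#' @param els reference \code{eigenlipid_set} (labels are taken from it).
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the permutations.
#' @return data.frame per EL: \code{el}, \code{igp}, \code{p},
#'   \code{n_members}, \code{n_perm}, \code{seed}; modules with no member
#'   present in the validation data are skipped with a note attribute.
#' @export
igp_reproducibility <- function(clr_val, els, n_perm = 199L, seed = 1L) {
  stopifnot_view(clr_val, "clr")
  if (ncol(clr_val) < 3L) stop("need >= 3 validation samples")
  if (n_perm < 99L) stop("n_perm must be >= 99")
  x <- as_ft_matrix(clr_val)
  labels <- els$labels[names(els$labels) %in% rownames(x)]
  labels <- labels[labels > 0L]
  skipped <- setdiff(paste0("EL", sort(unique(els$labels[els$labels > 0L]))),
                     paste0("EL", sort(unique(labels))))
  lip <- names(labels)
  xm <- x[lip, , drop = FALSE]
  mods <- sort(unique(labels))
  k <- length(mods)

  # leave-one-out nearest-centroid assignment, per-module hit rates
  igp_by_module <- function(lab) {
    sums <- rowsum(xm, group = lab)
    cnt <- as.integer(table(factor(lab, levels = rownames(sums))))
    names(cnt) <- rownames(sums)
    hit <- logical(length(lab))
    for (i in seq_along(lab)) {
      r <- match(as.character(lab[i]), rownames(sums))
      cent <- sums / cnt
      if (cnt[r] > 1L) {
        cent[r, ] <- (sums[r, ] - xm[i, ]) / (cnt[r] - 1L)
      } else {
        cent[r, ] <- NA_real_
      }
      d <- suppressWarnings(1 - stats::cor(xm[i, ], t(cent)))
      d[is.na(d)] <- Inf
      hit[i] <- which.min(d) == r
    }
    tapply(hit, factor(lab, levels = mods), mean)
  }

  obs <- igp_by_module(labels)
  null_mat <- matrix(NA_real_, n_perm, k)
  with_seed(seed, 3L, {
    for (b in seq_len(n_perm)) {
      null_mat[b, ] <- igp_by_module(sample(labels))
    }
  })
  p <- vapply(seq_len(k), function(j) {
    (1 + sum(null_mat[, j] >= obs[j] - 1e-12)) / (n_perm + 1)
  }, numeric(1))
  out <- data.frame(el = paste0("EL", mods),
                    igp = as.numeric(obs),
                    p = p,
                    n_members = as.integer(table(labels)),
                    n_perm = n_perm, seed = seed,
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  attr(out, "null_igp") <- structure(null_mat,
                                     dimnames = list(NULL,
                                                     paste0("EL", mods)))
  out
}
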