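#' Chain length versus temperature regression
#'
#' Ordinary least squares of the per-sample intensity-weighted mean
#' carbons per fatty acid (membrane glycerolipids of one saturation class,
#' mixed-layer samples) on in situ temperature.
#'
#' @param features \code{feature_table} (raw or relative; the weighted
#'   mean is scale-invariant per sample).
#' @param species parsed + classified species table.
#' @param metadata sample metadata (temperature_c, depth_m, mld_m).
#' @param saturation "SFA/MUFA" or "PUFA-containing".
#' @param mixed_layer_only restrict to mixed-layer samples (default TRUE).
#' @return list: slope, intercept, r_squared, slope_se, slope_ci (95%),
#'   n, data (temperature, chain length per sample), model.
#' @export
chain_length_vs_temperature <- function(features, species, metadata,
                                        saturation = c("SFA/MUFA",
                                                       "PUFA-containing"),
                                        mixed_layer_only = TRUE) {
  saturation <- match.arg(saturation)
  md <- metadata[match(colnames(features), metadata$sample_id), ]
  keep_samples <- if (mixed_layer_only) in_mixed_layer(md) else
    rep(TRUE, nrow(md))
  sp <- species[match(rownames(features), species$id), ]
  sel <- sp$is_membrane & sp$species_class == saturation
  if (!any(sel)) stop("no membrane species in saturation class ", saturation)
  cl <- weighted_mean_chain_length(features, species,
                                   rownames(features)[sel])
  df <- data.frame(temperature = md$temperature_c[keep_samples],
                   chain_length = cl[keep_samples])
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 3L) stop("need >= 3 samples for the regression")
  fit <- stats::lm(chain_length ~ temperature, data = df)
  sm <- summary(fit)
  ci <- stats::confint(fit)["temperature", ]
  list(slope = unname(stats::coef(fit)["temperature"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       r_squared = sm$r.squared,
       slope_se = sm$coefficients["temperature", "Std. Error"],
       slope_ci = unname(ci),
       n = nrow(df), data = df, model = fit)
}

#' PCA of module intensities with environmental covariate projections
#'
#' PCA of the standardised sample x EL intensity matrix; environmental
#' covariates are projected as supplementary loading vectors (their
#' correlations with the score axes), and each EL's loading is projected
#' onto each covariate direction (longer projection = stronger
#' association).
#'
#' @param el_table samples x EL matrix.
#' @param metadata sample metadata.
#' @param covariates metadata column names (constant columns dropped with
#'   a note).
#' @param n_axes number of principal axes for the projections (default 2).
#' @return list: scores, el_loadings (scaled by axis sd), covariate_vectors
#'   (correlation with scores), projection (EL x covariate projection
#'   lengths), explained (variance fractions), dropped.
#' @export
pca_el_environment <- function(el_table, metadata,
                               covariates = c("temperature_c", "po4_um",
                                              "depth_m"),
                               n_axes = 2L) {
  md <- metadata[match(rownames(el_table), metadata$sample_id), ]
  keep <- covariates[vapply(covariates, function(cv) {
    v <- md[[cv]]
    !is.null(v) && stats::sd(v, na.rm = TRUE) > 0
  }, logical(1))]
  dropped <- setdiff(covariates, keep)
  if (length(keep) == 0L) stop("no usable covariates")
  pc <- stats::prcomp(el_table, center = TRUE, scale. = TRUE)
  ax <- seq_len(min(n_axes, ncol(pc$x)))
  scores <- pc$x[, ax, drop = FALSE]
  el_load <- sweep(pc$rotation[, ax, drop = FALSE], 2L, pc$sdev[ax], "*")
  cov_vec <- vapply(keep, function(cv) {
    stats::cor(md[[cv]], scores)[1, ]
  }, numeric(length(ax)))
  cov_vec <- matrix(cov_vec, nrow = length(ax),
                    dimnames = list(colnames(scores), keep))
  proj <- matrix(NA_real_, ncol(el_table), length(keep),
                 dimnames = list(colnames(el_table), keep))
  for (cv in keep) {
    v <- cov_vec[, cv]
    nv <- sqrt(sum(v^2))
    proj[, cv] <- if (nv == 0) 0 else as.numeric(el_load %*% (v / nv))
  }
  list(scores = scores, el_loadings = el_load, covariate_vectors = cov_vec,
       projection = proj,
       explained = pc$sdev^2 / sum(pc$sdev^2),
       dropped = dropped)
}

#' Random-forest attribution of environmental drivers
#'
#' Random-forest regression of a response on environmental predictors with
#' a 70:30 train-test split; impurity importances are normalised to sum to
#' one and scaled by max(test R-squared, 0). Individual conditional
#' expectation (ICE) curves are computed per test-set sample on a grid
#' over each predictor's observed range.
#'
#' @param X data.frame of predictors (e.g. temperature and phosphate).
#' @param y numeric response.
#' @param split training fraction (default 0.7).
#' @param seed integer seed (split and forest).
#' @param ntree forest size (default 500).
#' @param grid_points ICE grid resolution (default 50).
#' @param ice_max_curves cap on ICE curves kept (default 100).
#' @return list of class \code{rf_attribution}: r_squared,
#'   importance_raw (sums to 1), importance (scaled by R^2), ice (long
#'   data.frame: predictor, curve_id, grid_value, prediction), model,
#'   seed, n_train, n_test.
#' @export
rf_attribution <- function(X, y, split = 0.7, seed = 1L, ntree = 500L,
                           grid_points = 50L, ice_max_curves = 100L) {
  X <- as.data.frame(X)
  if (nrow(X) < 30L) stop("need >= 30 samples for attribution")
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  with_seed(seed, 5L, {
    n <- nrow(X)
    tr <- sample(n, floor(split * n))
    te <- setdiff(seq_len(n), tr)
    rf <- randomForest::randomForest(
      X[tr, , drop = FALSE], y[tr], ntree = ntree, mtry = ncol(X),
      importance = FALSE)
    pred <- stats::predict(rf, X[te, , drop = FALSE])
    ss_res <- sum((y[te] - pred)^2)
    ss_tot <- sum((y[te] - mean(y[te]))^2)
    r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
    imp <- randomForest::importance(rf, type = 2L)[, 1L]
    imp_raw <- if (sum(imp) > 0) imp / sum(imp) else
      stats::setNames(rep(0, length(imp)), names(imp))
    if (r2 < 0) {
      warning("held-out R^2 negative; scaled importances reported as 0")
    }
    imp_scaled <- imp_raw * max(r2, 0)

    ice_rows <- list()
    curves <- utils::head(te, ice_max_curves)
    for (pr in colnames(X)) {
      grid <- seq(min(X[[pr]]), max(X[[pr]]), length.out = grid_points)
      for (ci in seq_along(curves)) {
        xrep <- X[rep(curves[ci], grid_points), , drop = FALSE]
        xrep[[pr]] <- grid
        ice_rows[[length(ice_rows) + 1L]] <- data.frame(
          predictor = pr, curve_id = ci, grid_value = grid,
          prediction = as.numeric(stats::predict(rf, xrep)),
          stringsAsFactors = FALSE)
      }
    }
    structure(list(r_squared = r2, importance_raw = imp_raw,
                   importance = imp_scaled,
                   ice = do.call(rbind, ice_rows),
                   model = rf, seed = seed,
                   n_train = length(tr), n_test = length(te)),
              class = "rf_attribution")
  })
}

#' Per-sample class shares among SFA/MUFA lipids
#'
#' For each sample, the intensity of each lipid class restricted to
#' SFA/MUFA species divided by the total SFA/MUFA intensity; shares sum to
#' 1 per sample (NA when a sample has no SFA/MUFA intensity).
#'
#' @param features \code{feature_table} (raw or relative).
#' @param species classified species table.
#' @return matrix samples x class.
#' @export
sfa_mufa_class_intensity <- function(features, species) {
  x <- as_ft_matrix(features)
  sp <- species[match(rownames(x), species$id), ]
  sel <- sp$species_class == "SFA/MUFA"
  if (!any(sel)) stop("no SFA/MUFA species present")
  xs <- x[sel, , drop = FALSE]
  cls <- sp$headgroup[sel]
  tot <- colSums(xs)
  shares <- t(rowsum(xs, cls)) / ifelse(tot > 0, tot, NA)
  shares
}

#' Module ratio across sea-surface temperature, by layer
#'
#' The per-sample ratio a/(a+b) of two module intensities, summarised in
#' SST bins for mixed-layer and DCM samples: bootstrap 95% confidence
#' intervals of the bin mean per layer, a two-sided Welch t test of the
#' layer difference per bin (BH-adjusted), and a flag for bins where the
#' DCM ratio significantly exceeds the mixed-layer one.
#'
#' @param el_table samples x EL matrix containing the two columns.
#' @param el_a,el_b column names (ratio = a / (a + b)).
#' @param metadata sample metadata.
#' @param layer named character vector over samples ("mixed", "dcm",
#'   other), e.g. from \code{\link{assign_layer}}.
#' @param bin_width SST bin width in degrees C (default 2).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return data.frame per (bin, layer): sst_mid, layer, n, mean_ratio,
#'   ci_lo, ci_hi, and per bin: p, p_adj, dcm_higher.
#' @export
el_ratio_by_sst <- function(el_table, el_a, el_b, metadata, layer,
                            bin_width = 2, n_boot = 1000L, seed = 1L) {
  if (!all(c(el_a, el_b) %in% colnames(el_table))) {
    stop("ratio modules not present in the intensity table")
  }
  md <- metadata[match(rownames(el_table), metadata$sample_id), ]
  sst <- station_sst(metadata)[md$station]
  a <- el_table[, el_a]; b <- el_table[, el_b]
  denom <- a + b
  ratio <- ifelse(denom > 0, a / denom, NA)
  lay <- layer[rownames(el_table)]
  use <- !is.na(ratio) & lay %in% c("mixed", "dcm") & !is.na(sst)
  bins <- floor(sst / bin_width) * bin_width + bin_width / 2
  df <- data.frame(ratio = ratio[use], layer = lay[use], bin = bins[use])

  boot_ci <- function(v) {
    if (length(v) < 3L) return(c(NA_real_, NA_real_))
    means <- vapply(seq_len(n_boot), function(b) {
      mean(v[sample.int(length(v), replace = TRUE)])
    }, numeric(1))
    stats::quantile(means, c(0.025, 0.975), names = FALSE)
  }

  with_seed(seed, 6L, {
    rows <- list(); tests <- list()
    for (bn in sort(unique(df$bin))) {
      for (ly in c("mixed", "dcm")) {
        v <- df$ratio[df$bin == bn & df$layer == ly]
        ci <- boot_ci(v)
        rows[[length(rows) + 1L]] <- data.frame(
          sst_mid = bn, layer = ly, n = length(v),
          mean_ratio = if (length(v)) mean(v) else NA_real_,
          ci_lo = ci[1L], ci_hi = ci[2L], stringsAsFactors = FALSE)
      }
      vm <- df$ratio[df$bin == bn & df$layer == "mixed"]
      vd <- df$ratio[df$bin == bn & df$layer == "dcm"]
      p <- if (length(vm) >= 3L && length(vd) >= 3L &&
               (stats::sd(vm) > 0 || stats::sd(vd) > 0)) {
        stats::t.test(vd, vm)$p.value
      } else NA_real_
      tests[[length(tests) + 1L]] <- data.frame(
        sst_mid = bn, p = p,
        diff = if (length(vd) && length(vm)) mean(vd) - mean(vm) else
          NA_real_,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    tst <- do.call(rbind, tests)
    tst$p_adj <- bh_adjust(tst$p)
    tst$dcm_higher <- !is.na(tst$p_adj) & tst$p_adj < 0.05 & tst$diff > 0
    merge(out, tst, by = "sst_mid", all.x = TRUE)
  })
}

#' Sea-surface temperature per station
#'
#' Temperature of the shallowest sampled depth of each station.
#'
#' @param metadata sample metadata.
#' @return named numeric vector over stations.
#' @export
station_sst <- function(metadata) {
  vapply(split(metadata, metadata$station), function(md) {
    md$temperature_c[which.min(md$depth_m)]
  }, numeric(1))
}

#' Assign samples to water-column layers
#'
#' "mixed" when depth <= the station mixed-layer depth; "dcm" when depth
#' is the sampled depth closest to the station DCM (and below the mixed
#' layer); "other" otherwise.
#'
#' @param metadata sample metadata.
#' @param dcm optional data.frame from \code{\link{dcm_depth}}; defaults
#'   to computing it from the fluorescence profiles.
#' @return named character vector over sample ids.
#' @export
assign_layer <- function(metadata, dcm = NULL) {
  if (is.null(dcm)) dcm <- dcm_depth(metadata)
  dcm_of <- stats::setNames(dcm$dcm_m, dcm$station)
  out <- rep("other", nrow(metadata))
  ml <- in_mixed_layer(metadata)
  out[ml] <- "mixed"
  for (st in unique(metadata$station)) {
    i <- which(metadata$station == st)
    d0 <- dcm_of[st]
    if (is.na(d0)) next
    j <- i[which.min(abs(metadata$depth_m[i] - d0))]
    if (!ml[j]) out[j] <- "dcm"
  }
  stats::setNames(out, metadata$sample_id)
}

#' PUFA layer contrast per lipid class
#'
#' For each lipid class: the per-sample relative intensity of its
#' PUFA-containing species (as a fraction of total annotated intensity)
#' compared between DCM and mixed-layer samples with a two-sided Welch t
#' test and Cohen's d (DCM minus mixed), BH adjustment across classes.
#' Classes with fewer than \code{min_n} samples in a layer are skipped.
#'
#' @param features \code{feature_table} (raw view).
#' @param species classified species table.
#' @param layer named layer vector from \code{\link{assign_layer}}.
#' @param min_n minimum samples per layer (default 3).
#' @return data.frame: class, d, p, p_adj, n_dcm, n_mixed, dcm_higher.
#' @export
pufa_layer_contrast <- function(features, species, layer, min_n = 3L) {
  stopifnot_view(features, "raw")
  x <- as_ft_matrix(features)
  sp <- species[match(rownames(x), species$id), ]
  tot <- colSums(x)
  lay <- layer[colnames(x)]
  cls_with_pufa <- sort(unique(
    sp$headgroup[sp$species_class == "PUFA-containing"]))
  if (length(cls_with_pufa) == 0L) stop("no PUFA-containing species")
  rows <- list()
  for (cl in cls_with_pufa) {
    sel <- sp$headgroup == cl & sp$species_class == "PUFA-containing"
    ri <- colSums(x[sel, , drop = FALSE]) / tot
    vd <- ri[lay == "dcm"]; vm <- ri[lay == "mixed"]
    if (length(vd) < min_n || length(vm) < min_n) next
    d <- cohens_d(vd, vm)
    p <- if (stats::sd(vd) > 0 || stats::sd(vm) > 0) {
      stats::t.test(vd, vm)$p.value
    } else 1
    rows[[length(rows) + 1L]] <- data.frame(
      class = cl, d = d, p = p, n_dcm = length(vd), n_mixed = length(vm),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no class sampled in both layers")
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$dcm_higher <- out$p_adj < 0.05 & out$d > 0
  out
}

#' EPA maximum depth versus the DCM
#'
#' Per station: the sampled depth at which the summed intensity of
#' EPA-containing species (any 20:5 chain) is maximal (ties shallowest),
#' its difference from the DCM depth, and a Wilcoxon signed-rank test of
#' the differences against zero.
#'
#' @param features \code{feature_table} (raw view).
#' @param species classified species table (needs \code{has_epa}).
#' @param metadata sample metadata.
#' @param dcm optional precomputed \code{\link{dcm_depth}} result.
#' @return list: per_station (station, epa_depth_m, dcm_m, difference_m,
#'   flat), p (signed-rank), median_difference.
#' @export
epa_depth_vs_dcm <- function(features, species, metadata, dcm = NULL) {
  stopifnot_view(features, "raw")
  x <- as_ft_matrix(features)
  sp <- species[match(rownames(x), species$id), ]
  if (!any(sp$has_epa)) stop("no EPA (20:5) species in the table")
  epa <- colSums(x[sp$has_epa, , drop = FALSE])
  if (is.null(dcm)) dcm <- dcm_depth(metadata)
  dcm_of <- stats::setNames(dcm$dcm_m, dcm$station)
  md <- metadata[match(colnames(x), metadata$sample_id), ]
  rows <- list()
  for (st in unique(md$station)) {
    i <- which(md$station == st)
    if (length(i) < 2L || is.na(dcm_of[st])) next
    i <- i[order(md$depth_m[i])]
    v <- epa[i]
    flat <- length(unique(v)) == 1L
    depth <- md$depth_m[i][which.max(v)]
    rows[[length(rows) + 1L]] <- data.frame(
      station = st, epa_depth_m = depth, dcm_m = unname(dcm_of[st]),
      difference_m = depth - unname(dcm_of[st]), flat = flat,
      stringsAsFactors = FALSE)
  }
  per_station <- do.call(rbind, rows)
  diffs <- per_station$difference_m
  p <- if (all(diffs == 0)) 1 else {
    suppressWarnings(stats::wilcox.test(diffs, mu = 0)$p.value)
  }
  list(per_station = per_station, p = p,
       median_difference = stats::median(diffs))
}
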