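#' Structural profiles of modules
#'
#' Intensity-weighted structural summaries per EL: headgroup composition,
#' mean chain length (carbons per FA), mean double bonds per chain,
#' saturation-class fractions, phosphorus-free fraction and odd-chain
#' fraction. Weights are each species' mean relative intensity across
#' samples. ELs with fewer than \code{min_annotated} species carrying a
#' recognised headgroup are excluded (reported in the \code{excluded}
#' attribute).
#'
#' @param labels named module labels (0 = unassigned, excluded).
#' @param species parsed + saturation-classified species table.
#' @param features \code{feature_table} in relative view (for weights).
#' @param min_annotated minimum recognised-headgroup species per EL
#'   (default 5).
#' @return data.frame, one row per retained EL, with list-column-free
#'   numeric fields plus a \code{headgroup_composition} attribute (EL x
#'   headgroup fraction matrix).
#' @export
structural_profiles <- function(labels, species, features,
                                min_annotated = 5L) {
  stopifnot_view(features, "relative")
  x <- as_ft_matrix(features)
  lab <- labels[rownames(x)]
  mods <- sort(unique(lab[lab > 0L]))
  sp <- species[match(rownames(x), species$id), ]
  w_all <- rowMeans(x)
  hg_levels <- sort(unique(sp$headgroup))
  rows <- list(); comp <- list(); excluded <- character(0)
  for (m in mods) {
    el <- paste0("EL", m)
    i <- which(lab == m)
    annotated <- i[sp$headgroup[i] != "other"]
    if (length(annotated) < min_annotated) {
      excluded <- c(excluded, el)
      next
    }
    w <- w_all[annotated]
    s <- sp[annotated, ]
    wn <- w / sum(w)
    hg_frac <- vapply(hg_levels, function(h) {
      sum(wn[s$headgroup == h])
    }, numeric(1))
    db_per_chain <- s$total_double_bonds / s$n_chains
    cpf <- s$total_carbons / s$n_chains
    odd <- vapply(seq_len(nrow(s)), function(j) {
      if (is.na(s$chains[j])) {
        as.numeric(s$total_carbons[j] %% 2L == 1L)
      } else {
        ch <- strsplit(s$chains[j], "/")[[1]]
        carb <- as.integer(vapply(strsplit(ch, ":"), `[[`, "", 1L))
        mean(carb %% 2L == 1L)
      }
    }, numeric(1))
    rows[[el]] <- data.frame(
      el = el,
      n_species = length(annotated),
      mean_chain_length = sum(wn * cpf),
      mean_double_bonds = sum(wn * db_per_chain),
      frac_pufa = sum(wn[s$species_class == "PUFA-containing"]),
      frac_phosphorus_free = sum(wn[!s$has_phosphorus]),
      frac_odd_chain = sum(wn * odd),
      frac_chloroplast = sum(wn[s$is_chloroplast]),
      frac_betaine = sum(wn[s$is_betaine]),
      stringsAsFactors = FALSE)
    comp[[el]] <- hg_frac
  }
  if (length(rows) == 0L) stop("no EL retains enough annotated species")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "headgroup_composition") <- do.call(rbind, comp)
  attr(out, "excluded") <- excluded
  out
}

#' Per-sample, per-module structural property values
#'
#' Intensity-weighted structural property (e.g. mean chain length) of each
#' EL within each sample, the long-format input of
#' \code{\link{property_mixed_model}}.
#'
#' @param features \code{feature_table} (relative view).
#' @param labels named module labels.
#' @param species parsed species table.
#' @param property one of "chain_length", "double_bonds", "pufa_fraction".
#' @return data.frame: sample, el, value.
#' @export
property_by_sample_el <- function(features, labels, species,
                                  property = c("chain_length",
                                               "double_bonds",
                                               "pufa_fraction")) {
  property <- match.arg(property)
  stopifnot_view(features, "relative")
  x <- as_ft_matrix(features)
  lab <- labels[rownames(x)]
  sp <- species[match(rownames(x), species$id), ]
  val <- switch(property,
    chain_length = sp$total_carbons / sp$n_chains,
    double_bonds = sp$total_double_bonds / sp$n_chains,
    pufa_fraction = as.numeric(sp$species_class == "PUFA-containing"))
  mods <- sort(unique(lab[lab > 0L]))
  rows <- list()
  for (m in mods) {
    i <- which(lab == m)
    w <- x[i, , drop = FALSE]
    tot <- colSums(w)
    v <- colSums(w * val[i]) / ifelse(tot > 0, tot, NA)
    rows[[length(rows) + 1L]] <- data.frame(
      sample = colnames(x), el = paste0("EL", m), value = v,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mixed-effects model of structural differences between modules
#'
#' Random-intercept model \code{value ~ el + (1 | sample)} fit by REML
#' (reference-coded EL fixed effects, sample-specific variation as the
#' random effect); coefficient significance by z statistics, BH-adjusted
#' across EL contrasts. If the mixed fit fails, a fixed-effects model with
#' cluster-robust (sample-clustered sandwich) standard errors is used and
#' flagged.
#'
#' @param df long data.frame from \code{\link{property_by_sample_el}}.
#' @return list with \code{coefficients} (data.frame: term, estimate, se,
#'   z, p, p_adj), \code{random_intercept_sd}, \code{fallback} flag,
#'   \code{model}.
#' @export
property_mixed_model <- function(df) {
  df <- df[stats::complete.cases(df), ]
  if (length(unique(df$sample)) < 10L) {
    stop("need >= 10 samples for the mixed model")
  }
  df$el <- factor(df$el)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(value ~ el + (1 | sample), data = df, REML = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    sm <- summary(fit)$coefficients
    ri_sd <- sqrt(as.numeric(lme4::VarCorr(fit)$sample[1L]))
    fallback <- FALSE
  } else {
    lmfit <- stats::lm(value ~ el, data = df)
    sm <- cluster_robust_coefs(lmfit, df$sample)
    ri_sd <- NA_real_
    fallback <- TRUE
  }
  est <- sm[, 1L]; se <- sm[, 2L]
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  contrasts <- grepl("^el", rownames(sm))
  p_adj <- rep(NA_real_, length(p))
  p_adj[contrasts] <- bh_adjust(p[contrasts])
  list(coefficients = data.frame(term = rownames(sm), estimate = est,
                                 se = se, z = z, p = p, p_adj = p_adj,
                                 row.names = NULL,
                                 stringsAsFactors = FALSE),
       random_intercept_sd = ri_sd,
       fallback = fallback,
       model = if (is.null(fit)) NULL else fit)
}

# CR0 cluster-robust covariance for lm, by hand (no extra dependency)
cluster_robust_coefs <- function(fit, cluster) {
  X <- stats::model.matrix(fit)
  u <- stats::resid(fit)
  xtx_inv <- solve(crossprod(X))
  meat <- matrix(0, ncol(X), ncol(X))
  for (g in split(seq_along(u), cluster)) {
    xg <- X[g, , drop = FALSE]
    sg <- crossprod(xg, u[g])
    meat <- meat + tcrossprod(sg)
  }
  vc <- xtx_inv %*% meat %*% xtx_inv
  cbind(Estimate = stats::coef(fit), `Std. Error` = sqrt(diag(vc)))
}

#' Structural dendrogram over modules
#'
#' Gower-type distance over the structural profile fields: ranged numeric
#' fields (mean chain length, mean double bonds, PUFA fraction,
#' phosphorus-free fraction, odd-chain fraction) each contribute
#' |difference| / observed range, and the headgroup composition contributes
#' its total-variation distance (half the L1 distance); the distance is
#' the mean over valid fields. Constant fields are dropped with a note.
#' Average-linkage clustering.
#'
#' @param profiles result of \code{\link{structural_profiles}}.
#' @return list with \code{tree} (hclust), \code{distance} (matrix),
#'   \code{dropped_fields}, \code{cophenetic}.
#' @export
structural_dendrogram <- function(profiles) {
  if (nrow(profiles) < 3L) stop("need >= 3 retained ELs")
  num_fields <- c("mean_chain_length", "mean_double_bonds", "frac_pufa",
                  "frac_phosphorus_free", "frac_odd_chain")
  comp <- attr(profiles, "headgroup_composition")
  n <- nrow(profiles)
  contribs <- list(); dropped <- character(0)
  for (f in num_fields) {
    v <- profiles[[f]]
    rng <- diff(range(v))
    if (rng == 0) { dropped <- c(dropped, f); next }
    contribs[[f]] <- abs(outer(v, v, "-")) / rng
  }
  if (!is.null(comp)) {
    tv <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        tv[i, j] <- sum(abs(comp[i, ] - comp[j, ])) / 2
      }
    }
    if (any(tv > 0)) contribs[["headgroup_composition"]] <- tv
    else dropped <- c(dropped, "headgroup_composition")
  }
  if (length(contribs) == 0L) stop("all structural fields are constant")
  d <- Reduce(`+`, contribs) / length(contribs)
  dimnames(d) <- list(profiles$el, profiles$el)
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  list(tree = tree, distance = d, dropped_fields = dropped,
       cophenetic = cophenetic_correlation(tree, d))
}

# ---- tanglegram entanglement ----------------------------------------------

# leaf order of an hclust given a flip state per internal node
leaf_order_flipped <- function(tree, flips) {
  n_nodes <- nrow(tree$merge)
  rec <- function(nd) {
    kids <- tree$merge[nd, ]
    if (flips[nd]) kids <- rev(kids)
    unlist(lapply(kids, function(kd) {
      if (kd < 0L) -kd else rec(kd)
    }))
  }
  idx <- rec(n_nodes)
  tree$labels[idx]
}

entanglement_score <- function(order_left, order_right, L) {
  n <- length(order_left)
  r_left <- seq_len(n)
  r_right <- match(order_left, order_right)
  num <- sum(abs(r_left - r_right)^L)
  denom <- sum(abs(seq_len(n) - rev(seq_len(n)))^L)
  if (denom == 0) 0 else num / denom
}

#' Tanglegram entanglement between two dendrograms
#'
#' Entanglement is the normalised sum of absolute leaf-rank discrepancies
#' \eqn{\sum_i |r_{left}(i) - r_{right}(i)|^L}, divided by the value of the
#' fully reversed configuration; 0 means identical leaf orders, 1 the worst
#' case. Before scoring, a two-sided stepwise untangling heuristic flips
#' internal branches of either tree (alternating sides) while the score
#' improves.
#'
#' @param left,right \code{hclust} trees over the same leaf set.
#' @param L rank-difference exponent (default 1.5).
#' @param untangle apply the stepwise heuristic (default TRUE).
#' @param max_rounds maximum alternating passes.
#' @return list of class \code{tanglegram_result}: \code{entanglement}
#'   (after untangling), \code{entanglement_raw} (input orders),
#'   \code{order_left}, \code{order_right}, \code{L}.
#' @export
entanglement <- function(left, right, L = 1.5, untangle = TRUE,
                         max_rounds = 10L) {
  if (is.null(left$labels)) left$labels <- as.character(seq_along(left$order))
  if (is.null(right$labels)) {
    right$labels <- as.character(seq_along(right$order))
  }
  if (!setequal(left$labels, right$labels)) {
    stop("leaf sets differ: ",
         paste(c(setdiff(left$labels, right$labels),
                 setdiff(right$labels, left$labels)), collapse = ", "))
  }
  fl <- rep(FALSE, nrow(left$merge))
  fr <- rep(FALSE, nrow(right$merge))
  score <- function(fl, fr) {
    entanglement_score(leaf_order_flipped(left, fl),
                       leaf_order_flipped(right, fr), L)
  }
  raw <- score(fl, fr)
  best <- raw
  if (untangle) {
    for (round in seq_len(max_rounds)) {
      improved <- FALSE
      for (side in c("left", "right")) {
        nf <- if (side == "left") length(fl) else length(fr)
        for (nd in seq_len(nf)) {
          fl2 <- fl; fr2 <- fr
          if (side == "left") fl2[nd] <- !fl2[nd] else fr2[nd] <- !fr2[nd]
          s <- score(fl2, fr2)
          if (s < best - 1e-12) {
            best <- s; fl <- fl2; fr <- fr2; improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
  }
  structure(list(entanglement = best, entanglement_raw = raw,
                 order_left = leaf_order_flipped(left, fl),
                 order_right = leaf_order_flipped(right, fr),
                 L = L),
            class = "tanglegram_result")
}

#' Export a dendrogram as Newick text
#'
#' @param tree an \code{hclust}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
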