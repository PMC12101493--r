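#' Per-sample relative intensity of each module
#'
#' For each sample and module, the summed raw intensity of member lipids
#' divided by the total intensity of all annotated lipids in the sample.
#' The EL0/unassigned share plus the module shares sum to 1.
#'
#' @param features \code{feature_table} in raw view.
#' @param labels named module labels (0 = unassigned) covering the feature
#'   rows.
#' @return matrix samples x EL (columns EL1..ELn, plus \code{EL0}).
#' @export
el_relative_intensity <- function(features, labels) {
  stopifnot_view(features, "raw")
  x <- as_ft_matrix(features)
  if (!all(rownames(x) %in% names(labels))) {
    stop("labels do not cover all features")
  }
  lab <- labels[rownames(x)]
  tot <- colSums(x)
  if (any(tot <= 0)) {
    stop("sample(s) with zero total intensity: ",
         paste(colnames(x)[tot <= 0], collapse = ", "))
  }
  mods <- sort(unique(lab))
  out <- vapply(mods, function(m) {
    colSums(x[lab == m, , drop = FALSE]) / tot
  }, numeric(ncol(x)))
  if (is.null(dim(out))) out <- matrix(out, nrow = ncol(x))
  colnames(out) <- paste0("EL", mods)
  rownames(out) <- colnames(x)
  # order EL1..ELn first, EL0 last
  ord <- c(setdiff(colnames(out), "EL0"), intersect("EL0", colnames(out)))
  out[, ord, drop = FALSE]
}

#' Depth of maximum relative intensity per station and module
#'
#' For each station with at least two sampled depths, the sampled depth at
#' which each EL's relative intensity is maximal; ties resolve to the
#' shallowest depth. Single-depth stations are excluded and listed in the
#' \code{excluded} attribute.
#'
#' @param el_table samples x EL matrix from
#'   \code{\link{el_relative_intensity}}.
#' @param metadata sample metadata with \code{sample_id}, \code{station},
#'   \code{depth_m}.
#' @return data.frame station x EL of depths (long format: station, el,
#'   max_depth_m).
#' @export
el_maximum_depth <- function(el_table, metadata) {
  md <- metadata[match(rownames(el_table), metadata$sample_id), ]
  if (anyNA(md$station)) stop("metadata does not cover all samples")
  stations <- split(seq_len(nrow(el_table)), md$station)
  excluded <- names(stations)[vapply(stations, function(i) {
    length(unique(md$depth_m[i])) < 2L
  }, logical(1))]
  stations <- stations[!names(stations) %in% excluded]
  rows <- lapply(names(stations), function(st) {
    i <- stations[[st]]
    i <- i[order(md$depth_m[i])]          # shallowest-first tie rule
    depth <- md$depth_m[i]
    data.frame(station = st, el = colnames(el_table),
               max_depth_m = depth[apply(el_table[i, , drop = FALSE], 2L,
                                         which.max)],
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(station = character(0), el = character(0),
               max_depth_m = numeric(0))
  }
  attr(out, "excluded") <- excluded
  out
}

#' Deep chlorophyll maximum depth per station
#'
#' The sampled depth of maximum chlorophyll-a fluorescence, optionally
#' after 3-point running-median smoothing of the profile; ties resolve
#' shallowest. A monotone-decreasing profile returns the surface depth
#' flagged \code{no_subsurface_maximum}; a flat profile yields NA.
#'
#' @param metadata sample metadata with \code{station}, \code{depth_m},
#'   \code{fluorescence}.
#' @param smooth apply 3-point median smoothing (default FALSE).
#' @return data.frame: station, dcm_m, flag ("" | "no_subsurface_maximum" |
#'   "flat_profile").
#' @export
dcm_depth <- function(metadata, smooth = FALSE) {
  if (!"fluorescence" %in% names(metadata)) {
    stop("metadata lacks a fluorescence column")
  }
  rows <- lapply(split(metadata, metadata$station), function(md) {
    md <- md[order(md$depth_m), ]
    f <- md$fluorescence
    if (smooth && length(f) >= 3L) f <- stats::runmed(f, 3L)
    if (length(unique(f)) == 1L) {
      return(data.frame(station = md$station[1L], dcm_m = NA_real_,
                        flag = "flat_profile", stringsAsFactors = FALSE))
    }
    i <- which.max(f)                     # first max = shallowest
    flag <- if (i == 1L) "no_subsurface_maximum" else ""
    data.frame(station = md$station[1L], dcm_m = md$depth_m[i], flag = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise depth comparisons between modules (and the DCM)
#'
#' Every EL-vs-EL and EL-vs-DCM contrast of per-station maximum depths:
#' two-sided Mann-Whitney U, Cliff's Delta, Benjamini-Hochberg adjustment
#' over the whole family. Sign convention: positive Delta means the
#' \code{y} entity reaches deeper than the \code{x} entity.
#'
#' @param el_max data.frame from \code{\link{el_maximum_depth}}.
#' @param dcm optional data.frame from \code{\link{dcm_depth}}.
#' @param min_n minimum stations per entity to test (default 3).
#' @return data.frame: x, y, delta, p, p_adj, n_x, n_y, underpowered.
#' @export
depth_comparisons <- function(el_max, dcm = NULL, min_n = 3L) {
  vals <- split(el_max$max_depth_m, el_max$el)
  if (!is.null(dcm)) {
    vals$DCM <- dcm$dcm_m[!is.na(dcm$dcm_m)]
  }
  ents <- names(vals)
  if (length(ents) < 2L) stop("need at least two entities to compare")
  pairs <- utils::combn(ents, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    xe <- pairs[1L, j]; ye <- pairs[2L, j]
    xv <- vals[[xe]]; yv <- vals[[ye]]
    under <- length(xv) < min_n || length(yv) < min_n
    if (under) {
      return(data.frame(x = xe, y = ye, delta = NA_real_, p = NA_real_,
                        n_x = length(xv), n_y = length(yv),
                        underpowered = TRUE, stringsAsFactors = FALSE))
    }
    mw <- mann_whitney_test(yv, xv, alternative = "two.sided")
    data.frame(x = xe, y = ye, delta = cliffs_delta(yv, xv), p = mw$p,
               n_x = length(xv), n_y = length(yv), underpowered = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Mixed-layer sample mask
#'
#' A sample belongs to the mixed layer when its depth does not exceed the
#' station's recorded mixed-layer depth.
#'
#' @param metadata sample metadata with \code{depth_m} and \code{mld_m}.
#' @return logical vector over metadata rows.
#' @export
in_mixed_layer <- function(metadata) {
  if (!all(c("depth_m", "mld_m") %in% names(metadata))) {
    stop("metadata needs depth_m and mld_m for mixed-layer selection")
  }
  metadata$depth_m <= metadata$mld_m
}

#' Province enrichment of modules in the mixed layer
#'
#' For every EL and province: one-sided Mann-Whitney U of the EL's
#' mixed-layer relative intensities in the province against all other
#' provinces (province greater), Cliff's Delta, BH adjustment over the
#' whole EL x province family. Provinces with fewer than \code{min_n}
#' mixed-layer samples are skipped.
#'
#' @param el_table samples x EL matrix.
#' @param metadata sample metadata (needs province, depth_m, mld_m).
#' @param min_n minimum samples per province (default 3).
#' @return data.frame: el, province, delta, p, p_adj, n_province, n_rest.
#' @export
province_enrichment <- function(el_table, metadata, min_n = 3L) {
  md <- metadata[match(rownames(el_table), metadata$sample_id), ]
  ml <- in_mixed_layer(md)
  el_ml <- el_table[ml, , drop = FALSE]
  prov <- md$province[ml]
  tab <- table(prov)
  use <- names(tab)[tab >= min_n]
  skipped <- setdiff(names(tab), use)
  if (length(use) < 2L) stop("need >= 2 provinces with >= ", min_n,
                             " mixed-layer samples")
  rows <- list()
  for (el in colnames(el_ml)) {
    for (p in use) {
      xv <- el_ml[prov == p, el]
      yv <- el_ml[prov != p, el]
      mw <- mann_whitney_test(xv, yv, alternative = "greater")
      rows[[length(rows) + 1L]] <- data.frame(
        el = el, province = p, delta = cliffs_delta(xv, yv), p = mw$p,
        n_province = length(xv), n_rest = length(yv),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  attr(out, "skipped") <- skipped
  out
}

#' Headgroup enrichment across modules
#'
#' For each headgroup, a chi-square goodness-of-fit test of the observed
#' member counts across ELs against a uniform distribution (expected =
#' total count of the headgroup / number of ELs), df = #ELs - 1, BH
#' adjustment across headgroups. Headgroups whose expected count is zero
#' are dropped with a note.
#'
#' @param labels named module labels (EL0 members are excluded).
#' @param species parsed species table (id, headgroup).
#' @return data.frame: headgroup, chisq, df, p, p_adj, plus an
#'   \code{observed} attribute (headgroup x EL count matrix).
#' @export
headgroup_enrichment <- function(labels, species) {
  lab <- labels[labels > 0L]
  if (length(unique(lab)) < 2L) stop("need >= 2 ELs for enrichment")
  hg <- species$headgroup[match(names(lab), species$id)]
  counts <- table(hg, factor(lab))
  k <- ncol(counts)
  dropped <- rownames(counts)[rowSums(counts) == 0]
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  rows <- lapply(rownames(counts), function(h) {
    obs <- as.numeric(counts[h, ])
    expd <- sum(obs) / k
    chisq <- sum((obs - expd)^2 / expd)
    data.frame(headgroup = h, chisq = chisq, df = k - 1L,
               p = stats::pchisq(chisq, k - 1L, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  attr(out, "observed") <- counts
  attr(out, "dropped") <- dropped
  out
}

#' Correlation of module intensities with a pigment covariate
#'
#' Spearman (default) correlation of each EL's relative intensity with a
#' pigment column across samples, BH-adjusted over ELs.
#'
#' @param el_table samples x EL matrix.
#' @param metadata sample metadata.
#' @param pigment name of the metadata column (default "fluorescence").
#' @param method correlation method.
#' @return data.frame: el, rho, p, p_adj, n.
#' @export
correlate_el_with_pigment <- function(el_table, metadata,
                                      pigment = "fluorescence",
                                      method = "spearman") {
  if (!pigment %in% names(metadata)) {
    stop("metadata lacks pigment column '", pigment, "'")
  }
  v <- metadata[[pigment]][match(rownames(el_table), metadata$sample_id)]
  if (stats::sd(v, na.rm = TRUE) == 0) {
    stop("pigment column is constant; correlation undefined")
  }
  rows <- lapply(colnames(el_table), function(el) {
    ct <- suppressWarnings(
      stats::cor.test(el_table[, el], v, method = method, exact = FALSE))
    data.frame(el = el, rho = unname(ct$estimate), p = ct$p.value,
               n = sum(stats::complete.cases(el_table[, el], v)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out
}
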