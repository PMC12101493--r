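#' Synthetic ocean configuration
#'
#' Defines the sampling design and planted structure of the synthetic
#' cruises: a multi-region, multi-station, depth-resolved lipidome with
#' planted co-occurrence modules, province/depth-specific enrichment, a
#' temperature-dependent chain-length signal and contaminant features that
#' are high in blank runs.
#'
#' @param n_regions number of ocean regions (region 1 is the network
#'   reference region).
#' @param provinces_per_region Longhurst-style provinces per region.
#' @param stations_per_province stations per province.
#' @param depth_grid strictly increasing sampled depths in metres.
#' @param n_modules number of planted co-occurrence modules.
#' @param lipids_per_module member lipids per module.
#' @param n_unassigned_lipids background lipids with no planted module.
#' @param n_contaminants features flagged as contaminants (drawn from the
#'   unassigned set; must not exceed it).
#' @param noise_sd log-scale standard deviation of measurement noise.
#' @param unassigned_sd log-scale idiosyncratic variability of unassigned
#'   lipids (biological scatter, larger than measurement noise).
#' @param loading module loading multiplying the unit-variance latent.
#' @param chain_length_slope planted carbons-per-fatty-acid change per
#'   degree C of in situ temperature (SFA/MUFA membrane lipids).
#' @param chain_length_base mean carbons per FA of SFA/MUFA membrane lipids
#'   at 0 degrees C.
#' @param blank_margin fold separation of blank medians from the 20-fold
#'   boundary on either side.
#' @param seed integer seed; every generator draw derives from it.
#' @return list of class \code{ocean_config}.
#' @export
ocean_config <- function(n_regions = 3L,
                         provinces_per_region = 3L,
                         stations_per_province = 5L,
                         depth_grid = c(5, 25, 50, 100, 200, 400),
                         n_modules = 5L,
                         lipids_per_module = 60L,
                         n_unassigned_lipids = 40L,
                         n_contaminants = 6L,
                         noise_sd = 0.15,
                         unassigned_sd = 0.6,
                         loading = 1,
                         chain_length_slope = 0.04,
                         chain_length_base = 14.5,
                         blank_margin = 4,
                         seed = 1L) {
  cfg <- list(n_regions = as.integer(n_regions),
              provinces_per_region = as.integer(provinces_per_region),
              stations_per_province = as.integer(stations_per_province),
              depth_grid = as.numeric(depth_grid),
              n_modules = as.integer(n_modules),
              lipids_per_module = as.integer(lipids_per_module),
              n_unassigned_lipids = as.integer(n_unassigned_lipids),
              n_contaminants = as.integer(n_contaminants),
              noise_sd = as.numeric(noise_sd),
              unassigned_sd = as.numeric(unassigned_sd),
              loading = as.numeric(loading),
              chain_length_slope = as.numeric(chain_length_slope),
              chain_length_base = as.numeric(chain_length_base),
              blank_margin = as.numeric(blank_margin),
              seed = as.integer(seed))
  validate_ocean_config(cfg)
  class(cfg) <- "ocean_config"
  cfg
}

validate_ocean_config <- function(cfg) {
  counts <- c("n_regions", "provinces_per_region", "stations_per_province",
              "n_modules", "lipids_per_module", "n_unassigned_lipids",
              "n_contaminants")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L) {
      stop("invalid configuration: ", f, " must be a non-negative count")
    }
  }
  if (length(cfg$depth_grid) < 1L || any(diff(cfg$depth_grid) <= 0)) {
    stop("invalid configuration: depth_grid must be strictly increasing")
  }
  if (cfg$noise_sd < 0) stop("invalid configuration: noise_sd must be >= 0")
  if (cfg$n_contaminants > cfg$n_unassigned_lipids) {
    stop("invalid configuration: n_contaminants exceeds unassigned lipids")
  }
  invisible(TRUE)
}

# run code under a derived seed without disturbing the caller's RNG state
with_seed <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((abs(seed) %% 1000000000L) * 2L + offset)
  force(code)
}

# Longhurst-style province codes, ordered warm -> cold so the global
# province index maps onto a surface-temperature gradient.
PROVINCE_POOL <- c("WTRA", "NPTG", "NATR", "CARB", "SATL", "NASW", "GUIA",
                   "GFST", "NADR", "NWCS", "PSAE", "ARCT", "APLR")

# fixed per-province surface temperatures: evenly spaced 28 -> -1 C
province_surface_temp <- function(n_provinces) {
  if (n_provinces == 1L) return(14)
  seq(28, -1, length.out = n_provinces)
}

#' Generate synthetic sample metadata
#'
#' One row per (station, depth). Temperature decreases with depth and with
#' the province's latitude band; phosphate is low where the surface is warm
#' and increases with depth; chlorophyll-a fluorescence is a single-peaked
#' Gaussian per station whose peak (the planted deep chlorophyll maximum)
#' sits deeper in warm provinces; a mixed-layer depth is recorded per
#' station (deeper in cold provinces). Provinces are interleaved across
#' regions so every region spans the surface-temperature gradient.
#'
#' @param cfg an \code{ocean_config}.
#' @return data.frame with columns sample_id, region, province, station,
#'   latitude, longitude, depth_m, temperature_c, po4_um, fluorescence,
#'   mld_m, dcm_m (the planted DCM, also recoverable from the fluorescence
#'   profile).
#' @export
generate_metadata <- function(cfg) {
  validate_ocean_config(cfg)
  n_prov <- cfg$n_regions * cfg$provinces_per_region
  if (n_prov == 0L || cfg$stations_per_province == 0L) {
    stop("invalid configuration: no stations to generate")
  }
  prov_codes <- rep_len(PROVINCE_POOL, n_prov)
  t0 <- province_surface_temp(n_prov)
  region_of_prov <- rep_len(seq_len(cfg$n_regions), n_prov)

  with_seed(cfg$seed, 1L, {
    rows <- list()
    st_id <- 0L
    for (p in seq_len(n_prov)) {
      for (s in seq_len(cfg$stations_per_province)) {
        st_id <- st_id + 1L
        jit <- stats::runif(4L) - 0.5
        t_surf <- t0[p] + jit[1] * 6   # +-3 C station spread
        dcm <- 25 + 2.5 * max(t_surf, 0) + jit[2] * 8
        mld <- min(80, max(18, 55 - 1.1 * t_surf + jit[3] * 10))
        depth <- cfg$depth_grid
        temp <- pmin(32, pmax(-2, 2 + (t_surf - 2) * exp(-depth / 120)))
        # station-level nutrient patchiness keeps PO4 from being a pure
        # deterministic function of temperature and depth
        po4 <- pmax(0.02, 0.05 + 2.0 * (1 - max(t_surf, 0) / 32) +
                      1.3 * (1 - exp(-depth / 300)) + jit[4] * 1.6)
        fluor <- 0.15 + exp(-(depth - dcm)^2 / (2 * 25^2))
        lat <- 62 - 2.1 * t0[p] + jit[1] * 2
        lon <- -60 + 35 * (region_of_prov[p] - 1) + s
        rows[[st_id]] <- data.frame(
          sample_id = sprintf("S%03d_d%04d", st_id, round(depth)),
          region = paste0("region", region_of_prov[p]),
          province = prov_codes[p],
          station = sprintf("S%03d", st_id),
          latitude = lat, longitude = lon,
          depth_m = depth, temperature_c = temp, po4_um = po4,
          fluorescence = fluor, mld_m = mld, dcm_m = dcm,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# module archetypes, cycled when n_modules > 5:
#   1 deep-peak storage lipids (TAG/DAG, outside the membrane tilt)
#   2 warm-province glycolipids (MGDG/SQDG, longer chains)
#   3 temperature-tracking betaine/storage lipids
#   4 DCM-tracking chloroplast PUFA lipids (carry EPA 20:5 chains)
#   5 cold-province phospholipids (shorter chains)
module_archetypes <- function(n_modules, provinces) {
  # the indicator module uses a mid-gradient province: an extreme-province
  # indicator is nearly collinear with the temperature latent, which would
  # confound the planted responses by construction
  mid <- provinces[min(2L, length(provinces))]
  cold <- provinces[length(provinces)]
  base <- list(
    list(type = "depth_peak", peak = 50, classes = c("TAG", "DAG"),
         sat = "SFA/MUFA", chain_mean = 16),
    list(type = "province", province = mid, classes = c("MGDG", "SQDG"),
         sat = "SFA/MUFA", chain_mean = 18),
    list(type = "temperature", classes = c("DGTS/A", "DGCC", "TAG"),
         sat = "SFA/MUFA", chain_mean = 15),
    list(type = "dcm_peak", classes = c("SQDG", "MGDG", "DGDG", "PG"),
         sat = "PUFA", chain_mean = 18),
    list(type = "province", province = cold, classes = c("PG", "PE"),
         sat = "SFA/MUFA", chain_mean = 12)
  )
  out <- vector("list", n_modules)
  extra_peaks <- c(200, 100, 400, 25)
  for (m in seq_len(n_modules)) {
    a <- base[[((m - 1L) %% 5L) + 1L]]
    if (m > 5L && a$type == "depth_peak") {
      a$peak <- extra_peaks[((m - 1L) %/% 5L - 1L) %% length(extra_peaks) + 1L]
    }
    if (m > 5L && a$type == "province") {
      a$province <- provinces[((m - 1L) %% length(provinces)) + 1L]
    }
    out[[m]] <- a
  }
  out
}

# unit-variance latent over samples for one archetype
module_latent <- function(arch, metadata) {
  raw <- switch(arch$type,
    depth_peak = exp(-(metadata$depth_m - arch$peak)^2 / (2 * 30^2)),
    dcm_peak = exp(-(metadata$depth_m - metadata$dcm_m)^2 / (2 * 20^2)),
    province = as.numeric(metadata$province == arch$province),
    temperature = metadata$temperature_c,
    stop("unknown module archetype type: ", arch$type))
  s <- stats::sd(raw)
  if (is.na(s) || s == 0) {
    stop("degenerate module latent (constant over samples)")
  }
  (raw - mean(raw)) / s
}

even_near <- function(x) 2 * round(x / 2)

# one shorthand name. Module members (fixed_cpf = TRUE) share an exact
# carbons-per-FA signature: the chain split varies but the sum is fixed,
# so the module's structural identity is homogeneous. Unassigned lipids
# draw each chain independently around the mean (`spread` carbons).
make_species_name <- function(classes, sat, chain_mean, spread = 4,
                              fixed_cpf = FALSE) {
  cls <- sample(classes, 1L)
  n_ch <- if (cls == "TAG") 3L else 2L
  if (sat == "PUFA") {
    # PUFA chains are never tilted, so the partner chain may vary freely
    c2 <- if (fixed_cpf) {
      2L * chain_mean - 20L + sample(c(-2L, 0L, 2L), 1L)
    } else {
      min(22, max(12, even_near(chain_mean + stats::runif(1, -spread,
                                                          spread))))
    }
    chains <- sprintf("20:5/%d:%d", c2, stats::rbinom(1L, 1L, 0.5))
  } else if (fixed_cpf) {
    off <- sample(c(-2L, 0L, 2L), n_ch - 1L, replace = TRUE)
    carb <- c(chain_mean + off, n_ch * chain_mean - sum(chain_mean + off))
    carb <- pmin(24L, pmax(10L, carb))
    db <- stats::rbinom(n_ch, 1L, 0.4)
    chains <- paste(sprintf("%d:%d", carb, db), collapse = "/")
  } else {
    draw_c <- function() {
      min(22, max(12, even_near(chain_mean + stats::runif(1, -spread,
                                                          spread))))
    }
    carb <- vapply(seq_len(n_ch), function(i) draw_c(), numeric(1))
    db <- stats::rbinom(n_ch, 1L, 0.4)
    chains <- paste(sprintf("%d:%d", carb, db), collapse = "/")
  }
  paste(cls, chains)
}

#' Generate the synthetic lipidome
#'
#' Builds a lipid roster (module members with shared structural signatures
#' plus unassigned background lipids), assigns each module a latent
#' environmental response (Gaussian depth peak, DCM-tracking peak, province
#' indicator, or monotone temperature response), and composes per-sample
#' log-intensities as \code{base + loading * latent (+ tilt) + noise}.
#'
#' The chain-length tilt reweights SFA/MUFA membrane-lipid intensities by
#' an exponential factor in carbons-per-FA whose per-sample coefficient is
#' solved so that the intensity-weighted mean carbons per fatty acid of
#' that set equals \code{chain_length_base + chain_length_slope *
#' temperature} exactly before noise. Intensities are strictly positive
#' (log-normal noise).
#'
#' @param cfg an \code{ocean_config}.
#' @param metadata result of \code{\link{generate_metadata}} for the same
#'   config.
#' @return list with \code{features} (\code{feature_table}, raw view),
#'   \code{species} (parsed annotation table, one row per feature) and
#'   \code{truth} (planted ground truth: module_label, latent_profiles,
#'   module_info, contaminant_flag, chain_length_slope).
#' @export
generate_lipidome <- function(cfg, metadata) {
  validate_ocean_config(cfg)
  need <- c("sample_id", "province", "depth_m", "temperature_c", "dcm_m")
  if (!all(need %in% names(metadata))) {
    stop("metadata does not match config: missing columns ",
         paste(setdiff(need, names(metadata)), collapse = ", "))
  }
  n_samples <- nrow(metadata)
  if (n_samples < 2L) stop("metadata must contain at least two samples")
  # province-indicator modules are planted in provinces of the first
  # region (the network reference region), kept in warm->cold order
  ref_region <- metadata$region[1L]
  provinces <- unique(metadata$province[metadata$region == ref_region])
  arch <- module_archetypes(cfg$n_modules, provinces)

  n_assigned <- cfg$n_modules * cfg$lipids_per_module
  n_lipids <- n_assigned + cfg$n_unassigned_lipids
  if (n_lipids == 0L) stop("configuration yields an empty lipidome")
  module_label <- c(rep(seq_len(cfg$n_modules), each = cfg$lipids_per_module),
                    rep(0L, cfg$n_unassigned_lipids))
  all_classes <- c("PC", "PE", "PG", "SQDG", "MGDG", "DGDG", "DGTS/A",
                   "DGCC", "TAG", "GADG")

  with_seed(cfg$seed, 2L, {
    # ---- lipid roster ----------------------------------------------------
    names_vec <- character(n_lipids)
    tier_vec <- character(n_lipids)
    for (i in seq_len(n_lipids)) {
      m <- module_label[i]
      if (m > 0L) {
        a <- arch[[m]]
        names_vec[i] <- make_species_name(a$classes, a$sat, a$chain_mean,
                                          fixed_cpf = TRUE)
        tier_vec[i] <- if (stats::runif(1) < 0.8) "Ann.1" else "Ann.2"
      } else {
        names_vec[i] <- make_species_name(all_classes, "SFA/MUFA", 15,
                                          spread = 4)
        tier_vec[i] <- if (stats::runif(1) < 0.5) "Ann.2" else "Ann.3"
      }
    }
    ids <- sprintf("lipid_%04d", seq_len(n_lipids))
    species <- parse_lipid_name(names_vec, annotation_tier = tier_vec)
    species$id <- ids
    species <- classify_saturation(species)

    # ---- latent responses ------------------------------------------------
    latents <- if (cfg$n_modules > 0L) {
      vapply(arch, module_latent, numeric(n_samples), metadata = metadata)
    } else {
      matrix(0, n_samples, 0L)
    }
    if (cfg$n_modules > 0L) {
      colnames(latents) <- paste0("module", seq_len(cfg$n_modules))
      rownames(latents) <- metadata$sample_id
    }

    # ---- deterministic log-intensity surface -----------------------------
    base_i <- 9 + stats::runif(n_lipids, -0.8, 0.8)
    logI <- matrix(rep(base_i, n_samples), nrow = n_lipids)
    for (m in seq_len(cfg$n_modules)) {
      mem <- module_label == m
      logI[mem, ] <- logI[mem, , drop = FALSE] +
        matrix(rep(cfg$loading * latents[, m], each = sum(mem)),
               nrow = sum(mem))
    }

    # contaminants are flagged up front: the blank filter removes them, so
    # the chain-length target below is solved over the analysis-grade set
    un <- module_label == 0L
    contaminant <- rep(FALSE, n_lipids)
    if (cfg$n_contaminants > 0L) {
      contaminant[which(un)[seq_len(cfg$n_contaminants)]] <- TRUE
    }

    # ---- chain-length tilt -----------------------------------------------
    # the intensity-weighted mean C/FA of the SFA/MUFA membrane set is
    # driven to base + slope * T by tilting the module members only;
    # unassigned lipids keep their planted "pure noise" behaviour
    sel <- species$is_membrane & species$species_class == "SFA/MUFA" &
      !contaminant
    tilt <- sel & module_label > 0L
    cpf <- species$total_carbons / species$n_chains
    if (cfg$chain_length_slope != 0 && sum(tilt) >= 2L &&
        stats::sd(cpf[tilt]) > 0) {
      target <- cfg$chain_length_base +
        cfg$chain_length_slope * metadata$temperature_c
      cc <- cpf[sel]
      is_tilt <- tilt[sel]
      ccm <- cc - mean(cc[is_tilt])
      # solve on expected noisy weights (log-normal mean inflation), so the
      # planted slope survives the later noise in expectation
      sig2 <- rep(cfg$noise_sd^2, sum(sel))
      sig2[!is_tilt] <- sig2[!is_tilt] + cfg$unassigned_sd^2
      for (s in seq_len(n_samples)) {
        w0 <- exp(logI[sel, s] + sig2 / 2 - max(logI[sel, s]))
        fmean <- function(theta) {
          w <- w0
          w[is_tilt] <- w[is_tilt] * exp(theta * ccm[is_tilt])
          sum(w * cc) / sum(w)
        }
        lo_val <- fmean(-12); hi_val <- fmean(12)
        tg <- min(max(target[s], min(lo_val, hi_val) + 1e-6),
                  max(lo_val, hi_val) - 1e-6)
        theta <- tryCatch(
          stats::uniroot(function(t) fmean(t) - tg,
                         lower = -12, upper = 12, tol = 1e-10)$root,
          error = function(e) NA_real_)
        if (!is.na(theta)) {
          logI[sel, s][is_tilt] <- logI[sel, s][is_tilt] +
            theta * ccm[is_tilt]
        }
      }
    } else if (cfg$chain_length_slope != 0 && sum(tilt) >= 2L) {
      warning("chain-length tilt skipped: no carbon spread among ",
              "SFA/MUFA membrane module members")
    }

    # ---- unassigned idiosyncratic variation + measurement noise ----------
    if (any(un) && cfg$unassigned_sd > 0) {
      logI[un, ] <- logI[un, , drop = FALSE] +
        matrix(stats::rnorm(sum(un) * n_samples, 0, cfg$unassigned_sd),
               nrow = sum(un))
    }
    if (cfg$noise_sd > 0) {
      logI <- logI + matrix(stats::rnorm(n_lipids * n_samples, 0,
                                         cfg$noise_sd), nrow = n_lipids)
    }

    intens <- exp(logI)
    dimnames(intens) <- list(ids, metadata$sample_id)
    features <- feature_table(intens, "raw")

    contaminant_flag <- stats::setNames(contaminant, ids)

    module_info <- if (cfg$n_modules > 0L) {
      data.frame(
        module = seq_len(cfg$n_modules),
        type = vapply(arch, `[[`, character(1), "type"),
        peak_depth = vapply(arch, function(a) {
          if (a$type == "depth_peak") a$peak else NA_real_
        }, numeric(1)),
        province_enriched = vapply(arch, function(a) {
          if (a$type == "province") a$province else NA_character_
        }, character(1)),
        stringsAsFactors = FALSE)
    } else {
      data.frame(module = integer(0), type = character(0),
                 peak_depth = numeric(0), province_enriched = character(0))
    }

    truth <- list(module_label = stats::setNames(module_label, ids),
                  latent_profiles = latents,
                  module_info = module_info,
                  contaminant_flag = contaminant_flag,
                  chain_length_slope = cfg$chain_length_slope)
    list(features = features, species = species, truth = truth)
  })
}

#' Generate blank-run intensities
#'
#' Five synthetic blank runs per feature. Contaminant-flagged features get a
#' blank median of \code{blank_margin} times sample_median / 20 (so they
#' fail the 20-fold rule); all other features get sample_median /
#' (20 * blank_margin) (comfortably retained). The middle blank run carries
#' the median exactly, so the planted kept/removed sets are deterministic.
#'
#' @param features \code{feature_table} (raw) from
#'   \code{\link{generate_lipidome}}.
#' @param truth planted truth from the same call.
#' @param cfg the \code{ocean_config}.
#' @return numeric matrix features x 5 blank runs.
#' @export
generate_blanks <- function(features, truth, cfg) {
  ids <- rownames(features)
  if (!identical(ids, names(truth$contaminant_flag))) {
    stop("truth is not aligned to the feature table")
  }
  med_s <- apply(as_ft_matrix(features), 1L, stats::median)
  target <- ifelse(truth$contaminant_flag,
                   med_s / 20 * cfg$blank_margin,
                   med_s / (20 * cfg$blank_margin))
  spread <- c(0.7, 0.9, 1, 1.12, 1.3)
  b <- outer(target, spread)
  dimnames(b) <- list(ids, sprintf("blank_%d", seq_along(spread)))
  b
}

#' Simulate a complete synthetic ocean dataset
#'
#' Convenience wrapper running \code{\link{generate_metadata}},
#' \code{\link{generate_lipidome}} and \code{\link{generate_blanks}}.
#'
#' @param cfg an \code{ocean_config} (default: the package defaults).
#' @return list with metadata, features, species, blanks, truth, cfg.
#' @export
simulate_ocean <- function(cfg = ocean_config()) {
  metadata <- generate_metadata(cfg)
  lip <- generate_lipidome(cfg, metadata)
  blanks <- generate_blanks(lip$features, lip$truth, cfg)
  list(metadata = metadata, features = lip$features, species = lip$species,
       blanks = blanks, truth = lip$truth, cfg = cfg)
}

#' Write a synthetic dataset to plain-text files
#'
#' Feature, blank, metadata and species tables as TSV, planted truth as
#' JSON and the configuration as YAML, in a directory.
#'
#' @param sim result of \code{\link{simulate_ocean}}.
#' @param dir output directory (created if absent).
#' @return invisibly, the named paths written.
#' @export
write_ocean_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    features = file.path(dir, "features.tsv"),
    blanks = file.path(dir, "blanks.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    species = file.path(dir, "species.tsv"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.yaml"))
  write_feature_table(sim$features, paths["features"])
  utils::write.table(data.frame(lipid_id = rownames(sim$blanks), sim$blanks,
                                check.names = FALSE),
                     paths["blanks"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$metadata, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$species, paths["species"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_json <- sim$truth
  truth_json$latent_profiles <- NULL  # bulky; recomputable from the config
  jsonlite::write_json(truth_json, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  yaml::write_yaml(unclass(sim$cfg), paths["config"])
  invisible(paths)
}
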