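#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end run with their defaults:
#' synthetic-ocean settings (used when no input paths are given), blank
#' fold threshold, network settings, statistical settings and output
#' controls. Supply a YAML file with any subset of these keys to override.
#'
#' @param ... named overrides.
#' @return named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    input = list(features = NULL, blanks = NULL, metadata = NULL,
                 species = NULL),
    synthetic = unclass(ocean_config()),
    reference_region = "region1",
    blank_fold = 20,
    network = list(mode = "signed", beta = NULL,
                   beta_candidates = c(1:10, seq(12, 20, 2)),
                   beta_target = 0.8, min_module_size = 10, cut_frac = 0.99),
    igp = list(n_perm = 199, seed = 7),
    meta = list(k = NULL, weights = c(1, 1, 1), n_sim = 199, seed = 11,
                depth_bins = c(0, 25, 50, 100, 200, 400)),
    structure = list(min_annotated = 5, entanglement_L = 1.5),
    env = list(ratio_el_a = NULL, ratio_el_b = NULL, sst_bin_width = 2,
               n_boot = 1000, rf_ntree = 500, rf_seed = 13),
    fdr_level = 0.05,
    out_dir = "results")
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- modify_defaults(cfg[[nm]], over[[nm]])
  validate_run_config(cfg)
  cfg
}

modify_defaults <- function(base, new) {
  if (!is.list(base) || !is.list(new)) return(new)
  for (nm in names(new)) base[[nm]] <- modify_defaults(base[[nm]], new[[nm]])
  base
}

validate_run_config <- function(cfg) {
  if (!is.numeric(cfg$fdr_level) || cfg$fdr_level <= 0 ||
      cfg$fdr_level >= 1) {
    stop("config validation: fdr_level must be in (0, 1)")
  }
  if (cfg$blank_fold <= 0) {
    stop("config validation: blank_fold must be positive")
  }
  if (!is.null(cfg$network$beta) && cfg$network$beta < 1) {
    stop("config validation: network beta must be >= 1")
  }
  invisible(TRUE)
}

#' Load a run configuration from YAML
#' @param path YAML file with (a subset of) the \code{default_config} keys.
#' @return full config list with defaults filled in.
#' @export
read_run_config <- function(path) {
  over <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(over)) cfg[[nm]] <- modify_defaults(cfg[[nm]], over[[nm]])
  validate_run_config(cfg)
  cfg
}

load_inputs <- function(cfg) {
  inp <- cfg$input
  if (!is.null(inp$features)) {
    features <- read_feature_table(inp$features, view = "raw")
    blanks_df <- utils::read.delim(inp$blanks, check.names = FALSE)
    blanks <- as.matrix(blanks_df[, -1, drop = FALSE])
    rownames(blanks) <- blanks_df[[1L]]
    metadata <- utils::read.delim(inp$metadata, stringsAsFactors = FALSE)
    ann <- utils::read.delim(inp$species, stringsAsFactors = FALSE)
    species <- parse_lipid_name(ann$name, annotation_tier = ann$annotation_tier)
    species$id <- ann$id
    species <- classify_saturation(species)
    list(features = features, blanks = blanks, metadata = metadata,
         species = species, truth = NULL)
  } else {
    scfg <- do.call(ocean_config, cfg$synthetic)
    simulate_ocean(scfg)
  }
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full eigenlipid pipeline
#'
#' Preprocessing (blank filter, total normalisation, CLR), network module
#' detection on the reference region, projection of the remaining regions,
#' in-group proportion reproducibility, spatial statistics, meta-
#' clustering, structural comparison and environmental response, writing
#' tidy TSV/JSON results and a manifest into \code{cfg$out_dir}.
#'
#' @param cfg configuration list from \code{\link{default_config}} or
#'   \code{\link{read_run_config}}.
#' @param sample_filter optional logical/character filter over sample ids
#'   (used by \code{\link{subset_run}}).
#' @return invisible list of all in-memory results.
#' @export
run_pipeline <- function(cfg = default_config(), sample_filter = NULL) {
  validate_run_config(cfg)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message(sprintf(...))

  dat <- load_inputs(cfg)
  features <- dat$features
  metadata <- dat$metadata
  if (!is.null(sample_filter)) {
    keep <- if (is.character(sample_filter)) {
      colnames(features) %in% sample_filter
    } else sample_filter
    if (!any(keep)) stop("sample filter leaves no samples")
    features <- feature_table(as_ft_matrix(features)[, keep, drop = FALSE],
                              "raw")
    metadata <- metadata[metadata$sample_id %in% colnames(features), ]
  }
  log_stage("input: %d lipids x %d samples", nrow(features), ncol(features))

  # ---- preprocess --------------------------------------------------------
  bl <- blank_subtract(features, dat$blanks, fold = cfg$blank_fold)
  feats <- bl$features
  log_stage("blank filter: %d kept, %d removed (fold %.0f)",
            sum(bl$report$kept), sum(!bl$report$kept), cfg$blank_fold)
  rel <- normalize_total(feats)
  clr <- clr_transform(rel)
  write_tsv(bl$report, file.path(out_dir, "blank_report.tsv"))

  # ---- network on reference region --------------------------------------
  md <- metadata[match(colnames(feats), metadata$sample_id), ]
  ref <- md$region == cfg$reference_region
  if (!any(ref)) stop("reference region '", cfg$reference_region,
                      "' has no samples")
  clr_ref <- feature_table(as_ft_matrix(clr)[, ref, drop = FALSE], "clr")
  beta <- cfg$network$beta
  fit_tab <- NULL
  if (is.null(beta)) {
    st <- pick_soft_threshold(clr_ref, powers = cfg$network$beta_candidates,
                              target = cfg$network$beta_target,
                              mode = cfg$network$mode)
    beta <- st$power
    fit_tab <- st$fit_table
  }
  net <- adjacency_matrix(clr_ref, beta = beta, mode = cfg$network$mode)
  tom <- tom_similarity(net)
  det <- detect_modules(tom, min_module_size = cfg$network$min_module_size,
                        cut_frac = cfg$network$cut_frac)
  n_mod <- sum(det$sizes > 0)
  log_stage("network: beta %.0f, %d modules, %d unassigned lipids",
            beta, length(det$sizes), sum(det$labels == 0L))
  els <- compute_eigenlipids(clr_ref, det$labels)
  memb <- membership_scores(clr_ref, els)

  write_tsv(data.frame(lipid_id = names(det$labels),
                       el = paste0("EL", det$labels)),
            file.path(out_dir, "module_labels.tsv"))
  write_tsv(data.frame(sample_id = rownames(els$profiles), els$profiles,
                       check.names = FALSE),
            file.path(out_dir, "eigenlipid_profiles.tsv"))
  write_tsv(data.frame(lipid_id = rownames(memb$scores), memb$scores,
                       check.names = FALSE),
            file.path(out_dir, "membership_scores.tsv"))
  jsonlite::write_json(
    list(beta = beta, mode = cfg$network$mode,
         min_module_size = cfg$network$min_module_size,
         cut_frac = cfg$network$cut_frac, cut_height = det$cut_height,
         sizes = as.list(det$sizes),
         fit_table = fit_tab),
    file.path(out_dir, "network_summary.json"), auto_unbox = TRUE,
    digits = NA, dataframe = "rows")

  # ---- projection + reproducibility -------------------------------------
  proj <- NULL; igp <- NULL
  if (any(!ref)) {
    clr_val <- feature_table(as_ft_matrix(clr)[, !ref, drop = FALSE], "clr")
    proj <- project_region(clr_val, els)
    igp <- igp_reproducibility(clr_val, els, n_perm = cfg$igp$n_perm,
                               seed = cfg$igp$seed)
    write_tsv(igp, file.path(out_dir, "igp_reproducibility.tsv"))
    log_stage("reproducibility: median IGP %.2f over %d modules",
              stats::median(igp$igp), nrow(igp))
  }

  # ---- spatial statistics ------------------------------------------------
  el_tab <- el_relative_intensity(feats, det$labels)
  el_cols <- setdiff(colnames(el_tab), "EL0")
  dcm <- dcm_depth(metadata)
  el_max <- el_maximum_depth(el_tab[, el_cols, drop = FALSE], metadata)
  depth_cmp <- depth_comparisons(el_max, dcm)
  prov <- province_enrichment(el_tab[, el_cols, drop = FALSE], metadata)
  hg <- headgroup_enrichment(det$labels, dat$species)
  pig <- correlate_el_with_pigment(el_tab[, el_cols, drop = FALSE], metadata)
  write_tsv(el_max, file.path(out_dir, "el_maximum_depth.tsv"))
  write_tsv(depth_cmp, file.path(out_dir, "depth_comparisons.tsv"))
  write_tsv(prov, file.path(out_dir, "province_enrichment.tsv"))
  write_tsv(hg, file.path(out_dir, "headgroup_enrichment.tsv"))
  write_tsv(pig, file.path(out_dir, "pigment_correlations.tsv"))
  log_stage("spatial: %d depth contrasts (%d at FDR %.2f), %d province
 tests (%d at FDR %.2f)",
            nrow(depth_cmp), sum(depth_cmp$p_adj < cfg$fdr_level,
                                 na.rm = TRUE), cfg$fdr_level,
            nrow(prov), sum(prov$p_adj < cfg$fdr_level), cfg$fdr_level)

  # ---- meta-clustering ---------------------------------------------------
  meta <- NULL
  if (length(el_cols) >= 3L) {
    # project all samples so the distributional view spans every region
    all_prof <- project_region(clr, els)$profiles
    els_all <- els; els_all$profiles <- all_prof
    dists <- build_el_distances(els_all, el_tab, metadata,
                                weights = cfg$meta$weights,
                                depth_bins = cfg$meta$depth_bins)
    pre_tree <- stats::hclust(stats::as.dist(dists$integrated),
                              method = "average")
    nodes <- node_significance(t(all_prof), pre_tree,
                               n_sim = cfg$meta$n_sim,
                               seed = cfg$meta$seed,
                               alpha = cfg$fdr_level)
    k <- cfg$meta$k
    if (is.null(k)) {
      k <- max(2L, min(sum(nodes$significant) + 1L,
                       length(el_cols) - 1L))
    }
    meta_d <- meta_dendrogram(dists, k = k)
    meta <- list(distances = dists, dendrogram = meta_d, nodes = nodes)
    write_tsv(data.frame(el = names(meta_d$clusters),
                         meta_cluster = meta_d$clusters),
              file.path(out_dir, "meta_clusters.tsv"))
    jsonlite::write_json(nodes, file.path(out_dir, "node_significance.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    write_dendrogram_newick(meta_d$tree,
                            file.path(out_dir, "meta_dendrogram.nwk"))
    log_stage("meta-clustering: k = %d, cophenetic %.2f", k,
              meta_d$cophenetic)
  }

  # ---- structural comparison --------------------------------------------
  struct <- NULL
  prof <- tryCatch(structural_profiles(det$labels, dat$species, rel,
                                       min_annotated =
                                         cfg$structure$min_annotated),
                   error = function(e) NULL)
  if (!is.null(prof) && nrow(prof) >= 3L && !is.null(meta)) {
    sd_tree <- structural_dendrogram(prof)
    shared <- intersect(prof$el, colnames(el_tab))
    # distributional tree restricted to the structurally retained ELs
    dsub <- meta$distances$integrated[shared, shared]
    dist_tree <- stats::hclust(stats::as.dist(dsub), method = "average")
    tangle <- entanglement(dist_tree, sd_tree$tree,
                           L = cfg$structure$entanglement_L)
    chain_prop <- property_by_sample_el(rel, det$labels, dat$species,
                                        "chain_length")
    mixed <- property_mixed_model(chain_prop)
    struct <- list(profiles = prof, dendrogram = sd_tree,
                   entanglement = tangle, mixed_model = mixed)
    write_tsv(prof, file.path(out_dir, "structural_profiles.tsv"))
    write_dendrogram_newick(sd_tree$tree,
                            file.path(out_dir, "structural_dendrogram.nwk"))
    jsonlite::write_json(
      list(entanglement = tangle$entanglement,
           entanglement_raw = tangle$entanglement_raw,
           L = tangle$L,
           cophenetic_distributional = meta$dendrogram$cophenetic,
           cophenetic_structural = sd_tree$cophenetic),
      file.path(out_dir, "entanglement.json"), auto_unbox = TRUE,
      digits = NA)
    write_tsv(mixed$coefficients,
              file.path(out_dir, "structural_mixed_model.tsv"))
    log_stage("structure: entanglement %.3f (raw %.3f)",
              tangle$entanglement, tangle$entanglement_raw)
  }

  # ---- environmental response -------------------------------------------
  layer <- assign_layer(metadata, dcm)
  env <- list()
  env$chain_sfa <- tryCatch(
    chain_length_vs_temperature(feats, dat$species, metadata, "SFA/MUFA"),
    error = function(e) NULL)
  env$pca <- tryCatch(
    pca_el_environment(el_tab[, el_cols, drop = FALSE], metadata),
    error = function(e) NULL)
  shares <- tryCatch(sfa_mufa_class_intensity(feats, dat$species),
                     error = function(e) NULL)
  if (!is.null(shares)) {
    md_all <- metadata[match(rownames(shares), metadata$sample_id), ]
    surf <- in_mixed_layer(md_all)
    Xrf <- data.frame(temperature_c = md_all$temperature_c[surf],
                      po4_um = md_all$po4_um[surf])
    env$rf <- lapply(colnames(shares), function(cl) {
      tryCatch(rf_attribution(Xrf, shares[surf, cl],
                              seed = cfg$env$rf_seed,
                              ntree = cfg$env$rf_ntree),
               error = function(e) NULL)
    })
    names(env$rf) <- colnames(shares)
    rf_tab <- do.call(rbind, lapply(names(env$rf), function(cl) {
      r <- env$rf[[cl]]
      if (is.null(r)) return(NULL)
      data.frame(class = cl, r_squared = r$r_squared,
                 t(r$importance), check.names = FALSE)
    }))
    if (!is.null(rf_tab)) {
      write_tsv(rf_tab, file.path(out_dir, "rf_attribution.tsv"))
    }
  }
  ra <- cfg$env$ratio_el_a; rb <- cfg$env$ratio_el_b
  if (is.null(ra) && length(el_cols) >= 2L) {
    # default: the DCM-associated vs the warmest-province module, chosen
    # as the two ELs with the most negative / positive SST correlation
    sst <- station_sst(metadata)
    md_tab <- metadata[match(rownames(el_tab), metadata$sample_id), ]
    cors <- apply(el_tab[, el_cols, drop = FALSE], 2L, function(v) {
      suppressWarnings(stats::cor(v, sst[md_tab$station],
                                  use = "complete.obs"))
    })
    ra <- names(which.max(cors)); rb <- names(which.min(cors))
  }
  if (!is.null(ra) && !is.null(rb)) {
    env$ratio <- tryCatch(
      el_ratio_by_sst(el_tab, ra, rb, metadata, layer,
                      bin_width = cfg$env$sst_bin_width,
                      n_boot = cfg$env$n_boot, seed = cfg$env$rf_seed),
      error = function(e) NULL)
    if (!is.null(env$ratio)) {
      write_tsv(env$ratio, file.path(out_dir, "el_ratio_by_sst.tsv"))
    }
  }
  env$pufa <- tryCatch(pufa_layer_contrast(feats, dat$species, layer),
                       error = function(e) NULL)
  if (!is.null(env$pufa)) {
    write_tsv(env$pufa, file.path(out_dir, "pufa_layer_contrast.tsv"))
  }
  env$epa <- tryCatch(epa_depth_vs_dcm(feats, dat$species, metadata, dcm),
                      error = function(e) NULL)
  if (!is.null(env$chain_sfa)) {
    jsonlite::write_json(
      list(slope = env$chain_sfa$slope,
           intercept = env$chain_sfa$intercept,
           r_squared = env$chain_sfa$r_squared,
           slope_ci = env$chain_sfa$slope_ci, n = env$chain_sfa$n),
      file.path(out_dir, "chain_length_regression.json"),
      auto_unbox = TRUE, digits = NA)
  }

  # ---- manifest ----------------------------------------------------------
  files <- sort(list.files(out_dir, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("eigenlipid")),
    config = strip_null(cfg),
    n_lipids_in = nrow(features), n_lipids_kept = nrow(feats),
    n_samples = ncol(feats),
    n_modules = length(det$sizes),
    output_hashes = as.list(tools::md5sum(files)))
  names(manifest$output_hashes) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(config = cfg, data = dat, blank_report = bl$report,
                 clr = clr, beta = beta, tom = tom, modules = det,
                 eigenlipids = els, membership = memb, projection = proj,
                 igp = igp, el_table = el_tab, dcm = dcm, el_max = el_max,
                 depth_comparisons = depth_cmp,
                 province_enrichment = prov,
                 headgroup_enrichment = hg, pigment = pig, meta = meta,
                 structure = struct, env = env, layer = layer))
}

strip_null <- function(x) {
  if (!is.list(x)) return(x)
  x <- lapply(x, strip_null)
  x[!vapply(x, is.null, logical(1))]
}

#' Run the pipeline on a sample subset
#'
#' Applies a filter (mixed-layer-only, one region, or a depth range) and
#' reruns the full pipeline, reporting the per-module Jaccard overlap of
#' member sets against a reference (full) run.
#'
#' @param cfg configuration list.
#' @param filter one of \code{"mixed_layer"}, \code{"region:<name>"}, or
#'   \code{"depth:<min>-<max>"}.
#' @param reference optional result of \code{\link{run_pipeline}} to
#'   compare module memberships against.
#' @return list: \code{result} (pipeline output), \code{overlap}
#'   (data.frame of best Jaccard matches per reference module, when a
#'   reference is given).
#' @export
subset_run <- function(cfg = default_config(), filter = "mixed_layer",
                       reference = NULL) {
  dat <- load_inputs(cfg)
  md <- dat$metadata
  keep <- if (filter == "mixed_layer") {
    in_mixed_layer(md)
  } else if (startsWith(filter, "region:")) {
    md$region == sub("^region:", "", filter)
  } else if (startsWith(filter, "depth:")) {
    rng <- as.numeric(strsplit(sub("^depth:", "", filter), "-")[[1]])
    md$depth_m >= rng[1] & md$depth_m <= rng[2]
  } else stop("unknown filter: ", filter)
  if (!any(keep)) stop("empty subset")
  res <- run_pipeline(cfg, sample_filter = md$sample_id[keep])
  overlap <- NULL
  if (!is.null(reference)) {
    ref_lab <- reference$modules$labels
    new_lab <- res$modules$labels
    shared <- intersect(names(ref_lab), names(new_lab))
    rows <- list()
    for (m in sort(unique(ref_lab[ref_lab > 0L]))) {
      a <- shared[ref_lab[shared] == m]
      mods_new <- sort(unique(new_lab[new_lab > 0L]))
      jac <- vapply(mods_new, function(m2) {
        b <- shared[new_lab[shared] == m2]
        length(intersect(a, b)) / length(union(a, b))
      }, numeric(1))
      names(jac) <- mods_new
      rows[[length(rows) + 1L]] <- data.frame(
        reference_el = paste0("EL", m),
        best_match = if (length(jac)) paste0("EL", names(which.max(jac)))
          else NA_character_,
        jaccard = if (length(jac)) max(jac) else 0)
    }
    overlap <- do.call(rbind, rows)
  }
  list(result = res, overlap = overlap)
}
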