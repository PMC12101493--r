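#!/usr/bin/env Rscript
# Preprocess the feature table (20-fold blank rule, total-intensity
# normalisation, centered log-ratio) and run the weighted correlation
# network analysis on the reference region (region 1): soft threshold,
# topological overlap, adaptive branch cut, eigenlipids, Spearman
# membership. The other regions are projected onto the reference
# eigenlipids and the modules' reproducibility is scored with the
# in-group proportion permutation test.

source("analysis/common.R")

dat <- load_study_data()

bl <- blank_subtract(dat$features, dat$blanks, fold = 20)
message(sprintf("blank filter: %d of %d features removed",
                sum(!bl$report$kept), nrow(dat$features)))
write_tsv(bl$report, OUT("network", "blank_report.tsv"))

clr <- clr_transform(normalize_total(bl$features))
ref <- dat$metadata$region[match(colnames(clr),
                                 dat$metadata$sample_id)] == "region1"
clr_ref <- feature_table(unclass(clr)[, ref, drop = FALSE], "clr")
clr_val <- feature_table(unclass(clr)[, !ref, drop = FALSE], "clr")

soft <- suppressWarnings(pick_soft_threshold(clr_ref))
message(sprintf("soft threshold: power %d (best scale-free fit %.2f)",
                soft$power, max(soft$fit_table$fit, na.rm = TRUE)))
net <- adjacency_matrix(clr_ref, beta = soft$power)
tom <- tom_similarity(net)
det <- detect_modules(tom, min_module_size = 10L)
message(sprintf("detected %d modules (sizes %s), %d lipids unassigned",
                length(det$sizes), paste(det$sizes, collapse = ", "),
                sum(det$labels == 0L)))

els <- compute_eigenlipids(clr_ref, det$labels)
memb <- membership_scores(clr_ref, els)
proj <- project_region(clr_val, els)
igp <- igp_reproducibility(clr_val, els, n_perm = 199L, seed = SEED)
message(sprintf("in-group proportion over held-out regions: %s",
                paste(sprintf("%s=%.2f (p=%.3f)", igp$el, igp$igp, igp$p),
                      collapse = ", ")))

write_tsv(data.frame(lipid_id = names(det$labels),
                     el = paste0("EL", det$labels)),
          OUT("network", "module_labels.tsv"))
write_tsv(data.frame(sample_id = rownames(els$profiles), els$profiles,
                     check.names = FALSE),
          OUT("network", "eigenlipid_profiles.tsv"))
write_tsv(data.frame(sample_id = rownames(proj$profiles), proj$profiles,
                     check.names = FALSE),
          OUT("network", "projected_profiles.tsv"))
write_tsv(data.frame(lipid_id = rownames(memb$scores), memb$scores,
                     check.names = FALSE),
          OUT("network", "membership_scores.tsv"))
write_tsv(igp, OUT("network", "igp_reproducibility.tsv"))
jsonlite::write_json(
  list(beta = soft$power, fit_table = soft$fit_table,
       cut_height = det$cut_height, sizes = as.list(det$sizes)),
  OUT("network", "network_summary.json"),
  auto_unbox = TRUE, digits = NA, dataframe = "rows")
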