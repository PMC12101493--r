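#!/usr/bin/env Rscript
# Environmental drivers of lipid remodelling: mixed-layer chain length
# versus in situ temperature (OLS, both saturation classes), PCA of
# module intensities with environmental loading vectors, random-forest
# attribution of temperature vs phosphate for SFA/MUFA class shares
# (with ICE curves), the warm/cold module intensity ratio across SST by
# layer, PUFA enrichment at the DCM per lipid class, and the depth of
# peak EPA relative to the DCM.

source("analysis/common.R")

dat <- load_study_data()
labels_df <- utils::read.delim(OUT("network", "module_labels.tsv"))
labels <- stats::setNames(as.integer(sub("^EL", "", labels_df$el)),
                          labels_df$lipid_id)
feats <- feature_table(unclass(dat$features)[labels_df$lipid_id, ], "raw")
el_df <- utils::read.delim(OUT("spatial", "el_relative_intensity.tsv"),
                           check.names = FALSE)
el_tab <- as.matrix(el_df[, -1]); rownames(el_tab) <- el_df[[1]]
el_cols <- setdiff(colnames(el_tab), "EL0")
species <- dat$species
md <- dat$metadata

for (cls in c("SFA/MUFA", "PUFA-containing")) {
  r <- tryCatch(chain_length_vs_temperature(feats, species, md, cls),
                error = function(e) NULL)
  if (is.null(r)) next
  message(sprintf(
    "%s chain length ~ temperature: slope %.4f C/FA per degree (95%% CI %.4f..%.4f), R^2 %.2f, n %d",
    cls, r$slope, r$slope_ci[1], r$slope_ci[2], r$r_squared, r$n))
  tag <- if (cls == "SFA/MUFA") "sfa_mufa" else "pufa"
  jsonlite::write_json(r[c("slope", "intercept", "r_squared", "slope_se",
                           "slope_ci", "n")],
                       OUT("environment", paste0("chain_length_", tag,
                                                 ".json")),
                       auto_unbox = TRUE, digits = NA)
}

pca <- pca_el_environment(el_tab[, el_cols, drop = FALSE], md)
top <- rownames(pca$projection)[which.max(
  abs(pca$projection[, "temperature_c"]))]
message(sprintf("PCA: %s has the longest projection onto temperature", top))
write_tsv(data.frame(el = rownames(pca$projection), pca$projection,
                     check.names = FALSE),
          OUT("environment", "pca_projections.tsv"))

shares <- sfa_mufa_class_intensity(feats, species)
surf <- in_mixed_layer(md)[match(rownames(shares), md$sample_id)]
X <- data.frame(
  temperature_c = md$temperature_c[match(rownames(shares),
                                         md$sample_id)][surf],
  po4_um = md$po4_um[match(rownames(shares), md$sample_id)][surf])
rf_rows <- list(); ice_rows <- list()
for (cls in colnames(shares)) {
  r <- tryCatch(suppressWarnings(
    rf_attribution(X, shares[surf, cls], seed = SEED)),
    error = function(e) NULL)
  if (is.null(r)) next
  rf_rows[[cls]] <- data.frame(class = cls, r_squared = r$r_squared,
                               t(r$importance), check.names = FALSE)
  ice <- r$ice; ice$class <- cls
  ice_rows[[cls]] <- ice
}
rf_tab <- do.call(rbind, rf_rows)
write_tsv(rf_tab, OUT("environment", "rf_attribution.tsv"))
write_tsv(do.call(rbind, ice_rows), OUT("environment", "ice_curves.tsv"))
best <- rf_tab[order(-rf_tab$r_squared), ][1, ]
message(sprintf("random forest: best-predicted class %s (R^2 %.2f)",
                best$class, best$r_squared))

dcm <- dcm_depth(md)
layer <- assign_layer(md, dcm)
sst <- station_sst(md)
cors <- apply(el_tab[, el_cols, drop = FALSE], 2, function(v) {
  suppressWarnings(stats::cor(v, sst[md$station[match(rownames(el_tab),
                                                      md$sample_id)]],
                              use = "complete.obs"))
})
ra <- names(which.max(cors)); rb <- names(which.min(cors))
ratio <- el_ratio_by_sst(el_tab, ra, rb, md, layer, seed = SEED)
message(sprintf("ratio %s/(%s+%s): %d SST bins with a significant DCM excess",
                ra, ra, rb, sum(ratio$dcm_higher, na.rm = TRUE) / 2))
write_tsv(ratio, OUT("environment", "el_ratio_by_sst.tsv"))

pufa <- pufa_layer_contrast(feats, species, layer)
message(sprintf("PUFA DCM enrichment: %s",
                paste(pufa$class[pufa$dcm_higher], collapse = ", ")))
write_tsv(pufa, OUT("environment", "pufa_layer_contrast.tsv"))

epa <- epa_depth_vs_dcm(feats, species, md, dcm)
message(sprintf(
  "EPA max depth vs DCM: median offset %.0f m (signed-rank p = %.3f, %d stations)",
  epa$median_difference, epa$p, nrow(epa$per_station)))
write_tsv(epa$per_station, OUT("environment", "epa_depth_vs_dcm.tsv"))
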