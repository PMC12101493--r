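#!/usr/bin/env Rscript
# Integrate the distributional, province and depth views of the modules
# into one meta-dendrogram (Monte Carlo node significance, cophenetic
# consistency), build the structural dendrogram from intensity-weighted
# profiles (headgroups, chain length, saturation, phosphorus), compare
# the two clusterings as a tanglegram, and test structural differences
# with a sample-random-intercept mixed model.

source("analysis/common.R")

dat <- load_study_data()
labels_df <- utils::read.delim(OUT("network", "module_labels.tsv"))
labels <- stats::setNames(as.integer(sub("^EL", "", labels_df$el)),
                          labels_df$lipid_id)
feats <- feature_table(unclass(dat$features)[labels_df$lipid_id, ], "raw")
el_df <- utils::read.delim(OUT("spatial", "el_relative_intensity.tsv"),
                           check.names = FALSE)
el_tab <- as.matrix(el_df[, -1]); rownames(el_tab) <- el_df[[1]]
prof_df <- utils::read.delim(OUT("network", "projected_profiles.tsv"),
                             check.names = FALSE)
ref_df <- utils::read.delim(OUT("network", "eigenlipid_profiles.tsv"),
                            check.names = FALSE)
profiles <- rbind(as.matrix(ref_df[, -1]), as.matrix(prof_df[, -1]))
rownames(profiles) <- c(ref_df[[1]], prof_df[[1]])

els <- structure(list(profiles = profiles), class = "eigenlipid_set")
dists <- build_el_distances(els, el_tab, dat$metadata)
tree <- stats::hclust(stats::as.dist(dists$integrated), "average")
nodes <- node_significance(t(profiles), tree, n_sim = 499L, seed = SEED)
k <- max(2L, min(sum(nodes$significant) + 1L, nrow(dists$integrated) - 1L))
meta <- meta_dendrogram(dists, k = k)
message(sprintf("meta-clustering: %d clusters (%s); cophenetic %.2f",
                k, paste(sprintf("%s:%s", names(meta$clusters),
                                 meta$clusters), collapse = " "),
                meta$cophenetic))
write_tsv(data.frame(el = names(meta$clusters),
                     meta_cluster = meta$clusters),
          OUT("meta", "meta_clusters.tsv"))
jsonlite::write_json(nodes, OUT("meta", "node_significance.json"),
                     auto_unbox = TRUE, digits = NA, dataframe = "rows")
write_dendrogram_newick(meta$tree, OUT("meta", "meta_dendrogram.nwk"))

rel <- normalize_total(feats)
species <- dat$species
prof <- structural_profiles(labels, species, rel, min_annotated = 5L)
if (length(attr(prof, "excluded"))) {
  message("excluded from structural analysis (too few annotated species): ",
          paste(attr(prof, "excluded"), collapse = ", "))
}
write_tsv(prof, OUT("meta", "structural_profiles.tsv"))
sd_tree <- structural_dendrogram(prof)
write_dendrogram_newick(sd_tree$tree, OUT("meta",
                                          "structural_dendrogram.nwk"))

shared <- intersect(prof$el, colnames(dists$integrated))
dist_tree <- stats::hclust(stats::as.dist(
  dists$integrated[shared, shared]), "average")
tangle <- entanglement(dist_tree, sd_tree$tree, L = 1.5)
message(sprintf(
  "tanglegram: entanglement %.3f after untangling (raw %.3f); cophenetic %.2f (distributional) / %.2f (structural)",
  tangle$entanglement, tangle$entanglement_raw, meta$cophenetic,
  sd_tree$cophenetic))
jsonlite::write_json(
  list(entanglement = tangle$entanglement,
       entanglement_raw = tangle$entanglement_raw, L = tangle$L,
       cophenetic_distributional = meta$cophenetic,
       cophenetic_structural = sd_tree$cophenetic,
       order_distributional = tangle$order_left,
       order_structural = tangle$order_right),
  OUT("meta", "entanglement.json"), auto_unbox = TRUE, digits = NA)

chain_prop <- property_by_sample_el(rel, labels, species, "chain_length")
mm <- property_mixed_model(chain_prop)
message(sprintf("mixed model (chain length ~ module + (1|sample)): %d of %d contrasts at FDR 0.05",
                sum(mm$coefficients$p_adj < 0.05, na.rm = TRUE),
                sum(!is.na(mm$coefficients$p_adj))))
write_tsv(mm$coefficients, OUT("meta", "structural_mixed_model.tsv"))
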