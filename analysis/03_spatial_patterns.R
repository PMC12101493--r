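#!/usr/bin/env Rscript
# Spatial characterisation of the modules: per-sample relative
# intensities, the depth at which each module peaks per station and its
# relation to the deep chlorophyll maximum (two-sided Mann-Whitney with
# Cliff's Delta, BH-adjusted), mixed-layer Longhurst-province enrichment
# (one-sided), headgroup enrichment (chi-square goodness of fit against a
# uniform spread over modules) and module-pigment correlations.

source("analysis/common.R")

dat <- load_study_data()
labels_df <- utils::read.delim(OUT("network", "module_labels.tsv"))
labels <- stats::setNames(as.integer(sub("^EL", "", labels_df$el)),
                          labels_df$lipid_id)
feats <- feature_table(unclass(dat$features)[labels_df$lipid_id, ], "raw")

el_tab <- el_relative_intensity(feats, labels)
el_cols <- setdiff(colnames(el_tab), "EL0")
write_tsv(data.frame(sample_id = rownames(el_tab), el_tab,
                     check.names = FALSE),
          OUT("spatial", "el_relative_intensity.tsv"))

dcm <- dcm_depth(dat$metadata)
el_max <- el_maximum_depth(el_tab[, el_cols, drop = FALSE], dat$metadata)
cmp <- depth_comparisons(el_max, dcm)
message(sprintf("depth contrasts: %d of %d significant at FDR 0.05",
                sum(cmp$p_adj < 0.05, na.rm = TRUE), nrow(cmp)))
write_tsv(dcm, OUT("spatial", "dcm_depth.tsv"))
write_tsv(el_max, OUT("spatial", "el_maximum_depth.tsv"))
write_tsv(cmp, OUT("spatial", "depth_comparisons.tsv"))

prov <- province_enrichment(el_tab[, el_cols, drop = FALSE], dat$metadata)
sig <- prov[prov$p_adj < 0.05 & prov$delta > 0, ]
message(sprintf("province enrichment: %d module-province pairs at FDR 0.05 (%s)",
                nrow(sig),
                paste(unique(paste0(sig$el, ">", sig$province)),
                      collapse = ", ")))
write_tsv(prov, OUT("spatial", "province_enrichment.tsv"))

hg <- headgroup_enrichment(labels, dat$species)
write_tsv(hg, OUT("spatial", "headgroup_enrichment.tsv"))

pig <- correlate_el_with_pigment(el_tab[, el_cols, drop = FALSE],
                                 dat$metadata)
message(sprintf("chlorophyll tracking: strongest positive rho %s (%.2f)",
                pig$el[which.max(pig$rho)], max(pig$rho)))
write_tsv(pig, OUT("spatial", "pigment_correlations.tsv"))
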