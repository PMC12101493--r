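test_that("chain-length regression reproduces an exact collinear fit", {
  # two species at 14 and 18 C/FA; weights chosen so the per-sample
  # weighted mean is 14, 14.4, 14.8 at T = 0, 10, 20
  sp <- classify_saturation(parse_lipid_name(c("PC 28:0", "PC 36:0")))
  sp$id <- c("a", "b")
  w18 <- c(0, 0.1, 0.2)
  x <- rbind(a = 1 - w18, b = w18)
  colnames(x) <- sprintf("s%d", 1:3)
  md <- data.frame(sample_id = colnames(x), temperature_c = c(0, 10, 20),
                   depth_m = 5, mld_m = 30)
  r <- suppressWarnings(          # exact fit: lm warns about perfection
    chain_length_vs_temperature(feature_table(x, "raw"), sp, md,
                                "SFA/MUFA"))
  expect_equal(r$slope, 0.04, tolerance = 1e-12)
  expect_equal(r$intercept, 14, tolerance = 1e-12)
  expect_equal(r$r_squared, 1)
  expect_error(chain_length_vs_temperature(feature_table(x[, 1:2], "raw"),
                                           sp, md, "SFA/MUFA"), ">= 3")
})

test_that("the planted slope is recovered within 2 standard errors", {
  sim <- simulate_ocean(ocean_config(seed = 71L))
  filt <- blank_subtract(sim$features, sim$blanks)$features
  r <- chain_length_vs_temperature(filt, sim$species, sim$metadata,
                                   "SFA/MUFA")
  expect_gte(r$n, 90)
  expect_lt(abs(r$slope - 0.04), 2 * r$slope_se)
})

test_that("PCA projections single out a temperature-tracking module", {
  set.seed(72)
  n <- 60
  md <- data.frame(sample_id = sprintf("s%02d", 1:n),
                   temperature_c = seq(0, 30, length.out = n),
                   po4_um = runif(n), depth_m = 5)
  el <- cbind(ELt = md$temperature_c / 30 + rnorm(n, 0, 0.02),
              ELa = runif(n), ELb = runif(n), ELc = runif(n))
  rownames(el) <- md$sample_id
  p <- pca_el_environment(el, md, covariates = c("temperature_c", "po4_um"))
  proj <- p$projection[, "temperature_c"]
  expect_equal(names(which.max(abs(proj))), "ELt")
  # total variance identity for standardised input
  expect_equal(sum(p$explained), 1)
  expect_error(pca_el_environment(el, transform(md, po4_um = 1),
                                  covariates = "po4_um"), "no usable")
})

test_that("random forests attribute a planted monotone driver", {
  set.seed(73)
  n <- 120
  X <- data.frame(temperature_c = runif(n, 0, 30),
                  po4_um = runif(n, 0, 2))
  y <- X$temperature_c / 30                  # deterministic in temperature
  r <- rf_attribution(X, y, seed = 7L, ntree = 300L)
  expect_gt(r$importance_raw["temperature_c"], r$importance_raw["po4_um"])
  expect_gt(r$r_squared, 0.9)
  expect_equal(sum(r$importance_raw), 1)
  # ICE curves are monotone for the monotone response
  ice_t <- r$ice[r$ice$predictor == "temperature_c", ]
  mean_curve <- tapply(ice_t$prediction, ice_t$grid_value, mean)
  expect_true(all(diff(mean_curve[order(as.numeric(names(mean_curve)))])
                  >= -1e-9))
  # permuting the response collapses the attribution
  set.seed(74)
  rp <- suppressWarnings(rf_attribution(X, sample(y), seed = 7L,
                                        ntree = 300L))
  expect_lt(sum(rp$importance), 0.15)        # R^2-scaled ~ 0
})

test_that("SFA/MUFA class shares are proportions that sum to one", {
  sp <- classify_saturation(parse_lipid_name(
    c("MGDG 32:1", "SQDG 30:0", "PC 34:1", "PC 16:0/20:5")))
  sp$id <- sprintf("L%d", 1:4)
  x <- matrix(c(30, 10, 60, 50), 4, 1, dimnames = list(sp$id, "s1"))
  sh <- sfa_mufa_class_intensity(feature_table(x, "raw"), sp)
  expect_equal(unname(sh["s1", c("MGDG", "SQDG", "PC")]),
               c(0.3, 0.1, 0.6))              # PUFA PC excluded
  expect_equal(sum(sh), 1)
})

test_that("module ratio curves detect a planted layer shift in warm bins", {
  set.seed(75)
  n_st <- 40
  md <- data.frame(sample_id = sprintf("s%03d", 1:(2 * n_st)),
                   station = rep(sprintf("S%02d", 1:n_st), each = 2),
                   depth_m = rep(c(5, 80), n_st),
                   mld_m = 30,
                   temperature_c = rep(seq(2, 29, length.out = n_st),
                                       each = 2))
  layer <- stats::setNames(rep(c("mixed", "dcm"), n_st), md$sample_id)
  warm <- rep(md$temperature_c[seq(1, 2 * n_st, 2)] > 16, each = 2)
  a <- 1 + 0.1 * rnorm(2 * n_st)
  a[layer == "dcm" & warm] <- a[layer == "dcm" & warm] + 2.5
  b <- rep(1, 2 * n_st)
  el <- cbind(EL8 = pmax(a, 0.1), EL16 = b)
  rownames(el) <- md$sample_id
  r <- el_ratio_by_sst(el, "EL8", "EL16", md, layer, bin_width = 4,
                       n_boot = 200L, seed = 3L)
  expect_true(all(r$mean_ratio >= 0 & r$mean_ratio <= 1, na.rm = TRUE))
  flagged <- unique(r$sst_mid[r$dcm_higher])
  expect_true(all(flagged > 14))
  expect_gt(length(flagged), 0)
  # equal modules: ratio 0.5 and nothing significant
  el2 <- cbind(EL8 = rep(1, 2 * n_st), EL16 = rep(1, 2 * n_st))
  rownames(el2) <- md$sample_id
  r2 <- el_ratio_by_sst(el2, "EL8", "EL16", md, layer, n_boot = 100L)
  expect_true(all(r2$mean_ratio == 0.5, na.rm = TRUE))
  expect_false(any(r2$dcm_higher, na.rm = TRUE))
})

test_that("PUFA layer contrast flags the planted chloroplast enrichment", {
  sim <- simulate_ocean(ocean_config(seed = 76L))
  layer <- assign_layer(sim$metadata)
  r <- pufa_layer_contrast(sim$features, sim$species, layer)
  chloro <- c("SQDG", "MGDG", "DGDG", "PG")
  hits <- r$class[r$dcm_higher]
  expect_true(all(chloro %in% r$class))
  expect_true(all(hits %in% chloro))
  expect_true(length(hits) >= 3)
})

test_that("EPA maximum depth tracks the planted DCM module", {
  sim <- simulate_ocean(recovery_config(seed = 77L))
  r <- epa_depth_vs_dcm(sim$features, sim$species, sim$metadata)
  grid <- ocean_config()$depth_grid
  step <- max(diff(grid))
  expect_lte(abs(r$median_difference), step)
  expect_true(all(c("epa_depth_m", "dcm_m", "difference_m") %in%
                    names(r$per_station)))
})

test_that("layer assignment separates mixed, DCM and other samples", {
  sim <- simulate_ocean(ocean_config(n_regions = 1L, seed = 78L))
  layer <- assign_layer(sim$metadata)
  md <- sim$metadata
  expect_true(all(md$depth_m[layer == "mixed"] <= md$mld_m[layer ==
                                                             "mixed"]))
  expect_true(all(c("mixed", "dcm", "other") %in% unique(layer)))
})
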