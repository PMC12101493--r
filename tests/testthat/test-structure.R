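toy_profile_inputs <- function() {
  nms <- c("PC 32:0", "PC 36:2", "SQDG 28:0", "DGDG 36:6", "PG 34:1",
           "PC 30:0", "PC 34:1", "PC 32:1", "PC 36:1", "PC 28:0",
           "SQDG 30:1", "DGDG 32:0", "SQDG 34:2", "PG 32:0", "DGDG 30:1")
  sp <- classify_saturation(parse_lipid_name(nms))
  sp$id <- sprintf("L%02d", seq_along(nms))
  labels <- stats::setNames(c(rep(1L, 10), rep(2L, 5)), sp$id)
  x <- matrix(1, length(nms), 4,
              dimnames = list(sp$id, sprintf("s%d", 1:4)))
  rel <- normalize_total(feature_table(x, "raw"))
  list(sp = sp, labels = labels, rel = rel)
}

test_that("structural profiles aggregate compositions and exclusions", {
  ti <- toy_profile_inputs()
  prof <- structural_profiles(ti$labels, ti$sp, ti$rel, min_annotated = 5L)
  comp <- attr(prof, "headgroup_composition")
  # EL2 is all chloroplast glycolipid/PG, phosphorus-free except PG
  expect_equal(prof$frac_chloroplast[prof$el == "EL2"], 1)
  expect_equal(prof$frac_phosphorus_free[prof$el == "EL2"], 4 / 5)
  expect_equal(sum(comp["EL1", ]), 1)
  # a pure-PC module has composition {PC: 1}
  spP <- ti$sp[1:6, ]; spP$headgroup <- "PC"
  labP <- stats::setNames(c(rep(1L, 3), rep(2L, 3)), spP$id)
  relP <- normalize_total(feature_table(
    matrix(1, 6, 3, dimnames = list(spP$id, sprintf("s%d", 1:3))), "raw"))
  profP <- structural_profiles(labP, spP, relP, min_annotated = 2L)
  expect_equal(unname(attr(profP, "headgroup_composition")[, "PC"]),
               c(1, 1))
  # exclusion below the annotation threshold
  prof5 <- structural_profiles(ti$labels, ti$sp, ti$rel, min_annotated = 6L)
  expect_equal(attr(prof5, "excluded"), "EL2")
})

test_that("equal-intensity chain lengths average to the midpoint", {
  sp <- classify_saturation(parse_lipid_name(c("PC 28:0", "PC 32:0")))
  sp$id <- c("a", "b")
  rel <- normalize_total(feature_table(
    matrix(1, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2"))), "raw"))
  prof <- structural_profiles(stats::setNames(c(1L, 1L), c("a", "b")),
                              sp, rel, min_annotated = 1L)
  expect_equal(prof$mean_chain_length, 15)
})

test_that("the mixed model recovers a clean module offset", {
  set.seed(60)
  df <- expand.grid(sample = sprintf("s%02d", 1:30),
                    el = c("EL1", "EL2"), stringsAsFactors = FALSE)
  # no sample-specific variation: the random-intercept variance is ~0 and
  # the EL contrast equals the planted 1.0 offset
  df$value <- ifelse(df$el == "EL2", 2, 1) + rnorm(nrow(df), 0, 0.05)
  fit <- property_mixed_model(df)
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "elEL2"], 1, tolerance = 0.05)
  expect_lt(fit$random_intercept_sd, 0.05)
  expect_false(fit$fallback)
})

test_that("the mixed model z tests detect planted shifts, not nulls", {
  set.seed(61)
  mk <- function(shift) {
    df <- expand.grid(sample = sprintf("s%02d", 1:40),
                      el = c("EL1", "EL2", "EL3"), stringsAsFactors = FALSE)
    samp_eff <- stats::setNames(rnorm(40, 0, 0.5), sprintf("s%02d", 1:40))
    df$value <- samp_eff[df$sample] + rnorm(nrow(df), 0, 0.5) +
      ifelse(df$el == "EL3", shift, 0)
    df
  }
  hit <- property_mixed_model(mk(1))$coefficients
  expect_lt(hit$p_adj[hit$term == "elEL3"], 0.05)
  # null calibration: few false positives across replicates
  fp <- 0
  for (i in 1:30) {
    co <- property_mixed_model(mk(0))$coefficients
    if (any(co$p_adj < 0.05, na.rm = TRUE)) fp <- fp + 1
  }
  expect_lte(fp, 5)
})

test_that("structural dendrogram uses Gower-type field contributions", {
  prof <- data.frame(el = paste0("EL", 1:4),
                     n_species = 10,
                     mean_chain_length = c(14, 16, 14, 14),
                     mean_double_bonds = c(1, 1, 1, 1),
                     frac_pufa = c(0.2, 0.2, 0.2, 0.2),
                     frac_phosphorus_free = c(0.5, 0.5, 0.5, 0.5),
                     frac_odd_chain = c(0, 0, 0, 0))
  comp <- matrix(0.25, 4, 4, dimnames = list(prof$el, c("PC", "PG",
                                                        "SQDG", "DGDG")))
  attr(prof, "headgroup_composition") <- comp
  sd <- structural_dendrogram(prof)
  # only chain length varies: full-range difference contributes 1 / 1 field
  expect_equal(sd$distance["EL1", "EL2"], 1)
  expect_equal(sd$distance["EL1", "EL3"], 0)
  expect_true(all(c("mean_double_bonds", "frac_pufa") %in%
                    sd$dropped_fields))
  # duplicated profiles merge first
  expect_equal(min(sd$tree$height), 0)
})

test_that("entanglement identities hold on constructed trees", {
  left <- caterpillar_tree(letters[1:4])
  expect_equal(entanglement(left, left)$entanglement, 0)

  # right tree ((b,a),(d,c)): leaf order b, a, d, c
  right <- structure(list(merge = rbind(c(-2L, -1L), c(-4L, -3L),
                                        c(1L, 2L)),
                          height = c(1, 1, 2), order = 1:4,
                          labels = letters[1:4], method = "average"),
                     class = "hclust")
  raw <- entanglement(left, right, L = 1, untangle = FALSE)
  expect_equal(raw$entanglement_raw, 0.5)   # (1+1+1+1)/8

  rev_cat <- caterpillar_tree(rev(letters[1:4]))
  full <- entanglement(left, rev_cat, L = 1.5, untangle = FALSE)
  expect_equal(full$entanglement_raw, 1)

  unt <- entanglement(left, rev_cat, L = 1.5, untangle = TRUE)
  expect_lte(unt$entanglement, unt$entanglement_raw)
  # symmetry
  ab <- entanglement(left, right, L = 1.5)
  ba <- entanglement(right, left, L = 1.5)
  expect_equal(ab$entanglement, ba$entanglement)
  expect_error(entanglement(left, caterpillar_tree(letters[2:5])),
               "leaf sets differ")
})

test_that("untangling never increases the score on random trees", {
  set.seed(62)
  for (i in 1:10) {
    n <- 8
    dl <- stats::dist(matrix(rnorm(n * 3), n))
    dr <- stats::dist(matrix(rnorm(n * 3), n))
    tl <- stats::hclust(dl, method = "average")
    tr <- stats::hclust(dr, method = "average")
    tl$labels <- tr$labels <- paste0("EL", 1:n)
    res <- entanglement(tl, tr)
    expect_lte(res$entanglement, res$entanglement_raw + 1e-12)
    expect_gte(res$entanglement, 0)
    expect_lte(res$entanglement, 1)
  }
})
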