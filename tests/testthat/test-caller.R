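test_that("the ratio rule bands the positive quadrant exhaustively", {
  expect_equal(call_kasp(0.05, 0.05), "no_call")        # below floor
  expect_equal(call_kasp(0.10, 1.00), "target_hom")
  expect_equal(call_kasp(1.00, 0.10), "alt_hom")
  expect_equal(call_kasp(0.55, 0.55), "het")
  expect_equal(call_kasp(0.30, 0.70), "no_call")        # gap between bands
  expect_error(call_kasp(-0.1, 0.5), "non-negative")
  # partition property on a grid
  g <- expand.grid(fam = seq(0, 1.2, by = 0.04), hex = seq(0, 1.2, by = 0.04))
  calls <- call_kasp(g$fam, g$hex)
  expect_true(all(calls %in% c("target_hom", "alt_hom", "het", "no_call")))
  expect_length(calls, nrow(g))
})

test_that("the caller recovers at least 99% of simulated labels per class", {
  sd0 <- simulation_config()$fluorescence_noise_sd
  for (cls in c("target_hom", "alt_hom", "het")) {
    pts <- simulate_fluorescence(rep(cls, 1000), noise_sd = sd0, seed = 404)
    acc <- mean(call_kasp(pts$fam, pts$hex) == cls)
    expect_gte(acc, 0.99)
  }
  ntc <- simulate_fluorescence(rep("ntc", 1000), noise_sd = sd0, seed = 405)
  expect_gte(mean(call_kasp(ntc$fam, ntc$hex) == "no_call"), 0.99)
})

test_that("codominant band patterns classify by matched alleles", {
  co <- scar_assay("SCAR2", "codominant", c(target = 516, other = 537))
  expect_equal(call_scar2(c(516L), co), "target_only")
  expect_equal(call_scar2(c(516L, 537L), co), "both")
  expect_equal(call_scar2(c(537L), co), "other_only")
  expect_equal(call_scar2(integer(0), co), "none")
  expect_equal(call_scar2(c(514L), co), "target_only")  # within +-5 bp
  expect_error(call_scar2(c(400L), co), "matches no mapped")
  expect_error(call_scar2(c(516L), co, size_tolerance = 15), "ambiguous")
  dom <- scar_assay("SCAR1", "dominant", c(target = NA_real_, other = 116))
  expect_error(call_scar2(integer(0), dom), "codominant")
})

test_that("the merged two-locus rule encodes the validated combined table", {
  expect_equal(combined_scar_classify(FALSE, "target_only"), "target")
  expect_equal(combined_scar_classify(FALSE, "both"), "target")
  expect_equal(combined_scar_classify(TRUE, "target_only"), "target")
  expect_equal(combined_scar_classify(TRUE, "other_only"), "nontarget")
  expect_equal(combined_scar_classify(TRUE, "both"), "heterozygous_hybrid")
  # combinations outside the validated table fail safe
  expect_equal(combined_scar_classify(FALSE, "none"), "ambiguous")
  expect_equal(combined_scar_classify(FALSE, "other_only"), "ambiguous")
  expect_equal(combined_scar_classify(TRUE, "none"), "ambiguous")
})

test_that("per-sample KASP species call aggregates assays conservatively", {
  expect_equal(as.character(
    kasp_species_call(c("target_hom", "target_hom", "target_hom"))),
    "target")
  expect_equal(as.character(kasp_species_call(rep("alt_hom", 3))),
               "nontarget")
  expect_equal(as.character(kasp_species_call(c("het", "het", "het"))),
               "heterozygous_hybrid")
  expect_equal(as.character(
    kasp_species_call(c("target_hom", "alt_hom", "target_hom"))),
    "ambiguous")
  lc <- kasp_species_call(c("target_hom", "no_call", "target_hom"))
  expect_equal(as.character(lc), "target")
  expect_true(attr(lc, "low_confidence"))
  expect_equal(as.character(kasp_species_call(rep("no_call", 3))), "no_call")
  expect_error(kasp_species_call(character(0)), "at least one")
})
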