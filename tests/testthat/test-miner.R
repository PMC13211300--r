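test_that("the fixed-allele definition is enforced literally", {
  # reference all hom-alt, contrast all hom-ref -> candidate (alt)
  gm <- toy_gm(rbind(c(2L), c(2L), c(0L), c(0L)))
  hit <- mine_fixed_alleles(gm, c("S01", "S02"), c("S03", "S04"))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$diagnostic_allele, "alt")

  # diagnostic allele present in a contrast heterozygote -> rejected
  gm2 <- toy_gm(rbind(c(2L), c(2L), c(0L), c(1L)))
  expect_equal(nrow(mine_fixed_alleles(gm2, c("S01", "S02"),
                                       c("S03", "S04"))), 0L)

  # missing reference genotype -> rejected
  gm3 <- toy_gm(rbind(c(2L), c(NA), c(0L)))
  expect_equal(nrow(mine_fixed_alleles(gm3, c("S01", "S02"), "S03")), 0L)

  # heterozygous reference genotype -> rejected
  gm4 <- toy_gm(rbind(c(2L), c(1L), c(0L)))
  expect_equal(nrow(mine_fixed_alleles(gm4, c("S01", "S02"), "S03")), 0L)
})

test_that("set handling is validated", {
  gm <- toy_gm(rbind(c(2L), c(0L)))
  expect_error(mine_fixed_alleles(gm, "S01", "S01"), "disjoint")
  expect_error(mine_fixed_alleles(gm, character(0), "S02"), "non-empty")
  expect_error(mine_fixed_alleles(gm, "S01", "S99"), "unknown")
})

test_that("SCAR eligibility requires a large InDel; KASP accepts both types", {
  geno <- rbind(c(2L, 2L, 2L), c(2L, 2L, 2L), c(0L, 0L, 0L))
  gm <- toy_gm(geno, types = c("SNP", "InDel", "InDel"))
  gm$loci$ref[3] <- "CT"; gm$loci$alt[3] <- "C"   # 1-bp InDel
  hit <- mine_fixed_alleles(gm, c("S01", "S02"), "S03")
  expect_equal(hit$kasp_eligible, rep(TRUE, 3))
  expect_equal(hit$scar_eligible, c(FALSE, TRUE, FALSE))
})

test_that("miner equals the brute-force oracle on random panels", {
  set.seed(101)
  for (rep in 1:100) {
    gm <- random_gm(10, 50)
    ref_ids <- gm$sample_ids[1:4]
    con_ids <- gm$sample_ids[5:8]
    got <- mine_fixed_alleles(gm, ref_ids, con_ids)
    want <- oracle_fixed_alleles(gm, ref_ids, con_ids)
    expect_equal(got$locus_index, want$locus_index)
    expect_equal(got$diagnostic_allele, want$diagnostic_allele)
  }
})

test_that("mining is monotone under shrinking either sample set", {
  set.seed(202)
  for (rep in 1:25) {
    gm <- random_gm(12, 60)
    ref <- gm$sample_ids[1:5]
    con <- gm$sample_ids[6:10]
    full <- nrow(mine_fixed_alleles(gm, ref, con))
    expect_gte(nrow(mine_fixed_alleles(gm, ref[1:3], con)), full)
    expect_gte(nrow(mine_fixed_alleles(gm, ref, con[1:3])), full)
  }
})

test_that("stage 1 fails on a cryptic F1 in the reference; stage 2 recovers", {
  cfg <- simulation_config(
    n_loci = 60, n_fixed_diff = 20, n_fixed_indel = 2,
    class_counts = c(target_purebred = 6, target_variant = 1,
                     cryptic_f1 = 1, nontarget_species = 4, f1_hybrid = 2),
    missing_rate = 0, low_depth_rate = 0, low_mapq_rate = 0, seed = 31)
  pan <- simulate_panel(cfg)
  cls <- attr(pan$sheet, "sim_class")
  recl <- pan$sheet$id[cls %in% c("cryptic_f1", "target_variant")]
  mn <- two_stage_mining(pan$gm, pan$sheet, recl)
  planted <- sort(pan$fixed_diff$locus_index)
  expect_length(intersect(mn$stage1$locus_index, planted), 0L)
  expect_equal(sort(mn$stage2$locus_index), planted)
  # empty reclassification: stage 2 equals stage 1
  mn0 <- two_stage_mining(pan$gm, pan$sheet, character(0))
  expect_equal(mn0$stage2$locus_index, mn0$stage1$locus_index)
  # reclassified variants join the contrast: loci where a variant carries
  # the diagnostic allele are excluded (planted loci survive because the
  # simulated variants carry the non-target allele there)
  expect_true(all(mn$stage2$stage == "stage2"))
  expect_error(two_stage_mining(pan$gm, pan$sheet, pan$sheet$id[1:8]),
               "empties")
  expect_error(two_stage_mining(pan$gm, pan$sheet, "S99"), "subset")
})
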