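test_that("Wilson interval reproduces closed-form spot checks", {
  expect_equal(unname(round(wilson_interval(62, 64), 3)), c(0.893, 0.991))
  expect_equal(unname(round(wilson_interval(63, 64), 3)[2]), 0.997)
  expect_equal(unname(wilson_interval(64, 64)[2]), 1.0)
  ci <- wilson_interval(32, 64)
  expect_equal(unname(ci[1]), 1 - unname(ci[2]))   # symmetry about 1/2
  expect_error(wilson_interval(65, 64), "successes")
  expect_error(wilson_interval(3, 0), "n must")
  expect_error(wilson_interval(3, 10, 1), "confidence")
})

test_that("Wilson bounds match numerical inversion of the score test", {
  # the interval is exactly the set of p0 not rejected by the score test
  score_stat <- function(p0, x, n) (x / n - p0) / sqrt(p0 * (1 - p0) / n)
  z <- qnorm(0.975)
  for (n in c(5, 20, 64, 200)) {
    for (x in unique(c(0, 1, round(n / 3), n - 1, n))) {
      ci <- wilson_interval(x, n)
      for (side in 1:2) {
        b <- unname(ci[side])
        if (b <= 1e-9 || b >= 1 - 1e-9) next  # degenerate roots at 0/1
        expect_equal(abs(score_stat(b, x, n)), z, tolerance = 1e-6,
                     label = sprintf("x=%d n=%d side=%d", x, n, side))
      }
    }
  }
})

test_that("interval width shrinks with n at fixed proportion", {
  w <- function(x, n) diff(unname(wilson_interval(x, n)))
  expect_true(w(8, 16) > w(32, 64))
  expect_true(w(32, 64) > w(320, 640))
})

test_that("hybrid index: F1 exactly 0.5, purebreds at the poles", {
  ta <- rep(c("ref", "alt"), 10)
  f1 <- rep(1L, 20)
  expect_equal(hybrid_index(f1, ta), 0.5)
  pure <- ifelse(ta == "ref", 0L, 2L)
  expect_equal(hybrid_index(pure, ta), 1.0)
  other <- ifelse(ta == "ref", 2L, 0L)
  expect_equal(hybrid_index(other, ta), 0.0)
  # missing loci are dropped from the denominator
  f1[3] <- NA
  expect_equal(hybrid_index(f1, ta), 0.5)
  expect_error(hybrid_index(c(NA_integer_, NA_integer_), c("ref", "alt")),
               "missing")
})

test_that("BC1 hybrid index converges to 0.75 in expectation", {
  cfg <- simulation_config(
    n_loci = 200, n_fixed_diff = 200, n_fixed_indel = 0,
    class_counts = c(bc1_target = 30, target_purebred = 1,
                     nontarget_species = 1),
    missing_rate = 0, low_depth_rate = 0, low_mapq_rate = 0, seed = 99)
  pan <- simulate_panel(cfg)
  cls <- attr(pan$sheet, "sim_class")
  idx <- pan$fixed_diff$locus_index
  hi <- vapply(which(cls == "bc1_target"), function(i)
    hybrid_index(pan$gm$geno[i, idx], pan$fixed_diff$target_allele),
    numeric(1))
  # mean of 30 x 200 Bernoulli allele draws: tight around 0.75
  expect_lt(abs(mean(hi) - 0.75), 0.01)
})

test_that("scoring requires an explicit convention and consistent labels", {
  sheet <- sample_sheet(c("a", "b"), c("target", "nontarget_species"),
                        c("target", "nontarget"), c(TRUE, FALSE))
  calls <- data.frame(sample = c("a", "b"),
                      call = c("target", "nontarget"))
  expect_error(score_panel(calls, sheet), "convention")
  rep <- score_panel(calls, sheet, "morphological")
  expect_equal(rep$concordance, 1.0)
  expect_length(rep$discordant, 0)
  expect_error(score_panel(data.frame(sample = "zz", call = "target"),
                           sheet, "genetic"), "absent")
})

test_that("counts telescope and sensitivity/specificity recompute from them", {
  cfg <- simulation_config(seed = 17)
  sc <- simulate_scenario("S1", config = cfg)
  kc <- call_kasp_panel(
    sc$fluorescence[sc$fluorescence$sample %in% sc$sheet$id, ])
  for (conv in c("morphological", "genetic")) {
    r <- score_panel(kc, sc$sheet, conv)
    expect_equal(sum(r$counts), r$n)
    expect_equal(r$n - length(r$discordant),
                 r$counts[["tp"]] + r$counts[["tn"]])
    expect_equal(r$sensitivity,
                 r$counts[["tp"]] / (r$counts[["tp"]] + r$counts[["fn"]]))
    expect_equal(r$specificity,
                 r$counts[["tn"]] / (r$counts[["tn"]] + r$counts[["fp"]]))
    expect_true(r$concordance_ci[1] <= r$concordance &&
                  r$concordance <= r$concordance_ci[2])
  }
})

test_that("the cryptic F1 is discordant morphologically but not genetically", {
  sc <- simulate_scenario("S1", seed = 2)
  cls <- attr(sc$sheet, "sim_class")
  kc <- call_kasp_panel(
    sc$fluorescence[sc$fluorescence$sample %in% sc$sheet$id, ])
  rm_ <- score_panel(kc, sc$sheet, "morphological")
  expect_equal(rm_$discordant, sc$sheet$id[cls == "cryptic_f1"])
  rg <- score_panel(kc, sc$sheet, "genetic")
  expect_length(rg$discordant, 0)
})
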