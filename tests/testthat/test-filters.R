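test_that("depth masking respects the inclusive boundary and is idempotent", {
  geno <- matrix(c(1L, 2L, 0L), 1)
  depth <- matrix(c(2L, 3L, 50L), 1)
  gm <- toy_gm(geno, depth)
  m <- apply_depth_mask(gm, 3)
  expect_equal(unname(m$geno), matrix(c(NA, 2L, 0L), 1))
  expect_identical(apply_depth_mask(m, 3), m)
  expect_identical(apply_depth_mask(gm, 0)$geno, gm$geno)
  expect_error(apply_depth_mask(gm, -1), ">= 0")
})

test_that("exact HWE test matches hand-enumerated cases", {
  expect_equal(hwe_exact_test(5, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 0, 7), 1)
  # 4 ref + 4 alt alleles: het in {0,2,4}, observed configuration modal
  expect_equal(hwe_exact_test(1, 2, 1), 1)
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
  expect_error(hwe_exact_test(-1, 2, 1), ">= 0")
})

test_that("exact HWE test equals full enumeration for all tables with n <= 20", {
  for (n in c(1:8, 12)) {
    for (naa in 0:n) for (nab in 0:(n - naa)) {
      nbb <- n - naa - nab
      expect_equal(hwe_exact_test(naa, nab, nbb),
                   oracle_hwe(naa, nab, nbb),
                   tolerance = 1e-10,
                   label = sprintf("(%d,%d,%d)", naa, nab, nbb))
    }
  }
})

make_filter_panel <- function(seed) {
  set.seed(seed)
  random_gm(12, 40)
}

test_that("boundary semantics: MAF and missingness are strict, MAPQ inclusive", {
  # locus 1: MAF exactly 0.05 over 10 diploid samples (1 alt allele / 20)
  geno <- cbind(c(1L, rep(0L, 9)),            # maf = 0.05 -> removed
                c(rep(1L, 3), rep(0L, 7)),    # maf = 0.15 -> kept
                rep(0L, 10),                  # monomorphic -> removed
                c(rep(NA, 3), rep(1L, 4), 0L, 0L, 2L))  # missing 30% -> removed
  gm <- toy_gm(geno)
  gm$loci$site_mapq <- c(60, 20, 60, 60)      # mapq 20 inclusive -> kept
  res <- filter_loci(gm, filter_thresholds(), hwe_population = gm$sample_ids)
  expect_equal(ncol(res$gm$geno), 1L)
  expect_equal(res$gm$loci$pos, gm$loci$pos[2])
})

test_that("surviving set equals brute-force re-evaluation of all five rules", {
  thr <- filter_thresholds()
  for (seed in 1:5) {
    gm <- make_filter_panel(seed)
    pop <- gm$sample_ids[1:6]
    res <- filter_loci(gm, thr, hwe_population = pop)
    # oracle: direct evaluation per locus
    masked <- gm
    masked$geno[!is.na(masked$depth) & masked$depth < thr$min_depth] <- NA
    keep <- vapply(seq_len(ncol(gm$geno)), function(j) {
      g <- masked$geno[, j]
      if (masked$loci$site_mapq[j] < thr$min_mapq) return(FALSE)
      if (mean(is.na(g)) >= thr$max_missing) return(FALSE)
      gg <- g[!is.na(g)]
      if (!length(gg)) return(FALSE)
      p <- sum(gg) / (2 * length(gg))
      if (min(p, 1 - p) <= thr$min_maf) return(FALSE)
      sub <- masked$geno[match(pop, gm$sample_ids), j]
      sub <- sub[!is.na(sub)]
      pval <- if (!length(sub)) 1 else
        hwe_exact_test(sum(sub == 0), sum(sub == 1), sum(sub == 2))
      pval >= thr$hwe_alpha
    }, logical(1))
    expect_equal(locus_key(res$gm$loci), locus_key(masked$loci[keep, ]))
  }
})

test_that("filtering is idempotent and its report telescopes", {
  gm <- make_filter_panel(42)
  thr <- filter_thresholds()
  pop <- gm$sample_ids[1:6]
  r1 <- filter_loci(gm, thr, hwe_population = pop)
  r2 <- filter_loci(r1$gm, thr, hwe_population = pop)
  expect_equal(r2$gm$geno, r1$gm$geno)
  expect_equal(locus_key(r2$gm$loci), locus_key(r1$gm$loci))
  rep <- r1$report
  ent <- rep$entering_snp + rep$entering_indel
  sur <- rep$surviving_snp + rep$surviving_indel
  expect_true(all(sur <= ent))
  expect_equal(ent[-1], sur[-length(sur)])
})

test_that("tightening mapq/missing/maf/alpha thresholds never adds survivors", {
  gm <- make_filter_panel(7)
  pop <- gm$sample_ids[1:6]
  n_surv <- function(thr) ncol(filter_loci(gm, thr, pop)$gm$geno)
  base <- n_surv(filter_thresholds())
  expect_lte(n_surv(filter_thresholds(min_mapq = 40)), base)
  expect_lte(n_surv(filter_thresholds(max_missing = 0.15)), base)
  expect_lte(n_surv(filter_thresholds(min_maf = 0.2)), base)
  expect_lte(n_surv(filter_thresholds(hwe_alpha = 0.2)), base)
})

test_that("empty or unknown HWE population is refused", {
  gm <- make_filter_panel(9)
  expect_error(filter_loci(gm, filter_thresholds(),
                           hwe_population = character(0)), "non-empty")
  expect_error(filter_loci(gm, filter_thresholds(),
                           hwe_population = "nobody"), "unknown")
})
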