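test_that("primer properties: length and GC are exact, Tm is deterministic", {
  expect_equal(primer_properties("TCCACTTCAAGAACCACCTCCGCTCC")$length, 26L)
  p <- primer_properties("AGCATGAGAGGGCGCAAAGG")
  expect_equal(p$length, 20L)
  expect_equal(p$gc, 0.60)
  expect_equal(primer_properties("GGGG")$gc, 1.0)
  expect_equal(primer_properties("acgt")$gc, 0.5)  # case-insensitive
  t1 <- primer_properties("AGCATGAGAGGGCGCAAAGG")$tm
  expect_identical(t1, primer_properties("AGCATGAGAGGGCGCAAAGG")$tm)
  expect_error(primer_properties(""), "non-empty")
  expect_error(primer_properties("ACGTN"), "only A, C, G, T")
})

test_that("Tm responds to composition and concentration as thermodynamics demands", {
  at <- primer_properties(strrep("AT", 10))$tm
  gc <- primer_properties(strrep("GC", 10))$tm
  expect_gt(gc, at)
  lo <- primer_properties("AGCATGAGAGGGCGCAAAGG", na_conc = 0.01)$tm
  hi <- primer_properties("AGCATGAGAGGGCGCAAAGG", na_conc = 0.5)$tm
  expect_gt(hi, lo)
})

# a flank with workable composition around a SNP
design_fixture <- function(seed = 3, n = 301, ref = "C", alt = "T") {
  loci <- data.frame(chrom = "c", pos = 1, ref = ref, alt = alt,
                     variant_type = ifelse(nchar(ref) == nchar(alt),
                                           "SNP", "InDel"),
                     site_mapq = 60)
  simulate_flanks(loci, width = n, seed = seed)
}

test_that("KASP allele primers differ only at the 3' SNP base and validate", {
  fl <- design_fixture()
  k <- design_kasp(fl$seq, fl$offset, "C", "T", "ref")
  expect_s3_class(k, "kasp_assay")
  a <- k$allele_primers[["ref"]]; b <- k$allele_primers[["alt"]]
  expect_equal(nchar(a), nchar(b))
  expect_equal(substr(a, 1, nchar(a) - 1), substr(b, 1, nchar(b) - 1))
  last <- c(substr(a, nchar(a), nchar(a)), substr(b, nchar(b), nchar(b)))
  expect_setequal(last, if (k$details$strand == "+") c("C", "T")
                  else c("G", "A"))
  expect_true(validate_assay(k))
  expect_equal(unname(k$dye_map[["ref"]]), "HEX")
})

test_that("an all-A homopolymer flank is undesignable", {
  flank <- strrep("A", 301)
  expect_null(design_kasp(flank, 151, "A", "T", "ref"))
})

test_that("design is deterministic and mirror-symmetric", {
  fl <- design_fixture(seed = 8)
  k1 <- design_kasp(fl$seq, fl$offset, "C", "T", "ref")
  k2 <- design_kasp(fl$seq, fl$offset, "C", "T", "ref")
  expect_identical(k1, k2)
  rc <- revcomp(fl$seq)
  pos2 <- nchar(fl$seq) - fl$offset + 1
  km <- design_kasp(rc, pos2, "G", "A", "ref")
  # same physical molecules, opposite strand labels
  expect_setequal(unname(km$allele_primers), unname(k1$allele_primers))
  expect_identical(km$common_primer, k1$common_primer)
  expect_true(km$details$strand != k1$details$strand)
})

test_that("flank preconditions are enforced", {
  fl <- design_fixture()
  expect_error(design_kasp(substr(fl$seq, 1, 150), 75, "C", "T", "ref"),
               "200 bp")
  expect_error(design_kasp(fl$seq, 9999, "C", "T", "ref"), "inside")
  expect_error(design_kasp(fl$seq, fl$offset + 1, "C", "T", "ref"),
               "reference allele")
})

test_that("codominant SCAR sizes differ by the InDel length, small InDels refused", {
  set.seed(77)
  ins21 <- paste0("A", markermine:::random_seq(21))
  fl <- design_fixture(seed = 12, n = 601, ref = ins21, alt = "A")
  s <- design_scar(fl$seq, fl$offset, ins21, "A", "codominant")
  expect_s3_class(s, "scar_assay")
  expect_equal(s$mode, "codominant")
  expect_equal(abs(diff(s$size_map)), 21, ignore_attr = TRUE)
  expect_true(validate_assay(s))
  ins10 <- paste0("A", markermine:::random_seq(10))
  fl10 <- design_fixture(seed = 12, n = 601, ref = ins10, alt = "A")
  expect_null(design_scar(fl10$seq, fl10$offset, ins10, "A", "codominant"))
  expect_error(design_scar(fl$seq, fl$offset, "C", "T", "codominant"),
               "InDel")
})

test_that("dominant SCAR maps the deletion allele to no band", {
  set.seed(78)
  ins60 <- paste0("A", markermine:::random_seq(60))
  fl <- design_fixture(seed = 13, n = 601, ref = "A", alt = ins60)
  s <- design_scar(fl$seq, fl$offset, "A", ins60, "dominant")
  expect_s3_class(s, "scar_assay")
  expect_equal(s$mode, "dominant")
  expect_true(is.na(s$size_map[["ref"]]))   # deletion allele: null
  expect_gt(s$size_map[["alt"]], 0)
})
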