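# small hand-built genotype matrices for unit tests

toy_loci <- function(n, types = rep("SNP", n)) {
  ref <- ifelse(types == "SNP", "C", "CTGATTACGGATGCAAAGTCA")
  alt <- ifelse(types == "SNP", "T", "C")
  data.frame(chrom = "ctg0001", pos = seq(100, by = 100, length.out = n),
             ref = ref, alt = alt,
             variant_type = ifelse(nchar(ref) == nchar(alt), "SNP", "InDel"),
             site_mapq = 60, stringsAsFactors = FALSE)
}

toy_gm <- function(geno, depth = NULL, types = NULL) {
  geno <- as.matrix(geno)
  if (is.null(depth)) depth <- matrix(50L, nrow(geno), ncol(geno))
  if (is.null(types)) types <- rep("SNP", ncol(geno))
  genotype_matrix(geno, depth, toy_loci(ncol(geno), types),
                  sprintf("S%02d", seq_len(nrow(geno))))
}

random_gm <- function(n_samples, n_loci) {
  geno <- matrix(sample(c(0:2, NA), n_samples * n_loci, replace = TRUE,
                        prob = c(0.35, 0.2, 0.35, 0.1)),
                 n_samples, n_loci)
  depth <- matrix(sample(0:120, n_samples * n_loci, replace = TRUE),
                  n_samples, n_loci)
  loci <- toy_loci(n_loci)
  loci$site_mapq <- sample(c(10, 60), n_loci, replace = TRUE,
                           prob = c(0.1, 0.9))
  genotype_matrix(geno, depth, loci, sprintf("S%02d", seq_len(n_samples)))
}

# brute-force per-locus re-check of the fixed-allele definition
oracle_fixed_alleles <- function(gm, ref_ids, con_ids) {
  ri <- match(ref_ids, gm$sample_ids)
  ci <- match(con_ids, gm$sample_ids)
  hits <- data.frame(locus_index = integer(0),
                     diagnostic_allele = character(0))
  for (j in seq_len(ncol(gm$geno))) {
    r <- gm$geno[ri, j]; cc <- gm$geno[ci, j]
    if (anyNA(r) || anyNA(cc)) next
    for (al in c("ref", "alt")) {
      hom <- if (al == "ref") 0L else 2L
      if (all(r == hom) && !any(if (al == "ref") cc != 2L else cc != 0L)) {
        hits <- rbind(hits, data.frame(locus_index = j,
                                       diagnostic_allele = al))
      }
    }
  }
  hits
}

# enumeration oracle for the exact HWE test, written against the closed
# form (choose/factorial) rather than the recurrence-normalised implementation
oracle_hwe <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  nb <- 2L * nbb + nab
  na <- 2L * naa + nab
  nm <- min(na, nb)
  if (nm == 0) return(1)
  hets <- seq(nm %% 2L, nm, by = 2L)
  pr <- vapply(hets, function(h) {
    hb <- (nm - h) / 2
    ha <- n - hb - h
    exp(lchoose(n, ha) + lchoose(n - ha, h) + h * log(2) +
          lfactorial(nm) + lfactorial(2 * n - nm) - lfactorial(2 * n) -
          0)
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(nab, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}
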