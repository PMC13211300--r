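#' Quality-control thresholds for the variant filter cascade
#'
#' Defaults follow common practice for reduced-representation genotyping
#' panels: genotypes supported by fewer than 3 reads are masked, sites need
#' root-mean-square mapping quality of at least 20, per-locus missingness
#' must stay below 30%, folded minor-allele frequency must exceed 5%, and
#' loci deviating from Hardy-Weinberg equilibrium within the target-species
#' population at p < 0.001 are excluded. Depth and MAPQ bounds are
#' inclusive (`>=`); MAF and missingness are strict (`>`, `<`).
#'
#' @param min_depth minimum per-genotype read depth (reads).
#' @param min_mapq minimum site mapping quality (Phred).
#' @param max_missing maximum per-locus missing fraction (exclusive).
#' @param min_maf minimum folded minor-allele frequency (exclusive).
#' @param hwe_alpha Hardy-Weinberg exact-test significance level; loci with
#'   p < `hwe_alpha` are removed.
#' @return list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_depth = 3, min_mapq = 20,
                              max_missing = 0.30, min_maf = 0.05,
                              hwe_alpha = 0.001) {
  if (min_depth < 0) stop("min_depth must be >= 0")
  if (max_missing < 0 || max_missing > 1 || min_maf < 0 || min_maf > 1)
    stop("max_missing and min_maf must lie in [0, 1]")
  if (hwe_alpha <= 0 || hwe_alpha >= 1) stop("hwe_alpha must lie in (0, 1)")
  structure(list(min_depth = min_depth, min_mapq = min_mapq,
                 max_missing = max_missing, min_maf = min_maf,
                 hwe_alpha = hwe_alpha), class = "filter_thresholds")
}

#' Mask genotypes below a depth threshold
#'
#' Sets genotype calls supported by fewer than `min_depth` reads to missing;
#' all other entries are unchanged. Idempotent; `min_depth = 0` is the
#' identity.
#'
#' @param gm a [genotype_matrix].
#' @param min_depth minimum read depth (reads).
#' @return A [genotype_matrix] with low-depth genotypes masked.
#' @export
apply_depth_mask <- function(gm, min_depth = 3) {
  if (min_depth < 0) stop("min_depth must be >= 0")
  mask <- !is.na(gm$depth) & gm$depth < min_depth
  gm$geno[mask] <- NA_integer_
  gm
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact conditional test: given the observed allele counts, the
#' p-value is the total probability of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count
#' (heterozygote counts share the parity of the minor-allele count).
#' A monomorphic sample has a single attainable configuration, so p = 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (non-negative, total
#'   >= 1).
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0)) stop("genotype counts must be >= 0")
  n <- sum(counts)
  if (n < 1) stop("at least one genotyped sample is required")
  n_a <- 2L * n_hom_alt + n_het          # minor-or-not, symmetric anyway
  n_r <- 2L * n_hom_ref + n_het
  n_minor <- min(n_a, n_r)
  if (n_minor == 0) return(1)
  # attainable heterozygote counts share the parity of the minor count
  hets <- seq(n_minor %% 2L, n_minor, by = 2L)
  # log P(n_het = h | allele counts), from the multinomial/hypergeometric
  # conditional distribution
  logp <- vapply(hets, function(h) {
    haa <- (n_minor - h) / 2
    hbb <- n - haa - h
    lfactorial(n) - lfactorial(haa) - lfactorial(h) - lfactorial(hbb) +
      h * log(2) + lfactorial(n_minor) + lfactorial(2L * n - n_minor) -
      lfactorial(2L * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_het, hets)]
  if (is.na(p_obs)) stop("observed heterozygote count has impossible parity")
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

# folded minor-allele frequency over non-missing genotype codes
folded_maf <- function(codes) {
  codes <- codes[!is.na(codes)]
  if (!length(codes)) return(NA_real_)
  p_alt <- sum(codes) / (2 * length(codes))
  min(p_alt, 1 - p_alt)
}

#' Apply the full variant filter cascade
#'
#' Applies, in order: per-genotype depth masking; site MAPQ >= `min_mapq`;
#' per-locus missing fraction < `max_missing` (computed after depth masking,
#' over all samples); per-locus folded MAF > `min_maf` (over all non-missing
#' calls, panel-wide); exclusion of loci deviating from Hardy-Weinberg
#' equilibrium within `hwe_population` (exact test, retaining p >=
#' `hwe_alpha`). Loci with no genotyped individual in `hwe_population`
#' provide no evidence against equilibrium and are retained.
#'
#' @param gm a [genotype_matrix].
#' @param thresholds a [filter_thresholds()].
#' @param hwe_population character vector of sample ids (non-empty subset of
#'   `gm$sample_ids`) defining the population for the equilibrium test,
#'   typically the confirmed target-species purebreds.
#' @return list with elements `gm` (the filtered, depth-masked matrix) and
#'   `report` (a `filter_report` data.frame: per-stage entering/surviving
#'   locus counts split by SNP/InDel).
#' @export
filter_loci <- function(gm, thresholds = filter_thresholds(),
                        hwe_population) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  if (missing(hwe_population) || length(hwe_population) == 0)
    stop("hwe_population must be a non-empty set of sample ids")
  if (!all(hwe_population %in% gm$sample_ids))
    stop("hwe_population contains unknown sample ids")

  gm <- apply_depth_mask(gm, thresholds$min_depth)
  stages <- character(0)
  keep_history <- list()
  alive <- rep(TRUE, ncol(gm$geno))

  record <- function(stage, keep) {
    stages <<- c(stages, stage)
    keep_history[[stage]] <<- keep
  }

  # 1. site MAPQ
  keep <- gm$loci$site_mapq >= thresholds$min_mapq
  record("mapq", keep); alive <- alive & keep

  # 2. missingness (after depth masking, over all samples)
  miss_frac <- colMeans(is.na(gm$geno))
  keep <- miss_frac < thresholds$max_missing
  record("missing", keep); alive <- alive & keep

  # 3. folded MAF over non-missing calls, panel-wide
  maf <- apply(gm$geno, 2, folded_maf)
  keep <- !is.na(maf) & maf > thresholds$min_maf
  record("maf", keep); alive <- alive & keep

  # 4. HWE within the stated population
  sub <- gm$geno[match(hwe_population, gm$sample_ids), , drop = FALSE]
  hwe_p <- apply(sub, 2, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(1)
    hwe_exact_test(sum(g == GT_HOM_REF), sum(g == GT_HET),
                   sum(g == GT_HOM_ALT))
  })
  keep <- hwe_p >= thresholds$hwe_alpha
  record("hwe", keep); alive <- alive & keep

  # telescoping per-stage report split by variant type
  is_snp <- gm$loci$variant_type == "SNP"
  entering <- rep(TRUE, ncol(gm$geno))
  rows <- list()
  for (s in stages) {
    surviving <- entering & keep_history[[s]]
    rows[[s]] <- data.frame(
      stage = s,
      entering_snp = sum(entering & is_snp),
      entering_indel = sum(entering & !is_snp),
      surviving_snp = sum(surviving & is_snp),
      surviving_indel = sum(surviving & !is_snp),
      stringsAsFactors = FALSE)
    entering <- surviving
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  class(report) <- c("filter_report", "data.frame")
  list(gm = gm[, alive], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("variant filter cascade:\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-8s %6d SNP + %4d InDel -> %6d SNP + %4d InDel\n",
                x$stage[i], x$entering_snp[i], x$entering_indel[i],
                x$surviving_snp[i], x$surviving_indel[i]))
  }
  invisible(x)
}
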