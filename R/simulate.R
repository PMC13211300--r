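#' Simulation configuration for a hybrid-swarm genotype panel
#'
#' Describes a two-population diploid panel with a planted subset of
#' fixed-difference (diagnostic) loci, hybrid classes, and realistic
#' contamination (missingness, low-depth genotypes, low-MAPQ sites).
#'
#' Sample classes: `target_purebred` (true target species, typical
#' morphology), `target_variant` (atypical morphology, genetically non-target
#' at diagnostic loci), `cryptic_f1` (F1 hybrid whose morphology passes as a
#' purebred), `nontarget_species`, `f1_hybrid` (recognised natural F1),
#' `bc1_target` / `bc1_nontarget` (first backcross to either parent).
#'
#' @param n_loci total number of loci.
#' @param n_fixed_diff number of planted fixed-difference loci (>= 1,
#'   <= `n_loci`).
#' @param class_counts named integer vector over the classes above.
#' @param n_fixed_indel how many fixed-difference loci are InDels.
#' @param fixed_indel_len allele length differences (bp) for the fixed
#'   InDels, recycled.
#' @param beta_target,beta_nontarget `c(shape1, shape2)` of the Beta model
#'   for background allele frequencies in each population.
#' @param missing_rate fraction of genotype entries set missing.
#' @param low_depth_rate fraction of genotype entries whose depth is
#'   resampled below the usual depth filter (0-2 reads).
#' @param depth_mean,depth_size negative-binomial mean and dispersion of
#'   per-genotype read depth.
#' @param low_mapq_rate fraction of sites assigned MAPQ below 20.
#' @param fluorescence_noise_sd isotropic Gaussian noise of simulated
#'   endpoint fluorescence, in normalized intensity units.
#' @param seed integer seed; every draw is reproducible from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_loci = 500,
                              n_fixed_diff = 40,
                              class_counts = c(target_purebred = 32,
                                               target_variant = 3,
                                               cryptic_f1 = 1,
                                               nontarget_species = 16,
                                               f1_hybrid = 12,
                                               bc1_target = 0,
                                               bc1_nontarget = 0),
                              n_fixed_indel = 8,
                              fixed_indel_len = c(60, 21, 25, 30),
                              beta_target = c(0.8, 0.8),
                              beta_nontarget = c(0.8, 0.8),
                              missing_rate = 0.02,
                              low_depth_rate = 0.02,
                              depth_mean = 90,
                              depth_size = 8,
                              low_mapq_rate = 0.05,
                              fluorescence_noise_sd = 0.03,
                              seed = 1L) {
  classes <- c("target_purebred", "target_variant", "cryptic_f1",
               "nontarget_species", "f1_hybrid", "bc1_target",
               "bc1_nontarget")
  cc <- stats::setNames(integer(length(classes)), classes)
  cc[names(class_counts)] <- as.integer(class_counts)
  if (any(is.na(cc)) || any(cc < 0)) stop("class counts must be >= 0")
  if (sum(cc) == 0) stop("at least one sample class must be non-empty")
  if (n_fixed_diff < 1 || n_fixed_diff > n_loci)
    stop("n_fixed_diff must be in [1, n_loci]")
  rates <- c(missing_rate, low_depth_rate, low_mapq_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (fluorescence_noise_sd < 0) stop("fluorescence_noise_sd must be >= 0")
  if (n_fixed_indel > n_fixed_diff) stop("n_fixed_indel exceeds n_fixed_diff")
  structure(list(
    n_loci = as.integer(n_loci), n_fixed_diff = as.integer(n_fixed_diff),
    class_counts = cc, n_fixed_indel = as.integer(n_fixed_indel),
    fixed_indel_len = fixed_indel_len,
    beta_target = beta_target, beta_nontarget = beta_nontarget,
    missing_rate = missing_rate, low_depth_rate = low_depth_rate,
    depth_mean = depth_mean, depth_size = depth_size,
    low_mapq_rate = low_mapq_rate,
    fluorescence_noise_sd = fluorescence_noise_sd,
    seed = as.integer(seed)), class = "simulation_config")
}

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Simulate a genotype panel with planted diagnostic loci
#'
#' Generates a samples x loci genotype matrix from two diverged diploid
#' populations. At the planted fixed-difference loci the target population is
#' homozygous for a "target" allele and the non-target population homozygous
#' for the other; F1s (including the cryptic one) are obligate heterozygotes
#' there, and BC1 individuals are heterozygous at each such locus
#' independently with probability 1/2. Background loci are drawn under
#' Hardy-Weinberg proportions from per-population Beta-distributed allele
#' frequencies. Missingness, low-depth genotypes, and low-MAPQ sites are
#' applied after genotype assignment.
#'
#' @param config a [simulation_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{gm}{the contaminated [genotype_matrix];}
#'     \item{sheet}{the [sample_sheet()] (morphological label, genetic truth,
#'       training membership), with per-sample simulator classes attached as
#'       attribute `"sim_class"`;}
#'     \item{geno_clean}{the pre-contamination genotype code matrix;}
#'     \item{fixed_diff}{data.frame of planted loci: `locus_index`,
#'       `target_allele` (`"ref"`/`"alt"`).}
#'   }
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cc <- config$class_counts
  n <- sum(cc)
  L <- config$n_loci
  cls <- rep(names(cc), cc)
  ids <- sprintf("S%02d", seq_len(n))

  # --- locus metadata ---------------------------------------------------
  is_fixed <- logical(L)
  is_fixed[sample.int(L, config$n_fixed_diff)] <- TRUE
  fixed_idx <- which(is_fixed)
  is_indel <- logical(L)
  if (config$n_fixed_indel > 0)
    is_indel[fixed_idx[seq_len(config$n_fixed_indel)]] <- TRUE
  bg <- which(!is_fixed)
  n_bg_indel <- max(0L, round(0.08 * length(bg)))
  if (n_bg_indel > 0)
    is_indel[bg[sample.int(length(bg), n_bg_indel)]] <- TRUE
  pos <- sort(sample.int(5e6L, L))
  ref <- character(L); alt <- character(L)
  indel_len <- rep_len(config$fixed_indel_len, config$n_fixed_indel)
  k <- 0L
  for (j in seq_len(L)) {
    if (is_indel[j]) {
      if (is_fixed[j] && k < config$n_fixed_indel) {
        k <- k + 1L
        d <- indel_len[k]
      } else {
        d <- sample(1:8, 1)
      }
      anchor <- sample(BASES, 1)
      ins <- paste0(anchor, random_seq(d))
      if (stats::runif(1) < 0.5) { ref[j] <- ins; alt[j] <- anchor }
      else { ref[j] <- anchor; alt[j] <- ins }
    } else {
      ref[j] <- sample(BASES, 1)
      alt[j] <- sample(setdiff(BASES, ref[j]), 1)
    }
  }
  mapq <- ifelse(stats::runif(L) < config$low_mapq_rate,
                 stats::runif(L, 5, 19.5), 60)
  loci <- data.frame(
    chrom = sprintf("ctg%04d", 1L + (seq_len(L) - 1L) %/% 100L),
    pos = pos, ref = ref, alt = alt,
    variant_type = ifelse(nchar(ref) == nchar(alt), "SNP", "InDel"),
    site_mapq = mapq, stringsAsFactors = FALSE)
  # positions unique within chromosome by construction (global sort, 100/ctg)

  # target allele at fixed-difference loci (reference genome is from the
  # target species more often than not, but either role is allowed)
  target_allele <- ifelse(stats::runif(config$n_fixed_diff) < 0.5,
                          "ref", "alt")
  fixed_diff <- data.frame(locus_index = fixed_idx,
                           target_allele = target_allele,
                           stringsAsFactors = FALSE)

  # --- genotypes --------------------------------------------------------
  # background allele frequencies per population (freq of the ALT allele)
  p_t <- stats::rbeta(L, config$beta_target[1], config$beta_target[2])
  p_n <- stats::rbeta(L, config$beta_nontarget[1], config$beta_nontarget[2])
  geno <- matrix(NA_integer_, n, L)
  draw_hwe <- function(p) stats::rbinom(length(p), 2L, p)
  mix_f1 <- function(p1, p2) stats::rbinom(L, 1L, p1) + stats::rbinom(L, 1L, p2)
  for (i in seq_len(n)) {
    gi <- switch(cls[i],
      target_purebred = ,
      target_variant = draw_hwe(p_t),
      cryptic_f1 = ,
      f1_hybrid = mix_f1(p_t, p_n),
      nontarget_species = draw_hwe(p_n),
      bc1_target = stats::rbinom(L, 1L, p_t) +
        stats::rbinom(L, 1L, (p_t + p_n) / 2),
      bc1_nontarget = stats::rbinom(L, 1L, p_n) +
        stats::rbinom(L, 1L, (p_t + p_n) / 2))
    geno[i, ] <- gi
  }
  # overwrite planted fixed-difference loci with the class-determined pattern
  hom_t <- ifelse(target_allele == "ref", GT_HOM_REF, GT_HOM_ALT)
  hom_n <- ifelse(target_allele == "ref", GT_HOM_ALT, GT_HOM_REF)
  for (i in seq_len(n)) {
    geno[i, fixed_idx] <- switch(cls[i],
      target_purebred = hom_t,
      target_variant = ,
      nontarget_species = hom_n,
      cryptic_f1 = ,
      f1_hybrid = rep(GT_HET, length(fixed_idx)),
      bc1_target = ifelse(stats::runif(length(fixed_idx)) < 0.5,
                          GT_HET, hom_t),
      bc1_nontarget = ifelse(stats::runif(length(fixed_idx)) < 0.5,
                             GT_HET, hom_n))
  }
  # background loci must not be realized fixed differences between the
  # purebred pool and the non-target pool: planted loci are, by definition,
  # exactly the diagnostic fixed differences of the panel.  Columns that
  # fix by sampling accident are redrawn.
  ref_rows <- which(cls == "target_purebred")
  con_rows <- which(cls %in% c("nontarget_species", "target_variant"))
  if (length(ref_rows) && length(con_rows)) {
    is_fixed_col <- function(g) {
      r <- g[ref_rows]; cc <- g[con_rows]
      (all(r == GT_HOM_REF) && all(cc == GT_HOM_ALT)) ||
        (all(r == GT_HOM_ALT) && all(cc == GT_HOM_REF))
    }
    for (j in bg) {
      tries <- 0L
      while (is_fixed_col(geno[, j]) && tries < 50L) {
        p_t[j] <- stats::rbeta(1, config$beta_target[1],
                               config$beta_target[2])
        p_n[j] <- stats::rbeta(1, config$beta_nontarget[1],
                               config$beta_nontarget[2])
        for (i in seq_len(n)) {
          geno[i, j] <- switch(cls[i],
            target_purebred = ,
            target_variant = stats::rbinom(1, 2L, p_t[j]),
            cryptic_f1 = ,
            f1_hybrid = stats::rbinom(1, 1L, p_t[j]) +
              stats::rbinom(1, 1L, p_n[j]),
            nontarget_species = stats::rbinom(1, 2L, p_n[j]),
            bc1_target = stats::rbinom(1, 1L, p_t[j]) +
              stats::rbinom(1, 1L, (p_t[j] + p_n[j]) / 2),
            bc1_nontarget = stats::rbinom(1, 1L, p_n[j]) +
              stats::rbinom(1, 1L, (p_t[j] + p_n[j]) / 2))
        }
        tries <- tries + 1L
      }
    }
  }
  geno_clean <- geno

  # --- contamination ----------------------------------------------------
  depth <- matrix(stats::rnbinom(n * L, mu = config$depth_mean,
                                 size = config$depth_size), n, L)
  if (config$low_depth_rate > 0) {
    hit <- stats::runif(n * L) < config$low_depth_rate
    depth[hit] <- sample(0:2, sum(hit), replace = TRUE)
  }
  if (config$missing_rate > 0)
    geno[stats::runif(n * L) < config$missing_rate] <- NA_integer_

  gm <- genotype_matrix(geno, depth, loci, ids)
  morph <- c(target_purebred = "target", target_variant = "target_variant",
             cryptic_f1 = "target", nontarget_species = "nontarget_species",
             f1_hybrid = "nontarget_hybrid", bc1_target = "nontarget_hybrid",
             bc1_nontarget = "nontarget_hybrid")[cls]
  truth <- c(target_purebred = "target", target_variant = "nontarget",
             cryptic_f1 = "hybrid", nontarget_species = "nontarget",
             f1_hybrid = "hybrid", bc1_target = "hybrid",
             bc1_nontarget = "hybrid")[cls]
  sheet <- sample_sheet(ids, unname(morph), unname(truth),
                        morph %in% c("target", "target_variant"))
  attr(sheet, "sim_class") <- unname(cls)
  list(gm = gm, sheet = sheet, geno_clean = geno_clean,
       fixed_diff = fixed_diff)
}

# class-conditional endpoint fluorescence means (normalized units); the
# target allele reads out on HEX, the alternative on FAM, heterozygotes on
# both, and no-template controls sit near the origin
FLUOR_MEANS <- list(
  target_hom = c(fam = 0.10, hex = 1.00),
  alt_hom    = c(fam = 1.00, hex = 0.10),
  het        = c(fam = 0.55, hex = 0.55),
  ntc        = c(fam = 0.05, hex = 0.05))

#' Simulate endpoint FAM/HEX fluorescence readings
#'
#' Each sample's true genotype class maps to a fixed two-channel mean
#' (target homozygote high-HEX/low-FAM, alternative homozygote
#' high-FAM/low-HEX, heterozygote intermediate on both, NTC near the
#' origin); isotropic Gaussian noise is added and intensities clamped at 0.
#'
#' @param truth character vector over
#'   `{"target_hom","alt_hom","het","ntc"}`, optionally named by sample id.
#' @param noise_sd Gaussian noise standard deviation (>= 0), intensity units.
#' @param seed integer seed.
#' @return data.frame with columns `sample`, `fam`, `hex`.
#' @export
simulate_fluorescence <- function(truth, noise_sd = 0.03, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  bad <- setdiff(unique(truth), names(FLUOR_MEANS))
  if (length(bad)) stop("unknown genotype class: ", paste(bad, collapse = ", "))
  set.seed(as.integer(seed))
  m <- do.call(rbind, FLUOR_MEANS[truth])
  n <- length(truth)
  fam <- pmax(0, m[, "fam"] + stats::rnorm(n, 0, noise_sd))
  hex <- pmax(0, m[, "hex"] + stats::rnorm(n, 0, noise_sd))
  ids <- names(truth)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(n))
  data.frame(sample = ids, fam = fam, hex = hex,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate SCAR gel band patterns
#'
#' Each sample's band pattern is the union of the amplicon sizes that its two
#' alleles map to under the assay's size map; alleles mapping to "no band"
#' (`NA` in the size map) contribute nothing, so a homozygous null genotype
#' yields an empty pattern.
#'
#' @param alleles two-column character matrix (one row per sample) of allele
#'   names, each present in `names(assay$size_map)`.
#' @param assay a [scar_assay()].
#' @return list of integer vectors (sorted band sizes; possibly empty),
#'   named by rownames of `alleles` when present.
#' @export
simulate_scar_bands <- function(alleles, assay) {
  stopifnot(inherits(assay, "scar_assay"))
  alleles <- as.matrix(alleles)
  bad <- setdiff(unique(as.vector(alleles)), names(assay$size_map))
  if (length(bad))
    stop("allele(s) absent from assay size map: ", paste(bad, collapse = ", "))
  out <- lapply(seq_len(nrow(alleles)), function(i) {
    s <- assay$size_map[alleles[i, ]]
    sort(unique(as.integer(s[!is.na(s)])))
  })
  names(out) <- rownames(alleles)
  out
}

#' Map genotype codes to allele pairs at a diagnostic locus
#'
#' @param geno_codes integer vector of genotype codes (0/1/2/NA).
#' @param target_allele `"ref"` or `"alt"`: which VCF allele is the
#'   target-species allele at this locus.
#' @return two-column character matrix with entries `"target"`/`"other"`
#'   (rows of `NA` for missing genotypes).
#' @export
allele_pairs <- function(geno_codes, target_allele = c("ref", "alt")) {
  target_allele <- match.arg(target_allele)
  n_alt <- geno_codes
  n_target <- if (target_allele == "alt") n_alt else 2L - n_alt
  t(vapply(n_target, function(k) {
    if (is.na(k)) return(c(NA_character_, NA_character_))
    c(rep("target", k), rep("other", 2L - k))
  }, character(2)))
}

#' Genotype class at an assay locus
#'
#' @param geno_codes integer genotype codes.
#' @inheritParams allele_pairs
#' @return character vector over `{"target_hom","het","alt_hom"}` (NA kept).
#' @export
genotype_truth_class <- function(geno_codes, target_allele = c("ref", "alt")) {
  target_allele <- match.arg(target_allele)
  n_alt <- geno_codes
  n_target <- if (target_allele == "alt") n_alt else 2L - n_alt
  c("alt_hom", "het", "target_hom")[n_target + 1L]
}
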