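#' Mine fixed species-specific alleles
#'
#' Identifies the loci at which (a) every reference-set sample is non-missing
#' and homozygous for one common allele, and (b) that allele is completely
#' absent (frequency exactly 0, counting heterozygote carriers) from the
#' contrast set, with no missing contrast genotypes at the locus. Any missing
#' genotype in either set disqualifies the locus: "100% homozygous" and
#' "frequency = 0" are undefined under missingness, and the strict reading
#' protects assay specificity. A heterozygous reference genotype likewise
#' disqualifies a locus — fixation requires homozygosity.
#'
#' Eligibility flags: `kasp_eligible` for SNPs and InDels alike;
#' `scar_eligible` only for InDels whose allele length difference is at
#' least `min_scar_size_diff` (so the two amplicons resolve on a gel).
#'
#' @param gm a [genotype_matrix].
#' @param reference_set,contrast_set disjoint, non-empty character vectors
#'   of sample ids.
#' @param stage label stored with each candidate (`"stage1"`/`"stage2"`).
#' @param min_scar_size_diff minimum InDel length difference (bp) for SCAR
#'   eligibility.
#' @return data.frame of candidate loci: `chrom`, `pos`, `variant_type`,
#'   `diagnostic_allele` (`"ref"`/`"alt"`), `stage`, `n_reference_support`,
#'   `kasp_eligible`, `scar_eligible`, `locus_index` (column index in `gm`).
#' @export
mine_fixed_alleles <- function(gm, reference_set, contrast_set,
                               stage = "stage1", min_scar_size_diff = 20) {
  if (!length(reference_set) || !length(contrast_set))
    stop("reference and contrast sets must be non-empty")
  if (length(intersect(reference_set, contrast_set)))
    stop("reference and contrast sets must be disjoint")
  if (!all(c(reference_set, contrast_set) %in% gm$sample_ids))
    stop("unknown sample ids in reference or contrast set")
  ref_g <- gm$geno[match(reference_set, gm$sample_ids), , drop = FALSE]
  con_g <- gm$geno[match(contrast_set, gm$sample_ids), , drop = FALSE]

  ref_complete <- colSums(is.na(ref_g)) == 0
  con_complete <- colSums(is.na(con_g)) == 0
  all_hom_ref <- ref_complete & colSums(ref_g == GT_HOM_REF) == nrow(ref_g)
  all_hom_alt <- ref_complete & colSums(ref_g == GT_HOM_ALT) == nrow(ref_g)
  # diagnostic allele carried by any contrast genotype (hom or het) kills it
  ref_in_con <- colSums(con_g != GT_HOM_ALT, na.rm = TRUE) > 0
  alt_in_con <- colSums(con_g != GT_HOM_REF, na.rm = TRUE) > 0
  hit_ref <- all_hom_ref & con_complete & !ref_in_con
  hit_alt <- all_hom_alt & con_complete & !alt_in_con
  idx <- which(hit_ref | hit_alt)
  loci <- gm$loci[idx, , drop = FALSE]
  len_diff <- abs(nchar(loci$ref) - nchar(loci$alt))
  out <- data.frame(
    chrom = loci$chrom, pos = loci$pos,
    variant_type = loci$variant_type,
    diagnostic_allele = c("alt", "ref")[hit_ref[idx] + 1L],
    stage = rep(stage, length(idx)),
    n_reference_support = rep(length(reference_set), length(idx)),
    kasp_eligible = rep(TRUE, length(idx)),
    scar_eligible = loci$variant_type == "InDel" &
      len_diff >= min_scar_size_diff,
    locus_index = idx,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Two-stage mining with training-set refinement
#'
#' Stage 1 takes every sample flagged `in_training` in the sheet (the full
#' morphologically target-classified pool, typical plus atypical variants)
#' as the reference set, and the morphologically non-target *species*
#' samples as the contrast set. Stage 2 removes `reclassified_ids` — samples
#' the first validation round exposed as cryptic hybrids or reassigned
#' variants — from the reference and re-mines; reclassified samples whose
#' morphology marked them as variants join the contrast set, while
#' reclassified cryptic hybrids are excluded from both sets, since a hybrid
#' carries one target-derived allele at every genuinely diagnostic locus and
#' would veto the entire candidate list. Known natural hybrids
#' (`nontarget_hybrid`) are excluded from the contrast for the same reason.
#'
#' @param gm a [genotype_matrix].
#' @param sheet a [sample_sheet()].
#' @param reclassified_ids sample ids to drop from the stage-1 reference
#'   (must be a subset of it). Empty means stage 2 equals stage 1.
#' @param min_scar_size_diff passed to [mine_fixed_alleles()].
#' @return list with data.frames `stage1` and `stage2`.
#' @export
two_stage_mining <- function(gm, sheet, reclassified_ids = character(0),
                             min_scar_size_diff = 20) {
  ref1 <- sheet$id[sheet$in_training]
  contrast1 <- sheet$id[sheet$morphological_label == "nontarget_species"]
  if (!all(reclassified_ids %in% ref1))
    stop("reclassified_ids must be a subset of the stage-1 reference set")
  ref2 <- setdiff(ref1, reclassified_ids)
  if (!length(ref2))
    stop("reclassification empties the reference set")
  to_contrast <- reclassified_ids[
    sheet$morphological_label[match(reclassified_ids, sheet$id)] ==
      "target_variant"]
  stage1 <- mine_fixed_alleles(gm, ref1, contrast1, stage = "stage1",
                               min_scar_size_diff = min_scar_size_diff)
  stage2 <- mine_fixed_alleles(gm, ref2, c(contrast1, to_contrast),
                               stage = "stage2",
                               min_scar_size_diff = min_scar_size_diff)
  list(stage1 = stage1, stage2 = stage2)
}
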