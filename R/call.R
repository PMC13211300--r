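#' KASP calling parameters
#'
#' A deterministic allele-ratio rule on normalized endpoint fluorescence:
#' wells whose total intensity (FAM + HEX) falls below `intensity_floor` are
#' no-calls (NTC-like); otherwise the HEX fraction `r = hex / (fam + hex)`
#' is banded into target homozygote (`r >= hom_target_min`), alternative
#' homozygote (`r <= hom_alt_max`), heterozygote (`het_min <= r <= het_max`),
#' and no-call in the gaps between bands.
#'
#' @param intensity_floor minimum total intensity for a call.
#' @param hom_target_min,hom_alt_max,het_min,het_max HEX-ratio band edges.
#' @return list of class `kasp_thresholds`.
#' @export
kasp_thresholds <- function(intensity_floor = 0.30, hom_target_min = 0.80,
                            hom_alt_max = 0.20, het_min = 0.35,
                            het_max = 0.65) {
  stopifnot(hom_alt_max < het_min, het_min <= het_max,
            het_max < hom_target_min, intensity_floor >= 0)
  structure(list(intensity_floor = intensity_floor,
                 hom_target_min = hom_target_min,
                 hom_alt_max = hom_alt_max,
                 het_min = het_min, het_max = het_max),
            class = "kasp_thresholds")
}

#' Call a genotype class from one fluorescence point
#'
#' @param fam,hex non-negative normalized endpoint intensities (vectorized).
#' @param thresholds a [kasp_thresholds()].
#' @return character vector over
#'   `{"target_hom","alt_hom","het","no_call"}`; the bands partition the
#'   positive quadrant, so every point maps to exactly one class.
#' @export
call_kasp <- function(fam, hex, thresholds = kasp_thresholds()) {
  if (any(fam < 0 | hex < 0)) stop("intensities must be non-negative")
  total <- fam + hex
  r <- ifelse(total > 0, hex / total, 0)
  out <- rep("no_call", length(fam))
  ok <- total >= thresholds$intensity_floor
  out[ok & r >= thresholds$hom_target_min] <- "target_hom"
  out[ok & r <= thresholds$hom_alt_max] <- "alt_hom"
  out[ok & r >= thresholds$het_min & r <= thresholds$het_max] <- "het"
  out
}

#' Classify a codominant SCAR band pattern
#'
#' Observed band sizes are matched to the assay's two mapped allele sizes
#' within `size_tolerance`; a band within tolerance of both mapped sizes is
#' an ambiguity error, and unmatched bands raise an error as a suspect lane.
#'
#' @param bands integer vector of observed band sizes (possibly empty).
#' @param assay a codominant [scar_assay()].
#' @param size_tolerance band-size matching tolerance, bp.
#' @return one of `"target_only"`, `"other_only"`, `"both"`, `"none"`, where
#'   "target" refers to the allele named `"target"` in the size map (or the
#'   first map entry otherwise).
#' @export
call_scar2 <- function(bands, assay, size_tolerance = 5) {
  stopifnot(inherits(assay, "scar_assay"))
  if (assay$mode != "codominant")
    stop("call_scar2 requires a codominant assay")
  sizes <- assay$size_map
  target_name <- if ("target" %in% names(sizes)) "target" else names(sizes)[1]
  if (abs(diff(sizes)) <= 2 * size_tolerance)
    stop("mapped sizes are within tolerance of each other: matching ambiguous")
  seen <- c(FALSE, FALSE); names(seen) <- names(sizes)
  for (b in bands) {
    d <- abs(sizes - b)
    hit <- which(d <= size_tolerance)
    if (length(hit) == 0)
      stop("observed band ", b, " bp matches no mapped allele size")
    seen[hit] <- TRUE
  }
  t_seen <- seen[target_name]
  o_seen <- seen[setdiff(names(sizes), target_name)]
  if (t_seen && o_seen) "both"
  else if (t_seen) "target_only"
  else if (o_seen) "other_only"
  else "none"
}

#' Merged two-locus SCAR diagnostic rule
#'
#' Combines the dominant marker's presence/absence (the target species
#' carries a null allele, so purebred targets show no band) with the
#' codominant marker's allele pattern, following the validated combined
#' lookup: (absent, target_only), (absent, both) and (present, target_only)
#' are target; (present, other_only) is non-target; (present, both) is a
#' heterozygous hybrid (non-target side). Every combination outside the
#' validated table — e.g. a lane with no amplification at either locus —
#' returns `ambiguous`, never `target`: the fail-safe direction for a
#' conservation screen.
#'
#' @param scar1_present logical: any band at the dominant locus?
#' @param scar2 codominant allele pattern from [call_scar2()].
#' @return species call: one of `"target"`, `"nontarget"`,
#'   `"heterozygous_hybrid"`, `"ambiguous"`.
#' @export
combined_scar_classify <- function(scar1_present, scar2) {
  stopifnot(is.logical(scar1_present), length(scar1_present) == 1,
            scar2 %in% c("target_only", "other_only", "both", "none"))
  key <- paste(ifelse(scar1_present, "O", "X"), scar2, sep = ":")
  switch(key,
         "X:target_only" = "target",
         "X:both" = "target",
         "O:target_only" = "target",
         "O:other_only" = "nontarget",
         "O:both" = "heterozygous_hybrid",
         "ambiguous")
}

#' Species call from genotype classes across all KASP assays
#'
#' All-target homozygote calls give `target`; all-alternative give
#' `nontarget`; any heterozygous assay marks the sample as a
#' `heterozygous_hybrid` (a genuine hybrid is heterozygous at every
#' diagnostic locus, but one assay suffices to flag it); conflicting
#' homozygote calls give `ambiguous`; all-no-call gives `no_call`. A
#' no-call among otherwise consistent assays yields that consistent call
#' flagged low-confidence (attribute `"low_confidence"`).
#'
#' @param classes character vector of per-assay genotype classes (from
#'   [call_kasp()]), one element per assay; at least one.
#' @return a single species call with attribute `low_confidence`.
#' @export
kasp_species_call <- function(classes) {
  if (!length(classes)) stop("at least one assay call is required")
  stopifnot(all(classes %in% c("target_hom", "alt_hom", "het", "no_call")))
  called <- classes[classes != "no_call"]
  low_conf <- any(classes == "no_call")
  out <- if (!length(called)) "no_call"
  else if (any(called == "het")) "heterozygous_hybrid"
  else if (all(called == "target_hom")) "target"
  else if (all(called == "alt_hom")) "nontarget"
  else "ambiguous"
  attr(out, "low_confidence") <- low_conf && out != "no_call"
  out
}

#' Per-sample species calls from a fluorescence table
#'
#' @param fluor data.frame with columns `sample`, `assay`, `fam`, `hex`.
#' @param thresholds a [kasp_thresholds()].
#' @return data.frame with columns `sample`, `call`, `low_confidence`.
#' @export
call_kasp_panel <- function(fluor, thresholds = kasp_thresholds()) {
  fluor$class <- call_kasp(fluor$fam, fluor$hex, thresholds)
  ids <- unique(fluor$sample)
  calls <- vapply(ids, function(s) {
    kasp_species_call(fluor$class[fluor$sample == s])
  }, character(1))
  lc <- vapply(ids, function(s) {
    isTRUE(attr(kasp_species_call(fluor$class[fluor$sample == s]),
                "low_confidence"))
  }, logical(1))
  data.frame(sample = ids, call = unname(calls), low_confidence = unname(lc),
             stringsAsFactors = FALSE)
}

#' Per-sample species calls from a band table with the merged SCAR rule
#'
#' @param bands data.frame with columns `sample`, `assay`, `bands`
#'   (comma-separated sizes), covering a dominant and a codominant assay.
#' @param scar1,scar2 the dominant and codominant [scar_assay()]s; assay
#'   names must match the table's `assay` column.
#' @param size_tolerance bp tolerance for band matching.
#' @return data.frame with columns `sample`, `call`.
#' @export
call_scar_panel <- function(bands, scar1, scar2, size_tolerance = 5) {
  stopifnot(scar1$mode == "dominant", scar2$mode == "codominant")
  ids <- unique(bands$sample)
  calls <- vapply(ids, function(s) {
    b1 <- bands$bands[bands$sample == s & bands$assay == scar1$name]
    b2 <- bands$bands[bands$sample == s & bands$assay == scar2$name]
    if (length(b1) != 1 || length(b2) != 1)
      stop("sample ", s, " must have exactly one lane per assay")
    p1 <- parse_band_pattern(b1)
    p2 <- parse_band_pattern(b2)
    combined_scar_classify(length(p1) > 0,
                           call_scar2(p2, scar2, size_tolerance))
  }, character(1))
  data.frame(sample = ids, call = unname(calls), stringsAsFactors = FALSE)
}
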