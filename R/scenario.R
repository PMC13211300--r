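#' Named validation scenarios
#'
#' Scenario `"S1"` is the KASP validation panel: 64 samples composed of 32
#' target purebreds, one cryptic F1 whose morphology passes as a purebred
#' (so 33 samples carry the morphological target label), 3 atypical
#' variants (morphologically flagged, genetically non-target at diagnostic
#' loci), 16 non-target species individuals and 12 recognised natural F1
#' hybrids. Scenario `"S2"` is the same panel scored with the two SCAR
#' assays, in which two designated samples — the cryptic F1 and one
#' purebred — yield the heterozygous combined band pattern (the purebred's
#' lane emulating incomplete lineage sorting at the SCAR loci).
#'
#' @param scenario `"S1"` or `"S2"`.
#' @param seed integer seed.
#' @param config optional [simulation_config()] overriding the defaults.
#' @return list with elements `gm`, `sheet`, `geno_clean`, `fixed_diff`,
#'   `assay_loci` (data.frame: assay, locus_index, target_allele, type),
#'   `scar_assays` (dominant `SCAR1`, codominant `SCAR2`), `fluorescence`
#'   (per sample x KASP assay, plus one NTC well per assay), `bands`
#'   (per sample x SCAR assay), `designed_discordant` (sample ids whose
#'   SCAR lanes are overridden in S2), `config`.
#' @export
simulate_scenario <- function(scenario = c("S1", "S2"), seed = 1L,
                              config = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(config)) config <- simulation_config(seed = as.integer(seed))
  pan <- simulate_panel(config)
  gm <- pan$gm
  cls <- attr(pan$sheet, "sim_class")
  fixed <- pan$fixed_diff
  loci <- gm$loci[fixed$locus_index, ]
  len_diff <- abs(nchar(loci$ref) - nchar(loci$alt))
  snp_idx <- fixed$locus_index[loci$variant_type == "SNP"]
  big_indel <- fixed$locus_index[loci$variant_type == "InDel" &
                                   len_diff >= 20]
  if (length(snp_idx) < 2 || length(big_indel) < 2)
    stop("scenario requires >= 2 fixed SNPs and >= 2 large fixed InDels")
  # the dominant SCAR locus doubles as the third (InDel) KASP locus
  assay_idx <- c(KASP1 = snp_idx[1], KASP2 = snp_idx[2],
                 KASP3 = big_indel[1], SCAR1 = big_indel[1],
                 SCAR2 = big_indel[2])
  tgt <- fixed$target_allele[match(assay_idx, fixed$locus_index)]
  assay_loci <- data.frame(assay = names(assay_idx),
                           locus_index = unname(assay_idx),
                           target_allele = tgt,
                           type = gm$loci$variant_type[assay_idx],
                           stringsAsFactors = FALSE)

  scar_assays <- list(
    SCAR1 = scar_assay("SCAR1", "dominant",
                       c(target = NA_real_, other = 116),
                       locus = locus_key(gm$loci[assay_idx[["SCAR1"]], ])),
    SCAR2 = scar_assay("SCAR2", "codominant",
                       c(target = 516, other = 537),
                       locus = locus_key(gm$loci[assay_idx[["SCAR2"]], ])))

  # endpoint fluorescence for the three KASP assays, one NTC well each
  fluor <- list()
  for (k in 1:3) {
    a <- sprintf("KASP%d", k)
    j <- assay_idx[[a]]
    truth <- genotype_truth_class(pan$geno_clean[, j],
                                  assay_loci$target_allele[k])
    names(truth) <- gm$sample_ids
    truth <- c(truth, NTC = "ntc")
    pts <- simulate_fluorescence(truth, config$fluorescence_noise_sd,
                                 seed = config$seed * 13L + k)
    pts$assay <- a
    fluor[[a]] <- pts[, c("sample", "assay", "fam", "hex")]
  }
  fluorescence <- do.call(rbind, fluor)
  rownames(fluorescence) <- NULL

  # SCAR band patterns from the clean genotypes
  band_rows <- list()
  for (a in c("SCAR1", "SCAR2")) {
    j <- assay_idx[[a]]
    ta <- assay_loci$target_allele[assay_loci$assay == a]
    pairs <- allele_pairs(pan$geno_clean[, j], ta)
    rownames(pairs) <- gm$sample_ids
    pat <- simulate_scar_bands(pairs, scar_assays[[a]])
    band_rows[[a]] <- data.frame(
      sample = gm$sample_ids, assay = a,
      bands = vapply(pat, function(p) paste(p, collapse = ","),
                     character(1)),
      stringsAsFactors = FALSE)
  }
  bands <- do.call(rbind, band_rows)
  rownames(bands) <- NULL

  designed <- character(0)
  if (scenario == "S2") {
    # the cryptic F1 already shows the heterozygous combined pattern; one
    # designated purebred lane is overridden to the same pattern
    cryptic <- gm$sample_ids[cls == "cryptic_f1"][1]
    pure <- gm$sample_ids[cls == "target_purebred"]
    designated <- pure[length(pure)]
    bands$bands[bands$sample == designated & bands$assay == "SCAR1"] <- "116"
    bands$bands[bands$sample == designated & bands$assay == "SCAR2"] <-
      "516,537"
    designed <- c(cryptic, designated)
  }

  list(scenario = scenario, gm = gm, sheet = pan$sheet,
       geno_clean = pan$geno_clean, fixed_diff = fixed,
       assay_loci = assay_loci, scar_assays = scar_assays,
       fluorescence = fluorescence, bands = bands,
       designed_discordant = designed, config = config)
}

#' Simulate flanking sequences for chosen loci
#'
#' Generates a random flank of the requested width around each locus with
#' the reference allele embedded, at roughly balanced base composition so
#' that primer design constraints are satisfiable.
#'
#' @param loci data.frame of locus metadata (`chrom`, `pos`, `ref`, `alt`).
#' @param width total flank width in bp (before allele insertion).
#' @param seed integer seed.
#' @return data.frame with columns `key` (`chrom_pos`), `seq`, `offset`
#'   (1-based position of the variant within `seq`).
#' @export
simulate_flanks <- function(loci, width = 301, seed = 1L) {
  set.seed(as.integer(seed))
  half <- width %/% 2
  out <- lapply(seq_len(nrow(loci)), function(i) {
    left <- random_seq(half)
    right <- random_seq(half)
    data.frame(key = locus_key(loci[i, ]),
               seq = paste0(left, loci$ref[i], right),
               offset = half + 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write / read flank sequences as FASTA
#'
#' Headers carry the locus key and the variant offset within the record
#' (`>key offset=N`).
#'
#' @param flanks data.frame as from [simulate_flanks()].
#' @param path FASTA file path.
#' @return `read_flanks_fasta` returns the same data.frame shape.
#' @export
write_flanks_fasta <- function(flanks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(flanks))) {
    writeLines(sprintf(">%s offset=%d", flanks$key[i], flanks$offset[i]),
               con)
    writeLines(flanks$seq[i], con)
  }
  invisible(path)
}

#' @rdname write_flanks_fasta
#' @export
read_flanks_fasta <- function(path) {
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  annot <- vapply(fa, function(x) attr(x, "Annot"), character(1))
  offset <- as.integer(sub(".*offset=(\\d+).*", "\\1", annot))
  data.frame(key = names(fa), seq = toupper(unlist(fa, use.names = FALSE)),
             offset = offset, stringsAsFactors = FALSE, row.names = NULL)
}
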