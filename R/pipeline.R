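#' Simulate a scenario and write its panel files
#'
#' Writes the VCF, sample sheet, fluorescence and band tables, a YAML record
#' of the configuration, and a provenance log to `out_dir`. Re-running with
#' the same scenario and seed reproduces byte-identical files.
#'
#' @param scenario `"S1"` or `"S2"`.
#' @param seed integer seed.
#' @param out_dir output directory (created if absent).
#' @param config optional [simulation_config()] override.
#' @return named list of file paths, invisibly; the scenario object as
#'   attribute `"scenario"`.
#' @export
run_simulate <- function(scenario = c("S1", "S2"), seed = 1L, out_dir,
                         config = NULL) {
  scenario <- match.arg(scenario)
  sc <- simulate_scenario(scenario, seed = seed, config = config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(out_dir, "panel.vcf"),
    sheet = file.path(out_dir, "samples.tsv"),
    fluorescence = file.path(out_dir, "fluorescence.tsv"),
    bands = file.path(out_dir, "bands.tsv"),
    config = file.path(out_dir, "config.yaml"),
    log = file.path(out_dir, "simulate.log"))
  write_panel_vcf(sc$gm, paths$vcf)
  write_sample_sheet(sc$sheet, paths$sheet)
  write_fluorescence(sc$fluorescence, paths$fluorescence)
  write_bands(sc$bands, paths$bands)
  cfg <- sc$config
  yaml::write_yaml(list(scenario = scenario, seed = cfg$seed,
                        n_loci = cfg$n_loci,
                        n_fixed_diff = cfg$n_fixed_diff,
                        class_counts = as.list(cfg$class_counts),
                        missing_rate = cfg$missing_rate,
                        low_depth_rate = cfg$low_depth_rate,
                        low_mapq_rate = cfg$low_mapq_rate,
                        fluorescence_noise_sd = cfg$fluorescence_noise_sd),
                   paths$config)
  writeLines(c(sprintf("markermine %s",
                       as.character(utils::packageVersion("markermine"))),
               sprintf("scenario: %s  seed: %d", scenario, cfg$seed),
               sprintf("samples: %d  loci: %d (fixed-difference: %d)",
                       nrow(sc$gm$geno), ncol(sc$gm$geno),
                       cfg$n_fixed_diff)),
             paths$log)
  out <- paths
  attr(out, "scenario") <- sc
  invisible(out)
}

#' Run the full diagnostic pipeline on panel files
#'
#' Executes the validation workflow: read the genotype matrix; call species
#' from the KASP fluorescence table and use those calls to refine the
#' training set (a training sample whose KASP call is not `target` is a
#' cryptic hybrid or a mislabelled variant); QC-filter the matrix, testing
#' Hardy-Weinberg equilibrium within the confirmed purebred pool; run the
#' two-stage fixed-allele mining; optionally design KASP/SCAR primers for
#' mined candidates when a flank FASTA is supplied; call the merged
#' two-locus SCAR rule from the band table; and score both call sets
#' against the sample sheet under both conventions. All reports are written
#' to `out_dir` together with a provenance log.
#'
#' @param vcf,sheet,fluorescence,bands input file paths (see
#'   [run_simulate()] for the formats).
#' @param out_dir output directory.
#' @param thresholds a [filter_thresholds()].
#' @param kasp_thr a [kasp_thresholds()].
#' @param scar_assays list with dominant `SCAR1` and codominant `SCAR2`
#'   [scar_assay()]s matching the band table's assay names.
#' @param flanks optional flank FASTA (from [write_flanks_fasta()]) enabling
#'   the primer-design stage.
#' @param constraints a [design_constraints()] for the design stage.
#' @return list with `filter_report`, `mining` (stage1/stage2 candidate
#'   tables), `reclassified_ids`, `assays` (designed primers, possibly
#'   empty), `kasp_calls`, `scar_calls`, and `reports` (diagnostic reports:
#'   `kasp_morphological`, `kasp_genetic`, `scar_morphological`,
#'   `scar_genetic`).
#' @export
run_full <- function(vcf, sheet, fluorescence, bands, out_dir,
                     thresholds = filter_thresholds(),
                     kasp_thr = kasp_thresholds(),
                     scar_assays = list(
                       SCAR1 = scar_assay("SCAR1", "dominant",
                                          c(target = NA_real_, other = 116)),
                       SCAR2 = scar_assay("SCAR2", "codominant",
                                          c(target = 516, other = 537))),
                     flanks = NULL,
                     constraints = design_constraints()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gm <- tryCatch(read_vcf(vcf),
                 error = function(e) stop("stage 'read_vcf': ",
                                          conditionMessage(e), call. = FALSE))
  sh <- read_sample_sheet(sheet)
  fl <- read_fluorescence(fluorescence)
  bd <- read_bands(bands)
  fl <- fl[fl$sample %in% sh$id, ]   # NTC and foreign wells are not scored

  # 1. KASP species calls, then training-set refinement: a training sample
  # whose assays do not call target is a cryptic hybrid or mislabelled
  # variant and leaves the confirmed purebred pool
  kasp_calls <- tryCatch(call_kasp_panel(fl, kasp_thr),
                         error = function(e) stop("stage 'call_kasp': ",
                                                  conditionMessage(e),
                                                  call. = FALSE))
  training <- sh$id[sh$in_training]
  kc <- kasp_calls$call[match(training, kasp_calls$sample)]
  reclassified <- training[!is.na(kc) & kc != "target"]

  # 2. QC filter cascade; equilibrium is tested within the confirmed
  # purebred population (reclassified samples excluded — a mixed pool
  # violates equilibrium at exactly the diagnostic loci being sought)
  flt <- tryCatch(
    filter_loci(gm, thresholds,
                hwe_population = setdiff(training, reclassified)),
    error = function(e) stop("stage 'filter': ", conditionMessage(e),
                             call. = FALSE))

  mining <- tryCatch(
    two_stage_mining(flt$gm, sh, reclassified,
                     min_scar_size_diff = constraints$min_scar_size_diff),
    error = function(e) stop("stage 'mine': ", conditionMessage(e),
                             call. = FALSE))

  # 3. optional primer design over mined candidates with known flanks
  assays <- list()
  if (!is.null(flanks)) {
    fk <- read_flanks_fasta(flanks)
    cand <- mining$stage2
    cand$key <- paste(cand$chrom, cand$pos, sep = "_")
    for (i in seq_len(nrow(cand))) {
      row <- fk[fk$key == cand$key[i], ]
      if (!nrow(row)) next
      loc <- flt$gm$loci[cand$locus_index[i], ]
      k <- design_kasp(row$seq, row$offset, loc$ref, loc$alt,
                       cand$diagnostic_allele[i], constraints,
                       name = paste0("KASP_", cand$key[i]))
      if (!is.null(k)) assays[[k$name]] <- k
      if (cand$scar_eligible[i]) {
        s <- design_scar(row$seq, row$offset, loc$ref, loc$alt,
                         "codominant", constraints,
                         name = paste0("SCAR_", cand$key[i]))
        if (!is.null(s)) assays[[s$name]] <- s
      }
    }
  }

  # 4. merged two-locus SCAR calls
  scar_calls <- tryCatch(
    call_scar_panel(bd[bd$sample %in% sh$id, ],
                    scar_assays$SCAR1, scar_assays$SCAR2),
    error = function(e) stop("stage 'call_scar': ", conditionMessage(e),
                             call. = FALSE))

  # 5. score both call sets under both conventions
  reports <- list(
    kasp_morphological = score_panel(kasp_calls, sh, "morphological"),
    kasp_genetic = score_panel(kasp_calls, sh, "genetic"),
    scar_morphological = score_panel(scar_calls, sh, "morphological"),
    scar_genetic = score_panel(scar_calls, sh, "genetic"))

  # outputs
  utils::write.table(flt$report, file.path(out_dir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_candidates(mining$stage2, file.path(out_dir, "candidates.tsv"))
  utils::write.table(kasp_calls, file.path(out_dir, "kasp_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scar_calls, file.path(out_dir, "scar_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log <- file.path(out_dir, "run_full.log")
  digests <- tools::md5sum(c(vcf, sheet, fluorescence, bands))
  writeLines(c(
    sprintf("markermine %s",
            as.character(utils::packageVersion("markermine"))),
    sprintf("thresholds: depth>=%g mapq>=%g missing<%g maf>%g hwe_p>=%g",
            thresholds$min_depth, thresholds$min_mapq,
            thresholds$max_missing, thresholds$min_maf,
            thresholds$hwe_alpha),
    sprintf("reclassified: %s",
            if (length(reclassified)) paste(reclassified, collapse = ", ")
            else "(none)"),
    sprintf("input %s md5 %s", names(digests), unname(digests))), log)
  sink(file.path(out_dir, "diagnostic_reports.txt"))
  on.exit(sink(), add = TRUE)
  for (nm in names(reports)) { cat("## ", nm, "\n", sep = ""); print(reports[[nm]]) }
  sink(); on.exit()

  list(filter_report = flt$report, mining = mining,
       reclassified_ids = reclassified, assays = assays,
       kasp_calls = kasp_calls, scar_calls = scar_calls, reports = reports)
}
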