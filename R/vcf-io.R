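#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF (v4.x) with per-genotype GT (and optionally DP) fields and an
#' optional per-site MQ INFO key. Each biallelic record becomes one locus;
#' multi-allelic records are rejected with an error naming the site, since
#' the downstream fixed-allele definition is biallelic and no splitting rule
#' is assumed. A missing MQ is treated as passing (`Inf`) with a warning.
#'
#' @param path path to an (optionally gzipped) VCF file.
#' @return A [genotype_matrix].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file does not exist: ", path)
  # validate the header up front (a truncated or headerless file is
  # reported as a parse error rather than handed to the C parser)
  con <- file(path, "r")
  hdr_ok <- FALSE
  ln <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    ln <- ln + 1L
    if (!length(line)) break
    if (startsWith(line, "#CHROM")) { hdr_ok <- TRUE; break }
    if (!startsWith(line, "#")) break
  }
  close(con)
  if (!hdr_ok)
    stop("malformed VCF (no #CHROM header found by line ", ln, "): ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    i <- which(multi)[1]
    stop(sprintf("multi-allelic site not supported: %s:%s (ALT=%s)",
                 fix[i, "CHROM"], fix[i, "POS"], alt[i]))
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp_raw <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0")] <- GT_HOM_REF
    out[g %in% c("0/1", "1/0")] <- GT_HET
    out[g %in% c("1/1")] <- GT_HOM_ALT
    bad <- !is.na(g) & !(g %in% c("0/0", "0/1", "1/0", "1/1", "./.", "."))
    if (any(bad))
      stop("unparsable GT value(s): ", paste(unique(g[bad]), collapse = ", "))
    out
  }
  # extract.gt returns loci x samples; transpose to samples x loci
  geno <- t(matrix(code(as.vector(gt_raw)), nrow = nrow(gt_raw)))
  if (is.null(dp_raw)) {
    depth <- matrix(NA_integer_, nrow(geno), ncol(geno))
  } else {
    depth <- t(matrix(as.integer(dp_raw), nrow = nrow(dp_raw)))
  }
  # genotype_matrix requires depth wherever genotype is defined
  depth[is.na(depth) & !is.na(geno)] <- 0L
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "MQ")))
  if (all(is.na(mq))) {
    warning("no MQ INFO field found; treating all sites as passing MAPQ")
    mq <- rep(Inf, nrow(fix))
  } else if (anyNA(mq)) {
    warning("MQ missing for some sites; treating those as passing MAPQ")
    mq[is.na(mq)] <- Inf
  }
  ref <- fix[, "REF"]
  loci <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = ref,
    alt = alt,
    variant_type = ifelse(nchar(ref) == nchar(alt), "SNP", "InDel"),
    site_mapq = mq,
    stringsAsFactors = FALSE)
  genotype_matrix(geno, depth, loci, colnames(gt_raw))
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a minimal VCF v4.2 with GT and DP genotype fields and a per-site MQ
#' INFO key, such that `read_vcf(write_panel_vcf(gm, f))` reproduces `gm`
#' (genotypes, depths, coordinates, alleles and site MAPQ round-trip
#' losslessly; an infinite MAPQ is written by omitting MQ).
#'
#' @param gm a [genotype_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(gm, path) {
  if (ncol(gm$geno) == 0 || nrow(gm$geno) == 0)
    stop("cannot write an empty genotype matrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=markermine",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t")), con)
  gt_str <- matrix("./.", nrow(gm$geno), ncol(gm$geno))
  gt_str[!is.na(gm$geno) & gm$geno == GT_HOM_REF] <- "0/0"
  gt_str[!is.na(gm$geno) & gm$geno == GT_HET] <- "0/1"
  gt_str[!is.na(gm$geno) & gm$geno == GT_HOM_ALT] <- "1/1"
  dp_str <- ifelse(is.na(gm$depth), ".", as.character(gm$depth))
  for (j in seq_len(ncol(gm$geno))) {
    l <- gm$loci[j, ]
    info <- if (is.finite(l$site_mapq)) sprintf("MQ=%g", l$site_mapq) else "."
    fields <- paste(gt_str[, j], dp_str[, j], sep = ":")
    writeLines(paste(c(l$chrom, l$pos, ".", l$ref, l$alt, ".", "PASS",
                       info, "GT:DP", fields), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write mined candidate loci as TSV
#'
#' Deterministically ordered by (chrom, pos). An empty candidate list yields
#' a header-only file.
#'
#' @param candidates data.frame as returned by [mine_fixed_alleles()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  cols <- c("chrom", "pos", "variant_type", "diagnostic_allele", "stage",
            "n_reference_support", "kasp_eligible", "scar_eligible")
  if (nrow(candidates)) {
    candidates <- candidates[order(candidates$chrom, candidates$pos), cols]
  } else {
    candidates <- candidates[, cols]
  }
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write fluorescence and band-pattern tables
#'
#' Fluorescence tables are TSV with columns `sample`, `assay`, `fam`, `hex`
#' (normalized endpoint intensities). Band tables are TSV with columns
#' `sample`, `assay`, `bands` where `bands` is a comma-separated list of
#' amplicon sizes in bp (empty string = no amplification).
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return the data.frame (readers) or `path` invisibly (writers).
#' @export
write_fluorescence <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fluorescence
#' @export
read_fluorescence <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(sample = "character", assay = "character"))
}

#' @rdname write_fluorescence
#' @export
write_bands <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fluorescence
#' @export
read_bands <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                          colClasses = c(sample = "character",
                                         assay = "character",
                                         bands = "character"))
  df$bands[is.na(df$bands)] <- ""
  df
}

#' Parse a comma-separated band string into integer sizes
#' @param s character scalar like `"516,537"` or `""`.
#' @return integer vector (possibly empty).
#' @export
parse_band_pattern <- function(s) {
  if (is.na(s) || !nzchar(s)) return(integer(0))
  as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
}
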