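#' Genotype codes
#'
#' Diploid genotypes are stored as integer codes: `0` = homozygous reference,
#' `1` = heterozygous, `2` = homozygous alternative, `NA` = missing.
#' @name genotype-codes
#' @keywords internal
NULL

GT_HOM_REF <- 0L
GT_HET <- 1L
GT_HOM_ALT <- 2L

#' Construct a genotype matrix
#'
#' The central data object of the package: a samples x loci table of diploid
#' genotype codes with per-genotype read depth and per-site metadata
#' (position, alleles, variant type, site mapping quality).
#'
#' @param geno integer matrix (samples x loci) of genotype codes 0/1/2/NA.
#' @param depth integer matrix of per-genotype read depths, same shape as
#'   `geno`; must be non-negative and defined (non-NA) wherever the genotype
#'   is non-missing.
#' @param loci data.frame of per-locus metadata with columns `chrom`, `pos`
#'   (1-based), `ref`, `alt` (allele sequences), `variant_type`
#'   (`"SNP"`/`"InDel"`), `site_mapq` (Phred-scaled; `Inf` allowed when the
#'   source VCF carried no MQ field).
#' @param sample_ids character vector of unique sample identifiers.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `geno`, `depth`, `loci`, `sample_ids`.
#' @export
genotype_matrix <- function(geno, depth, loci, sample_ids) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  depth <- as.matrix(depth)
  storage.mode(depth) <- "integer"
  if (!identical(dim(geno), dim(depth)))
    stop("geno and depth must have identical dimensions")
  if (length(sample_ids) != nrow(geno))
    stop("length(sample_ids) must equal nrow(geno)")
  if (anyDuplicated(sample_ids))
    stop("sample ids must be unique")
  if (nrow(loci) != ncol(geno))
    stop("nrow(loci) must equal ncol(geno)")
  req <- c("chrom", "pos", "ref", "alt", "variant_type", "site_mapq")
  miss <- setdiff(req, names(loci))
  if (length(miss))
    stop("loci is missing columns: ", paste(miss, collapse = ", "))
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (any(loci$pos < 1L))
    stop("locus positions must be >= 1 (1-based)")
  if (any(!is.na(depth) & depth < 0L))
    stop("depths must be non-negative")
  if (any(!is.na(geno) & is.na(depth)))
    stop("depth must be defined wherever the genotype is non-missing")
  expected_type <- ifelse(nchar(loci$ref) == nchar(loci$alt), "SNP", "InDel")
  if (!all(loci$variant_type == expected_type))
    stop("variant_type must be InDel iff ref/alt lengths differ")
  rownames(geno) <- rownames(depth) <- sample_ids
  structure(
    list(geno = geno, depth = depth,
         loci = as.data.frame(loci, stringsAsFactors = FALSE),
         sample_ids = as.character(sample_ids)),
    class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' @export
print.genotype_matrix <- function(x, ...) {
  n_snp <- sum(x$loci$variant_type == "SNP")
  cat(sprintf("genotype_matrix: %d samples x %d loci (%d SNP, %d InDel)\n",
              nrow(x$geno), ncol(x$geno), n_snp, ncol(x$geno) - n_snp))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param i sample index (ids, positions or logical).
#' @param j locus index (positions or logical).
#' @param ... ignored.
#' @return A `genotype_matrix` restricted to the selected samples and loci.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(ncol(x$geno))
  genotype_matrix(x$geno[i, j, drop = FALSE],
                  x$depth[i, j, drop = FALSE],
                  x$loci[j, , drop = FALSE],
                  rownames(x$geno[i, , drop = FALSE]))
}

#' Locus keys ("chrom_pos") for a genotype matrix or locus table
#' @param loci data.frame with `chrom` and `pos` columns.
#' @return character vector of keys.
#' @export
locus_key <- function(loci) paste(loci$chrom, loci$pos, sep = "_")
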