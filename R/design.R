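#' Reverse complement of a DNA string
#' @param seq character scalar over A/C/G/T.
#' @return character scalar.
#' @export
revcomp <- function(seq) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# nearest-neighbor thermodynamic parameters (unified duplex set):
# dH in kcal/mol, dS in cal/(mol K), 5'->3' dinucleotide steps
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Primer length, GC content and melting temperature
#'
#' Tm is computed from nearest-neighbor duplex thermodynamics with the
#' standard unified parameter set, terminal initiation corrections, a
#' monovalent-salt entropy correction of 0.368 cal/(mol K) per phosphate at
#' the stated sodium concentration, and the two-state formula
#' `Tm = 1000 dH / (dS + R ln(Ct/4)) - 273.15` for a non-self-complementary
#' primer in excess over template.
#'
#' @param seq primer sequence (non-empty, A/C/G/T only).
#' @param primer_conc total primer concentration, mol/L.
#' @param na_conc monovalent cation concentration, mol/L.
#' @return list with `length` (nt), `gc` (fraction), `tm` (degrees C).
#' @export
primer_properties <- function(seq, primer_conc = 2e-7, na_conc = 0.05) {
  if (length(seq) != 1 || is.na(seq) || !nzchar(seq))
    stop("seq must be a non-empty string")
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  if (!all(chars %in% BASES))
    stop("seq must contain only A, C, G, T")
  n <- length(chars)
  gc <- mean(chars %in% c("G", "C"))
  if (n < 2) return(list(length = n, gc = gc, tm = NA_real_))
  steps <- paste0(chars[-n], chars[-1])
  dh <- sum(NN_DH[steps])
  ds <- sum(NN_DS[steps])
  for (term in chars[c(1, n)]) {
    if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (n - 1) * log(na_conc)
  tm <- 1000 * dh / (ds + 1.987 * log(primer_conc / 4)) - 273.15
  list(length = n, gc = gc, tm = tm)
}

#' Primer design constraints
#'
#' @param tm_range target melting-temperature window, degrees C.
#' @param gc_range GC-content window (closed at both ends), fraction.
#' @param length_range primer length window, nt.
#' @param min_scar_size_diff minimum amplicon size difference between
#'   alleles for gel discrimination, bp.
#' @return list of class `design_constraints`.
#' @export
design_constraints <- function(tm_range = c(58, 62),
                               gc_range = c(0.40, 0.60),
                               length_range = c(20, 30),
                               min_scar_size_diff = 20) {
  stopifnot(tm_range[1] <= tm_range[2], gc_range[1] <= gc_range[2],
            length_range[1] <= length_range[2], all(length_range > 0),
            min_scar_size_diff > 0)
  structure(list(tm_range = tm_range, gc_range = gc_range,
                 length_range = as.integer(length_range),
                 min_scar_size_diff = min_scar_size_diff),
            class = "design_constraints")
}

primer_ok <- function(seq, constraints) {
  p <- primer_properties(seq)
  p$length >= constraints$length_range[1] &&
    p$length <= constraints$length_range[2] &&
    p$gc >= constraints$gc_range[1] && p$gc <= constraints$gc_range[2] &&
    !is.na(p$tm) &&
    p$tm >= constraints$tm_range[1] && p$tm <= constraints$tm_range[2]
}

tm_dev <- function(seq) abs(primer_properties(seq)$tm - 60)

#' KASP assay definition
#'
#' @param name assay name.
#' @param allele_primers named character vector of the two allele-specific
#'   primers (names are the allele roles, e.g. `ref`/`alt`).
#' @param common_primer the shared reverse primer.
#' @param dye_map named character vector mapping each allele role to
#'   `"FAM"` or `"HEX"`.
#' @param locus optional locus key (`"chrom_pos"`).
#' @return list of class `kasp_assay`.
#' @export
kasp_assay <- function(name, allele_primers, common_primer, dye_map,
                       locus = NULL) {
  stopifnot(length(allele_primers) == 2, !is.null(names(allele_primers)),
            all(sort(names(allele_primers)) == sort(names(dye_map))),
            all(dye_map %in% c("FAM", "HEX")),
            length(unique(dye_map)) == 2)
  structure(list(name = name, allele_primers = allele_primers,
                 common_primer = common_primer, dye_map = dye_map,
                 locus = locus), class = "kasp_assay")
}

#' SCAR assay definition
#'
#' @param name assay name.
#' @param mode `"dominant"` (one allele yields no amplicon) or
#'   `"codominant"` (both alleles amplify at distinguishable sizes).
#' @param size_map named numeric vector mapping each allele role to its
#'   amplicon size in bp, with `NA` meaning "no band" (dominant mode only).
#' @param forward_primer,reverse_primer optional primer sequences.
#' @param locus optional locus key.
#' @param min_size_diff minimum codominant size difference enforced at
#'   construction.
#' @return list of class `scar_assay`.
#' @export
scar_assay <- function(name, mode = c("dominant", "codominant"), size_map,
                       forward_primer = NULL, reverse_primer = NULL,
                       locus = NULL, min_size_diff = 20) {
  mode <- match.arg(mode)
  stopifnot(length(size_map) == 2, !is.null(names(size_map)))
  if (mode == "dominant") {
    if (sum(is.na(size_map)) != 1)
      stop("dominant assay must map exactly one allele to no band")
  } else {
    if (anyNA(size_map))
      stop("codominant assay must map both alleles to a size")
    if (abs(diff(size_map)) < min_size_diff)
      stop("codominant size difference below the gel-discrimination minimum")
  }
  structure(list(name = name, mode = mode, size_map = size_map,
                 forward_primer = forward_primer,
                 reverse_primer = reverse_primer, locus = locus),
            class = "scar_assay")
}

# haplotype sequence for one allele: the flank carries `ref` at `pos`
haplotype <- function(flank, pos, ref, allele) {
  paste0(substr(flank, 1, pos - 1), allele,
         substr(flank, pos + nchar(ref), nchar(flank)))
}

# enumerate allele-specific primer pairs on one strand; returns best
# candidate as list(a, b, len, dev) or NULL.  `side` = "left" (forward
# strand, primer 3' end on the variant) or "right" (reverse strand).
best_as_pair <- function(hap_a, hap_b, pos, ref, alt, side, constraints,
                         is_snp) {
  lens <- seq(constraints$length_range[1], constraints$length_range[2])
  best <- NULL
  for (L in lens) {
    if (is_snp) {
      if (side == "left") {
        if (pos - L + 1 < 1) next
        pa <- substr(hap_a, pos - L + 1, pos)
        pb <- substr(hap_b, pos - L + 1, pos)
      } else {
        if (pos + L - 1 > nchar(hap_a)) next
        pa <- revcomp(substr(hap_a, pos, pos + L - 1))
        pb <- revcomp(substr(hap_b, pos, pos + L - 1))
      }
    } else {
      # junction-spanning: 3' end two bases past the variant start (left)
      # or two bases before the variant end (right) on each haplotype
      ends <- c(a = pos + 2, b = pos + 2)
      if (side == "left") {
        if (ends["a"] - L + 1 < 1) next
        pa <- substr(hap_a, ends["a"] - L + 1, ends["a"])
        pb <- substr(hap_b, ends["b"] - L + 1, ends["b"])
        if (ends["a"] > nchar(hap_a) || ends["b"] > nchar(hap_b)) next
      } else {
        sa <- pos + nchar(ref) - 3; sb <- pos + nchar(alt) - 3
        if (sa < 1 || sb < 1) next
        if (sa + L - 1 > nchar(hap_a) || sb + L - 1 > nchar(hap_b)) next
        pa <- revcomp(substr(hap_a, sa, sa + L - 1))
        pb <- revcomp(substr(hap_b, sb, sb + L - 1))
      }
      if (pa == pb) next  # must discriminate the alleles
    }
    if (!primer_ok(pa, constraints) || !primer_ok(pb, constraints)) next
    dev <- max(tm_dev(pa), tm_dev(pb))
    if (is.null(best) || dev < best$dev - 1e-9 ||
        (abs(dev - best$dev) <= 1e-9 && L < best$len)) {
      best <- list(a = pa, b = pb, len = L, dev = dev)
    }
  }
  best
}

# best common primer on the side opposite the AS primer.
# side = "right": reverse-strand primer downstream of the variant;
# side = "left": forward-strand primer upstream.  Mirror-invariant ranking:
# |Tm - 60|, then distance to the variant, then length.
best_common <- function(flank, pos, ref, side, constraints, max_amplicon) {
  lens <- seq(constraints$length_range[1], constraints$length_range[2])
  n <- nchar(flank)
  best <- NULL
  consider <- function(seqs, dist, L) {
    for (k in seq_along(seqs)) {
      if (!primer_ok(seqs[k], constraints)) next
      dev <- tm_dev(seqs[k])
      cand <- list(seq = seqs[k], dev = dev, dist = dist[k], len = L)
      if (is.null(best) || dev < best$dev - 1e-9 ||
          (abs(dev - best$dev) <= 1e-9 &&
           (cand$dist < best$dist ||
            (cand$dist == best$dist && L < best$len))))
        best <<- cand
    }
  }
  for (L in lens) {
    if (side == "right") {
      starts <- seq(pos + nchar(ref), min(n - L + 1, pos + max_amplicon - L))
      if (!length(starts) || starts[1] > starts[length(starts)]) next
      seqs <- vapply(starts, function(s)
        revcomp(substr(flank, s, s + L - 1)), character(1))
      consider(seqs, starts - (pos + nchar(ref)), L)
    } else {
      ends <- seq(max(L, pos - max_amplicon + L), pos - 1)
      ends <- ends[ends >= L & ends < pos]
      if (!length(ends)) next
      seqs <- vapply(ends, function(e)
        substr(flank, e - L + 1, e), character(1))
      consider(seqs, pos - 1 - ends, L)
    }
  }
  best
}

#' Design a KASP assay for a candidate locus
#'
#' Screens the flanking sequence for two allele-specific primers whose 3'
#' ends discriminate the alleles (terminating on the variant base for SNPs,
#' spanning the InDel junction for InDels) plus one common primer on the
#' opposite side and strand, all satisfying the Tm/GC/length constraints.
#' Both orientations are screened (allele-specific primers on either
#' strand); candidates are ranked by worst allele-primer |Tm - 60|, then the
#' common primer's |Tm - 60|, then primer length and distance to the
#' variant, with exact ties broken toward the input's forward strand — a
#' mirror-invariant rule, so designing on the reverse-complemented flank
#' returns the reverse-complemented assay. Returns `NULL` when no primer set
#' satisfies the constraints.
#'
#' @param flank flanking sequence containing the variant's reference allele.
#' @param pos 1-based position of the variant (first base of the reference
#'   allele) within `flank`; at least ~100 bp of context on either side is
#'   recommended and 200 bp total is required.
#' @param ref,alt the two allele sequences.
#' @param diagnostic_allele `"ref"` or `"alt"`: the target-species allele
#'   (read out on HEX; the other allele on FAM).
#' @param constraints a [design_constraints()].
#' @param max_amplicon maximum distance (bp) from the variant searched for
#'   the common primer.
#' @param name assay name.
#' @return A [kasp_assay()] (with `$details` holding strand, primer
#'   properties), or `NULL`.
#' @export
design_kasp <- function(flank, pos, ref, alt,
                        diagnostic_allele = c("ref", "alt"),
                        constraints = design_constraints(),
                        max_amplicon = 120, name = "KASP") {
  diagnostic_allele <- match.arg(diagnostic_allele)
  flank <- toupper(flank)
  if (nchar(flank) < 200) stop("flank must cover at least 200 bp")
  if (pos < 1 || pos + nchar(ref) - 1 > nchar(flank))
    stop("variant does not lie inside the flank")
  if (substr(flank, pos, pos + nchar(ref) - 1) != toupper(ref))
    stop("flank does not carry the reference allele at pos")
  is_snp <- nchar(ref) == nchar(alt)
  hap_a <- flank                                  # ref haplotype
  hap_b <- haplotype(flank, pos, ref, alt)        # alt haplotype

  configs <- list()
  as_left <- best_as_pair(hap_a, hap_b, pos, ref, alt, "left", constraints,
                          is_snp)
  if (!is.null(as_left)) {
    com <- best_common(flank, pos, ref, "right", constraints, max_amplicon)
    if (!is.null(com))
      configs$fwd <- list(as = as_left, com = com, strand = "+")
  }
  as_right <- best_as_pair(hap_a, hap_b, pos, ref, alt, "right", constraints,
                           is_snp)
  if (!is.null(as_right)) {
    com <- best_common(flank, pos, ref, "left", constraints, max_amplicon)
    if (!is.null(com))
      configs$rev <- list(as = as_right, com = com, strand = "-")
  }
  if (!length(configs)) return(NULL)
  score <- vapply(configs, function(cf)
    c(cf$as$dev, cf$com$dev, cf$as$len, cf$com$dist), numeric(4))
  pick <- if (ncol(score) == 1) 1L else {
    o <- do.call(order, as.data.frame(t(score)))
    o[1]
  }
  cf <- configs[[pick]]
  primers <- c(ref = cf$as$a, alt = cf$as$b)
  dye <- if (diagnostic_allele == "ref") c(ref = "HEX", alt = "FAM")
         else c(ref = "FAM", alt = "HEX")
  assay <- kasp_assay(name, primers, cf$com$seq, dye)
  assay$details <- list(strand = cf$strand,
                        as_tm_dev = cf$as$dev, common_tm_dev = cf$com$dev)
  assay$constraints <- constraints
  assay
}

#' Design a SCAR assay around an InDel locus
#'
#' In codominant mode both primers sit outside the InDel, so both alleles
#' amplify and differ in size by the InDel length (which must reach the
#' gel-discrimination minimum). In dominant mode the reverse primer is
#' placed inside the segment present only in the longer (insertion) allele,
#' so the shorter (deletion) allele yields no amplicon at all. Primers are
#' ranked by |Tm - 60|, then proximity to the InDel, then length. Returns
#' `NULL` when no satisfying primer pair exists.
#'
#' @inheritParams design_kasp
#' @param mode `"codominant"` or `"dominant"`.
#' @param max_amplicon maximum amplicon size screened, bp.
#' @return A [scar_assay()] with a computed `size_map` (bp per allele,
#'   `NA` = no band), or `NULL`.
#' @export
design_scar <- function(flank, pos, ref, alt,
                        mode = c("codominant", "dominant"),
                        constraints = design_constraints(),
                        max_amplicon = 600, name = "SCAR") {
  mode <- match.arg(mode)
  flank <- toupper(flank)
  if (nchar(ref) == nchar(alt)) stop("SCAR design requires an InDel locus")
  if (pos < 1 || pos + nchar(ref) - 1 > nchar(flank))
    stop("variant does not lie inside the flank")
  if (substr(flank, pos, pos + nchar(ref) - 1) != toupper(ref))
    stop("flank does not carry the reference allele at pos")
  len_diff <- abs(nchar(ref) - nchar(alt))
  if (mode == "codominant" && len_diff < constraints$min_scar_size_diff)
    return(NULL)

  fwd <- best_common(flank, pos, ref, "left", constraints, max_amplicon)
  if (is.null(fwd)) return(NULL)
  fwd_start <- pos - fwd$dist - fwd$len

  if (mode == "codominant") {
    rev <- best_common(flank, pos, ref, "right", constraints, max_amplicon)
    if (is.null(rev)) return(NULL)
    rev_end <- pos + nchar(ref) + rev$dist + rev$len - 1
    amp_ref <- rev_end - fwd_start + 1
    amp_alt <- amp_ref - nchar(ref) + nchar(alt)
    if (amp_ref > max_amplicon || amp_alt > max_amplicon) return(NULL)
    sizes <- c(ref = amp_ref, alt = amp_alt)
    assay <- scar_assay(name, "codominant", sizes, fwd$seq, rev$seq,
                        min_size_diff = constraints$min_scar_size_diff)
  } else {
    # reverse primer inside the insertion-specific segment
    long_is_ref <- nchar(ref) > nchar(alt)
    long_allele <- if (long_is_ref) ref else alt
    hap_long <- if (long_is_ref) flank else haplotype(flank, pos, ref, alt)
    ins_start <- pos + 1                       # shared left anchor base
    ins_end <- pos + nchar(long_allele) - 1
    lens <- seq(constraints$length_range[1], constraints$length_range[2])
    best <- NULL
    for (L in lens) {
      starts <- seq.int(ins_start, ins_end - L + 1)
      if (ins_end - L + 1 < ins_start) next
      for (s in starts) {
        p <- revcomp(substr(hap_long, s, s + L - 1))
        if (!primer_ok(p, constraints)) next
        dev <- tm_dev(p)
        if (is.null(best) || dev < best$dev - 1e-9)
          best <- list(seq = p, dev = dev, end = s + L - 1)
      }
    }
    if (is.null(best)) return(NULL)
    amp_long <- best$end - fwd_start + 1
    if (amp_long > max_amplicon) return(NULL)
    sizes <- if (long_is_ref) c(ref = amp_long, alt = NA_real_)
             else c(ref = NA_real_, alt = amp_long)
    assay <- scar_assay(name, "dominant", sizes, fwd$seq, best$seq)
  }
  assay$constraints <- constraints
  assay
}

#' Re-validate a designed assay against its constraints
#' @param assay a `kasp_assay` or `scar_assay` carrying `$constraints`.
#' @return `TRUE` if every primer satisfies the stored constraints.
#' @export
validate_assay <- function(assay) {
  cs <- assay$constraints
  if (is.null(cs)) stop("assay carries no constraints to validate against")
  primers <- if (inherits(assay, "kasp_assay"))
    c(assay$allele_primers, assay$common_primer)
  else c(assay$forward_primer, assay$reverse_primer)
  all(vapply(primers, primer_ok, logical(1), constraints = cs))
}
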