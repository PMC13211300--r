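#' Wilson score confidence interval for a binomial proportion
#'
#' Two-sided interval obtained by inverting the normal-approximation score
#' test, without continuity correction; well behaved at proportions near 0
#' and 1 (the upper bound is exactly 1 when all trials succeed).
#'
#' @param successes,n counts with `0 <= successes <= n`, `n >= 1`.
#' @param confidence two-sided confidence level in (0, 1).
#' @return numeric `c(lower, upper)`, both in `[0, 1]` and bracketing
#'   `successes / n`.
#' @export
wilson_interval <- function(successes, n, confidence = 0.95) {
  if (n < 1) stop("n must be >= 1")
  if (successes < 0 || successes > n)
    stop("successes must lie in [0, n]")
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must lie in (0, 1)")
  z <- stats::qnorm((1 + confidence) / 2)
  p <- successes / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Hybrid index over diagnostic loci
#'
#' The fraction of target-species alleles among all non-missing alleles at
#' the diagnostic loci: 1 for a pure target individual, 0.5 for an F1, 0
#' for the other parental species, and 0.75 in expectation for a first
#' backcross to the target.
#'
#' @param geno_codes integer genotype codes (0/1/2/NA) at the diagnostic
#'   loci for one sample.
#' @param target_alleles per-locus `"ref"`/`"alt"`: which allele is the
#'   target-species allele.
#' @return fraction in `[0, 1]`.
#' @export
hybrid_index <- function(geno_codes, target_alleles) {
  stopifnot(length(geno_codes) == length(target_alleles),
            all(target_alleles %in% c("ref", "alt")))
  ok <- !is.na(geno_codes)
  if (!any(ok)) stop("all diagnostic genotypes are missing")
  n_alt <- geno_codes[ok]
  n_target <- ifelse(target_alleles[ok] == "alt", n_alt, 2L - n_alt)
  sum(n_target) / (2 * sum(ok))
}

#' Score species calls against panel labels
#'
#' Each sample's species-level call is reduced to a binary side (`target`
#' vs `nontarget`; a heterozygous-hybrid call counts as non-target, while
#' `ambiguous`/`no_call` match nothing) and compared with the expected side
#' under the chosen convention. Under the `morphological` convention the
#' expectation comes from the field label (morphological `target` expects a
#' target call; variants, non-target species and recognised hybrids expect
#' a non-target call). Under the `genetic` convention it comes from the
#' genetic truth (`target` vs `hybrid`/`nontarget`). The convention must be
#' named explicitly — the two can differ materially on panels containing
#' cryptic hybrids, so no silent default is offered.
#'
#' Sensitivity is the concordant fraction among genetically confirmed
#' purebreds; specificity the concordant fraction among genetic non-targets
#' (hybrids included), each scored under the chosen convention.
#'
#' @param calls data.frame with columns `sample` and `call` (species calls).
#' @param sheet a [sample_sheet()]; every sample in `calls` must appear.
#' @param convention `"morphological"` or `"genetic"` (required).
#' @param confidence confidence level for Wilson intervals.
#' @return object of class `diagnostic_report`: list with `convention`,
#'   `n`, `concordance`, `concordance_ci`, `sensitivity`, `sensitivity_ci`,
#'   `specificity`, `specificity_ci`, `counts` (tp/fn/tn/fp),
#'   `discordant` (sample ids).
#' @export
score_panel <- function(calls, sheet, convention = c("morphological",
                                                     "genetic"),
                        confidence = 0.95) {
  if (missing(convention))
    stop("scoring convention must be named explicitly ",
         "('morphological' or 'genetic')")
  convention <- match.arg(convention)
  m <- match(calls$sample, sheet$id)
  if (anyNA(m)) stop("calls contain samples absent from the sheet")

  call_side <- ifelse(calls$call == "target", "target",
               ifelse(calls$call %in% c("nontarget", "heterozygous_hybrid"),
                      "nontarget", NA_character_))
  expected_side <- if (convention == "morphological") {
    ifelse(sheet$morphological_label[m] == "target", "target", "nontarget")
  } else {
    ifelse(sheet$genetic_truth[m] == "target", "target", "nontarget")
  }
  concordant <- !is.na(call_side) & call_side == expected_side
  is_pos <- sheet$genetic_truth[m] == "target"

  counts <- c(tp = sum(is_pos & concordant),
              fn = sum(is_pos & !concordant),
              tn = sum(!is_pos & concordant),
              fp = sum(!is_pos & !concordant))
  n <- length(concordant)
  sens_n <- sum(is_pos); spec_n <- sum(!is_pos)
  report <- list(
    convention = convention,
    n = n,
    concordance = mean(concordant),
    concordance_ci = wilson_interval(sum(concordant), n, confidence),
    sensitivity = if (sens_n) counts[["tp"]] / sens_n else NA_real_,
    sensitivity_ci = if (sens_n)
      wilson_interval(counts[["tp"]], sens_n, confidence) else NULL,
    specificity = if (spec_n) counts[["tn"]] / spec_n else NA_real_,
    specificity_ci = if (spec_n)
      wilson_interval(counts[["tn"]], spec_n, confidence) else NULL,
    counts = counts,
    discordant = calls$sample[!concordant])
  class(report) <- "diagnostic_report"
  report
}

# percentage rounded half away from zero, one decimal
fmt_pct <- function(x, digits = 1) {
  scaled <- x * 100 * 10^digits
  sprintf(paste0("%.", digits, "f"), sign(scaled) * floor(abs(scaled) + 0.5) /
            10^digits)
}

#' @export
print.diagnostic_report <- function(x, ...) {
  ci <- function(b) sprintf("(95%% CI: %s-%s%%)",
                            fmt_pct(b[1]), fmt_pct(b[2]))
  cat(sprintf("diagnostic report (%s convention, n = %d)\n",
              x$convention, x$n))
  cat(sprintf("  concordance: %s%% (%d/%d) %s\n",
              fmt_pct(x$concordance),
              x$counts[["tp"]] + x$counts[["tn"]], x$n,
              ci(x$concordance_ci)))
  if (!is.na(x$sensitivity))
    cat(sprintf("  sensitivity: %s%% (%d/%d)\n", fmt_pct(x$sensitivity),
                x$counts[["tp"]], x$counts[["tp"]] + x$counts[["fn"]]))
  if (!is.na(x$specificity))
    cat(sprintf("  specificity: %s%% (%d/%d)\n", fmt_pct(x$specificity),
                x$counts[["tn"]], x$counts[["tn"]] + x$counts[["fp"]]))
  if (length(x$discordant))
    cat("  discordant samples:", paste(x$discordant, collapse = ", "), "\n")
  else cat("  no discordant samples\n")
  invisible(x)
}
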