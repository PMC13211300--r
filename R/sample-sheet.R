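#' Construct a sample sheet
#'
#' Per-sample metadata pairing the field (morphological) classification with
#' the genetic ground truth, plus a flag marking membership in the stage-1
#' marker-training reference pool.
#'
#' Morphological labels follow the field classification of a hybrid-swarm
#' panel: `target` (typical target-species phenotype), `target_variant`
#' (atypical phenotype, e.g. aberrant flower colour), `nontarget_species`,
#' and `nontarget_hybrid` (recognised natural hybrids). Genetic truth is the
#' species-level identity: `target`, `hybrid`, or `nontarget`.
#'
#' @param id character vector of unique sample ids.
#' @param morphological_label one of `target`, `target_variant`,
#'   `nontarget_species`, `nontarget_hybrid` per sample.
#' @param genetic_truth one of `target`, `hybrid`, `nontarget` per sample.
#' @param in_training logical; whether the sample enters the stage-1
#'   reference (training) pool.
#' @return data.frame of class `sample_sheet`.
#' @export
sample_sheet <- function(id, morphological_label, genetic_truth, in_training) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("sample ids must be unique")
  if (length(morphological_label) != length(id) ||
      length(genetic_truth) != length(id) ||
      length(in_training) != length(id))
    stop("all sample-sheet columns must have one entry per sample")
  out <- data.frame(id = id,
                    morphological_label = as.character(morphological_label),
                    genetic_truth = as.character(genetic_truth),
                    in_training = as.logical(in_training),
                    stringsAsFactors = FALSE)
  stopifnot(all(out$morphological_label %in%
                  c("target", "target_variant", "nontarget_species",
                    "nontarget_hybrid")),
            all(out$genetic_truth %in% c("target", "hybrid", "nontarget")))
  class(out) <- c("sample_sheet", "data.frame")
  out
}

#' Write / read a sample sheet as TSV
#' @param sheet a `sample_sheet`.
#' @param path file path.
#' @return `read_sample_sheet` returns a `sample_sheet`.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sample_sheet(df$id, df$morphological_label, df$genetic_truth, df$in_training)
}
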