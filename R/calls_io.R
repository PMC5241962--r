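# Gene-call records and their TSV serialization.

CALL_COLS <- c("array_id", "gene_id", "n_probes", "n_significant",
               "frac_significant", "direction", "median_m", "is_cnv",
               "is_pav")

validate_calls <- function(calls) {
  require_cols(calls, CALL_COLS, "call table")
  if (any(calls$frac_significant < 0 | calls$frac_significant > 1))
    abort("frac_significant must lie in [0, 1]")
  if (!all(calls$direction %in% c("gain", "loss", "none")))
    abort("direction must be gain, loss or none")
  if (any(calls$is_pav & !calls$is_cnv))
    abort("is_pav implies is_cnv")
  if (any((calls$direction == "none") != !calls$is_cnv))
    abort("direction must be 'none' exactly when is_cnv is FALSE")
  calls[CALL_COLS]
}

#' Write gene CNV calls to a TSV file
#'
#' One row per (array, gene); columns are exactly the gene-call fields.
#' Records violating call invariants (e.g. a PAV flag on an uncalled
#' gene) are refused.
#'
#' @param calls data.frame of gene calls as produced by [call_array()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_calls <- function(calls, path) {
  calls <- validate_calls(calls)
  write_tsv(calls, path)
}

#' Read gene CNV calls written by [write_calls()]
#'
#' @param path TSV path.
#' @return data.frame of validated gene calls.
#' @export
read_calls <- function(path) {
  df <- read_tsv(path)
  if (nrow(df)) {
    df$is_cnv <- as_flag(df$is_cnv)
    df$is_pav <- as_flag(df$is_pav)
    df$array_id <- as.character(df$array_id)
    df$gene_id <- as.character(df$gene_id)
    df$n_probes <- as.integer(df$n_probes)
    df$n_significant <- as.integer(df$n_significant)
  } else {
    df <- empty_calls()
  }
  validate_calls(df)
}

empty_calls <- function() {
  data.frame(array_id = character(), gene_id = character(),
             n_probes = integer(), n_significant = integer(),
             frac_significant = numeric(), direction = character(),
             median_m = numeric(), is_cnv = logical(), is_pav = logical(),
             stringsAsFactors = FALSE)
}

#' Read a genetic map
#'
#' @param path TSV with columns `gene_id`, `linkage_group`, `position`
#'   (cM, non-negative; one row per gene).
#' @return data.frame of class `genetic_map`.
#' @export
read_genetic_map <- function(path) {
  df <- read_tsv(path)
  genetic_map(df)
}

#' Construct a genetic map
#'
#' @param df data.frame with columns `gene_id`, `linkage_group`,
#'   `position`.
#' @return The validated data.frame with class `genetic_map`.
#' @export
genetic_map <- function(df) {
  require_cols(df, c("gene_id", "linkage_group", "position"), "genetic map")
  df$gene_id <- as.character(df$gene_id)
  df$linkage_group <- as.character(df$linkage_group)
  if (anyDuplicated(df$gene_id))
    abort("genetic map assigns multiple positions to a gene")
  if (any(df$position < 0)) abort("map positions must be non-negative")
  rownames(df) <- NULL
  structure(df[c("gene_id", "linkage_group", "position")],
            class = c("genetic_map", "data.frame"))
}
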