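#' Construct a two-channel array experiment
#'
#' Holds the metadata and raw per-probe measurements of one hybridization:
#' a test genome against a reference genome, each measured as raw and
#' background fluorescence. Intensity columns are named by nominal role
#' (`i_test_*` / `i_ref_*`); when `dye_swap` is `TRUE` the test sample was
#' labeled with the dye of the nominal reference channel, and ratio
#' computation flips the sign of M accordingly.
#'
#' @param array_id,test_sample,ref_sample Identifiers.
#' @param measurements data.frame with columns `probe_id`, `i_test_raw`,
#'   `i_test_bg`, `i_ref_raw`, `i_ref_bg` (arbitrary fluorescence units,
#'   all non-negative).
#' @param family_id Family identifier or `NA`.
#' @param self_self `TRUE` for a self-self hybridization (then
#'   `test_sample` must equal `ref_sample`).
#' @param dye_swap `TRUE` when the dye orientation is reversed.
#' @return An object of class `array_experiment`.
#' @export
array_experiment <- function(array_id, test_sample, ref_sample, measurements,
                             family_id = NA_character_, self_self = FALSE,
                             dye_swap = FALSE) {
  if (!is_string(array_id)) abort("array_id must be a string")
  if (!is_flag(self_self) || !is_flag(dye_swap))
    abort("self_self and dye_swap must be single logicals")
  if (self_self && !identical(test_sample, ref_sample))
    abort("self-self array %s has test_sample != ref_sample", array_id)
  require_cols(measurements,
               c("probe_id", "i_test_raw", "i_test_bg", "i_ref_raw", "i_ref_bg"),
               sprintf("measurements of array %s", array_id))
  icols <- c("i_test_raw", "i_test_bg", "i_ref_raw", "i_ref_bg")
  if (any(as.matrix(measurements[icols]) < 0))
    abort("array %s has negative intensities", array_id)
  if (anyDuplicated(measurements$probe_id))
    abort("array %s has duplicated probe measurements", array_id)
  measurements$probe_id <- as.character(measurements$probe_id)
  rownames(measurements) <- NULL
  structure(list(array_id = array_id,
                 test_sample = as.character(test_sample),
                 ref_sample = as.character(ref_sample),
                 family_id = as.character(family_id),
                 self_self = self_self,
                 dye_swap = dye_swap,
                 measurements = measurements),
            class = "array_experiment")
}

#' @export
print.array_experiment <- function(x, ...) {
  cat(sprintf("array %s: %s vs %s (%d probes%s%s)\n", x$array_id,
              x$test_sample, x$ref_sample, nrow(x$measurements),
              if (x$self_self) ", self-self" else "",
              if (x$dye_swap) ", dye-swapped" else ""))
  invisible(x)
}

#' Read array experiments from intensity and metadata tables
#'
#' @param intensity_path TSV with columns `array_id`, `probe_id`,
#'   `i_test_raw`, `i_test_bg`, `i_ref_raw`, `i_ref_bg`.
#' @param metadata_path TSV with columns `array_id`, `test_sample`,
#'   `ref_sample`, `family_id`, `self_self`, `dye_swap`.
#' @param panel Optional [probe_panel()]; when given, every measured probe
#'   must exist in the panel, and probes of the panel missing from an array
#'   are reported with a message.
#' @return A named list of [array_experiment()] objects, one per metadata
#'   row.
#' @export
read_arrays <- function(intensity_path, metadata_path, panel = NULL) {
  meta <- read_tsv(metadata_path)
  require_cols(meta, c("array_id", "test_sample", "ref_sample",
                       "family_id", "self_self", "dye_swap"), "array metadata")
  meta$array_id <- as.character(meta$array_id)
  if (anyDuplicated(meta$array_id))
    abort("duplicated array_id in metadata")
  ints <- read_tsv(intensity_path)
  require_cols(ints, c("array_id", "probe_id", "i_test_raw", "i_test_bg",
                       "i_ref_raw", "i_ref_bg"), "intensity table")
  ints$array_id <- as.character(ints$array_id)

  orphan <- setdiff(unique(ints$array_id), meta$array_id)
  if (length(orphan))
    abort("intensities reference array(s) absent from metadata: %s",
          paste(orphan, collapse = ", "))
  empty <- setdiff(meta$array_id, unique(ints$array_id))
  if (length(empty))
    abort("metadata array(s) have no intensities: %s",
          paste(empty, collapse = ", "))
  if (!is.null(panel)) {
    unknown <- setdiff(unique(ints$probe_id), panel$probe_id)
    if (length(unknown))
      abort("intensities reference probe(s) absent from the panel: %s",
            paste(utils::head(unknown, 5), collapse = ", "))
  }

  by_array <- split(ints[setdiff(names(ints), "array_id")], ints$array_id)
  out <- lapply(seq_len(nrow(meta)), function(i) {
    row <- meta[i, ]
    m <- by_array[[row$array_id]]
    if (!is.null(panel)) {
      n_missing <- length(setdiff(panel$probe_id, m$probe_id))
      if (n_missing > 0)
        message(sprintf("array %s: %d panel probe(s) without measurements",
                        row$array_id, n_missing))
    }
    array_experiment(row$array_id, row$test_sample, row$ref_sample, m,
                     family_id = as.character(row$family_id),
                     self_self = as_flag(row$self_self),
                     dye_swap = as_flag(row$dye_swap))
  })
  names(out) <- meta$array_id
  out
}

#' Write array experiments to intensity and metadata tables
#'
#' Inverse of [read_arrays()].
#'
#' @param experiments List of [array_experiment()] objects.
#' @param intensity_path,metadata_path Output paths.
#' @return The metadata path, invisibly.
#' @export
write_arrays <- function(experiments, intensity_path, metadata_path) {
  meta <- do.call(rbind, lapply(experiments, function(e)
    data.frame(array_id = e$array_id, test_sample = e$test_sample,
               ref_sample = e$ref_sample, family_id = e$family_id,
               self_self = e$self_self, dye_swap = e$dye_swap,
               stringsAsFactors = FALSE)))
  ints <- do.call(rbind, lapply(experiments, function(e)
    cbind(array_id = e$array_id, e$measurements)))
  write_tsv(ints, intensity_path)
  write_tsv(meta, metadata_path)
}

#' Metadata table of a list of array experiments
#'
#' @param experiments List of [array_experiment()] objects.
#' @return data.frame with one row per array.
#' @export
array_metadata <- function(experiments) {
  do.call(rbind, lapply(experiments, function(e)
    data.frame(array_id = e$array_id, test_sample = e$test_sample,
               ref_sample = e$ref_sample, family_id = e$family_id,
               self_self = e$self_self, dye_swap = e$dye_swap,
               stringsAsFactors = FALSE, row.names = NULL)))
}
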