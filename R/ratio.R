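#' Construct a per-probe log-ratio table
#'
#' One row per retained probe of one array, with the log2 ratio `m` and
#' the average log2 intensity `a`. The normalization stage reached so far
#' is recorded in the `stage` attribute and advances strictly along
#' raw -> loess -> gc -> composition.
#'
#' @param array_id Array identifier.
#' @param df data.frame with columns `probe_id`, `m`, `a` (all finite).
#' @param stage One of `"raw"`, `"loess"`, `"gc"`, `"composition"`.
#' @param self_self Whether the source array was a self-self
#'   hybridization.
#' @param n_dropped Number of probes dropped for non-positive
#'   background-subtracted intensity.
#' @return A data.frame of class `ratio_table`.
#' @export
ratio_table <- function(array_id, df, stage = "raw", self_self = FALSE,
                        n_dropped = 0L) {
  require_cols(df, c("probe_id", "m", "a"), "ratio table")
  stage <- match.arg(stage, c("raw", "loess", "gc", "composition"))
  if (!all(is.finite(df$m)) || !all(is.finite(df$a)))
    abort("ratio table for array %s contains non-finite M or A", array_id)
  if (anyDuplicated(df$probe_id))
    abort("ratio table for array %s has duplicate probes", array_id)
  df$probe_id <- as.character(df$probe_id)
  rownames(df) <- NULL
  structure(df[c("probe_id", "m", "a")],
            class = c("ratio_table", "data.frame"),
            array_id = array_id, stage = stage,
            self_self = isTRUE(self_self), n_dropped = as.integer(n_dropped))
}

ratio_stage <- function(tab) attr(tab, "stage")

# Replace M, advance the stage, keep everything else.
advance_stage <- function(tab, m_new, stage) {
  ratio_table(attr(tab, "array_id"),
              data.frame(probe_id = tab$probe_id, m = m_new, a = tab$a),
              stage = stage, self_self = attr(tab, "self_self"),
              n_dropped = attr(tab, "n_dropped"))
}

#' Write ratio tables to one TSV
#'
#' @param tables List of [ratio_table()] objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ratio_tables <- function(tables, path) {
  rows <- do.call(rbind, lapply(tables, function(t)
    data.frame(array_id = attr(t, "array_id"), probe_id = t$probe_id,
               m = t$m, a = t$a, stage = attr(t, "stage"),
               self_self = attr(t, "self_self"), stringsAsFactors = FALSE)))
  write_tsv(rows, path)
}

#' Read ratio tables written by [write_ratio_tables()]
#'
#' @param path TSV path.
#' @return Named list of [ratio_table()] objects.
#' @export
read_ratio_tables <- function(path) {
  df <- read_tsv(path)
  require_cols(df, c("array_id", "probe_id", "m", "a", "stage", "self_self"),
               "ratio file")
  df$array_id <- as.character(df$array_id)
  out <- lapply(split(df, df$array_id), function(d)
    ratio_table(d$array_id[1L], d[c("probe_id", "m", "a")],
                stage = d$stage[1L], self_self = as_flag(d$self_self[1L])))
  out[unique(df$array_id)]
}
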