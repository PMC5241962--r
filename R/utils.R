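# Internal helpers shared across modules.

abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Logical parser tolerant of TSV round-trips ("TRUE", "true", "1").
as_flag <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(as.character(x))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out)) abort("cannot interpret '%s' as a logical flag", v[is.na(out)][1L])
  out
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) abort("file not found: %s", path)
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    abort("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "))
  invisible(df)
}
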