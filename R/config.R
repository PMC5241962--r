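#' Read a flat key = value configuration file
#'
#' Accepts the scalar subset of flat TOML: one `key = value` pair per
#' line, `#` comments, quoted strings, bare numbers and `true`/`false`.
#' Used by the command-line interface to carry detection parameters and
#' simulation settings.
#'
#' @param path Path to the configuration file.
#' @return Named list of scalars.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      abort("malformed config line: '%s'", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (grepl('^".*"$', val)) {
      out[[key]] <- sub('^"(.*)"$', "\\1", val)
    } else if (val %in% c("true", "false")) {
      out[[key]] <- val == "true"
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) abort("cannot parse config value '%s' for key '%s'",
                            val, key)
      out[[key]] <- num
    }
  }
  out
}

#' Write a flat key = value configuration file
#'
#' Inverse of [read_config()] for scalar values.
#'
#' @param config Named list of scalars.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  fmt <- vapply(config, function(v) {
    if (is.character(v)) sprintf('"%s"', v)
    else if (is.logical(v)) if (v) "true" else "false"
    else format(v, digits = 17)
  }, character(1))
  writeLines(paste(names(config), "=", fmt), path)
  invisible(path)
}
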