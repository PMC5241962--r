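#' Construct a probe panel
#'
#' A probe panel is the package's description of the array design: one row
#' per probe giving its gene, position within the gene sequence (0-based,
#' half-open interval `[start, start + length)`), strand orientation, GC
#' fraction and mononucleotide composition. Gene sequence lengths are kept
#' as an attribute and default to the end of the last probe of each gene.
#'
#' @param df A data.frame with columns `probe_id`, `gene_id`, `start`,
#'   `length`, `orientation` (`"sense"` or `"antisense"`), `gc`, and base
#'   fraction columns `f_a`, `f_c`, `f_g`, `f_t`.
#' @param seq_length Optional named numeric vector of gene sequence lengths
#'   (names are gene ids). Genes absent from the vector default to the end
#'   of their last probe.
#' @return A data.frame of class `probe_panel`, sorted by gene then start,
#'   with a `seq_length` attribute.
#' @export
probe_panel <- function(df, seq_length = NULL) {
  require_cols(df, c("probe_id", "gene_id", "start", "length",
                     "orientation", "gc", "f_a", "f_c", "f_g", "f_t"),
               "probe table")
  df$probe_id <- as.character(df$probe_id)
  df$gene_id <- as.character(df$gene_id)
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup))
    abort("duplicate probe_id: %s", paste(unique(dup), collapse = ", "))
  if (any(df$length <= 0)) abort("probe length must be positive")
  if (any(df$start < 0)) abort("probe start must be non-negative")
  if (!all(df$orientation %in% c("sense", "antisense")))
    abort("orientation must be 'sense' or 'antisense'")
  if (any(df$gc < 0 | df$gc > 1)) abort("gc must lie in [0, 1]")
  fsum <- df$f_a + df$f_c + df$f_g + df$f_t
  if (any(abs(fsum - 1) > 1e-9))
    abort("base fractions must sum to 1 (max deviation %.3g)",
          max(abs(fsum - 1)))
  if (any(abs(df$gc - (df$f_g + df$f_c)) > 1e-9))
    abort("gc must equal f_g + f_c")

  df <- df[order(df$gene_id, df$start), , drop = FALSE]
  rownames(df) <- NULL

  if (nrow(df) == 0) {
    sl <- stats::setNames(numeric(0), character(0))
  } else {
    ends <- tapply(df$start + df$length, df$gene_id, max)
    sl <- as.numeric(ends)
    names(sl) <- names(ends)
  }
  if (!is.null(seq_length)) {
    seq_length <- seq_length[names(seq_length) %in% names(sl)]
    bad <- names(seq_length)[seq_length[names(seq_length)] <
                               sl[names(seq_length)]]
    if (length(bad)) {
      first <- bad[1L]
      over <- df$probe_id[df$gene_id == first &
                            df$start + df$length > seq_length[first]][1L]
      abort("probe %s extends beyond seq_length of gene %s", over, first)
    }
    sl[names(seq_length)] <- seq_length
  }
  structure(df, class = c("probe_panel", "data.frame"), seq_length = sl)
}

#' Gene-level view of a probe panel
#'
#' Summarizes a panel per gene: probe count, sequence length and covered
#' length (distance from the start of the first probe to the end of the
#' last probe).
#'
#' @param panel A [probe_panel()].
#' @return A data.frame with columns `gene_id`, `seq_length`, `n_probes`,
#'   `covered_length`.
#' @export
gene_targets <- function(panel) {
  stopifnot(inherits(panel, "probe_panel"))
  sl <- attr(panel, "seq_length")
  first <- tapply(panel$start, panel$gene_id, min)
  last <- tapply(panel$start + panel$length, panel$gene_id, max)
  n <- tapply(panel$start, panel$gene_id, length)
  g <- names(first)
  data.frame(gene_id = g,
             seq_length = as.numeric(sl[g]),
             n_probes = as.integer(n[g]),
             covered_length = as.numeric(last[g] - first[g]),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Mononucleotide fractions of an ACGT sequence vector.
base_fractions <- function(sequence) {
  s <- toupper(sequence)
  n <- nchar(s)
  if (any(n == 0)) abort("empty probe sequence")
  count <- function(ch) n - nchar(gsub(ch, "", s, fixed = TRUE))
  fa <- count("A"); fc <- count("C"); fg <- count("G"); ft <- count("T")
  if (any(fa + fc + fg + ft != n))
    abort("probe sequences may only contain A, C, G, T")
  data.frame(f_a = fa / n, f_c = fc / n, f_g = fg / n, f_t = ft / n)
}

#' Read a probe panel from a tab-separated file
#'
#' Expected columns: `probe_id`, `gene_id`, `start`, `length`,
#' `orientation`, and either a `sequence` column (GC and base fractions are
#' computed from it) or a `gc` column (base fractions default to a
#' symmetric split unless `f_a`/`f_c`/`f_g`/`f_t` columns are present).
#' An optional `seq_length` column gives the gene sequence length.
#' Lines starting with `#` are comments.
#'
#' @param path Path to a TSV file.
#' @return A [probe_panel()].
#' @export
read_probes <- function(path) {
  df <- read_tsv(path)
  require_cols(df, c("probe_id", "gene_id", "start", "orientation"),
               "probes file")
  if ("sequence" %in% names(df)) {
    bf <- base_fractions(df$sequence)
    df$gc <- bf$f_c + bf$f_g
    if (!"length" %in% names(df)) df$length <- nchar(df$sequence)
    df <- cbind(df[setdiff(names(df), c("sequence", "f_a", "f_c", "f_g", "f_t"))], bf)
  } else if ("gc" %in% names(df)) {
    if (!all(c("f_a", "f_c", "f_g", "f_t") %in% names(df))) {
      df$f_c <- df$gc / 2
      df$f_g <- df$gc / 2
      df$f_a <- (1 - df$gc) / 2
      df$f_t <- (1 - df$gc) / 2
    }
  } else {
    abort("probes file needs a 'sequence' or 'gc' column")
  }
  require_cols(df, "length", "probes file")
  sl <- NULL
  if ("seq_length" %in% names(df)) {
    sl <- tapply(df$seq_length, df$gene_id, max)
    v <- as.numeric(sl); names(v) <- names(sl); sl <- v
    df$seq_length <- NULL
  }
  probe_panel(df, seq_length = sl)
}

#' Write a probe panel to a tab-separated file
#'
#' Emits the panel columns plus a `seq_length` column so that
#' [read_probes()] round-trips losslessly.
#'
#' @param panel A [probe_panel()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_probes <- function(panel, path) {
  stopifnot(inherits(panel, "probe_panel"))
  sl <- attr(panel, "seq_length")
  out <- as.data.frame(panel)
  out$seq_length <- as.numeric(sl[out$gene_id])
  write_tsv(out, path)
}
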