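#' Probe quality filter from pilot hybridizations
#'
#' Keeps a probe when its raw intensity is at least `ratio` times its
#' background intensity in at least `min_pass` of the pilot datasets
#' (the original design used 10 datasets: 5 hybridizations x 2 channels).
#' The boundary is inclusive: raw exactly twice background passes.
#'
#' @param raw,background Numeric matrices (probes x datasets) with probe
#'   ids as rownames and matching dimensions.
#' @param min_pass Minimum number of passing datasets (default 6).
#' @param n_datasets Expected dataset count (default 10); a different
#'   column count triggers a warning and the rule generalizes to
#'   `min_pass` of `ncol(raw)`.
#' @param ratio Raw/background ratio required (default 2).
#' @return Character vector of kept probe ids.
#' @export
filter_probe_quality <- function(raw, background, min_pass = 6,
                                 n_datasets = 10, ratio = 2) {
  if (!identical(dim(raw), dim(background)))
    abort("raw and background matrices must have identical dimensions")
  if (is.null(rownames(raw))) abort("raw matrix needs probe ids as rownames")
  if (ncol(raw) != n_datasets)
    warn("expected %d datasets but found %d; applying the %d-of-%d rule",
         n_datasets, ncol(raw), min_pass, ncol(raw))
  passes <- rowSums(raw >= ratio * background)
  rownames(raw)[passes >= min_pass]
}

#' Remove the weaker member of sense/antisense probe pairs
#'
#' Probes of opposite orientation targeting the same position (same gene
#' and start) are redundant; the one with the lower mean intensity across
#' the pilot datasets is removed. Ties keep the sense probe. Unpaired
#' probes pass through unchanged.
#'
#' @param panel A [probe_panel()].
#' @param mean_intensity Named numeric vector of per-probe mean intensity
#'   across the pilot datasets.
#' @return The deduplicated [probe_panel()].
#' @export
dedup_orientation <- function(panel, mean_intensity) {
  stopifnot(inherits(panel, "probe_panel"))
  if (is.null(names(mean_intensity)))
    abort("mean_intensity must be named by probe_id")
  key <- paste(panel$gene_id, panel$start, sep = "\r")
  drop <- character(0)
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    sub <- panel[idx, ]
    if (length(unique(sub$orientation)) < 2L) next
    mi <- mean_intensity[sub$probe_id]
    if (anyNA(mi)) abort("mean_intensity missing for probe(s): %s",
                         paste(sub$probe_id[is.na(mi)], collapse = ", "))
    lo <- which(mi == min(mi))
    victim <- if (length(lo) > 1L)
      sub$probe_id[sub$orientation == "antisense"][1L]
    else sub$probe_id[lo]
    drop <- c(drop, victim)
  }
  subset_panel(panel, !(panel$probe_id %in% drop))
}

# Subset a panel while preserving class and seq_length attribute.
subset_panel <- function(panel, keep) {
  sl <- attr(panel, "seq_length")
  df <- as.data.frame(panel)[keep, , drop = FALSE]
  rownames(df) <- NULL
  probe_panel(df, seq_length = sl[names(sl) %in% df$gene_id])
}

#' Gene eligibility for the final array design
#'
#' A gene stays on the design when it retains at least `min_probes`
#' quality probes and its covered length (start of first probe to end of
#' last probe) is strictly greater than `min_covered` bp.
#'
#' @param panel A [probe_panel()] (already quality-filtered).
#' @param min_probes Minimum probe count (default 6).
#' @param min_covered Covered length that must be exceeded (default 500).
#' @return data.frame with columns `gene_id`, `n_probes`,
#'   `covered_length`, `eligible`.
#' @export
gene_eligibility <- function(panel, min_probes = 6, min_covered = 500) {
  gt <- gene_targets(panel)
  gt$eligible <- gt$n_probes >= min_probes & gt$covered_length > min_covered
  gt[c("gene_id", "n_probes", "covered_length", "eligible")]
}

#' Drop ineligible genes from a panel
#'
#' @inheritParams gene_eligibility
#' @return The filtered [probe_panel()].
#' @export
filter_gene_eligibility <- function(panel, min_probes = 6,
                                    min_covered = 500) {
  el <- gene_eligibility(panel, min_probes, min_covered)
  keep_genes <- el$gene_id[el$eligible]
  subset_panel(panel, panel$gene_id %in% keep_genes)
}

#' Thin probes to a minimum spacing
#'
#' Greedy left-to-right thinning: within each gene a probe is kept when
#' its start is at least `s` bp beyond the last kept start, where `s` is
#' `spacing_large` (200 bp) for genes entering with `count_switch` (16) or
#' more probes and `spacing_small` (100 bp) otherwise. The spacing
#' decision uses the probe count before thinning, and the leftmost probe
#' is always kept.
#'
#' @param panel A [probe_panel()].
#' @param spacing_large,spacing_small Minimum spacings in bp.
#' @param count_switch Probe count at or above which the large spacing
#'   applies.
#' @return The thinned [probe_panel()].
#' @export
enforce_spacing <- function(panel, spacing_large = 200,
                            spacing_small = 100, count_switch = 16) {
  stopifnot(inherits(panel, "probe_panel"))
  if (nrow(panel) == 0) return(panel)
  keep <- logical(nrow(panel))
  for (idx in split(seq_len(nrow(panel)), panel$gene_id)) {
    s <- if (length(idx) >= count_switch) spacing_large else spacing_small
    starts <- panel$start[idx]
    last <- -Inf
    for (j in seq_along(idx)) {
      if (starts[j] >= last + s) {
        keep[idx[j]] <- TRUE
        last <- starts[j]
      }
    }
  }
  subset_panel(panel, keep)
}

#' Full design-time probe selection chain
#'
#' Applies, in order: probe quality filtering (k-of-n raw >= 2x
#' background), sense/antisense deduplication, gene eligibility (probe
#' count and covered length), and spacing enforcement.
#'
#' @param panel A [probe_panel()].
#' @param raw,background Pilot intensity matrices as in
#'   [filter_probe_quality()].
#' @param min_pass,n_datasets,ratio Quality-rule settings.
#' @param min_probes,min_covered Eligibility settings.
#' @param spacing_large,spacing_small,count_switch Spacing settings.
#' @return List with the final `panel` and a `report` of per-stage probe
#'   and gene counts.
#' @export
select_probes <- function(panel, raw, background, min_pass = 6,
                          n_datasets = 10, ratio = 2, min_probes = 6,
                          min_covered = 500, spacing_large = 200,
                          spacing_small = 100, count_switch = 16) {
  counts <- function(p) c(probes = nrow(p), genes = length(unique(p$gene_id)))
  report <- list(input = counts(panel))
  kept_ids <- filter_probe_quality(raw, background, min_pass, n_datasets, ratio)
  panel <- subset_panel(panel, panel$probe_id %in% kept_ids)
  report$quality <- counts(panel)
  panel <- dedup_orientation(panel, rowMeans(raw))
  report$dedup <- counts(panel)
  panel <- filter_gene_eligibility(panel, min_probes, min_covered)
  report$eligibility <- counts(panel)
  panel <- enforce_spacing(panel, spacing_large, spacing_small, count_switch)
  report$spacing <- counts(panel)
  list(panel = panel, report = report)
}
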