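#' Estimate the false discovery rate from self-self hybridizations
#'
#' In a self-self hybridization the two channels carry the same genome,
#' so every gene called CNV is a false positive by construction. The FDR
#' of a parameter pair is the fraction of tested genes called CNV, per
#' array, and the pooled estimate is the mean across arrays.
#'
#' @param tables List of [ratio_table()]s from self-self arrays (each
#'   must carry `self_self = TRUE`; anything else is an error).
#' @param panel A [probe_panel()].
#' @param params A [detection_params()].
#' @return List with `per_array` (data.frame `array_id`, `tested`,
#'   `called`, `fdr`) and `pooled` (mean FDR).
#' @export
estimate_fdr <- function(tables, panel, params = detection_params()) {
  flags <- vapply(tables, function(t) isTRUE(attr(t, "self_self")), logical(1))
  if (!all(flags))
    abort("non-self-self array(s) in FDR input: %s",
          paste(vapply(tables[!flags], attr, "", "array_id"), collapse = ", "))
  rows <- lapply(tables, function(t) {
    res <- call_array(t, panel, params)
    data.frame(array_id = attr(t, "array_id"),
               tested = unname(res$summary["tested"]),
               called = unname(res$summary["called"]),
               fdr = unname(res$summary["called"] / res$summary["tested"]),
               stringsAsFactors = FALSE)
  })
  per_array <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(per_array = per_array, pooled = mean(per_array$fdr))
}

#' Candidate grid for detection-parameter calibration
#'
#' Defaults cover the copy-ratio thresholds `|log2(k/4)|` for k = 3, 2, 1
#' (0.415, 1, 2) and significant-probe fractions spanning the values
#' discussed for this design (0.75 to 1.0, including both 0.83 and 0.85).
#'
#' @param tau Numeric vector of probe thresholds.
#' @param frac Numeric vector of probe fractions.
#' @return data.frame of class `calibration_grid` with one row per
#'   (tau, frac) cell.
#' @export
calibration_grid <- function(tau = abs(log2(c(3, 2, 1) / 4)),
                             frac = c(0.75, 0.83, 0.85, 0.90, 1.0)) {
  if (!length(tau) || !length(frac)) abort("grid must be non-empty")
  if (any(tau <= 0) || any(frac <= 0 | frac > 1))
    abort("grid requires tau > 0 and frac in (0, 1]")
  g <- expand.grid(tau = sort(tau), frac = sort(frac),
                   KEEP.OUT.ATTRS = FALSE)
  structure(g[order(g$tau, g$frac), ], class = c("calibration_grid",
                                                 "data.frame"))
}

#' Choose detection parameters by grid search on self-self arrays
#'
#' Evaluates the pooled FDR of every grid cell on the self-self arrays
#' and selects, among the cells with pooled FDR at or below
#' `fdr_ceiling`, the one with the smallest `tau` and then the smallest
#' `frac` — the most sensitive admissible operating point. The full grid
#' report is always returned.
#'
#' @param tables List of self-self [ratio_table()]s.
#' @param panel A [probe_panel()].
#' @param grid A [calibration_grid()].
#' @param fdr_ceiling Admissibility ceiling on the pooled FDR (default
#'   0.01).
#' @param pav_tau,min_probes Passed through to the candidate
#'   [detection_params()].
#' @return List with `params` (chosen [detection_params()]) and `grid`
#'   (report data.frame with pooled FDR and call counts per cell). When
#'   no cell is admissible the function throws an error naming the best
#'   cell.
#' @export
grid_search <- function(tables, panel, grid = calibration_grid(),
                        fdr_ceiling = 0.01, pav_tau = 3.0, min_probes = 6L) {
  stopifnot(inherits(grid, "calibration_grid"))
  report <- grid
  report$pooled_fdr <- NA_real_
  report$total_calls <- NA_integer_
  for (i in seq_len(nrow(report))) {
    p <- detection_params(tau = report$tau[i], frac = report$frac[i],
                          pav_tau = max(pav_tau, report$tau[i] + 1e-6),
                          min_probes = min_probes)
    est <- estimate_fdr(tables, panel, p)
    report$pooled_fdr[i] <- est$pooled
    report$total_calls[i] <- sum(est$per_array$called)
  }
  admissible <- report$pooled_fdr <= fdr_ceiling
  if (!any(admissible)) {
    best <- report[which.min(report$pooled_fdr), ]
    abort(paste0("no grid cell meets the FDR ceiling %.4g; best cell is ",
                 "tau=%.4f frac=%.2f with pooled FDR %.4g"),
          fdr_ceiling, best$tau, best$frac, best$pooled_fdr)
  }
  adm <- report[admissible, ]
  pick <- adm[order(adm$tau, adm$frac), ][1L, ]
  list(params = detection_params(tau = pick$tau, frac = pick$frac,
                                 pav_tau = max(pav_tau, pick$tau + 1e-6),
                                 min_probes = min_probes),
       grid = report)
}
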