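#' Compute per-probe M and A from a two-channel experiment
#'
#' With background-subtracted channel intensities I1 (test) and I2
#' (reference), `M = log2(I1/I2)` and `A = log2(sqrt(I1 * I2))`. Probes
#' with a non-positive background-subtracted intensity in either channel
#' are dropped (their count is recorded in the `n_dropped` attribute and
#' reported with a message) because M is undefined for them. For
#' dye-swapped arrays the sign of M is flipped so that M always follows
#' the test-over-reference convention.
#'
#' @param experiment An [array_experiment()].
#' @return A [ratio_table()] at stage `"raw"`.
#' @export
compute_ma <- function(experiment) {
  stopifnot(inherits(experiment, "array_experiment"))
  meas <- experiment$measurements
  i1 <- meas$i_test_raw - meas$i_test_bg
  i2 <- meas$i_ref_raw - meas$i_ref_bg
  ok <- i1 > 0 & i2 > 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(sprintf("array %s: dropped %d probe(s) with non-positive %s",
                    experiment$array_id, n_dropped,
                    "background-subtracted intensity"))
  m <- log2(i1[ok] / i2[ok])
  if (experiment$dye_swap) m <- -m
  a <- 0.5 * log2(i1[ok] * i2[ok])
  ratio_table(experiment$array_id,
              data.frame(probe_id = meas$probe_id[ok], m = m, a = a),
              stage = "raw", self_self = experiment$self_self,
              n_dropped = n_dropped)
}

# Robust locally weighted fit of y on x, evaluated at x.
lowess_fit <- function(x, y, span, iters) {
  fit <- stats::lowess(x, y, f = span, iter = iters)
  stats::approx(fit$x, fit$y, xout = x, rule = 2, ties = "ordered")$y
}

#' Dye-bias (intensity-dependent) LOESS normalization
#'
#' Fits a robust locally weighted regression of M on A per array and
#' subtracts the fit: the classic MA-plot normalization that removes the
#' intensity-dependent dye bias of two-color arrays.
#'
#' @param table A [ratio_table()] at stage `"raw"`.
#' @param span LOESS span (fraction of points in each local window), in
#'   (0, 1].
#' @param robust_iters Number of robustifying iterations.
#' @return A [ratio_table()] at stage `"loess"`.
#' @export
loess_dye_correct <- function(table, span = 0.3, robust_iters = 3) {
  stopifnot(inherits(table, "ratio_table"))
  if (!is_number(span) || span <= 0 || span > 1)
    abort("span must lie in (0, 1]")
  if (ratio_stage(table) != "raw")
    abort("loess_dye_correct expects a 'raw' table, got '%s'",
          ratio_stage(table))
  if (nrow(table) < 100)
    abort("LOESS normalization needs at least 100 probes (got %d)",
          nrow(table))
  fit <- lowess_fit(table$a, table$m, span, robust_iters)
  advance_stage(table, table$m - fit, "loess")
}

#' GC-wave correction
#'
#' Removes the "genome wave": a locally weighted regression of M on probe
#' GC fraction is fitted per array and subtracted. With
#' `level = "gene"` the covariate is the mean GC of the probes of each
#' gene (the contig-level variant); the default corrects at probe level.
#' Degenerate input (constant GC) is skipped with a warning.
#'
#' @param table A [ratio_table()] at stage `"loess"`.
#' @param panel A [probe_panel()] supplying GC per probe.
#' @param level `"probe"` or `"gene"`.
#' @param span,robust_iters Smoother settings.
#' @return A [ratio_table()] at stage `"gc"`.
#' @export
gc_correct <- function(table, panel, level = c("probe", "gene"),
                       span = 0.4, robust_iters = 3) {
  stopifnot(inherits(table, "ratio_table"), inherits(panel, "probe_panel"))
  level <- match.arg(level)
  if (ratio_stage(table) != "loess")
    abort("gc_correct expects a 'loess' table, got '%s'", ratio_stage(table))
  idx <- match(table$probe_id, panel$probe_id)
  if (anyNA(idx)) abort("ratio table contains probes absent from the panel")
  gc <- panel$gc[idx]
  if (level == "gene") {
    gene <- panel$gene_id[idx]
    gc <- stats::ave(gc, gene)
  }
  if (stats::sd(gc) < 1e-12) {
    warn("GC is constant; skipping GC correction")
    return(advance_stage(table, table$m, "gc"))
  }
  fit <- lowess_fit(gc, table$m, span, robust_iters)
  advance_stage(table, table$m - fit, "gc")
}

#' Probe-composition correction
#'
#' Regresses M on the probe mononucleotide fractions (fA, fC, fG; fT is
#' the complement and would be collinear) by least squares per array and
#' keeps the residuals. Redundant (aliased) covariates are dropped with a
#' warning. The fitted coefficients are attached as the `coefficients`
#' attribute of the result.
#'
#' @param table A [ratio_table()] at stage `"gc"`.
#' @param panel A [probe_panel()] supplying base fractions.
#' @return A [ratio_table()] at stage `"composition"`.
#' @export
composition_correct <- function(table, panel) {
  stopifnot(inherits(table, "ratio_table"), inherits(panel, "probe_panel"))
  if (ratio_stage(table) != "gc")
    abort("composition_correct expects a 'gc' table, got '%s'",
          ratio_stage(table))
  idx <- match(table$probe_id, panel$probe_id)
  if (anyNA(idx)) abort("ratio table contains probes absent from the panel")
  dat <- data.frame(m = table$m, f_a = panel$f_a[idx],
                    f_c = panel$f_c[idx], f_g = panel$f_g[idx])
  fit <- stats::lm(m ~ f_a + f_c + f_g, data = dat)
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased))
    warn("dropping collinear composition covariate(s): %s",
         paste(aliased, collapse = ", "))
  out <- advance_stage(table, stats::residuals(fit), "composition")
  attr(out, "coefficients") <- stats::coef(fit)
  out
}

#' Full normalization pipeline for one array
#'
#' Runs raw M/A computation, LOESS dye correction, GC-wave correction and
#' probe-composition correction in that fixed order.
#'
#' @param experiment An [array_experiment()].
#' @param panel A [probe_panel()].
#' @param span LOESS span for the dye correction.
#' @param gc_level GC correction level (`"probe"` or `"gene"`).
#' @return A [ratio_table()] at stage `"composition"`.
#' @export
normalize_array <- function(experiment, panel, span = 0.3,
                            gc_level = "probe") {
  tab <- compute_ma(experiment)
  tab <- loess_dye_correct(tab, span = span)
  tab <- gc_correct(tab, panel, level = gc_level)
  composition_correct(tab, panel)
}
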