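#' Detection parameters for probe thresholding and gene-level voting
#'
#' Bundles the four tunables of the CNV caller: the probe-level absolute
#' log2-ratio threshold `tau`, the minimum fraction `frac` of
#' consistent-sign significant probes required to call a gene, the
#' presence/absence (PAV) threshold `pav_tau` on the absolute gene median
#' log2 ratio, and the minimum probe count `min_probes` below which a gene
#' is not testable.
#'
#' The default `tau` is the exact value `abs(log2(4/3))` (~0.41504), the
#' ratio expected for a 3-vs-4 copy difference; published work typically
#' prints it rounded to 0.42. The default `frac` of 0.83 corresponds to
#' 5 of 6 probes on the smallest callable genes.
#'
#' @param tau Positive probe-level threshold on |M|; a probe is significant
#'   only when |M| exceeds `tau` strictly.
#' @param frac Minimum fraction of same-sign significant probes per gene,
#'   in (0, 1]. The required count is `ceiling(frac * n_probes)`.
#' @param pav_tau Threshold on |median M| above which a called gene is
#'   flagged as presence/absence variation; must exceed `tau`.
#' @param min_probes Minimum number of probes for a gene to be testable.
#' @return An object of class `detection_params`.
#' @examples
#' detection_params()
#' detection_params(tau = 0.42, frac = 0.85)
#' @export
detection_params <- function(tau = abs(log2(4 / 3)), frac = 0.83,
                             pav_tau = 3.0, min_probes = 6L) {
  if (!is_number(tau) || tau <= 0) abort("tau must be a positive number")
  if (!is_number(frac) || frac <= 0 || frac > 1)
    abort("frac must lie in (0, 1]")
  if (!is_number(pav_tau) || pav_tau <= tau)
    abort("pav_tau must exceed tau")
  if (!is_number(min_probes) || min_probes < 1)
    abort("min_probes must be at least 1")
  structure(list(tau = tau, frac = frac, pav_tau = pav_tau,
                 min_probes = as.integer(min_probes)),
            class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat(sprintf(
    "CNV detection parameters: tau=%.5f frac=%.3f pav_tau=%.2f min_probes=%d\n",
    x$tau, x$frac, x$pav_tau, x$min_probes))
  invisible(x)
}
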