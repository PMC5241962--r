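#' Probe-level significance
#'
#' A probe is a gain when its corrected log2 ratio strictly exceeds `tau`,
#' a loss when it is strictly below `-tau`, and `none` otherwise (the
#' threshold itself does not pass: the criterion is "superior to" tau).
#'
#' @param m Numeric vector of corrected log2 ratios.
#' @param tau Positive threshold.
#' @return Character vector in `{"gain", "loss", "none"}`.
#' @export
probe_significant <- function(m, tau) {
  if (any(!is.finite(m))) abort("probe log ratios must be finite")
  out <- rep("none", length(m))
  out[m > tau] <- "gain"
  out[m < -tau] <- "loss"
  out
}

#' Minimum significant-probe count for a gene
#'
#' The voting rule requires at least a fraction `frac` of the probes, i.e.
#' `ceiling(frac * n_probes)` probes (a small epsilon guards against
#' floating-point representation of products like 0.83 * 100).
#'
#' @param n_probes Probe count (>= 1).
#' @param frac Required fraction in (0, 1].
#' @return Integer count.
#' @export
min_significant <- function(n_probes, frac) {
  if (any(n_probes < 1)) abort("n_probes must be at least 1")
  as.integer(ceiling(frac * n_probes - 1e-9))
}

#' Call one gene on one array
#'
#' Counts gains `g` and losses `l` among the gene's probes; the majority
#' sign wins (ties go to gain, which cannot produce a call unless the
#' count passes the quorum anyway). The gene is a CNV when the
#' majority-sign count reaches `ceiling(frac * n)`; only consistent-sign
#' probes count toward the quorum, so a gene split between gains and
#' losses is not called. The gene summary ratio is the median probe M;
#' called genes whose |median M| strictly exceeds `pav_tau` are flagged as
#' presence/absence variants.
#'
#' @param probe_ms Numeric vector of corrected log2 ratios for the gene.
#' @param params A [detection_params()].
#' @param array_id,gene_id Identifiers recorded in the call.
#' @return One-row data.frame with the gene-call fields.
#' @export
call_gene <- function(probe_ms, params, array_id = "array",
                      gene_id = "gene") {
  stopifnot(inherits(params, "detection_params"))
  n <- length(probe_ms)
  if (n < params$min_probes)
    abort("gene %s has %d probes, fewer than min_probes = %d: untested",
          gene_id, n, params$min_probes)
  sig <- probe_significant(probe_ms, params$tau)
  g <- sum(sig == "gain")
  l <- sum(sig == "loss")
  n_sig <- max(g, l)
  s <- if (g >= l) "gain" else "loss"
  is_cnv <- n_sig >= min_significant(n, params$frac)
  med <- stats::median(probe_ms)
  data.frame(array_id = array_id, gene_id = gene_id, n_probes = n,
             n_significant = as.integer(n_sig),
             frac_significant = n_sig / n,
             direction = if (is_cnv) s else "none",
             median_m = med, is_cnv = is_cnv,
             is_pav = is_cnv && abs(med) > params$pav_tau,
             stringsAsFactors = FALSE)
}

#' Call every testable gene of one array
#'
#' Vectorized application of the probe-voting rule to a corrected ratio
#' table. Genes with fewer than `params$min_probes` measured probes are
#' untested (absent from the calls, listed separately), not negative.
#'
#' @param table A [ratio_table()] (normally at stage `"composition"`).
#' @param panel A [probe_panel()] mapping probes to genes.
#' @param params A [detection_params()].
#' @return List with `calls` (data.frame of gene calls), `untested`
#'   (data.frame `gene_id`, `n_probes`), and `summary` (tested/called/
#'   gain/loss/PAV counts).
#' @export
call_array <- function(table, panel, params = detection_params()) {
  stopifnot(inherits(table, "ratio_table"), inherits(panel, "probe_panel"))
  idx <- match(table$probe_id, panel$probe_id)
  if (anyNA(idx)) abort("ratio table contains probes absent from the panel")
  gene <- panel$gene_id[idx]
  m <- table$m

  gf <- factor(gene)
  lev <- levels(gf)
  n <- as.integer(table(gf))
  gains <- as.integer(rowsum((m > params$tau) + 0, gf))
  losses <- as.integer(rowsum((m < -params$tau) + 0, gf))
  med <- vapply(split(m, gf), stats::median, numeric(1))

  testable <- n >= params$min_probes
  n_sig <- pmax(gains, losses)
  quorum <- min_significant(pmax(n, 1L), params$frac)
  is_cnv <- testable & (n_sig >= quorum)
  dir <- ifelse(gains >= losses, "gain", "loss")
  dir[!is_cnv] <- "none"

  calls <- data.frame(array_id = attr(table, "array_id"), gene_id = lev,
                      n_probes = n, n_significant = n_sig,
                      frac_significant = n_sig / n, direction = dir,
                      median_m = as.numeric(med), is_cnv = is_cnv,
                      is_pav = is_cnv & abs(med) > params$pav_tau,
                      stringsAsFactors = FALSE)[testable, ]
  rownames(calls) <- NULL
  untested <- data.frame(gene_id = lev[!testable],
                         n_probes = n[!testable], stringsAsFactors = FALSE)
  summary <- c(tested = sum(testable), called = sum(calls$is_cnv),
               gains = sum(calls$direction == "gain"),
               losses = sum(calls$direction == "loss"),
               pavs = sum(calls$is_pav))
  list(calls = calls, untested = untested, summary = summary)
}
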