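#' Simulation settings for synthetic aCGH experiments
#'
#' Describes the synthetic world the generator emulates: a probe panel
#' matching the array-design constraints (minimum 6 probes per gene, mean
#' 12.6, maximum 114; genes of at least ~600 bp averaging ~2.9 kb), a
#' full-sib family of `n_offspring` descendants compared against one
#' parent, and two-channel intensities in which the true copy ratio enters
#' the per-probe log2 ratio M together with an intensity-dependent dye
#' bias, a GC "genome wave" and independent Gaussian noise.
#'
#' @param n_genes Number of genes on the panel.
#' @param probe_mean,probe_min,probe_max Probe-count distribution per gene:
#'   `probe_min + Poisson(probe_mean - probe_min)`, capped at `probe_max`.
#' @param probe_len Probe length in bp.
#' @param gene_length_min,gene_length_mean Gene sequence length in bp
#'   (gamma-distributed above the minimum).
#' @param n_offspring Full sibs per family.
#' @param p_cnv Fraction of genes carrying a segregating CNV allele in one
#'   parent.
#' @param p_both Given a variant gene, probability that both parents carry
#'   the variant genotype (otherwise one parent is chosen at random).
#'   Both-parent segregation is what lets an offspring reach zero copies
#'   (presence/absence variation) when heterozygous deletions meet.
#' @param copy_states Diploid copy numbers a variant genotype can take in
#'   the carrier parent (1 = heterozygous deletion, 3 = heterozygous
#'   duplication; 0 and 4 are homozygous states).
#' @param sigma SD of the per-probe Gaussian noise on M.
#' @param dye_intercept,dye_slope Dye bias added to M as
#'   `dye_intercept + dye_slope * (A - a_mean)`.
#' @param gc_amplitude GC wave added to M as
#'   `gc_amplitude * 2 * (gc - 0.5)`.
#' @param a_mean,a_sd Baseline distribution of the average log2 intensity
#'   A, drawn Normal per probe.
#' @param pav_floor Value of the expected M when the test genome has zero
#'   copies; a floor stands in for -Inf because array fluorescence
#'   saturates the measurable range.
#' @param n_selfself Number of self-self (null) arrays to generate.
#' @param seed Integer seed; all generator draws descend from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000, probe_mean = 12.6, probe_min = 6,
                       probe_max = 114, probe_len = 60,
                       gene_length_min = 600, gene_length_mean = 2869,
                       n_offspring = 19, p_cnv = 0.05, p_both = 0.2,
                       copy_states = c(1, 3), sigma = 0.15,
                       dye_intercept = 0.2, dye_slope = 0.15,
                       gc_amplitude = 0.3, a_mean = 10, a_sd = 1,
                       pav_floor = -4, n_selfself = 0, seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes), probe_mean = probe_mean,
              probe_min = as.integer(probe_min),
              probe_max = as.integer(probe_max),
              probe_len = as.integer(probe_len),
              gene_length_min = gene_length_min,
              gene_length_mean = gene_length_mean,
              n_offspring = as.integer(n_offspring), p_cnv = p_cnv,
              p_both = p_both,
              copy_states = as.integer(copy_states), sigma = sigma,
              dye_intercept = dye_intercept, dye_slope = dye_slope,
              gc_amplitude = gc_amplitude, a_mean = a_mean, a_sd = a_sd,
              pav_floor = pav_floor, n_selfself = as.integer(n_selfself),
              seed = as.integer(seed))
  if (cfg$n_offspring < 1) abort("n_offspring must be at least 1")
  if (cfg$p_cnv < 0 || cfg$p_cnv > 1) abort("p_cnv must lie in [0, 1]")
  if (cfg$p_both < 0 || cfg$p_both > 1) abort("p_both must lie in [0, 1]")
  if (cfg$sigma <= 0) abort("sigma must be positive")
  if (cfg$probe_min < 6) abort("probe_min below the 6-probe design floor")
  if (cfg$gene_length_min < 500)
    abort("gene_length_min below the 500-bp design floor")
  if (!all(cfg$copy_states %in% 0:4) || any(cfg$copy_states == 2))
    abort("copy_states must be drawn from {0, 1, 3, 4}")
  structure(cfg, class = "sim_config")
}

#' Simulate a probe panel
#'
#' Generates `cfg$n_genes` genes whose probe counts, lengths and GC
#' composition satisfy the array-design constraints (>= 6 probes, > 500 bp
#' covered). Probes are placed evenly along the gene; GC is drawn from a
#' unimodal Beta distribution rescaled to (0.2, 0.8).
#'
#' @param cfg A [sim_config()].
#' @param seed Seed used for the draws; defaults to `cfg$seed`.
#' @return A [probe_panel()].
#' @export
simulate_panel <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  n_probes <- pmin(cfg$probe_min +
                     stats::rpois(cfg$n_genes, cfg$probe_mean - cfg$probe_min),
                   cfg$probe_max)
  extra_mean <- cfg$gene_length_mean - cfg$gene_length_min
  lens <- round(cfg$gene_length_min +
                  stats::rgamma(cfg$n_genes, shape = 2, scale = extra_mean / 2))
  gene_ids <- sprintf("g%05d", seq_len(cfg$n_genes))

  rows <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    n <- n_probes[i]
    len <- lens[i]
    if (len - cfg$probe_len + 1 < n)
      abort("gene %s of %d bp cannot host %d probes", gene_ids[i], len, n)
    starts <- as.integer(round(seq(0, len - cfg$probe_len, length.out = n)))
    for (j in seq_len(n)[-1])
      if (starts[j] <= starts[j - 1]) starts[j] <- starts[j - 1] + 1L
    gc <- 0.2 + 0.6 * stats::rbeta(n, 2, 2)
    u <- stats::runif(n, 0.35, 0.65)
    v <- stats::runif(n, 0.35, 0.65)
    rows[[i]] <- data.frame(
      probe_id = sprintf("%s_p%03d", gene_ids[i], seq_len(n)),
      gene_id = gene_ids[i], start = starts, length = cfg$probe_len,
      orientation = sample(c("sense", "antisense"), n, replace = TRUE),
      gc = gc, f_a = (1 - gc) * v, f_c = gc * u, f_g = gc * (1 - u),
      f_t = (1 - gc) * (1 - v), stringsAsFactors = FALSE)
  }
  sl <- as.numeric(lens)
  names(sl) <- gene_ids
  probe_panel(do.call(rbind, rows), seq_length = sl)
}

# Expected per-probe M for a (cn_test, cn_ref) pair, with a floor for
# zero-copy genomes.
expected_log_ratio <- function(cn_test, cn_ref, pav_floor) {
  out <- numeric(length(cn_test))
  both0 <- cn_test == 0 & cn_ref == 0
  t0 <- cn_test == 0 & cn_ref > 0
  r0 <- cn_ref == 0 & cn_test > 0
  ok <- !(both0 | t0 | r0)
  out[ok] <- log2(cn_test[ok] / cn_ref[ok])
  out[t0] <- pav_floor
  out[r0] <- -pav_floor
  out[both0] <- 0
  out
}

#' Simulate a full-sib family with Mendelian CNV inheritance
#'
#' Each gene carries, with probability `cfg$p_cnv`, a segregating CNV
#' genotype: heterozygous states 1 and 3 put one variant allele (0 or 2
#' copies) next to a normal allele, homozygous states 0 and 4 set both
#' alleles. With probability `cfg$p_both` both parents carry the variant
#' genotype (so heterozygous deletions can meet and produce a zero-copy
#' offspring); otherwise the carrier parent is chosen at random. Every
#' offspring inherits one allele from each parent uniformly at random.
#' Parent 1 is the reference genome.
#'
#' @param cfg A [sim_config()].
#' @param panel A [probe_panel()], typically from [simulate_panel()].
#' @param seed Seed; defaults to `cfg$seed + 1`.
#' @return List with `parent_alleles` (list of two 2 x n_genes matrices of
#'   per-allele copy contributions), `offspring` (character vector of
#'   individual ids), `ref_sample`, and `truth`: a data.frame
#'   (`individual`, `gene_id`, `cn_test`, `cn_ref`, `expected_m`).
#' @export
simulate_family <- function(cfg, panel, seed = cfg$seed + 1) {
  stopifnot(inherits(cfg, "sim_config"), inherits(panel, "probe_panel"))
  set.seed(seed)
  genes <- unique(panel$gene_id)
  ng <- length(genes)

  p1 <- matrix(1L, nrow = 2, ncol = ng)  # allele copy contributions
  p2 <- matrix(1L, nrow = 2, ncol = ng)
  is_var <- stats::runif(ng) < cfg$p_cnv
  for (g in which(is_var)) {
    # sample() treats a scalar as 1:n; index explicitly instead
    state <- cfg$copy_states[sample.int(length(cfg$copy_states), 1L)]
    alleles <- if (state %in% c(0L, 4L)) c(state %/% 2L, state %/% 2L)
               else c(state - 1L, 1L)
    if (stats::runif(1) < cfg$p_both) {
      p1[, g] <- alleles
      p2[, g] <- alleles
    } else if (sample(1:2, 1L) == 1L) {
      p1[, g] <- alleles
    } else {
      p2[, g] <- alleles
    }
  }
  cn_ref <- colSums(p1)

  ids <- sprintf("F1_o%02d", seq_len(cfg$n_offspring))
  truth <- vector("list", cfg$n_offspring)
  for (k in seq_len(cfg$n_offspring)) {
    a1 <- p1[cbind(sample(1:2, ng, replace = TRUE), seq_len(ng))]
    a2 <- p2[cbind(sample(1:2, ng, replace = TRUE), seq_len(ng))]
    cn <- a1 + a2
    truth[[k]] <- data.frame(
      individual = ids[k], gene_id = genes, cn_test = cn, cn_ref = cn_ref,
      expected_m = expected_log_ratio(cn, cn_ref, cfg$pav_floor),
      stringsAsFactors = FALSE)
  }
  list(parent_alleles = list(p1 = p1, p2 = p2),
       genes = genes, offspring = ids, ref_sample = "P1",
       truth = do.call(rbind, truth))
}

# One synthetic hybridization. expected_m is a named (by gene) vector.
simulate_one_array <- function(cfg, panel, expected_m, array_id,
                               test_sample, ref_sample, self_self,
                               family_id = "F1") {
  np <- nrow(panel)
  a <- stats::rnorm(np, cfg$a_mean, cfg$a_sd)
  m <- expected_m[panel$gene_id] +
    cfg$dye_intercept + cfg$dye_slope * (a - cfg$a_mean) +
    cfg$gc_amplitude * 2 * (panel$gc - 0.5) +
    stats::rnorm(np, 0, cfg$sigma)
  i_test <- 2^(a + m / 2)
  i_ref <- 2^(a - m / 2)
  bg_test <- stats::runif(np, 0.5, 1.5) * 2^(cfg$a_mean - 7)
  bg_ref <- stats::runif(np, 0.5, 1.5) * 2^(cfg$a_mean - 7)
  array_experiment(
    array_id, test_sample, ref_sample,
    data.frame(probe_id = panel$probe_id,
               i_test_raw = i_test + bg_test, i_test_bg = bg_test,
               i_ref_raw = i_ref + bg_ref, i_ref_bg = bg_ref,
               stringsAsFactors = FALSE),
    family_id = family_id, self_self = self_self, dye_swap = FALSE)
}

#' Simulate two-channel array experiments
#'
#' Builds one hybridization per offspring in `truth` (test genome vs the
#' reference parent) plus `n_selfself` self-self arrays in which the
#' expected log ratio is zero for every gene. All arrays carry the
#' configured dye bias, GC wave and Gaussian probe noise; the copy-number
#' signal enters M only, leaving A independent of copy state
#' (`I_test = 2^(A + M/2)`, `I_ref = 2^(A - M/2)`). Background values are
#' small and positive, so background subtraction recovers the generated
#' channel intensities exactly.
#'
#' @param cfg A [sim_config()].
#' @param panel A [probe_panel()].
#' @param truth Truth table from [simulate_family()], or `NULL` to
#'   generate only self-self arrays.
#' @param n_selfself Number of self-self arrays; defaults to
#'   `cfg$n_selfself`.
#' @param seed Seed; defaults to `cfg$seed + 2`.
#' @return Named list of [array_experiment()] objects.
#' @export
simulate_arrays <- function(cfg, panel, truth = NULL,
                            n_selfself = cfg$n_selfself,
                            seed = cfg$seed + 2) {
  stopifnot(inherits(cfg, "sim_config"), inherits(panel, "probe_panel"))
  set.seed(seed)
  out <- list()
  if (!is.null(truth)) {
    tt <- if (is.list(truth) && !is.data.frame(truth)) truth$truth else truth
    for (ind in unique(tt$individual)) {
      sub <- tt[tt$individual == ind, ]
      em <- stats::setNames(sub$expected_m, sub$gene_id)
      aid <- paste0("arr_", ind)
      out[[aid]] <- simulate_one_array(cfg, panel, em, aid,
                                       test_sample = ind,
                                       ref_sample = "P1", self_self = FALSE)
    }
  }
  if (n_selfself > 0) {
    genes <- unique(panel$gene_id)
    em0 <- stats::setNames(rep(0, length(genes)), genes)
    for (k in seq_len(n_selfself)) {
      aid <- sprintf("arr_self%02d", k)
      out[[aid]] <- simulate_one_array(cfg, panel, em0, aid,
                                       test_sample = "P1",
                                       ref_sample = "P1", self_self = TRUE)
    }
  }
  out
}

#' Write a truth table to TSV
#'
#' @param truth Truth data.frame (or the list returned by
#'   [simulate_family()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_truth <- function(truth, path) {
  tt <- if (is.list(truth) && !is.data.frame(truth)) truth$truth else truth
  write_tsv(tt, path)
}
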