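# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# A minimal hand-built panel: genes with evenly spaced 60-bp probes.
# starts: named list gene_id -> integer vector of probe starts.
manual_panel <- function(starts, gc = 0.5, probe_len = 60,
                         orientation = "sense", seq_length = NULL) {
  rows <- lapply(names(starts), function(g) {
    s <- starts[[g]]
    data.frame(probe_id = sprintf("%s_p%02d", g, seq_along(s)),
               gene_id = g, start = s, length = probe_len,
               orientation = orientation, gc = gc,
               f_a = (1 - gc) / 2, f_c = gc / 2, f_g = gc / 2,
               f_t = (1 - gc) / 2, stringsAsFactors = FALSE)
  })
  probe_panel(do.call(rbind, rows), seq_length = seq_length)
}

# Ratio table with given per-probe M for a panel (A constant), at an
# arbitrary stage; self_self flag controls FDR-input eligibility.
manual_table <- function(panel, m, stage = "composition",
                         array_id = "arr1", self_self = FALSE, a = 10) {
  ratio_table(array_id,
              data.frame(probe_id = panel$probe_id, m = m,
                         a = rep_len(a, nrow(panel))),
              stage = stage, self_self = self_self)
}

# Null (self-self) corrected table: Gaussian M around 0.
null_table <- function(panel, sigma, seed, array_id = "null1") {
  set.seed(seed)
  manual_table(panel, stats::rnorm(nrow(panel), 0, sigma),
               array_id = array_id, self_self = TRUE)
}

# A routine mid-size simulated panel for property tests.
small_sim_panel <- function(n_genes = 120, seed = 42) {
  simulate_panel(sim_config(n_genes = n_genes, seed = seed))
}

# Plain TSV reader independent of the package's own IO layer.
read_tsv_for_test <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

# One-row gene call record for IO tests.
make_call <- function(array_id = "a1", gene_id = "g1", n_probes = 12L,
                      n_significant = 11L, direction = "gain",
                      median_m = 0.6, is_cnv = TRUE, is_pav = FALSE) {
  data.frame(array_id = array_id, gene_id = gene_id, n_probes = n_probes,
             n_significant = n_significant,
             frac_significant = n_significant / n_probes,
             direction = direction, median_m = median_m, is_cnv = is_cnv,
             is_pav = is_pav, stringsAsFactors = FALSE)
}
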