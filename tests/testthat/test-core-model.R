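# Domain types, invariants and tabular readers/writers.

test_that("read_probes groups, sorts and computes geometry", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# design fixture",
               "probe_id\tgene_id\tstart\tlength\torientation\tgc",
               "p2\tgA\t200\t60\tsense\t0.5",
               "p1\tgA\t0\t60\tsense\t0.4",
               "p3\tgA\t400\t60\tantisense\t0.6"), f)
  panel <- read_probes(f)
  expect_s3_class(panel, "probe_panel")
  expect_equal(panel$probe_id, c("p1", "p2", "p3"))  # sorted by start
  gt <- gene_targets(panel)
  expect_equal(nrow(gt), 1L)
  expect_equal(gt$covered_length, 460)
  expect_equal(gt$n_probes, 3L)
})

test_that("read_probes rejects duplicate probe ids by name", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\tgene_id\tstart\tlength\torientation\tgc",
               "pX\tgA\t0\t60\tsense\t0.5",
               "pX\tgA\t100\t60\tsense\t0.5"), f)
  expect_error(read_probes(f), "pX")
})

test_that("GC and base fractions are computed from sequences", {
  f <- withr::local_tempfile(fileext = ".tsv")
  seq60 <- paste0(strrep("AT", 15), strrep("GC", 15))  # 30 G/C of 60
  writeLines(c("probe_id\tgene_id\tstart\torientation\tsequence",
               paste("p1", "gA", 0, "sense", seq60, sep = "\t")), f)
  panel <- read_probes(f)
  expect_equal(panel$gc, 0.5)
  expect_equal(panel$length, 60L)
  expect_equal(panel$f_a + panel$f_c + panel$f_g + panel$f_t, 1)
})

test_that("a probe beyond seq_length is a hard error naming the probe", {
  df <- data.frame(probe_id = "pFar", gene_id = "gA", start = 500,
                   length = 60, orientation = "sense", gc = 0.5,
                   f_a = 0.25, f_c = 0.25, f_g = 0.25, f_t = 0.25)
  expect_error(probe_panel(df, seq_length = c(gA = 520)), "pFar")
})

test_that("probe panel invariants are rejected at construction", {
  base <- data.frame(probe_id = "p1", gene_id = "gA", start = 0,
                     length = 60, orientation = "sense", gc = 0.5,
                     f_a = 0.25, f_c = 0.25, f_g = 0.25, f_t = 0.25)
  bad_gc <- transform(base, gc = 1.2)
  expect_error(probe_panel(bad_gc), "gc")
  bad_sum <- transform(base, f_a = 0.4)
  expect_error(probe_panel(bad_sum), "sum to 1")
  bad_match <- transform(base, gc = 0.6)
  expect_error(probe_panel(bad_match), "f_g")
  bad_len <- transform(base, length = 0)
  expect_error(probe_panel(bad_len), "length")
})

test_that("probe tables round-trip through write/read", {
  panel <- small_sim_panel(30)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_probes(panel, f)
  back <- read_probes(f)
  expect_equal(as.data.frame(back), as.data.frame(panel),
               tolerance = 1e-12)
  expect_equal(attr(back, "seq_length"), attr(panel, "seq_length"))
})

test_that("read_arrays builds one experiment per metadata row", {
  panel <- manual_panel(list(gA = seq(0, 550, by = 50)))  # 12 probes
  cfg <- sim_config(n_genes = 5, seed = 1)
  fi <- withr::local_tempfile(fileext = ".tsv")
  fm <- withr::local_tempfile(fileext = ".tsv")
  meas <- data.frame(probe_id = panel$probe_id, i_test_raw = 100,
                     i_test_bg = 5, i_ref_raw = 90, i_ref_bg = 5)
  exps <- list(array_experiment("a1", "kid1", "mom", meas, family_id = "F1"),
               array_experiment("a2", "kid2", "mom", meas, family_id = "F1"))
  write_arrays(exps, fi, fm)
  back <- read_arrays(fi, fm, panel)
  expect_length(back, 2L)
  expect_equal(nrow(back$a1$measurements), 12L)
  expect_equal(back$a2$test_sample, "kid2")
  expect_false(back$a1$self_self)
})

test_that("array invariant violations are errors", {
  meas <- data.frame(probe_id = "p1", i_test_raw = 10, i_test_bg = 1,
                     i_ref_raw = 10, i_ref_bg = 1)
  expect_error(array_experiment("a1", "s1", "s2", meas, self_self = TRUE),
               "self-self")
  neg <- transform(meas, i_ref_raw = -1)
  expect_error(array_experiment("a1", "s1", "s2", neg), "negative")
})

test_that("read_arrays cross-checks intensities against metadata", {
  fi <- withr::local_tempfile(fileext = ".tsv")
  fm <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("array_id\tprobe_id\ti_test_raw\ti_test_bg\ti_ref_raw\ti_ref_bg",
               "a1\tp1\t10\t1\t10\t1"), fi)
  writeLines(c("array_id\ttest_sample\tref_sample\tfamily_id\tself_self\tdye_swap",
               "a1\ts1\ts2\tF1\tfalse\tfalse",
               "a2\ts3\ts2\tF1\tfalse\tfalse"), fm)
  expect_error(read_arrays(fi, fm), "a2")

  writeLines(c("array_id\ttest_sample\tref_sample\tfamily_id\tself_self\tdye_swap",
               "a1\ts1\ts2\tF1\tfalse\tfalse"), fm)
  writeLines(c("array_id\tprobe_id\ti_test_raw\ti_test_bg\ti_ref_raw\ti_ref_bg",
               "a1\tp1\t10\t1\t10\t1",
               "aX\tp1\t10\t1\t10\t1"), fi)
  expect_error(read_arrays(fi, fm), "aX")
})

test_that("gene calls round-trip and invariants are enforced", {
  calls <- do.call(rbind, lapply(1:5, function(i)
    make_call(gene_id = paste0("g", i), median_m = i / 10,
              direction = c("gain", "loss")[1 + i %% 2])))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_calls(calls, f)
  expect_equal(read_calls(f), calls, tolerance = 1e-12)

  write_calls(empty_calls <- calls[0, ], f)
  expect_equal(nrow(read_calls(f)), 0L)

  bad <- make_call(is_cnv = FALSE, is_pav = TRUE, direction = "none")
  expect_error(write_calls(bad, f), "is_pav")
  bad2 <- make_call(is_cnv = FALSE, direction = "gain")
  expect_error(write_calls(bad2, f), "direction")
})

test_that("ratio tables validate and round-trip", {
  panel <- manual_panel(list(gA = c(0, 200, 400)))
  expect_error(manual_table(panel, c(0, Inf, 1)), "finite")
  tabs <- list(manual_table(panel, c(0.1, -0.2, 0.3), array_id = "r1"),
               manual_table(panel, c(0, 0, 0), array_id = "r2",
                            self_self = TRUE))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ratio_tables(tabs, f)
  back <- read_ratio_tables(f)
  expect_equal(back$r1$m, tabs[[1]]$m)
  expect_equal(attr(back$r2, "self_self"), TRUE)
  expect_equal(attr(back$r1, "stage"), "composition")
})

test_that("genetic map invariants hold", {
  expect_error(genetic_map(data.frame(gene_id = c("g1", "g1"),
                                      linkage_group = "LG1",
                                      position = c(1, 2))), "multiple")
  expect_error(genetic_map(data.frame(gene_id = "g1",
                                      linkage_group = "LG1",
                                      position = -1)), "non-negative")
})

test_that("flat config files round-trip", {
  cfg <- list(tau = abs(log2(4 / 3)), frac = 0.83, label = "selfself",
              strict = TRUE)
  f <- withr::local_tempfile(fileext = ".toml")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(back$tau, cfg$tau)
  expect_identical(back$label, "selfself")
  expect_identical(back$strict, TRUE)
})
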