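# M/A computation and the three per-array corrections.

# panel with one probe per "gene" so probe-level covariates are free
big_manual_panel <- function(n, gc = NULL) {
  if (is.null(gc)) gc <- rep(0.5, n)
  df <- data.frame(probe_id = sprintf("p%04d", seq_len(n)),
                   gene_id = sprintf("g%04d", seq_len(n)),
                   start = 0, length = 60, orientation = "sense",
                   gc = gc, f_a = (1 - gc) / 2, f_c = gc / 2,
                   f_g = gc / 2, f_t = (1 - gc) / 2)
  probe_panel(df)
}

test_that("M and A follow their closed forms", {
  meas <- data.frame(probe_id = c("p1", "p2"),
                     i_test_raw = c(100, 400), i_test_bg = 0,
                     i_ref_raw = c(100, 100), i_ref_bg = 0)
  tab <- compute_ma(array_experiment("a1", "t", "r", meas))
  expect_equal(tab$m, c(0, 2))
  expect_equal(tab$a, c(log2(100), log2(200)))

  swapped <- data.frame(probe_id = c("p1", "p2"),
                        i_test_raw = c(100, 100), i_test_bg = 0,
                        i_ref_raw = c(100, 400), i_ref_bg = 0)
  tab2 <- compute_ma(array_experiment("a2", "t", "r", swapped))
  expect_equal(tab2$m, -tab$m)
  expect_equal(tab2$a, tab$a)
})

test_that("dye-swapped arrays are sign-flipped to the test/ref convention", {
  meas <- data.frame(probe_id = "p1", i_test_raw = 400, i_test_bg = 0,
                     i_ref_raw = 100, i_ref_bg = 0)
  plain <- compute_ma(array_experiment("a1", "t", "r", meas))
  flip <- compute_ma(array_experiment("a2", "t", "r", meas,
                                      dye_swap = TRUE))
  expect_equal(flip$m, -plain$m)
  expect_equal(flip$a, plain$a)
})

test_that("probes with non-positive subtracted intensity are dropped", {
  meas <- data.frame(probe_id = c("ok", "dead"),
                     i_test_raw = c(100, 5), i_test_bg = c(1, 10),
                     i_ref_raw = c(100, 100), i_ref_bg = 1)
  expect_message(tab <- compute_ma(array_experiment("a1", "t", "r", meas)),
                 "dropped 1")
  expect_equal(tab$probe_id, "ok")
  expect_equal(attr(tab, "n_dropped"), 1L)
})

test_that("LOESS removes linear trends and offsets, leaves noise alone", {
  n <- 500
  a <- seq(6, 14, length.out = n)
  lin <- ratio_table("lin", data.frame(probe_id = sprintf("p%03d", 1:n),
                                       m = 0.1 * (a - 10), a = a))
  out <- loess_dye_correct(lin)
  expect_lt(max(abs(out$m)), 0.02)
  expect_identical(attr(out, "stage"), "loess")

  off <- ratio_table("off", data.frame(probe_id = sprintf("p%03d", 1:n),
                                       m = rep(0.3, n), a = a))
  expect_lt(max(abs(loess_dye_correct(off)$m)), 1e-6)

  set.seed(21)
  noise <- rnorm(2000, 0, 0.1)
  wn <- ratio_table("wn", data.frame(probe_id = sprintf("q%04d", 1:2000),
                                     m = noise,
                                     a = runif(2000, 6, 14)))
  out2 <- loess_dye_correct(wn)
  expect_lt(mean(abs(out2$m - wn$m)), 0.1 / 5)
})

test_that("LOESS correction matches the limma oracle", {
  set.seed(22)
  n <- 1000
  a <- runif(n, 6, 14)
  m <- 0.3 + 0.12 * (a - 10) + rnorm(n, 0, 0.15)
  tab <- ratio_table("arr", data.frame(probe_id = sprintf("p%04d", 1:n),
                                       m = m, a = a))
  mine <- loess_dye_correct(tab, span = 0.3, robust_iters = 3)$m
  oracle <- limma::loessFit(m, a, span = 0.3, iterations = 4)$residuals
  expect_gt(cor(mine, oracle), 0.999)
  expect_lt(max(abs(mine - oracle)), 0.05)
})

test_that("stage order and span are enforced", {
  panel <- big_manual_panel(120)
  tab <- manual_table(panel, rnorm(120, 0, 0.1), stage = "raw")
  expect_error(loess_dye_correct(tab, span = 1.5), "span")
  expect_error(gc_correct(tab, panel), "loess")
  expect_error(composition_correct(tab, panel), "gc")
  expect_error(loess_dye_correct(manual_table(panel, rnorm(120),
                                              stage = "loess")), "raw")
  small <- ratio_table("s", data.frame(probe_id = "p1", m = 0, a = 10))
  expect_error(loess_dye_correct(small), "100")
})

test_that("GC correction removes an injected wave", {
  set.seed(23)
  gc <- runif(1000, 0.25, 0.75)
  panel <- big_manual_panel(1000, gc = gc)
  wave <- 0.8 * 2 * (gc - 0.5)
  clean <- manual_table(panel, wave, stage = "loess")
  out <- gc_correct(clean, panel)
  expect_lt(max(abs(out$m)), 0.02)

  # with noise: residual slope on gc compatible with zero
  noisy <- manual_table(panel, wave + rnorm(1000, 0, 0.1), stage = "loess")
  out2 <- gc_correct(noisy, panel)
  slope <- coef(lm(out2$m ~ gc))[2]
  expect_lt(abs(slope), 0.02 + 2 * summary(lm(out2$m ~ gc))$coef[2, 2])
})

test_that("constant GC is skipped with a warning", {
  panel <- big_manual_panel(150)  # gc all 0.5
  tab <- manual_table(panel, rnorm(150, 0, 0.1), stage = "loess")
  expect_warning(out <- gc_correct(tab, panel), "constant")
  expect_equal(out$m, tab$m)
  expect_identical(attr(out, "stage"), "gc")
})

test_that("composition correction recovers an injected linear effect", {
  set.seed(24)
  gc <- runif(600, 0.3, 0.7)
  u <- runif(600, 0.35, 0.65)   # independent C/G and A/T splits so the
  v <- runif(600, 0.35, 0.65)   # three covariates are not collinear
  df <- data.frame(probe_id = sprintf("p%04d", 1:600),
                   gene_id = sprintf("g%04d", 1:600), start = 0,
                   length = 60, orientation = "sense", gc = gc,
                   f_a = (1 - gc) * v, f_c = gc * u, f_g = gc * (1 - u),
                   f_t = (1 - gc) * (1 - v))
  panel <- probe_panel(df)
  fa <- df$f_a
  tab <- manual_table(panel, 0.5 * fa, stage = "gc")
  out <- composition_correct(tab, panel)
  expect_lt(max(abs(out$m - mean(out$m))), 0.02)

  null <- manual_table(panel, rnorm(600, 0, 0.1), stage = "gc")
  out2 <- composition_correct(null, panel)
  co <- attr(out2, "coefficients")
  expect_true(all(is.finite(co[!is.na(co)])))
})

test_that("collinear composition covariates are dropped with a warning", {
  u <- runif(200, 0.1, 0.3)
  v <- runif(200, 0.2, 0.4)
  df <- data.frame(probe_id = sprintf("p%03d", 1:200),
                   gene_id = sprintf("g%03d", 1:200), start = 0,
                   length = 60, orientation = "sense", gc = u + v,
                   f_a = u, f_c = u, f_g = v, f_t = 1 - 2 * u - v)
  # gc must equal f_c + f_g: adjust
  df$gc <- df$f_c + df$f_g
  panel <- probe_panel(df)
  tab <- manual_table(panel, rnorm(200, 0, 0.1), stage = "gc")
  expect_warning(out <- composition_correct(tab, panel), "collinear")
  expect_identical(attr(out, "stage"), "composition")
})

test_that("the full pipeline removes injected artifacts on null arrays", {
  cfg <- sim_config(n_genes = 600, sigma = 0.15, dye_intercept = 0.25,
                    dye_slope = 0.2, gc_amplitude = 0.5, seed = 25)
  panel <- simulate_panel(cfg)
  arr <- simulate_arrays(cfg, panel, truth = NULL, n_selfself = 1)[[1]]
  raw <- compute_ma(arr)
  lo <- loess_dye_correct(raw)
  gcc <- gc_correct(lo, panel)
  fin <- composition_correct(gcc, panel)
  expect_lt(abs(mean(fin$m)), 0.02)
  expect_lt(abs(sd(fin$m) - cfg$sigma) / cfg$sigma, 0.10)
  # every correction is variance non-increasing on null data (1% slack)
  expect_lte(sd(lo$m), sd(raw$m) * 1.01)
  expect_lte(sd(gcc$m), sd(lo$m) * 1.01)
  expect_lte(sd(fin$m), sd(gcc$m) * 1.01)
  expect_identical(attr(fin, "stage"), "composition")
})
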