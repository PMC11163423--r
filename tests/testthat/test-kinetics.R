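test_that("leakage normalisation reproduces the defining ratio and its limits", {
  t <- seq(0.5, 5, by = 0.5)
  mk <- function(v, ch) fluor_trace(t, rep(v, length(t)), ch)
  out <- normalize_leakage(mk(350, "sample"), mk(100, "baseline"), mk(600, "triton"))
  expect_equal(out$leakage_pct, rep(50, length(t)))

  expect_equal(normalize_leakage(mk(100, "sample"), mk(100, "baseline"),
                                 mk(600, "triton"))$leakage_pct,
               rep(0, length(t)))
  expect_equal(normalize_leakage(mk(600, "sample"), mk(100, "baseline"),
                                 mk(600, "triton"))$leakage_pct,
               rep(100, length(t)))
})

test_that("normalisation is invariant under a common affine rescaling", {
  spec <- leakage_trace_spec(a0 = 60, k = 0.3, tc = 5, t_end = 20)
  tr <- gen_leakage_traces(spec)
  ref <- normalize_leakage(tr$sample, tr$baseline, tr$triton)
  gain <- 2.7; offset <- 31
  rescale <- function(x) fluor_trace(x$times, gain * x$intensities + offset,
                                     x$channel)
  out <- normalize_leakage(rescale(tr$sample), rescale(tr$baseline),
                           rescale(tr$triton))
  expect_equal(out$leakage_pct, ref$leakage_pct, tolerance = 1e-12)
})

test_that("normalisation rejects mismatched axes and degenerate references", {
  t <- seq(0.5, 5, by = 0.5)
  s <- fluor_trace(t, rep(350, length(t)), "sample")
  b <- fluor_trace(t, rep(100, length(t)), "baseline")
  b2 <- fluor_trace(t + 0.1, rep(100, length(t)), "baseline")
  x <- fluor_trace(t, rep(600, length(t)), "triton")
  xd <- fluor_trace(t, rep(100, length(t)), "triton")
  expect_error(normalize_leakage(s, b2, x), "time axes")
  expect_error(normalize_leakage(s, b, xd), "degenerate")
})

test_that("three-point smoothing has the documented stencil and fixed points", {
  expect_equal(smooth3(c(0, 3, 0)), c(1.5, 1, 1.5))
  expect_equal(smooth3(rep(4.2, 10)), rep(4.2, 10))
  ramp <- 2 * (1:20) + 3
  expect_equal(smooth3(ramp)[2:19], ramp[2:19])
  expect_error(smooth3(c(1, 2)), "3 points")
})

test_that("repeated smoothing monotonically reduces white-noise variance", {
  set.seed(42)
  x <- rnorm(500)
  v0 <- var(x); v1 <- var(smooth3(x)); v2 <- var(smooth3(smooth3(x)))
  expect_lt(v1, v0)
  expect_lt(v2, v1)
})

test_that("sigmoid fit recovers noiseless generator parameters", {
  # raw (unsmoothed) path: machine-precision recovery
  leak <- make_leakage(c(a0 = 50, k = 0.2, tc = 10), t_end = 60)
  f <- fit_sigmoid(leak, smooth = FALSE)
  expect_true(f$converged)
  expect_equal(unname(coef(f)), c(50, 0.2, 10), tolerance = 1e-6)
  expect_lt(max(abs(coef(f) - c(50, 0.2, 10)) / c(50, 0.2, 10)), 1e-4)

  # reference fast-leakage system, default (smoothed) path
  p <- ref_kinetics$pc_chol_10_0
  f2 <- fit_sigmoid(make_leakage(p))
  expect_true(f2$converged)
  expect_lt(max(abs(coef(f2) - p[c("a0", "k", "tc")]) / p[c("a0", "k", "tc")]),
            0.005)
})

test_that("flat traces are reported as non-identifiable, plateau retained", {
  spec <- leakage_trace_spec(a0 = 3.05, k = 50, tc = 0.1, t_end = 40)
  tr <- gen_leakage_traces(spec)
  f <- fit_sigmoid(normalize_leakage(tr$sample, tr$baseline, tr$triton))
  expect_false(f$converged)
  expect_equal(f$a0, 3.05, tolerance = 1e-6)
  expect_true(is.na(f$k) && is.na(f$tc))
})

test_that("rate constant is recovered from noisy traces (median error < 10%)", {
  errs <- vapply(1:100, function(i) {
    spec <- leakage_trace_spec(a0 = 60, k = 0.3, tc = 8, t_end = 40, dt = 0.2,
                               noise_sd = 0.02 * 1100, seed = i)
    tr <- gen_leakage_traces(spec)
    f <- fit_sigmoid(normalize_leakage(tr$sample, tr$baseline, tr$triton))
    abs(f$k - 0.3) / 0.3
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.10)
})

test_that("percent lipid mixing implements the corrected-reference ratio", {
  t <- seq(0.5, 12, by = 0.5)
  mk <- function(v, ch) fluor_trace(t, rep(v, length(t)), ch)
  # derived: I0=100, Imax_obs=400, It=350, factor 1.5 -> (350-100)/(600-100)
  r <- percent_lipid_mixing(mk(350, "sample"), mk(100, "baseline"),
                            mk(400, "triton"))
  expect_equal(r$percent_mixing, 50)
  r0 <- percent_lipid_mixing(mk(100, "sample"), mk(100, "baseline"),
                             mk(400, "triton"))
  expect_equal(r0$percent_mixing, 0)
  rs <- percent_lipid_mixing(mk(600, "sample"), mk(100, "baseline"),
                             mk(600, "triton"), correction_factor = 1)
  expect_equal(rs$percent_mixing, 100)
  expect_error(percent_lipid_mixing(mk(350, "sample"), mk(100, "baseline"),
                                    mk(50, "triton"), correction_factor = 1),
               "degenerate")
  short <- fluor_trace(seq(0.5, 5, 0.5), rep(1, 10), "sample")
  expect_error(percent_lipid_mixing(short, mk(100, "baseline"),
                                    mk(400, "triton")),
               "read_time")
})
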