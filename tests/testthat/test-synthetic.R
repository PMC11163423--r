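test_that("leakage generator inverts exactly through normalisation", {
  # half of the plateau at t = tc
  spec <- leakage_trace_spec(a0 = 50, k = 0.2, tc = 10, t_end = 40)
  tr <- gen_leakage_traces(spec)
  leak <- normalize_leakage(tr$sample, tr$baseline, tr$triton)
  at_tc <- approx(leak$time_min, leak$leakage_pct, xout = 10)$y
  expect_equal(at_tc, 25.0, tolerance = 1e-9)

  # fast near-complete leakage saturates to a0 at long times
  spec2 <- leakage_trace_spec(a0 = 99.1, k = 0.52, tc = 0.87,
                              t_end = 200, dt = 0.5)
  tr2 <- gen_leakage_traces(spec2)
  leak2 <- normalize_leakage(tr2$sample, tr2$baseline, tr2$triton)
  expect_equal(leak2$leakage_pct[nrow(leak2)], 99.1, tolerance = 1e-6)

  # zero leakage: sample channel identical to the baseline
  spec3 <- leakage_trace_spec(a0 = 0, k = 0.2, tc = 10, t_end = 10)
  tr3 <- gen_leakage_traces(spec3)
  expect_identical(tr3$sample$intensities, tr3$baseline$intensities)

  # time axes identical across channels and starting at the dead time
  expect_identical(tr$sample$times, tr$baseline$times)
  expect_identical(tr$sample$times, tr$triton$times)
  expect_equal(tr$sample$times[1L], 30 / 60)
})

test_that("generator validation names the offending field", {
  expect_error(leakage_trace_spec(a0 = 130, k = 1, tc = 1), "`a0`")
  expect_error(leakage_trace_spec(a0 = 50, k = -1, tc = 1), "`k`")
  expect_error(leakage_trace_spec(a0 = 50, k = 1, tc = 1, I0_level = 500,
                                  Imax_level = 400), "`Imax_level`")
  expect_error(leakage_trace_spec(a0 = 50, k = 1, tc = 1, noise_sd = 2),
               "`seed`")
  expect_error(isotherm_model_spec(111, area_grid = c(100, 110, 90)),
               "`area_grid`")
})

test_that("generators are bit-reproducible under a fixed seed", {
  g <- function(s) gen_leakage_traces(
    leakage_trace_spec(a0 = 60, k = 0.3, tc = 5, t_end = 20,
                       noise_sd = 5, seed = s))
  expect_identical(g(11)$sample$intensities, g(11)$sample$intensities)
  expect_false(identical(g(11)$sample$intensities, g(12)$sample$intensities))

  iso <- function(s) gen_isotherm(
    isotherm_model_spec(111, noise_sd = 0.1, seed = s))
  expect_identical(iso(3)$pressure, iso(3)$pressure)
})

test_that("mixing generator hits the target fraction at the read point", {
  for (f_max in c(0, 0.5, 1)) {
    tr <- gen_mixing_traces(f_max, I0_level = 100, Imax_obs_level = 400)
    r <- percent_lipid_mixing(tr$sample, tr$baseline, tr$triton)
    expect_equal(r$percent_mixing, 100 * f_max, tolerance = 1e-9)
  }
  # algebraic inversion under the x1.5 correction: corrected I_max = 600
  tr <- gen_mixing_traces(0.5, I0_level = 100, Imax_obs_level = 400)
  it_read <- approx(tr$sample$times, tr$sample$intensities, xout = 10)$y
  expect_equal(it_read, 350, tolerance = 1e-9)
  expect_error(gen_mixing_traces(1.2), "`f_max`")
})

test_that("powder spectrum generator conserves deuterons and symmetry", {
  prof <- order_profile(2:4, c(0.2, 0.2, 0.2))
  sp <- gen_pake_spectrum(pake_spec(prof, n_points = 1024, n_theta = 800))
  dx <- sp$axis[2] - sp$axis[1]
  expect_equal(sum(sp$intensity) * dx, 7, tolerance = 0.01)  # 2+2+3 deuterons
  expect_equal(sp$intensity, rev(sp$intensity), tolerance = 1e-9)

  # 90-degree-edge singularities at +/- (3/4) chi |S| / 2
  pos <- sp$axis > 1
  expect_equal(sp$axis[pos][which.max(sp$intensity[pos])],
               0.75 * 167 * 0.2 / 2, tolerance = 0.5)

  # isotropic limit: single central line
  prof0 <- order_profile(2:4, c(0, 0, 0))
  sp0 <- gen_pake_spectrum(pake_spec(prof0, n_points = 1024, n_theta = 800))
  expect_equal(sp0$axis[which.max(sp0$intensity)], 0, tolerance = 0.1)

  # pattern wider than the axis is refused
  prof_big <- order_profile(2:4, c(0.5, 0.5, 0.5))
  expect_error(pake_spec(prof_big, spectral_width = 100), "`spectral_width`")
})

test_that("CSA generator has unit integral, stated width and edges", {
  sp <- gen_csa_spectrum(csa_spec(delta_sigma = 45.9, sigma_iso = 0,
                                  broadening = 0.3, n_points = 1024))
  dx <- sp$axis[2] - sp$axis[1]
  expect_equal(sum(sp$intensity) * dx, 1, tolerance = 0.01)
  # full powder width (between outer ~2% edges) equals |delta sigma|
  above <- sp$axis[sp$intensity > 0.02 * max(sp$intensity)]
  expect_equal(diff(range(above)), 45.9, tolerance = 1.5)
  # 90-degree edge (the intense peak) at sigma_iso - delta_sigma/3
  expect_equal(sp$axis[which.max(sp$intensity)], -45.9 / 3, tolerance = 0.5)

  sp0 <- gen_csa_spectrum(csa_spec(delta_sigma = 0, sigma_iso = 5,
                                   broadening = 0.5, n_points = 1024))
  expect_equal(sp0$axis[which.max(sp0$intensity)], 5, tolerance = 0.2)
})

test_that("isotherm generator is flat above lift-off and monotone below", {
  spec <- isotherm_model_spec(111)
  iso <- gen_isotherm(spec)
  expect_true(all(iso$pressure[iso$area > 111] == 0))
  below <- iso$pressure[iso$area <= 111]
  expect_true(all(diff(below) > 0))           # rises on compression
  expect_equal(max(iso$pressure), 45, tolerance = 1e-6)
})

test_that("mixture construction obeys exact area additivity plus excess", {
  c1 <- isotherm_model_spec(111, label = "POPC")
  c2 <- isotherm_model_spec(48, collapse_pressure = 50, label = "Chol")
  chi <- mixture_composition(c("POPC", "Chol"), c(0.8, 0.2))
  exc <- function(p) 0.5 + 0.01 * p
  mix <- gen_mixed_isotherm(c1, c2, chi, exc)
  a1 <- pure_on_grid(c1, c2, "a")
  a2 <- pure_on_grid(c1, c2, "b")
  # all four curves share the same pressure knots; compare areas there
  common <- sort(intersect(mix$pressure, a1$pressure), decreasing = FALSE)
  expect_gt(length(common), 100)
  at <- function(iso, p) iso$area[match(p, iso$pressure)]
  expect_equal(at(mix, common),
               0.8 * at(a1, common) + 0.2 * at(a2, common) +
                 vapply(common, exc, numeric(1)),
               tolerance = 1e-9)
})
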