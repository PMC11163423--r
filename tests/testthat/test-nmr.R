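test_that("splitting <-> order parameter conversion is the fixed convention", {
  expect_equal(splitting_to_scd(25.05, 167), 0.2)
  expect_equal(splitting_to_scd(0, 167), 0)
  expect_equal(splitting_to_scd(62.625, 167), 0.5)
  expect_error(splitting_to_scd(70, 167), "all-trans")
  # inverse identity over the physical range
  s <- seq(0, 0.5, length.out = 101)
  expect_equal(splitting_to_scd(scd_to_splitting(s, 167), 167), s,
               tolerance = 1e-12)
})

test_that("dePakeing resolves generating splittings to within one bin", {
  # single doublet
  prof <- order_profile(2:4, c(0.2, 0.2, 0.2))
  sp <- gen_pake_spectrum(pake_spec(prof, n_points = 1024, n_theta = 1000))
  dp <- depake(sp)
  bin <- dp$axis[2] - dp$axis[1]
  expect_lt(abs(dp$axis[which.max(dp$intensity)] - 25.05), bin + 1e-9)

  # isotropic line inverts to zero splitting
  sp0 <- gen_pake_spectrum(pake_spec(order_profile(2:4, rep(0, 3)),
                                     n_points = 1024, n_theta = 1000))
  dp0 <- depake(sp0)
  expect_lt(dp0$axis[which.max(dp0$intensity)], 3 * bin)

  # two nested doublets, equal deuteron weights, 1:1 integrated mass
  prof2 <- order_profile(c(2, 3), c(0.2, 0.1), check_monotone = TRUE)
  prof2$deuteron_weights <- c(2, 2)
  sp2 <- gen_pake_spectrum(pake_spec(prof2, n_points = 1024, n_theta = 1000))
  dp2 <- depake(sp2)
  cut <- (12.525 + 25.05) / 2  # midway between the generating splittings
  m_in <- sum(dp2$intensity[dp2$axis < cut])
  m_out <- sum(dp2$intensity[dp2$axis >= cut])
  expect_equal(m_in / m_out, 1, tolerance = 0.05)
  pk <- function(sel) dp2$axis[sel][which.max(dp2$intensity[sel])]
  expect_lt(abs(pk(dp2$axis < cut) - 12.525), bin + 1e-9)
  expect_lt(abs(pk(dp2$axis >= cut) - 25.05), bin + 1e-9)
})

test_that("a heavily asymmetric spectrum triggers the symmetry warning", {
  prof <- order_profile(2:4, rep(0.15, 3))
  sp <- gen_pake_spectrum(pake_spec(prof, n_points = 1024, n_theta = 800))
  skew <- sp
  skew$intensity[sp$axis > 0] <- skew$intensity[sp$axis > 0] * 1.3
  expect_warning(depake(skew), "asymmetry")
})

test_that("smoothed profile recovers flat and plateau-decay ground truths", {
  # degenerate monotone case: flat profile
  prof <- order_profile(2:6, rep(0.2, 5))
  sp <- gen_pake_spectrum(pake_spec(prof, n_points = 1024, n_theta = 1000))
  rp <- smoothed_profile(depake(sp), n_carbons = 6)
  expect_equal(rp$s_cd, rep(0.2, 5), tolerance = 0.02)

  # plateau-decay template, full pipeline, pointwise within 5%
  truth <- template_profile(0.161)
  sp2 <- gen_pake_spectrum(pake_spec(truth, n_points = 2048, n_theta = 2000))
  rp2 <- smoothed_profile(depake(sp2), n_carbons = 16)
  expect_lt(max(abs(rp2$s_cd - truth$s_cd) / truth$s_cd), 0.05)
  expect_true(all(diff(rp2$s_cd) <= 1e-12))  # monotone toward the methyl
  # forward-inverse mean absolute error < 0.01 in |S_CD|
  expect_lt(mean(abs(rp2$s_cd - truth$s_cd)), 0.01)
})

test_that("average order parameter supports both weighting conventions", {
  prof <- order_profile(2:4, c(0.3, 0.3, 0.3))
  expect_equal(average_order(prof), 0.3)
  prof2 <- order_profile(2:3, c(0.3, 0.1))
  expect_equal(average_order(prof2), 0.2)
  # deuteron weighting: (2*0.3 + 3*0.1)/5
  expect_equal(average_order(prof2, deuteron_weighted = TRUE), 0.18)
})

test_that("mean-torque chain extent matches its closed-form anchors", {
  all_trans <- order_profile(2:16, rep(0.5, 15))
  expect_equal(chain_extent(all_trans)$Lc_star, 15 * 1.27)
  branch <- order_profile(2:16, rep(0.125, 15))
  expect_equal(chain_extent(branch)$Lc_star, 15 * 1.27 * 0.5)  # <cos b> = 1/2

  # monotone in pointwise profile ordering, continuous at the branch
  lo <- template_profile(0.15); hi <- template_profile(0.2)
  expect_lt(chain_extent(lo)$Lc_star, chain_extent(hi)$Lc_star)
  expect_lt(average_order(lo), average_order(hi))
  eps <- 1e-6
  f <- function(s) chain_extent(order_profile(2:4, rep(s, 3)))$Lc_star
  expect_equal(f(0.125 - eps), f(0.125 + eps), tolerance = 1e-2)
})

test_that("uniform disordering lowers both <S> and the chain extent", {
  base <- template_profile(0.295)
  disordered <- order_profile(base$carbons, base$s_cd * 0.7)
  expect_lt(average_order(disordered), average_order(base))
  expect_lt(chain_extent(disordered)$Lc_star, chain_extent(base)$Lc_star)
})

test_that("CSA line-shape fit recovers the generating anisotropy", {
  sp <- gen_csa_spectrum(csa_spec(delta_sigma = 30, broadening = 1,
                                  n_points = 1024, n_theta = 1000))
  fit <- estimate_csa(sp)
  expect_true(fit$converged)
  expect_lt(abs(fit$delta_sigma - 30), 0.5)
  expect_lt(abs(fit$sigma_iso), 0.5)

  sp0 <- gen_csa_spectrum(csa_spec(delta_sigma = 0, broadening = 1,
                                   n_points = 1024, n_theta = 1000))
  expect_lt(estimate_csa(sp0)$delta_sigma, 1)

  expect_error(estimate_csa(gen_pake_spectrum(
    pake_spec(order_profile(2:4, rep(0.1, 3)), n_points = 1024))), "31P")
})
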