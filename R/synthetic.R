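#' @section Seeding:
#' All generators take an integer `seed`; identical seeds give
#' bit-identical output and the caller's RNG state is left untouched.
#' @noRd
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # initialise RNG state
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

check_field <- function(ok, field, msg) {
  if (!ok) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

#' Specification of a synthetic dye-leakage experiment
#'
#' Ground-truth parameters for a simulated calcein leakage run: the
#' logistic leakage course plus raw-channel levels. The instrument dead
#' time (default 30 s: mixing and cuvette transfer) sets the first
#' recorded time point.
#'
#' @param a0 plateau leakage (\%), in `[0, 100]`.
#' @param k rate constant (1/min), >= 0.
#' @param tc half-leakage time (min).
#' @param t_start dead time (s), default 30.
#' @param t_end trace duration (min), default 40.
#' @param dt sampling interval (min), default 0.1.
#' @param I0_level baseline channel intensity (a.u.).
#' @param Imax_level Triton reference intensity (a.u.),
#'   `> I0_level`.
#' @param noise_sd additive Gaussian noise sigma on raw intensities (a.u.).
#' @param seed integer RNG seed (required when `noise_sd > 0`).
#' @return A list of class `leakage_trace_spec`.
#' @export
leakage_trace_spec <- function(a0, k, tc, t_start = 30, t_end = 40, dt = 0.1,
                               I0_level = 100, Imax_level = 1100,
                               noise_sd = 0, seed = NULL) {
  check_field(is.numeric(a0) && a0 >= 0 && a0 <= 100, "a0", "must be in [0, 100] %")
  check_field(is.numeric(k) && k >= 0, "k", "must be >= 0")
  check_field(is.numeric(tc) && is.finite(tc), "tc", "must be finite")
  check_field(t_start >= 0, "t_start", "must be >= 0 s")
  check_field(dt > 0, "dt", "must be > 0")
  check_field(t_end > t_start / 60, "t_end", "must exceed the dead time")
  check_field(Imax_level > I0_level, "Imax_level", "must exceed I0_level")
  check_field(noise_sd >= 0, "noise_sd", "must be >= 0")
  check_field(noise_sd == 0 || !is.null(seed), "seed",
              "must be set when noise_sd > 0")
  structure(list(a0 = a0, k = k, tc = tc, t_start = t_start, t_end = t_end,
                 dt = dt, I0_level = I0_level, Imax_level = Imax_level,
                 noise_sd = noise_sd, seed = seed),
            class = "leakage_trace_spec")
}

#' Simulate the three channels of a calcein leakage assay
#'
#' Forward model of the leakage normalisation: percent leakage follows
#' \eqn{a_0/(1+e^{-(t-t_c)k})} and the sample channel is reconstructed
#' from it between the baseline and Triton reference levels, so that
#' [normalize_leakage()] inverts the generator exactly when
#' `noise_sd = 0`. All three traces share one time axis starting at the
#' dead time.
#'
#' @param spec a [leakage_trace_spec()].
#' @return A list with elements `sample`, `baseline`, `triton`
#'   ([fluor_trace()] objects) and `truth` (the generating parameters).
#' @export
gen_leakage_traces <- function(spec) {
  stopifnot(inherits(spec, "leakage_trace_spec"))
  t <- seq(spec$t_start / 60, spec$t_end, by = spec$dt)
  leak <- sigmoid_model(t, spec$a0, spec$k, spec$tc)
  i0 <- rep(spec$I0_level, length(t))
  imax <- rep(spec$Imax_level, length(t))
  it <- i0 + leak / 100 * (imax - i0)
  if (spec$noise_sd > 0) {
    with_local_seed(spec$seed, {
      it <- it + stats::rnorm(length(t), sd = spec$noise_sd)
      i0 <- i0 + stats::rnorm(length(t), sd = spec$noise_sd)
      imax <- imax + stats::rnorm(length(t), sd = spec$noise_sd)
    })
  }
  meta <- list(assay = "leakage", a0 = spec$a0, k = spec$k, tc = spec$tc)
  list(sample = fluor_trace(t, it, "sample", meta),
       baseline = fluor_trace(t, i0, "baseline", meta),
       triton = fluor_trace(t, imax, "triton", meta),
       truth = spec)
}

#' Simulate the three channels of a probe-dilution lipid-mixing assay
#'
#' NBD-PE dequenching rises exponentially toward the target mixing
#' fraction and is anchored so that [percent_lipid_mixing()] applied to
#' the noiseless output at the read point returns exactly
#' `100 * f_max`. The Triton channel carries the *observed* (pre-
#' correction) lysed intensity; the generator and the analysis share the
#' same correction-factor convention.
#'
#' @param f_max true mixing fraction in `[0, 1]`.
#' @param I0_level baseline intensity (a.u.).
#' @param Imax_obs_level observed (uncorrected) Triton intensity, > 0.
#' @param noise_sd additive Gaussian noise sigma (a.u.).
#' @param seed integer RNG seed.
#' @param read_time read point (min), default 10.
#' @param correction_factor Triton correction (default 1.5).
#' @param tau rise time constant (min), default 2.
#' @return A list with `sample`, `baseline`, `triton` traces and
#'   `truth`.
#' @export
gen_mixing_traces <- function(f_max, I0_level = 100, Imax_obs_level = 400,
                              noise_sd = 0, seed = NULL, read_time = 10,
                              correction_factor = 1.5, tau = 2) {
  check_field(f_max >= 0 && f_max <= 1, "f_max", "must be in [0, 1]")
  check_field(Imax_obs_level > 0, "Imax_obs_level", "must be > 0")
  check_field(noise_sd == 0 || !is.null(seed), "seed",
              "must be set when noise_sd > 0")
  t <- seq(0.5, read_time + 2, by = 0.1)
  imax_corr <- correction_factor * Imax_obs_level
  # fraction anchored to hit f_max exactly at the read point
  raw <- 1 - exp(-(t - t[1L]) / tau)
  anchor <- 1 - exp(-(read_time - t[1L]) / tau)
  f <- f_max * raw / anchor
  it <- I0_level + f * (imax_corr - I0_level)
  i0 <- rep(I0_level, length(t))
  imax <- rep(Imax_obs_level, length(t))
  if (noise_sd > 0) {
    with_local_seed(seed, {
      it <- it + stats::rnorm(length(t), sd = noise_sd)
      i0 <- i0 + stats::rnorm(length(t), sd = noise_sd)
      imax <- imax + stats::rnorm(length(t), sd = noise_sd)
    })
  }
  meta <- list(assay = "mixing", f_max = f_max)
  list(sample = fluor_trace(t, it, "sample", meta),
       baseline = fluor_trace(t, i0, "baseline", meta),
       triton = fluor_trace(t, imax, "triton", meta),
       truth = list(f_max = f_max, correction_factor = correction_factor,
                    read_time = read_time))
}

#' Specification of a synthetic 2H powder spectrum
#'
#' @param profile an [order_profile()] supplying |S_CD| per carbon.
#' @param chi_q static quadrupolar coupling constant (kHz), default 167
#'   for a C-D bond.
#' @param broadening Lorentzian half-width at half-maximum (kHz).
#' @param n_points spectrum length (>= 256).
#' @param spectral_width full axis width (kHz); must exceed twice the
#'   largest 0-degree edge frequency.
#' @param n_theta powder-average grid size (>= 500).
#' @param noise_sd additive Gaussian noise sigma (a.u.).
#' @param seed integer RNG seed.
#' @return A list of class `pake_spec`.
#' @export
pake_spec <- function(profile, chi_q = 167, broadening = 0.5,
                      n_points = 2048, spectral_width = 125,
                      n_theta = 2000, noise_sd = 0, seed = NULL) {
  check_field(inherits(profile, "order_profile") && length(profile$s_cd) > 0,
              "profile", "must be a non-empty order_profile")
  check_field(chi_q > 0, "chi_q", "must be > 0 kHz")
  check_field(broadening >= 0, "broadening", "must be >= 0")
  check_field(n_points >= 256, "n_points", "must be >= 256")
  check_field(n_theta >= 500, "n_theta", "must be >= 500")
  check_field(noise_sd == 0 || !is.null(seed), "seed",
              "must be set when noise_sd > 0")
  dmax <- max(edge_splitting(profile$s_cd, chi_q))
  # the theta = 0 edge sits at the full splitting (twice the 90-degree
  # edge frequency); the axis must contain the whole pattern
  check_field(spectral_width > 2 * dmax, "spectral_width",
              sprintf("must exceed the largest full pattern width (%.1f kHz)",
                      2 * dmax))
  structure(list(profile = profile, chi_q = chi_q, broadening = broadening,
                 n_points = n_points, spectral_width = spectral_width,
                 n_theta = n_theta, noise_sd = noise_sd, seed = seed),
            class = "pake_spec")
}

# 90-degree-edge quadrupolar splitting (kHz) for |S_CD|; the single
# place fixing the splitting convention shared by generator and
# analysis: delta_nu(90 deg) = (3/4) chi_q |S_CD|.
edge_splitting <- function(s_cd, chi_q) 0.75 * chi_q * abs(s_cd)

#' Simulate a deuterium powder spectrum from an order profile
#'
#' Deuteron-weighted superposition of axially symmetric Pake doublets:
#' each carbon with order parameter |S_CD| contributes transitions at
#' \eqn{\pm(\delta/2)(3\cos^2\theta - 1)} with 90-degree-edge splitting
#' \eqn{\delta = (3/4)\,\chi_q\,|S_{CD}|}, powder-averaged over a
#' uniform theta grid with \eqn{\sin\theta} weights and convolved with a
#' Lorentzian. The spectrum is symmetric about zero and its integral
#' equals the total deuteron count (2 per CD2, 3 for the CD3).
#'
#' @param spec a [pake_spec()].
#' @return A [powder_spectrum()] (`nucleus = "2H"`) with the generating
#'   parameters in `meta`.
#' @export
gen_pake_spectrum <- function(spec) {
  stopifnot(inherits(spec, "pake_spec"))
  axis <- seq(-spec$spectral_width / 2, spec$spectral_width / 2,
              length.out = spec$n_points)
  dx <- axis[2L] - axis[1L]
  theta <- (seq_len(spec$n_theta) - 0.5) * (pi / 2) / spec$n_theta
  w_theta <- sin(theta)
  w_theta <- w_theta / sum(w_theta)
  ang <- (3 * cos(theta)^2 - 1) / 2  # nu(theta)/delta for one transition
  hist <- numeric(spec$n_points)
  delta <- edge_splitting(spec$profile$s_cd, spec$chi_q)
  for (i in seq_along(delta)) {
    d_i <- spec$profile$deuteron_weights[i]
    for (sgn in c(1, -1)) {
      nu <- sgn * delta[i] * ang
      hist <- hist + deposit_sticks(nu, 0.5 * d_i * w_theta, axis)
    }
  }
  y <- hist / dx
  if (spec$broadening > 0) y <- lorentz_convolve(y, dx, spec$broadening)
  if (spec$noise_sd > 0)
    y <- with_local_seed(spec$seed,
                         y + stats::rnorm(length(y), sd = spec$noise_sd))
  powder_spectrum(axis, pmax(y, 0), "2H",
                  meta = list(chi_q = spec$chi_q, broadening = spec$broadening,
                              s_cd = spec$profile$s_cd,
                              deuteron_weights = spec$profile$deuteron_weights))
}

# deposit stick weights onto a uniform axis, splitting each stick
# linearly between the two neighbouring bins (keeps mirror symmetry
# exact and first-order accurate in the bin width)
deposit_sticks <- function(pos, w, axis) {
  n <- length(axis)
  dx <- axis[2L] - axis[1L]
  hist <- numeric(n)
  u <- (pos - axis[1L]) / dx
  lo <- floor(u)
  frac <- u - lo
  lo <- lo + 1L  # 1-based lower bin
  for (off in 0:1) {
    idx <- lo + off
    ww <- w * if (off == 0) (1 - frac) else frac
    ok <- idx >= 1L & idx <= n & ww > 0
    if (any(ok)) {
      acc <- tapply(ww[ok], idx[ok], sum)
      ii <- as.integer(names(acc))
      hist[ii] <- hist[ii] + as.numeric(acc)
    }
  }
  hist
}

# convolve a sampled density with a unit-integral Lorentzian of HWHM
# gamma; open convolution trimmed back to the original support
lorentz_convolve <- function(y, dx, gamma) {
  n <- length(y)
  half <- n - 1L
  xk <- (-half:half) * dx
  kern <- (gamma / pi) / (xk^2 + gamma^2)
  kern <- kern / (sum(kern) * dx)
  out <- stats::convolve(y, rev(kern), type = "open") * dx
  out[(half + 1L):(half + n)]
}

#' Specification of a synthetic 31P CSA powder pattern
#'
#' @param delta_sigma chemical shift anisotropy
#'   \eqn{\Delta\sigma = \sigma_\parallel - \sigma_\perp} (ppm); the
#'   full powder width equals `abs(delta_sigma)`.
#' @param sigma_iso isotropic shift (ppm).
#' @param broadening Lorentzian HWHM (ppm).
#' @param n_points spectrum length (>= 256).
#' @param n_theta powder grid size.
#' @param spectral_width axis width (ppm); default generous around the
#'   pattern.
#' @param noise_sd additive Gaussian noise sigma.
#' @param seed integer RNG seed.
#' @return A list of class `csa_spec`.
#' @export
csa_spec <- function(delta_sigma, sigma_iso = 0, broadening = 1,
                     n_points = 2048, n_theta = 2000,
                     spectral_width = NULL, noise_sd = 0, seed = NULL) {
  check_field(is.numeric(delta_sigma) && is.finite(delta_sigma),
              "delta_sigma", "must be finite")
  check_field(n_points >= 256, "n_points", "must be >= 256")
  check_field(n_theta >= 500, "n_theta", "must be >= 500")
  check_field(broadening >= 0, "broadening", "must be >= 0")
  check_field(noise_sd == 0 || !is.null(seed), "seed",
              "must be set when noise_sd > 0")
  if (is.null(spectral_width))
    spectral_width <- 2 * abs(delta_sigma) + 20 * max(broadening, 1) + 10
  structure(list(delta_sigma = delta_sigma, sigma_iso = sigma_iso,
                 broadening = broadening, n_points = n_points,
                 n_theta = n_theta, spectral_width = spectral_width,
                 noise_sd = noise_sd, seed = seed),
            class = "csa_spec")
}

#' Simulate an axially symmetric 31P CSA powder pattern
#'
#' Powder average of the axially symmetric shift tensor
#' \eqn{\sigma(\theta) = \sigma_{iso} + (\Delta\sigma/3)(3\cos^2\theta - 1)}
#' (0-degree shoulder at \eqn{\sigma_{iso} + 2\Delta\sigma/3},
#' 90-degree edge at \eqn{\sigma_{iso} - \Delta\sigma/3}), Lorentzian
#' broadened and normalised to unit integral.
#'
#' @param spec a [csa_spec()].
#' @return A [powder_spectrum()] (`nucleus = "31P"`).
#' @export
gen_csa_spectrum <- function(spec) {
  stopifnot(inherits(spec, "csa_spec"))
  axis <- seq(spec$sigma_iso - spec$spectral_width / 2,
              spec$sigma_iso + spec$spectral_width / 2,
              length.out = spec$n_points)
  dx <- axis[2L] - axis[1L]
  y <- csa_lineshape(axis, spec$delta_sigma, spec$sigma_iso,
                     spec$broadening, spec$n_theta)
  if (spec$noise_sd > 0)
    y <- with_local_seed(spec$seed,
                         y + stats::rnorm(length(y), sd = spec$noise_sd))
  powder_spectrum(axis, pmax(y, 0), "31P",
                  meta = list(delta_sigma = spec$delta_sigma,
                              sigma_iso = spec$sigma_iso,
                              broadening = spec$broadening))
}

# axially symmetric CSA powder line shape, unit integral; shared by the
# generator and (as the model function) by estimate_csa
csa_lineshape <- function(axis, delta_sigma, sigma_iso, broadening,
                          n_theta = 1000) {
  n <- length(axis)
  dx <- axis[2L] - axis[1L]
  theta <- (seq_len(n_theta) - 0.5) * (pi / 2) / n_theta
  w <- sin(theta); w <- w / sum(w)
  sig <- sigma_iso + (delta_sigma / 3) * (3 * cos(theta)^2 - 1)
  y <- deposit_sticks(sig, w, axis) / dx
  if (broadening > 0) y <- lorentz_convolve(y, dx, broadening)
  y
}

#' Specification of a synthetic pressure-area isotherm
#'
#' Smooth LE-to-LC compression isotherm with a sharp lift-off: zero
#' pressure above the lift-off area, then a short exponential onset knee
#' blended into a convex power-law rise reaching the collapse pressure
#' at the smallest grid area. The knee makes the nominal lift-off a
#' well-defined, recoverable ground truth; experimental LE onsets are
#' typically softer.
#'
#' @param lift_off_area lift-off area (\eqn{\mbox{\AA}^2}/molecule), > 0.
#' @param collapse_pressure pressure reached at the smallest grid area
#'   (mN/m), > 0.
#' @param steepness power-law exponent of the compression branch
#'   (dimensionless), default 3.
#' @param area_grid strictly decreasing areas (\eqn{\mbox{\AA}^2}/molecule);
#'   default spans 1.4x the lift-off area down to 45\% of it in 0.1
#'   steps.
#' @param knee_height amplitude of the onset knee (mN/m), default 1.
#' @param knee_width area scale of the onset knee (\eqn{\mbox{\AA}^2}),
#'   default 0.05.
#' @param label component label stored in the composition metadata.
#' @param noise_sd additive Gaussian pressure noise sigma (mN/m).
#' @param seed integer RNG seed.
#' @return A list of class `isotherm_model_spec`.
#' @export
isotherm_model_spec <- function(lift_off_area, collapse_pressure = 45,
                                steepness = 3, area_grid = NULL,
                                knee_height = 1, knee_width = 0.05,
                                label = "component",
                                noise_sd = 0, seed = NULL) {
  check_field(lift_off_area > 0, "lift_off_area", "must be > 0")
  check_field(collapse_pressure > 0, "collapse_pressure", "must be > 0")
  check_field(steepness > 0, "steepness", "must be > 0")
  check_field(knee_height >= 0 && knee_width > 0, "knee_width",
              "knee parameters must be positive")
  if (is.null(area_grid))
    area_grid <- seq(round(1.4 * lift_off_area), round(0.45 * lift_off_area),
                     by = -0.1)
  check_field(all(diff(area_grid) < 0), "area_grid",
              "must be strictly decreasing")
  check_field(min(area_grid) < lift_off_area, "area_grid",
              "must extend below the lift-off area")
  check_field(noise_sd == 0 || !is.null(seed), "seed",
              "must be set when noise_sd > 0")
  structure(list(lift_off_area = lift_off_area,
                 collapse_pressure = collapse_pressure,
                 steepness = steepness, area_grid = area_grid,
                 knee_height = knee_height, knee_width = knee_width,
                 label = label, noise_sd = noise_sd, seed = seed),
            class = "isotherm_model_spec")
}

# noiseless model pressure at areas A for an isotherm_model_spec
isotherm_model_pressure <- function(spec, area) {
  x <- pmax(spec$lift_off_area - area, 0)
  x_end <- spec$lift_off_area - min(spec$area_grid)
  knee <- spec$knee_height * (1 - exp(-x / spec$knee_width))
  knee_end <- spec$knee_height * (1 - exp(-x_end / spec$knee_width))
  amp <- spec$collapse_pressure - knee_end
  if (amp < 0)
    stop("collapse_pressure must exceed the onset knee height", call. = FALSE)
  knee + amp * (x / x_end)^spec$steepness
}

#' Simulate a single-component pressure-area isotherm
#'
#' @param spec an [isotherm_model_spec()].
#' @return An [isotherm()] with the generating parameters in `meta`.
#' @export
gen_isotherm <- function(spec) {
  stopifnot(inherits(spec, "isotherm_model_spec"))
  p <- isotherm_model_pressure(spec, spec$area_grid)
  if (spec$noise_sd > 0)
    p <- with_local_seed(spec$seed,
                         p + stats::rnorm(length(p), sd = spec$noise_sd))
  isotherm(spec$area_grid, pmax(p, -0.49),
           composition = mixture_composition(spec$label, 1),
           meta = list(lift_off_area = spec$lift_off_area,
                       collapse_pressure = spec$collapse_pressure))
}

#' Simulate a binary-mixture isotherm by area additivity plus an excess
#'
#' Builds the mixed-monolayer isotherm on a common pressure grid from
#' two component models: \eqn{A_{12}(\pi) = \chi_1 A_1(\pi) + \chi_2
#' A_2(\pi) + A_{exc}(\pi)}, with a caller-supplied excess-area function
#' (Å^2/molecule as a function of pressure; `NULL` means ideal mixing).
#' This makes the excess Gibbs free energy of the generated mixture
#' exactly the pressure integral of `excess_area_fn`, providing ground
#' truth for [gibbs_excess()].
#'
#' @param spec_1,spec_2 [isotherm_model_spec()] objects for the pure
#'   components.
#' @param composition a two-component [mixture_composition()].
#' @param excess_area_fn function of pressure (mN/m) returning the
#'   excess area (\eqn{\mbox{\AA}^2}/molecule), or `NULL` for ideal mixing.
#' @param pi_max largest pressure on the grid (default 0.95x the
#'   smaller collapse pressure).
#' @param n_points grid size.
#' @param noise_sd additive Gaussian pressure noise applied to the
#'   returned curve (mN/m).
#' @param seed integer RNG seed.
#' @return An [isotherm()] for the mixture.
#' @export
gen_mixed_isotherm <- function(spec_1, spec_2, composition,
                               excess_area_fn = NULL, pi_max = NULL,
                               n_points = 600, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(spec_1, "isotherm_model_spec"),
            inherits(spec_2, "isotherm_model_spec"),
            inherits(composition, "mixture_composition"))
  if (length(composition$mole_fractions) != 2L)
    stop("`composition` must be binary", call. = FALSE)
  check_field(noise_sd == 0 || !is.null(seed), "seed",
              "must be set when noise_sd > 0")
  if (is.null(pi_max))
    pi_max <- 0.95 * min(spec_1$collapse_pressure, spec_2$collapse_pressure)
  pi_grid <- seq(0, pi_max, length.out = n_points)
  a1 <- isotherm_model_area(spec_1, pi_grid)
  a2 <- isotherm_model_area(spec_2, pi_grid)
  exc <- if (is.null(excess_area_fn)) 0 else vapply(pi_grid, excess_area_fn,
                                                    numeric(1))
  chi <- composition$mole_fractions
  a12 <- chi[1L] * a1 + chi[2L] * a2 + exc
  p <- pi_grid
  if (noise_sd > 0)
    p <- with_local_seed(seed, p + stats::rnorm(length(p), sd = noise_sd))
  o <- order(a12, decreasing = TRUE)
  a_sorted <- a12[o]; p_sorted <- p[o]
  keep <- !duplicated(a_sorted)
  isotherm(a_sorted[keep], pmax(p_sorted[keep], -0.49),
           composition = composition,
           meta = list(ideal = is.null(excess_area_fn)))
}

# invert the noiseless isotherm model: area at given pressures.
# pi = 0 maps to the lift-off area (onset of the compression branch).
isotherm_model_area <- function(spec, pressures) {
  x_end <- spec$lift_off_area - min(spec$area_grid)
  vapply(pressures, function(p) {
    if (p <= 0) return(spec$lift_off_area)
    if (p > isotherm_model_pressure(spec, min(spec$area_grid)))
      stop(sprintf("pressure %.3g mN/m exceeds the model's collapse pressure", p),
           call. = FALSE)
    f <- function(a) isotherm_model_pressure(spec, a) - p
    stats::uniroot(f, c(min(spec$area_grid), spec$lift_off_area),
                   tol = 1e-10)$root
  }, numeric(1))
}
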