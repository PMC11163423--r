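#' Convert a 90-degree-edge quadrupolar splitting to |S_CD|
#'
#' The powder-pattern edge (90-degree orientation) splitting of a C-D
#' deuteron relates to the bond order parameter as
#' \eqn{\Delta\nu_{90} = (3/4)\,\chi_q\,|S_{CD}|}; this is the single
#' convention shared by the forward simulator and all inversions.
#'
#' @param delta_nu_90 splitting (kHz), >= 0.
#' @param chi_q static quadrupolar coupling constant (kHz), default 167.
#' @return |S_CD| (dimensionless, in `[0, 0.5]`).
#' @seealso [scd_to_splitting()]
#' @export
splitting_to_scd <- function(delta_nu_90, chi_q = 167) {
  if (chi_q <= 0) stop("`chi_q` must be > 0", call. = FALSE)
  if (any(delta_nu_90 < 0)) stop("splittings must be >= 0", call. = FALSE)
  s <- delta_nu_90 / (0.75 * chi_q)
  if (any(s > 0.5 + 1e-9))
    stop("splitting implies |S_CD| > 0.5 (beyond the all-trans methylene limit)",
         call. = FALSE)
  pmin(s, 0.5)
}

#' @rdname splitting_to_scd
#' @param s_cd |S_CD| values.
#' @export
scd_to_splitting <- function(s_cd, chi_q = 167) edge_splitting(s_cd, chi_q)

#' dePake a deuterium powder spectrum
#'
#' Numerically inverts a powder (randomly oriented) 2H spectrum into the
#' distribution of quadrupolar splittings -- the oriented-sample
#' subspectrum. The powder spectrum is modelled as
#' \eqn{P(\nu) = \int K(\nu; \Delta) f(\Delta)\, d\Delta} with the
#' analytic axially symmetric doublet kernel (Lorentzian-broadened) and
#' solved for the non-negative splitting density \eqn{f} by
#' Tikhonov-regularised least squares under a non-negativity constraint
#' (box-constrained quasi-Newton on the quadratic objective).
#'
#' The spectrum is symmetrised first (a warning is issued if the
#' asymmetry exceeds 2\% of the total intensity). The regularisation
#' strength is chosen by an L-curve scan when `reg_strength = NULL`.
#'
#' @param spectrum a [powder_spectrum()] with `nucleus = "2H"`.
#' @param reg_strength relative Tikhonov strength (second-difference
#'   penalty), or `NULL` for the L-curve default.
#' @param broadening Lorentzian HWHM (kHz) built into the kernel; taken
#'   from the spectrum's `meta` when available, else 0.5.
#' @param n_delta number of splitting-grid points (default 400).
#' @return An object of class `depaked_spectrum`: list with `axis`
#'   (splittings, kHz, >= 0), `intensity` (non-negative density),
#'   `reg_strength` (the value used) and `residual_rms`.
#' @examples
#' prof <- order_profile(2:4, c(0.2, 0.2, 0.2))
#' sp <- gen_pake_spectrum(pake_spec(prof, n_points = 1024, n_theta = 800))
#' dp <- depake(sp)
#' dp$axis[which.max(dp$intensity)]  # ~ 0.75 * 167 * 0.2 = 25.05 kHz
#' @export
depake <- function(spectrum, reg_strength = NULL, broadening = NULL,
                   n_delta = 400) {
  stopifnot(inherits(spectrum, "powder_spectrum"))
  if (spectrum$nucleus != "2H")
    stop("depake expects a 2H spectrum", call. = FALSE)
  if (is.null(broadening))
    broadening <- if (!is.null(spectrum$meta$broadening))
      spectrum$meta$broadening else 0.5

  axis <- spectrum$axis
  y <- spectrum$intensity
  # symmetrise about zero frequency
  ys <- (y + rev(y)) / 2
  asym <- sum(abs(y - rev(y))) / max(sum(abs(y)), .Machine$double.eps)
  if (asym > 0.02)
    warning(sprintf("spectrum asymmetry %.1f%% exceeds tolerance; symmetrised",
                    100 * asym))
  dx <- axis[2L] - axis[1L]
  dmax <- max(abs(axis))
  # splittings beyond dmax/... the theta=0 edge of splitting D sits at D
  deltas <- seq(0, dmax, length.out = n_delta + 1L)[-1L]
  ddelta <- deltas[2L] - deltas[1L]

  K <- pake_kernel(axis, deltas, broadening)

  # quadratic program: || K f - y ||^2 + lambda^2 || D2 f ||^2, f >= 0
  KtK <- crossprod(K)
  Kty <- crossprod(K, ys)
  D2 <- diff(diag(n_delta), differences = 2)
  DtD <- crossprod(D2)
  scale_ref <- mean(diag(KtK))

  solve_f <- function(lam2) {
    A <- KtK + lam2 * scale_ref * DtD
    fn <- function(f) sum(f * (A %*% f)) / 2 - sum(f * Kty)
    gr <- function(f) as.numeric(A %*% f) - as.numeric(Kty)
    f0 <- rep(sum(ys) * dx / n_delta, n_delta)
    res <- stats::optim(f0, fn, gr, method = "L-BFGS-B", lower = 0,
                        control = list(maxit = 500, factr = 1e7))
    pmax(res$par, 0)
  }

  if (is.null(reg_strength)) {
    lams <- 10^seq(-7, -2, length.out = 6)
    pts <- lapply(lams, function(l) {
      f <- solve_f(l)
      c(r = log(sum((K %*% f - ys)^2) + 1e-300),
        s = log(sum((D2 %*% f)^2) + 1e-300))
    })
    r <- vapply(pts, `[[`, numeric(1), "r")
    s <- vapply(pts, `[[`, numeric(1), "s")
    # discrete curvature of the L-curve; fall back to the middle value
    curv <- rep(NA_real_, length(lams))
    for (i in 2:(length(lams) - 1L)) {
      d1r <- (r[i + 1] - r[i - 1]) / 2; d1s <- (s[i + 1] - s[i - 1]) / 2
      d2r <- r[i + 1] - 2 * r[i] + r[i - 1]
      d2s <- s[i + 1] - 2 * s[i] + s[i - 1]
      curv[i] <- (d1r * d2s - d1s * d2r) / (d1r^2 + d1s^2)^1.5
    }
    reg_strength <- if (all(!is.finite(curv))) 1e-4
                    else lams[which.max(replace(curv, !is.finite(curv), -Inf))]
  }
  f <- solve_f(reg_strength)
  resid <- as.numeric(K %*% f) - ys
  structure(list(axis = deltas, intensity = f / ddelta,
                 reg_strength = reg_strength,
                 residual_rms = sqrt(mean(resid^2)),
                 chi_q = spectrum$meta$chi_q),
            class = "depaked_spectrum")
}

#' @export
print.depaked_spectrum <- function(x, ...) {
  cat(sprintf("<depaked_spectrum> %d splitting bins up to %.1f kHz, reg = %.2g\n",
              length(x$axis), max(x$axis), x$reg_strength))
  invisible(x)
}

#' @export
plot.depaked_spectrum <- function(x, ...) {
  graphics::plot(x$axis, x$intensity, type = "l",
                 xlab = "quadrupolar splitting (kHz)",
                 ylab = "density", ...)
  invisible(x)
}

# Powder kernel matrix: column j is the unit-area, Lorentzian-broadened
# doublet line shape for 90-degree-edge splitting deltas[j], sampled on
# `axis`. Bin masses are exact: with u = cos(theta) uniform on [0,1] and
# nu = delta * (3u^2 - 1)/2 per transition, the CDF in nu is
# u(nu) = sqrt((2 nu/delta + 1)/3) on [-delta/2, delta], so each axis
# bin receives u(hi) - u(lo).
pake_kernel <- function(axis, deltas, broadening) {
  n <- length(axis)
  dx <- axis[2L] - axis[1L]
  edges <- c(axis - dx / 2, axis[n] + dx / 2)
  K <- matrix(0, n, length(deltas))
  ucdf <- function(nu, delta) {
    nu <- pmin(pmax(nu, -delta / 2), delta)
    sqrt((2 * nu / delta + 1) / 3)
  }
  for (j in seq_along(deltas)) {
    d <- deltas[j]
    mass_pos <- ucdf(edges[-1L], d) - ucdf(edges[-(n + 1L)], d)
    # mirror transition at -nu
    mass_neg <- rev(mass_pos)
    K[, j] <- (mass_pos + mass_neg) / 2 / dx
  }
  if (broadening > 0)
    K <- apply(K, 2L, lorentz_convolve, dx = dx, gamma = broadening)
  K
}

#' Smoothed chain order-parameter profile from a dePaked spectrum
#'
#' Assigns splittings to carbon positions under the standard
#' monotonicity assumption: |S_CD| decreases from the plateau (upper
#' chain) toward the terminal methyl. The cumulative deuteron-weighted
#' integral of the dePaked splitting density is partitioned into one
#' block per carbon (2 deuterons per CD2, 3 for the terminal CD3,
#' smallest splittings belonging to the methyl end) and |S_CD| is read
#' at the centre quantile of each block.
#'
#' @param depaked a [depake()] result.
#' @param n_carbons number of labelled carbons; the profile covers
#'   positions `2:n_carbons` (default 16 for a perdeuterated palmitoyl
#'   chain).
#' @param weights optional deuteron weights per position (default 2 per
#'   CD2 and 3 for the terminal CD3).
#' @param chi_q quadrupolar coupling constant (kHz); taken from the
#'   depaked object when available.
#' @return An [order_profile()].
#' @export
smoothed_profile <- function(depaked, n_carbons = 16, weights = NULL,
                             chi_q = NULL) {
  stopifnot(inherits(depaked, "depaked_spectrum"))
  if (n_carbons < 3) stop("`n_carbons` must be >= 3", call. = FALSE)
  if (is.null(chi_q))
    chi_q <- if (!is.null(depaked$chi_q)) depaked$chi_q else 167
  carbons <- 2:n_carbons
  if (is.null(weights)) {
    weights <- rep(2, length(carbons))
    weights[length(weights)] <- 3
  }
  if (length(weights) != length(carbons))
    stop("`weights` must have one entry per carbon position", call. = FALSE)

  ddelta <- depaked$axis[2L] - depaked$axis[1L]
  mass <- depaked$intensity * ddelta
  total <- sum(mass)
  if (total <= 0) stop("dePaked spectrum has non-positive total integral",
                       call. = FALSE)
  w_total <- sum(weights)
  cum <- cumsum(mass) / total * w_total  # cumulative deuterons, small->large splitting
  # block centres, counted from the methyl end (smallest splittings)
  w_rev <- rev(weights)  # methyl first
  targets <- cumsum(w_rev) - w_rev / 2
  grid <- c(0, depaked$axis)
  cumg <- c(0, cum)
  delta_at <- stats::approx(cumg, grid, xout = targets, ties = "ordered",
                            rule = 2)$y
  s_rev <- splitting_to_scd(delta_at, chi_q)
  s <- rev(cummax(s_rev))  # enforce monotone non-increasing along chain
  order_profile(carbons, pmin(s, 0.5), check_monotone = FALSE)
}

#' Average chain order parameter
#'
#' Mean |S_CD| over the labelled carbons; by convention the unweighted
#' per-carbon mean. A deuteron-weighted mean (2 per CD2, 3 for the
#' methyl) is available behind a flag.
#'
#' @param profile an [order_profile()].
#' @param deuteron_weighted use deuteron weights instead of the
#'   per-carbon mean (default `FALSE`).
#' @return The scalar mean order parameter.
#' @export
average_order <- function(profile, deuteron_weighted = FALSE) {
  stopifnot(inherits(profile, "order_profile"))
  if (deuteron_weighted)
    sum(profile$s_cd * profile$deuteron_weights) / sum(profile$deuteron_weights)
  else mean(profile$s_cd)
}

#' Chain extent from an order profile (first-order mean-torque model)
#'
#' Projects each chain segment onto the bilayer normal using the
#' first-order mean-torque mapping
#' \eqn{\langle\cos\beta_i\rangle = \tfrac12\left(1 +
#' \sqrt{(8|S_{CD,i}| - 1)/3}\right)} for \eqn{|S| \ge 1/8}, with a
#' continuous linear continuation \eqn{0.375 + |S|} below the branch
#' point, and sums the projected segment lengths:
#' \eqn{L_c^* = \sum_i l_{cc} \langle\cos\beta_i\rangle}. The all-trans
#' limit (|S| = 0.5 everywhere) gives the fully extended length
#' `1.27 * n_segments` Angstrom.
#'
#' @param profile an [order_profile()]; one segment per profile entry.
#' @param l_cc projected C-C bond length per segment (Angstrom),
#'   default 1.27.
#' @return A list of class `chain_summary` with `avg_S`, `Lc_star`
#'   (Angstrom), `chi_q` = NA (not used here), `n_segments`.
#' @export
chain_extent <- function(profile, l_cc = 1.27) {
  stopifnot(inherits(profile, "order_profile"))
  s <- profile$s_cd
  if (any(s < 0 | s > 0.5)) stop("|S_CD| must be in [0, 0.5]", call. = FALSE)
  cosb <- ifelse(s >= 1 / 8,
                 0.5 * (1 + sqrt(pmax(8 * s - 1, 0) / 3)),
                 0.375 + s)
  structure(list(avg_S = mean(s), Lc_star = sum(l_cc * cosb),
                 l_cc = l_cc, n_segments = length(s)),
            class = "chain_summary")
}

#' @export
print.chain_summary <- function(x, ...) {
  cat(sprintf("Chain summary: <S> = %.3f, L_c* = %.2f A (%d segments, l_cc = %g A)\n",
              x$avg_S, x$Lc_star, x$n_segments, x$l_cc))
  invisible(x)
}

#' Fit an axially symmetric CSA powder pattern
#'
#' Least-squares fit of a Lorentzian-broadened, axially symmetric
#' chemical-shift powder line shape to a 31P spectrum. The chemical
#' shift anisotropy is reported as a magnitude (the ppm width of the
#' powder pattern); the isotropic shift and the broadening are
#' co-estimated and the amplitude is profiled out analytically.
#'
#' @param spectrum a [powder_spectrum()] with `nucleus = "31P"`.
#' @param n_theta powder grid used in the model function.
#' @return An object of class `csa_fit` with `delta_sigma` (ppm,
#'   magnitude), `sigma_iso` (ppm), `broadening` (ppm), `fit_rms`,
#'   `converged`, and the fitted curve.
#' @export
estimate_csa <- function(spectrum, n_theta = 800) {
  stopifnot(inherits(spectrum, "powder_spectrum"))
  if (spectrum$nucleus != "31P")
    stop("estimate_csa expects a 31P spectrum", call. = FALSE)
  axis <- spectrum$axis
  y <- spectrum$intensity
  dx <- axis[2L] - axis[1L]
  tot <- sum(y) * dx
  if (tot <= 0) stop("spectrum has non-positive integral", call. = FALSE)

  centroid <- sum(axis * y) / sum(y)  # = sigma_iso for a powder average
  above <- axis[y > 0.02 * max(y)]
  width0 <- diff(range(above))
  peak <- axis[which.max(y)]
  sign0 <- if (peak <= centroid) 1 else -1  # 90-deg edge below centroid => positive
  ds0 <- sign0 * max(width0 * 0.8, dx)
  b0 <- max(width0 * 0.02, dx)

  obj <- function(par) {
    ds <- par[1L]; si <- par[2L]; gb <- exp(par[3L])
    m <- csa_lineshape(axis, ds, si, gb, n_theta)
    amp <- sum(m * y) / max(sum(m * m), .Machine$double.eps)
    sum((y - amp * m)^2)
  }
  res <- stats::optim(c(ds0, centroid, log(b0)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  ds <- res$par[1L]; si <- res$par[2L]; gb <- exp(res$par[3L])
  m <- csa_lineshape(axis, ds, si, gb, n_theta)
  amp <- sum(m * y) / max(sum(m * m), .Machine$double.eps)
  structure(list(delta_sigma = abs(ds), delta_sigma_signed = ds,
                 sigma_iso = si, broadening = gb,
                 fit_rms = sqrt(res$value / length(y)),
                 converged = res$convergence == 0,
                 axis = axis, observed = y, fitted = amp * m),
            class = "csa_fit")
}

#' @export
print.csa_fit <- function(x, ...) {
  cat(sprintf("31P CSA line-shape fit: |Delta sigma| = %.2f ppm (sigma_iso = %.2f ppm, HWHM = %.2f ppm)\n",
              x$delta_sigma, x$sigma_iso, x$broadening))
  cat(sprintf("  residual RMS %.3g, converged: %s\n", x$fit_rms, x$converged))
  invisible(x)
}

#' @export
coef.csa_fit <- function(object, ...) {
  c(delta_sigma = object$delta_sigma, sigma_iso = object$sigma_iso,
    broadening = object$broadening)
}

#' @export
plot.csa_fit <- function(x, ...) {
  graphics::plot(x$axis, x$observed, type = "l", col = "grey40",
                 xlab = "chemical shift (ppm)", ylab = "intensity", ...)
  graphics::lines(x$axis, x$fitted, col = 2, lwd = 2)
  invisible(x)
}
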