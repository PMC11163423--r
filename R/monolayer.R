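# unit conversion: 1 (A^2/molecule) * (mN/m) = 1e-20 m^2 * 1e-3 N/m
# = 1e-23 J per molecule = 6.02214076 J/mol. Defined once.
AREA_PRESSURE_TO_J_PER_MOL <- 6.02214076
AVOGADRO <- 6.02214076e23

#' Mole percent of an amphiphile in a lipid mixture
#'
#' \eqn{100\,[IL] / ([IL] + [Lipid])} from the molar concentrations of
#' the two stock solutions combined for spreading.
#'
#' @param conc_il,conc_lipid molar concentrations, >= 0, not both zero.
#' @return mol \% of the amphiphile.
#' @export
molpercent_il <- function(conc_il, conc_lipid) {
  if (any(conc_il < 0) || any(conc_lipid < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  if (any(conc_il + conc_lipid == 0))
    stop("concentrations must not both be zero", call. = FALSE)
  100 * conc_il / (conc_il + conc_lipid)
}

#' Spread-molecule count and starting mean molecular area
#'
#' Converts a spreading protocol (trough area, spread volume, stock
#' concentration, mean molar mass) into the number of molecules at the
#' interface and the mean molecular area before compression.
#'
#' @param trough_area trough surface area (cm^2).
#' @param spread_volume spread volume (microlitre).
#' @param stock_conc stock concentration (mg/mL).
#' @param mean_molar_mass mean molar mass (g/mol).
#' @return A list with `n_molecules` and `mma_start`
#'   (\eqn{\mbox{\AA}^2}/molecule).
#' @examples
#' mma_axis(273, 40, 0.5, 760.08)  # POPC: ~1.58e16 molecules, ~172 A^2
#' @export
mma_axis <- function(trough_area, spread_volume, stock_conc, mean_molar_mass) {
  if (any(c(trough_area, spread_volume, stock_conc, mean_molar_mass) <= 0))
    stop("all arguments must be positive", call. = FALSE)
  mass_g <- spread_volume * 1e-3 * stock_conc * 1e-3      # uL * mg/mL -> g
  n <- mass_g / mean_molar_mass * AVOGADRO
  if (n < 1) stop("fewer than one molecule spread; check inputs", call. = FALSE)
  list(n_molecules = n, mma_start = trough_area * 1e16 / n)
}

#' Static in-plane elasticity (compressional modulus) of a monolayer
#'
#' \eqn{C_s^{-1}(A) = -A\,(\partial\pi/\partial A)_T}, with the
#' derivative estimated by a Savitzky-Golay-type local quadratic fit
#' (one-sided stencils at the endpoints). Positive wherever pressure
#' strictly increases on compression.
#'
#' @param iso an [isotherm()] (>= 7 points).
#' @param smoothing_window odd window length of the local fit,
#'   default 11.
#' @return A data frame with columns `area`, `pressure`, `elasticity`
#'   (mN/m).
#' @export
static_elasticity <- function(iso, smoothing_window = 11) {
  stopifnot(inherits(iso, "isotherm"))
  n <- length(iso$area)
  if (n < 7) stop("need at least 7 isotherm points", call. = FALSE)
  w <- as.integer(smoothing_window)
  if (w %% 2L == 0L) w <- w + 1L
  if (w > n) stop("smoothing window larger than the series", call. = FALSE)
  if (w < 5L) w <- 5L
  half <- (w - 1L) %/% 2L
  dpda <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    if (hi - lo + 1L < w) {            # one-sided stencil at the edges
      if (lo == 1L) hi <- min(n, lo + w - 1L) else lo <- max(1L, hi - w + 1L)
    }
    a <- iso$area[lo:hi] - iso$area[i]
    p <- iso$pressure[lo:hi]
    fit <- stats::lm.fit(cbind(1, a, a^2), p)
    dpda[i] <- fit$coefficients[2L]
  }
  data.frame(area = iso$area, pressure = iso$pressure,
             elasticity = -iso$area * dpda)
}

#' Lift-off area of a compression isotherm
#'
#' The lift-off area is the largest mean molecular area at which the
#' surface pressure first rises above the zero-pressure baseline during
#' compression -- the onset of molecular interaction in the LE phase.
#' The baseline is the median pressure over the largest-area decile of
#' the curve; detection is the first crossing of baseline + `threshold`
#' scanning from large to small areas.
#'
#' @param iso an [isotherm()] including a zero-pressure region.
#' @param threshold detection threshold above baseline (mN/m),
#'   default 0.5.
#' @return The lift-off area (\eqn{\mbox{\AA}^2}/molecule).
#' @export
liftoff_area <- function(iso, threshold = 0.5) {
  stopifnot(inherits(iso, "isotherm"))
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  n <- length(iso$area)
  n_base <- max(3L, ceiling(n / 10))
  baseline <- stats::median(iso$pressure[seq_len(min(n_base, n))])
  idx <- which(iso$pressure > baseline + threshold)
  if (!length(idx))
    stop("no lift-off: pressure never exceeds baseline + threshold",
         call. = FALSE)
  iso$area[idx[1L]]
}

#' Excess Gibbs free energy of mixing of a binary monolayer
#'
#' Integrates the deviation of the mixed monolayer's mean molecular
#' area from mole-fraction-weighted ideality over surface pressure:
#' \deqn{\Delta G_{exc} = \int_{\pi_{lo}}^{\pi_{hi}}
#'   \left(A_{12} - \chi_1 A_1 - \chi_2 A_2\right) d\pi,}
#' with all three isotherms interpolated onto a common pressure grid
#' (monotone piecewise-linear in pressure; non-monotone noise segments
#' are projected to monotone first, with a warning) and the trapezoidal
#' rule. The result is converted from
#' \eqn{\mbox{\AA}^2\cdot}mN/m per molecule to J/mol
#' (1 \eqn{\mbox{\AA}^2\cdot}mN/m = 6.022 J/mol). Negative values
#' indicate favourable mixing (condensation).
#'
#' @param iso_mix mixed-monolayer [isotherm()].
#' @param iso_1,iso_2 pure-component isotherms.
#' @param chi a binary [mixture_composition()] (order matching
#'   `iso_1`, `iso_2`).
#' @param pi_lo,pi_hi integration bounds (mN/m), default 0 and 30.
#' @param n_grid pressure-grid size, default 301.
#' @return An object of class `gibbs_excess` with `delta_G_exc`
#'   (J/mol), `pressure_range`, and the interpolated `A1`, `A2`, `A12`
#'   (with the grid) used.
#' @export
gibbs_excess <- function(iso_mix, iso_1, iso_2, chi, pi_lo = 0, pi_hi = 30,
                         n_grid = 301) {
  for (x in list(iso_mix, iso_1, iso_2))
    if (!inherits(x, "isotherm")) stop("isotherm inputs required", call. = FALSE)
  stopifnot(inherits(chi, "mixture_composition"))
  if (length(chi$mole_fractions) != 2L)
    stop("`chi` must be binary", call. = FALSE)
  if (pi_hi <= pi_lo) stop("pi_hi must exceed pi_lo", call. = FALSE)
  for (nm in c("iso_mix", "iso_1", "iso_2")) {
    x <- get(nm)
    if (max(x$pressure) < pi_hi - 1e-9)
      stop(sprintf("%s reaches only %.2f mN/m < pi_hi = %g mN/m",
                   nm, max(x$pressure), pi_hi), call. = FALSE)
  }
  grid <- seq(pi_lo, pi_hi, length.out = n_grid)
  a1 <- area_at_pressure(iso_1, grid)
  a2 <- area_at_pressure(iso_2, grid)
  a12 <- area_at_pressure(iso_mix, grid)
  excess <- a12 - chi$mole_fractions[1L] * a1 - chi$mole_fractions[2L] * a2
  dpi <- diff(grid)
  integral <- sum((excess[-1L] + excess[-n_grid]) / 2 * dpi)
  structure(list(delta_G_exc = integral * AREA_PRESSURE_TO_J_PER_MOL,
                 pressure_range = c(pi_lo, pi_hi),
                 grid = grid, A1 = a1, A2 = a2, A12 = a12,
                 chi = chi$mole_fractions),
            class = "gibbs_excess")
}

#' @export
print.gibbs_excess <- function(x, ...) {
  cat(sprintf("Excess Gibbs free energy: %.2f J/mol over [%g, %g] mN/m (chi = %s)\n",
              x$delta_G_exc, x$pressure_range[1L], x$pressure_range[2L],
              paste(format(x$chi), collapse = "/")))
  invisible(x)
}

# interpolate A(pi) on a pressure grid; pressure is made monotone
# non-decreasing along compression by isotonic projection if noise
# produced local inversions
area_at_pressure <- function(iso, grid) {
  p <- iso$pressure        # along compression (area decreasing)
  a <- iso$area
  if (any(diff(p) < 0)) {
    p_iso <- rev(-stats::isoreg(seq_along(p), -rev(p))$yf)  # non-decreasing
    if (max(abs(p_iso - p)) > 1e-9)
      warning("non-monotone pressure segments projected to monotone before interpolation")
    p <- p_iso
  }
  # collapse duplicate pressures (flat baseline): keep the smallest area
  # at each pressure so pi = 0 maps to the lift-off onset, not to the
  # start of the compression ramp
  keep <- !duplicated(p, fromLast = TRUE)
  stats::approx(p[keep], a[keep], xout = grid, rule = 2, ties = "ordered")$y
}
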