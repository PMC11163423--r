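#' Fluorescence time trace
#'
#' Container for a single-channel fluorescence time series from a
#' cuvette assay (calcein leakage or NBD dequenching). Times are in
#' minutes and must be strictly increasing; the first point is normally
#' the instrument dead time (30 s) since mixing.
#'
#' @param times numeric vector of times (min), strictly increasing.
#' @param intensities numeric vector of intensities (arbitrary units),
#'   finite, same length as `times`.
#' @param channel one of `"sample"`, `"baseline"`, `"triton"`.
#' @param meta optional named list of free-form labels (lipid system,
#'   amphiphile concentration, ...).
#' @return An object of class `fluor_trace`: a list with elements
#'   `times`, `intensities`, `channel`, `meta`.
#' @examples
#' tr <- fluor_trace(seq(0.5, 5, by = 0.5), rep(100, 10), "baseline")
#' tr
#' @export
fluor_trace <- function(times, intensities, channel = c("sample", "baseline", "triton"),
                        meta = list()) {
  channel <- match.arg(channel)
  times <- as.numeric(times)
  intensities <- as.numeric(intensities)
  if (length(times) != length(intensities))
    stop("`times` and `intensities` must have equal length", call. = FALSE)
  if (length(times) < 1L || any(!is.finite(times)))
    stop("`times` must be finite and non-empty", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (any(!is.finite(intensities)))
    stop("`intensities` must be finite", call. = FALSE)
  structure(list(times = times, intensities = intensities,
                 channel = channel, meta = meta),
            class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("<fluor_trace> channel=%s, %d points, t = [%.3g, %.3g] min\n",
              x$channel, length(x$times), x$times[1L], x$times[length(x$times)]))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.fluor_trace <- function(x, ...) {
  data.frame(time_min = x$times, intensity = x$intensities)
}

#' Powder spectrum
#'
#' Frequency-domain powder (randomly oriented sample) spectrum, either a
#' deuterium quadrupolar spectrum (axis in kHz, centred at zero) or a
#' phosphorus-31 chemical-shift spectrum (axis in ppm).
#'
#' @param axis numeric axis, uniformly spaced and increasing: frequency
#'   offset (kHz) for `"2H"`, chemical shift (ppm) for `"31P"`.
#' @param intensity non-negative intensities on `axis`.
#' @param nucleus `"2H"` or `"31P"`.
#' @param meta optional named list (generating parameters, source file).
#' @return An object of class `powder_spectrum`.
#' @export
powder_spectrum <- function(axis, intensity, nucleus = c("2H", "31P"),
                            meta = list()) {
  nucleus <- match.arg(nucleus)
  axis <- as.numeric(axis); intensity <- as.numeric(intensity)
  if (length(axis) != length(intensity))
    stop("`axis` and `intensity` must have equal length", call. = FALSE)
  d <- diff(axis)
  if (any(d <= 0))
    stop("`axis` must be increasing", call. = FALSE)
  if (max(d) - min(d) > 1e-6 * mean(d))
    stop("`axis` must be uniformly spaced", call. = FALSE)
  if (any(!is.finite(intensity)) || any(intensity < -1e-12 * max(abs(intensity))))
    stop("`intensity` must be finite and non-negative", call. = FALSE)
  structure(list(axis = axis, intensity = pmax(intensity, 0),
                 nucleus = nucleus, meta = meta),
            class = "powder_spectrum")
}

#' @export
print.powder_spectrum <- function(x, ...) {
  unit <- if (x$nucleus == "2H") "kHz" else "ppm"
  cat(sprintf("<powder_spectrum> %s, %d points, axis = [%.4g, %.4g] %s\n",
              x$nucleus, length(x$axis), min(x$axis), max(x$axis), unit))
  invisible(x)
}

#' @export
plot.powder_spectrum <- function(x, ...) {
  unit <- if (x$nucleus == "2H") "frequency (kHz)" else "chemical shift (ppm)"
  graphics::plot(x$axis, x$intensity, type = "l", xlab = unit,
                 ylab = "intensity (a.u.)", ...)
  invisible(x)
}

#' Chain order-parameter profile
#'
#' Per-carbon absolute C-D bond order parameters |S_CD| for a
#' perdeuterated saturated sn-1 chain. Carbons are numbered from the
#' carbonyl (position 2) to the terminal methyl; methylene carbons carry
#' two deuterons, the terminal methyl three. The smoothed-profile
#' construction guarantees a monotone non-increasing profile toward the
#' methyl end.
#'
#' @param carbons integer carbon positions, typically `2:16` for a
#'   palmitoyl chain.
#' @param s_cd numeric |S_CD| per carbon, in `[0, 0.5]`.
#' @param check_monotone if `TRUE`, require the profile to be monotone
#'   non-increasing along the chain (default).
#' @return An object of class `order_profile` with a `deuteron_weights`
#'   element (2 per CD2, 3 for the terminal CD3).
#' @export
order_profile <- function(carbons, s_cd, check_monotone = TRUE) {
  carbons <- as.integer(carbons); s_cd <- as.numeric(s_cd)
  if (length(carbons) != length(s_cd) || length(carbons) < 1L)
    stop("`carbons` and `s_cd` must be non-empty and of equal length", call. = FALSE)
  if (any(diff(carbons) != 1L))
    stop("`carbons` must be consecutive positions", call. = FALSE)
  if (any(!is.finite(s_cd)) || any(s_cd < 0) || any(s_cd > 0.5))
    stop("|S_CD| must lie in [0, 0.5]", call. = FALSE)
  if (check_monotone && any(diff(s_cd) > 1e-9))
    stop("profile must be monotone non-increasing toward the methyl end",
         call. = FALSE)
  w <- rep(2, length(carbons))
  w[length(w)] <- 3  # terminal CD3
  structure(list(carbons = carbons, s_cd = s_cd, deuteron_weights = w),
            class = "order_profile")
}

#' @export
print.order_profile <- function(x, ...) {
  cat(sprintf("<order_profile> carbons %d..%d, <S> = %.4f\n",
              min(x$carbons), max(x$carbons), mean(x$s_cd)))
  invisible(x)
}

#' @export
plot.order_profile <- function(x, ...) {
  graphics::plot(x$carbons, x$s_cd, type = "b", pch = 16,
                 xlab = "carbon position", ylab = "|S_CD|",
                 ylim = c(0, max(0.3, max(x$s_cd))), ...)
  invisible(x)
}

#' Binary (or n-ary) mixture composition
#'
#' @param components character labels.
#' @param mole_fractions numeric mole fractions, non-negative, summing
#'   to 1 within 1e-9.
#' @return An object of class `mixture_composition`.
#' @export
mixture_composition <- function(components, mole_fractions) {
  mole_fractions <- as.numeric(mole_fractions)
  if (length(components) != length(mole_fractions))
    stop("`components` and `mole_fractions` must have equal length", call. = FALSE)
  if (any(mole_fractions < 0))
    stop("mole fractions must be non-negative", call. = FALSE)
  if (abs(sum(mole_fractions) - 1) > 1e-9)
    stop("mole fractions must sum to 1", call. = FALSE)
  structure(list(components = as.character(components),
                 mole_fractions = mole_fractions),
            class = "mixture_composition")
}

#' Pressure-area isotherm
#'
#' Langmuir monolayer compression isotherm: surface pressure versus mean
#' molecular area, ordered by compression (area strictly decreasing).
#'
#' @param area mean molecular area (\eqn{\mbox{\AA}^2}/molecule), strictly decreasing.
#' @param pressure surface pressure (mN/m); small negative noise
#'   (>= -0.5) is tolerated.
#' @param temperature temperature (degrees C), default 25.
#' @param composition optional [mixture_composition()].
#' @param meta optional named list.
#' @return An object of class `isotherm`.
#' @export
isotherm <- function(area, pressure, temperature = 25, composition = NULL,
                     meta = list()) {
  area <- as.numeric(area); pressure <- as.numeric(pressure)
  if (length(area) != length(pressure) || length(area) < 2L)
    stop("`area` and `pressure` must have equal length >= 2", call. = FALSE)
  if (any(diff(area) >= 0))
    stop("`area` must be strictly decreasing (compression order)", call. = FALSE)
  if (any(!is.finite(pressure)) || any(pressure < -0.5))
    stop("`pressure` must be finite and >= -0.5 mN/m", call. = FALSE)
  if (!is.null(composition) && !inherits(composition, "mixture_composition"))
    stop("`composition` must be a mixture_composition", call. = FALSE)
  structure(list(area = area, pressure = pressure, temperature = temperature,
                 composition = composition, meta = meta),
            class = "isotherm")
}

#' @export
print.isotherm <- function(x, ...) {
  cat(sprintf("<isotherm> %d points, A = [%.1f, %.1f] A^2/molecule, pi up to %.1f mN/m\n",
              length(x$area), min(x$area), max(x$area), max(x$pressure)))
  if (!is.null(x$composition))
    cat("  composition:", paste(x$composition$components,
                                format(x$composition$mole_fractions),
                                sep = ":", collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.isotherm <- function(x, ...) {
  graphics::plot(x$area, x$pressure, type = "l",
                 xlab = expression("mean molecular area (" * ring(A)^2 * "/molecule)"),
                 ylab = "surface pressure (mN/m)",
                 xlim = rev(range(x$area)), ...)
  invisible(x)
}
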