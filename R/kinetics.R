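#' Normalise a dye-leakage trace to percent leakage
#'
#' Converts raw calcein fluorescence into percent dye leakage using the
#' matched baseline (vesicles without amphiphile, \eqn{I_{0,t}}) and
#' detergent-lysed reference (\eqn{I_{max,t}}, after 1\% Triton X-100)
#' channels recorded for the same vesicle preparation:
#' \deqn{\%\,leakage(t) = 100\,(I_t - I_{0,t}) / (I_{max,t} - I_{0,t}).}
#'
#' Values are reported as computed: negative or >100\% excursions are
#' preserved for quality control rather than clipped.
#'
#' @param sample,baseline,triton [fluor_trace()] objects sharing an
#'   identical time axis.
#' @return A data frame with columns `time_min` and `leakage_pct`.
#' @examples
#' t <- seq(0.5, 10, by = 0.5)
#' s <- fluor_trace(t, rep(350, length(t)), "sample")
#' b <- fluor_trace(t, rep(100, length(t)), "baseline")
#' x <- fluor_trace(t, rep(600, length(t)), "triton")
#' head(normalize_leakage(s, b, x))
#' @seealso [fit_sigmoid()], [smooth3()]
#' @export
normalize_leakage <- function(sample, baseline, triton) {
  for (tr in list(sample, baseline, triton))
    if (!inherits(tr, "fluor_trace"))
      stop("all inputs must be fluor_trace objects", call. = FALSE)
  if (!isTRUE(all.equal(sample$times, baseline$times, tolerance = 1e-9)) ||
      !isTRUE(all.equal(sample$times, triton$times, tolerance = 1e-9)))
    stop("time axes of sample, baseline and triton traces do not match",
         call. = FALSE)
  den <- triton$intensities - baseline$intensities
  if (any(abs(den) < .Machine$double.eps^0.5 * max(abs(triton$intensities), 1)))
    stop("degenerate reference: I_max,t equals I_0,t at some time points",
         call. = FALSE)
  pct <- 100 * (sample$intensities - baseline$intensities) / den
  data.frame(time_min = sample$times, leakage_pct = pct)
}

#' Three-point moving-average smoothing
#'
#' Centred moving mean with window 3, as applied to normalised leakage
#' traces before plotting and fitting. Endpoints use the one-sided
#' two-point mean so length is preserved; constants and affine interior
#' segments pass through unchanged.
#'
#' @param x numeric vector (>= 3 points) or a data frame whose second
#'   column is the series (first column is left untouched).
#' @return Same shape as `x`, smoothed.
#' @export
smooth3 <- function(x) {
  if (is.data.frame(x)) {
    x[[2L]] <- smooth3(x[[2L]])
    return(x)
  }
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stop("smooth3 needs at least 3 points", call. = FALSE)
  y <- x
  y[1L] <- mean(x[1:2])
  y[n] <- mean(x[(n - 1L):n])
  y[2:(n - 1L)] <- (x[1:(n - 2L)] + x[2:(n - 1L)] + x[3:n]) / 3
  y
}

sigmoid_model <- function(t, a0, k, tc) a0 / (1 + exp(-(t - tc) * k))

#' Fit sigmoidal leakage kinetics
#'
#' Fits the logistic leakage model
#' \deqn{\%\,leakage(t) = a_0 / (1 + e^{-(t - t_c)\,k})}
#' to a percent-leakage time series by bounded nonlinear least squares,
#' returning the plateau leakage \eqn{a_0} (\%), the rate constant
#' \eqn{k} (1/min) and the half-leakage time \eqn{t_c} (min) with
#' standard errors.
#'
#' Traces with no identifiable rise -- flat traces, or kinetics so fast
#' or slow that the rate is not constrained by the data -- are reported
#' with `converged = FALSE` and `NA` rate parameters rather than
#' spurious numbers; the plateau is still estimated as the series mean.
#' Identifiability is judged by the profile-likelihood confidence
#' interval of `k` (Wald fallback): a fit whose interval reaches the
#' parameter bounds is declared non-identifiable.
#'
#' @param leakage data frame with columns `time_min`, `leakage_pct`
#'   (the output of [normalize_leakage()]), or a numeric vector with a
#'   separate `times` argument.
#' @param times optional numeric time axis when `leakage` is a vector.
#' @param smooth apply [smooth3()] before fitting (default `TRUE`; the
#'   raw normalised series can be fitted with `smooth = FALSE`).
#' @param bounds named list of lower/upper bounds; defaults
#'   `a0` in `[0, 110]`, `k` in `[0, 50]` 1/min, `tc` in `[0, max(t)]`.
#' @param level confidence level of the identifiability interval.
#' @return An object of class `sigmoid_fit` with components `a0`, `k`,
#'   `tc`, `se_a0`, `se_k`, `se_tc`, `converged`, `residual_rms`,
#'   `data`, and the underlying `nls` fit (or `NULL`).
#' @examples
#' spec <- leakage_trace_spec(a0 = 50, k = 0.2, tc = 10, noise_sd = 0)
#' tr <- gen_leakage_traces(spec)
#' fit <- fit_sigmoid(normalize_leakage(tr$sample, tr$baseline, tr$triton))
#' coef(fit)
#' @export
fit_sigmoid <- function(leakage, times = NULL, smooth = TRUE,
                        bounds = NULL, level = 0.95) {
  if (is.data.frame(leakage)) {
    t <- leakage[[1L]]; y <- leakage[[2L]]
  } else {
    if (is.null(times)) stop("`times` required when `leakage` is a vector",
                             call. = FALSE)
    t <- as.numeric(times); y <- as.numeric(leakage)
  }
  if (length(t) < 6L)
    stop("need at least 6 points to fit the sigmoid", call. = FALSE)
  if (smooth) y <- smooth3(y)

  b <- list(a0 = c(0, 110), k = c(0, 50), tc = c(0, max(t)))
  if (!is.null(bounds)) b[names(bounds)] <- bounds

  # initial guesses: plateau from max, tc at half-max crossing, k from
  # the 10-90% rise time
  a0_0 <- max(y)
  half <- a0_0 / 2
  tc_0 <- t[which.min(abs(y - half))]
  t10 <- t[which(y >= 0.1 * a0_0)[1L]]
  t90 <- t[which(y >= 0.9 * a0_0)[1L]]
  k_0 <- if (!is.na(t10) && !is.na(t90) && t90 > t10) 4 / (t90 - t10) else 1
  k_0 <- min(max(k_0, b$k[1L] + 1e-3), b$k[2L])
  tc_0 <- min(max(tc_0, b$tc[1L]), b$tc[2L])

  df <- data.frame(t = t, y = y)
  fit <- tryCatch(
    stats::nls(y ~ a0 / (1 + exp(-(t - tc) * k)), data = df,
               start = list(a0 = a0_0, k = k_0, tc = tc_0),
               lower = c(b$a0[1L], b$k[1L], b$tc[1L]),
               upper = c(b$a0[2L], b$k[2L], b$tc[2L]),
               algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)

  if (is.null(fit)) {
    # no identifiable rise: plateau-only summary, N.D. rate parameters
    out <- list(a0 = mean(y), k = NA_real_, tc = NA_real_,
                se_a0 = stats::sd(y) / sqrt(length(y)),
                se_k = NA_real_, se_tc = NA_real_,
                converged = FALSE,
                residual_rms = sqrt(mean((y - mean(y))^2)),
                data = df, fit = NULL)
    return(structure(out, class = "sigmoid_fit"))
  }

  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  names(se) <- names(cf)

  identifiable <- sigmoid_k_identifiable(fit, cf, se, b, level)
  res <- stats::resid(fit)
  out <- list(a0 = unname(cf["a0"]), k = unname(cf["k"]), tc = unname(cf["tc"]),
              se_a0 = unname(se["a0"]), se_k = unname(se["k"]),
              se_tc = unname(se["tc"]),
              converged = identifiable,
              residual_rms = sqrt(mean(res^2)),
              data = df, fit = fit)
  if (!identifiable) {
    out$k <- NA_real_; out$tc <- NA_real_
    out$se_k <- NA_real_; out$se_tc <- NA_real_
    out$a0 <- mean(df$y)
  }
  structure(out, class = "sigmoid_fit")
}

# k is declared non-identifiable when its confidence interval spans a
# parameter bound: profile likelihood when available, Wald otherwise.
sigmoid_k_identifiable <- function(fit, cf, se, b, level) {
  k_hat <- unname(cf["k"])
  if (!is.finite(k_hat)) return(FALSE)
  ci <- tryCatch(suppressWarnings(suppressMessages(
    stats::confint(fit, "k", level = level))),
    error = function(e) NULL)
  if (is.null(ci) || any(!is.finite(ci))) {
    if (!is.finite(se["k"])) return(FALSE)
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- c(k_hat - z * se["k"], k_hat + z * se["k"])
  }
  lo <- min(ci); hi <- max(ci)
  width <- b$k[2L] - b$k[1L]
  !(lo <= b$k[1L] + 1e-9 * width || hi >= b$k[2L] - 1e-9 * width)
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("Sigmoidal leakage kinetics fit\n")
  fmt <- function(v, s) {
    if (!is.finite(v)) return("N.D.")
    if (is.finite(s)) sprintf("%.4g ± %.2g", v, s) else sprintf("%.4g", v)
  }
  cat("  a0 (plateau, %):   ", fmt(x$a0, x$se_a0), "\n")
  cat("  k  (rate, 1/min):  ", fmt(x$k, x$se_k), "\n")
  cat("  tc (half-time, min):", fmt(x$tc, x$se_tc), "\n")
  cat(sprintf("  converged: %s, residual RMS: %.3g %%\n",
              x$converged, x$residual_rms))
  invisible(x)
}

#' @export
summary.sigmoid_fit <- function(object, ...) {
  est <- c(a0 = object$a0, k = object$k, tc = object$tc)
  se <- c(a0 = object$se_a0, k = object$se_k, tc = object$se_tc)
  structure(list(coefficients = cbind(Estimate = est, `Std. Error` = se),
                 converged = object$converged,
                 residual_rms = object$residual_rms,
                 n = nrow(object$data)),
            class = "summary.sigmoid_fit")
}

#' @export
print.summary.sigmoid_fit <- function(x, ...) {
  cat(sprintf("Sigmoidal leakage fit on %d points (converged: %s)\n",
              x$n, x$converged))
  stats::printCoefmat(x$coefficients, na.print = "N.D.")
  cat(sprintf("Residual RMS: %.3g %%\n", x$residual_rms))
  invisible(x)
}

#' @export
coef.sigmoid_fit <- function(object, ...) {
  c(a0 = object$a0, k = object$k, tc = object$tc)
}

#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t
       else if (is.data.frame(newdata)) newdata[[1L]] else as.numeric(newdata)
  if (!object$converged)
    return(rep(object$a0, length(t)))
  sigmoid_model(t, object$a0, object$k, object$tc)
}

#' @export
residuals.sigmoid_fit <- function(object, ...) {
  object$data$y - predict(object)
}

#' @export
plot.sigmoid_fit <- function(x, ...) {
  graphics::plot(x$data$t, x$data$y, pch = 1, cex = 0.6,
                 xlab = "time (min)", ylab = "dye leakage (%)", ...)
  tt <- seq(min(x$data$t), max(x$data$t), length.out = 400)
  graphics::lines(tt, predict(x, tt), col = 2, lwd = 2)
  invisible(x)
}

#' Percent lipid mixing from a probe-dilution assay
#'
#' Quantifies FRET-probe dilution (NBD-PE dequenching) at a fixed read
#' time after amphiphile addition:
#' \deqn{\%\,mixing = 100\,(I_t - I_{0,t}) / (I_{max,corr} - I_{0,t}),}
#' where \eqn{I_{max,corr}} is the Triton-lysed reference intensity
#' multiplied by a correction factor (default 1.5) because Triton X-100
#' reduces NBD-PE fluorescence.
#'
#' @param sample,baseline,triton [fluor_trace()] objects; each must
#'   cover `read_time`.
#' @param correction_factor positive multiplier applied to the observed
#'   Triton intensity (default 1.5).
#' @param read_time read-out time in minutes (default 10).
#' @return A list of class `mixing_result` with `percent_mixing`,
#'   `correction_factor`, `read_time`.
#' @export
percent_lipid_mixing <- function(sample, baseline, triton,
                                 correction_factor = 1.5, read_time = 10) {
  for (tr in list(sample, baseline, triton))
    if (!inherits(tr, "fluor_trace"))
      stop("all inputs must be fluor_trace objects", call. = FALSE)
  if (correction_factor <= 0)
    stop("`correction_factor` must be positive", call. = FALSE)
  at_read <- function(tr) {
    if (read_time < min(tr$times) - 1e-9 || read_time > max(tr$times) + 1e-9)
      stop(sprintf("trace (%s) does not cover read_time = %g min",
                   tr$channel, read_time), call. = FALSE)
    stats::approx(tr$times, tr$intensities, xout = read_time, rule = 2)$y
  }
  it <- at_read(sample); i0 <- at_read(baseline); imax_obs <- at_read(triton)
  imax_corr <- correction_factor * imax_obs
  den <- imax_corr - i0
  if (den <= 0)
    stop("degenerate reference: corrected Triton intensity does not exceed baseline",
         call. = FALSE)
  structure(list(percent_mixing = 100 * (it - i0) / den,
                 correction_factor = correction_factor,
                 read_time = read_time),
            class = "mixing_result")
}

#' @export
print.mixing_result <- function(x, ...) {
  cat(sprintf("Lipid mixing: %.2f %% at %g min (Triton correction x%g)\n",
              x$percent_mixing, x$read_time, x$correction_factor))
  invisible(x)
}
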