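# Coefficient of determination about the mean; 1 for a zero-variance
# response. Avoids summary.lm's perfect-fit warning on noiseless data.
r_squared_about_mean <- function(y, yhat) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  max(0, min(1, 1 - sum((y - yhat)^2) / ss_tot))
}

#' Extract per-point peak intensities from a titration series
#'
#' Reads one intensity per titration point at a fixed emission wavelength
#' (linear interpolation on the emission grid). The read wavelength defaults
#' to the emission maximum of the zero-quencher spectrum, matching the
#' convention of analysing peak intensities rather than band areas. Points
#' where F exceeds F0 are returned as-is; no silent clipping.
#'
#' @param series A \code{\link{titration_series}}.
#' @param read_nm Read wavelength (nm); default the F0 emission maximum.
#' @param integrate If \code{TRUE}, use the integrated band area (trapezoid
#'   over the full emission grid) instead of the peak intensity.
#' @return A data frame with columns \code{conc_M} and \code{F}; the first
#'   row is (0, F0). The read wavelength is attached as attribute
#'   \code{"read_nm"}.
#' @export
extract_intensities <- function(series, read_nm = NULL, integrate = FALSE) {
  stopifnot(inherits(series, "titration_series"))
  em0 <- series$points[[1]]$emission
  if (integrate) {
    F <- vapply(series$points, function(p) {
      wl <- p$emission$wavelengths_nm
      y <- p$emission$intensity_au
      sum(diff(wl) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
    }, numeric(1))
    read_nm <- NA_real_
  } else {
    if (is.null(read_nm))
      read_nm <- em0$wavelengths_nm[which.max(em0$intensity_au)]
    rng <- range(em0$wavelengths_nm)
    if (read_nm < rng[1] || read_nm > rng[2])
      stop(sprintf("read_nm %g outside emission grid [%g, %g]", read_nm,
                   rng[1], rng[2]), call. = FALSE)
    F <- vapply(series$points, function(p)
      stats::approx(p$emission$wavelengths_nm, p$emission$intensity_au,
                    xout = read_nm)$y, numeric(1))
  }
  conc <- vapply(series$points, function(p) p$quencher_conc_M, numeric(1))
  structure(data.frame(conc_M = conc, F = F), read_nm = read_nm)
}

#' Fit the Stern-Volmer quenching model
#'
#' Ordinary least squares of F0/F on quencher concentration:
#' F0/F = 1 + Ksv[Q]. The slope is the Stern-Volmer constant Ksv (M^-1)
#' and the bimolecular quenching constant follows as Kq = Ksv / tau0. With
#' \code{intercept_mode = "fixed_one"} the regression line is forced through
#' (0, 1). A free-intercept fit whose intercept deviates from 1 by more than
#' 5\% triggers a data-quality warning.
#'
#' @param pairs Data frame with columns \code{conc_M} and \code{F} (as from
#'   \code{\link{extract_intensities}}); >= 3 points including [Q] = 0, all
#'   F > 0.
#' @param tau0_s Fluorophore lifetime in the absence of quencher (s);
#'   default 5.7e-9 s, the literature HSA tryptophan value.
#' @param intercept_mode \code{"free"} (default) or \code{"fixed_one"}.
#' @param temperature_K,excitation_nm Optional metadata stamped on the fit.
#' @return An object of class \code{"sv_fit"} with elements
#'   \code{ksv_M_inv}, \code{intercept}, \code{kq_M_inv_s_inv},
#'   \code{tau0_s}, \code{r_squared}, \code{temperature_K},
#'   \code{excitation_nm}, \code{data}.
#' @export
fit_stern_volmer <- function(pairs, tau0_s = 5.7e-9,
                             intercept_mode = c("free", "fixed_one"),
                             temperature_K = NA_real_,
                             excitation_nm = NA_real_) {
  intercept_mode <- match.arg(intercept_mode)
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) < 3) stop("need at least 3 titration points", call. = FALSE)
  if (pairs$conc_M[1] != 0 || !any(pairs$conc_M == 0))
    stop("pairs must include a [Q] = 0 point first (defines F0)",
         call. = FALSE)
  if (any(pairs$F <= 0)) stop("all intensities must be > 0", call. = FALSE)
  if (tau0_s <= 0) stop("tau0_s must be > 0", call. = FALSE)
  F0 <- pairs$F[pairs$conc_M == 0][1]
  y <- F0 / pairs$F
  x <- pairs$conc_M
  if (intercept_mode == "free") {
    fit <- stats::lm(y ~ x)
    intercept <- unname(stats::coef(fit)[1])
    ksv <- unname(stats::coef(fit)[2])
  } else {
    fit <- stats::lm(I(y - 1) ~ x - 1)
    intercept <- 1
    ksv <- unname(stats::coef(fit)[1])
  }
  r2 <- r_squared_about_mean(y, intercept + ksv * x)
  if (intercept_mode == "free" && abs(intercept - 1) > 0.05)
    warning(sprintf("Stern-Volmer intercept %.3f deviates from 1 by > 5%%",
                    intercept), call. = FALSE)
  structure(
    list(ksv_M_inv = ksv, intercept = intercept,
         kq_M_inv_s_inv = ksv / tau0_s, tau0_s = tau0_s,
         r_squared = max(0, min(1, r2)),
         temperature_K = temperature_K, excitation_nm = excitation_nm,
         intercept_mode = intercept_mode,
         data = data.frame(conc_M = x, ratio = y)),
    class = "sv_fit"
  )
}

#' @export
print.sv_fit <- function(x, ...) {
  cat(sprintf(
    "Stern-Volmer fit: Ksv = %.4g M^-1, Kq = %.4g M^-1 s^-1 (tau0 = %.3g s), R^2 = %.4f\n",
    x$ksv_M_inv, x$kq_M_inv_s_inv, x$tau0_s, x$r_squared))
  if (!is.na(x$temperature_K))
    cat(sprintf("  T = %.2f K, ex %.0f nm\n", x$temperature_K,
                x$excitation_nm))
  invisible(x)
}

#' @export
coef.sv_fit <- function(object, ...) {
  c(intercept = object$intercept, ksv_M_inv = object$ksv_M_inv)
}

#' @export
predict.sv_fit <- function(object, conc_M = object$data$conc_M, ...) {
  object$intercept + object$ksv_M_inv * conc_M
}

#' @export
residuals.sv_fit <- function(object, ...) {
  object$data$ratio - predict(object)
}

#' @export
summary.sv_fit <- function(object, ...) {
  cat(sprintf("Stern-Volmer quenching fit (%d points, intercept %s)\n",
              nrow(object$data), object$intercept_mode))
  print(object)
  cat(sprintf("  intercept = %.4f, residual sd = %.3g\n", object$intercept,
              stats::sd(residuals(object))))
  invisible(object)
}

#' @export
plot.sv_fit <- function(x, ...) {
  graphics::plot(x$data$conc_M, x$data$ratio, xlab = "[Q] (M)",
                 ylab = expression(F[0] / F),
                 main = "Stern-Volmer plot", ...)
  graphics::abline(x$intercept, x$ksv_M_inv, col = "steelblue")
  invisible(x)
}

#' Classify the quenching mechanism from temperature-resolved fits
#'
#' Collisional (dynamic) quenching grows with temperature while ground-state
#' complex (static) quenching shrinks; very large bimolecular quenching
#' constants (far above the ~1e10 M^-1 s^-1 diffusion-controlled limit) also
#' indicate the static regime. The call is \code{"dynamic"} when Ksv is
#' non-decreasing with temperature (ties allowed within \code{rel_tol}) and
#' the largest Kq stays below \code{kq_static_threshold}; \code{"static"}
#' when Ksv is non-increasing or Kq exceeds the threshold;
#' \code{"indeterminate"} otherwise (non-monotone or flat).
#'
#' @param fits List of >= 3 \code{\link{fit_stern_volmer}} results at
#'   distinct temperatures.
#' @param rel_tol Relative tolerance for ties in the temperature trend.
#' @param kq_static_threshold Kq (M^-1 s^-1) above which the static regime
#'   is called regardless of trend.
#' @return A list of class \code{"mechanism_call"}: \code{label},
#'   \code{ksv_trend} (+1, -1 or 0), \code{kq_magnitude_ratio}
#'   (max Kq / 1e10).
#' @export
classify_mechanism <- function(fits, rel_tol = 0.02,
                               kq_static_threshold = 1e12) {
  if (length(fits) < 3)
    stop("need fits at >= 3 distinct temperatures", call. = FALSE)
  temps <- vapply(fits, function(f) f$temperature_K, numeric(1))
  if (anyNA(temps) || anyDuplicated(temps))
    stop("fits must carry distinct temperatures", call. = FALSE)
  o <- order(temps)
  ksv <- vapply(fits, function(f) f$ksv_M_inv, numeric(1))[o]
  kq_max <- max(vapply(fits, function(f) f$kq_M_inv_s_inv, numeric(1)))
  d <- diff(ksv)
  scale <- pmax(abs(utils::head(ksv, -1)), .Machine$double.eps)
  nondec <- all(d >= -rel_tol * scale)
  noninc <- all(d <= rel_tol * scale)
  trend <- if (nondec && !noninc) 1L else if (noninc && !nondec) -1L else 0L
  label <- if (kq_max > kq_static_threshold) "static"
    else if (trend == 1L) "dynamic"
    else if (trend == -1L) "static"
    else "indeterminate"
  structure(list(label = label, ksv_trend = trend,
                 kq_magnitude_ratio = kq_max / 1e10),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf(
    "Quenching mechanism: %s (Ksv temperature trend %+d, max Kq = %.3g x 1e10 M^-1 s^-1)\n",
    x$label, x$ksv_trend, x$kq_magnitude_ratio))
  invisible(x)
}
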