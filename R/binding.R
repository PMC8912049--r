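#' Fit the double-logarithm binding model
#'
#' Ordinary least squares of log10((F0 - F)/F) on log10[Q]:
#' log((F0 - F)/F) = log Kb + n log[Q]. The intercept gives the apparent
#' binding constant Kb (M^-1) and the slope the binding-site number n.
#' Points with [Q] = 0 or F0 - F <= 0 cannot enter the log transform; they
#' are excluded and reported in the \code{excluded} element, never clamped.
#'
#' @param pairs Data frame with columns \code{conc_M} and \code{F}; the
#'   [Q] = 0 row defines F0. At least 3 usable points required.
#' @param temperature_K Optional temperature stamped on the fit.
#' @return An object of class \code{"binding_fit"} with elements
#'   \code{kb_M_inv}, \code{n_sites}, \code{r_squared},
#'   \code{temperature_K}, \code{excluded} (data frame of dropped points),
#'   \code{data} (the log-log design actually fitted).
#' @export
fit_double_log <- function(pairs, temperature_K = NA_real_) {
  pairs <- as.data.frame(pairs)
  if (!any(pairs$conc_M == 0))
    stop("pairs must include a [Q] = 0 point (defines F0)", call. = FALSE)
  F0 <- pairs$F[pairs$conc_M == 0][1]
  cand <- pairs[pairs$conc_M > 0, , drop = FALSE]
  usable <- cand$F > 0 & (F0 - cand$F) > 0
  excluded <- cand[!usable, , drop = FALSE]
  cand <- cand[usable, , drop = FALSE]
  if (nrow(cand) < 3)
    stop(sprintf("need >= 3 usable points with [Q] > 0 and F0 - F > 0 (have %d)",
                 nrow(cand)), call. = FALSE)
  x <- log10(cand$conc_M)
  y <- log10((F0 - cand$F) / cand$F)
  fit <- stats::lm(y ~ x)
  kb <- 10^unname(stats::coef(fit)[1])
  n <- unname(stats::coef(fit)[2])
  structure(
    list(kb_M_inv = kb, n_sites = n,
         r_squared = r_squared_about_mean(y, stats::fitted(fit)),
         temperature_K = temperature_K, f0 = F0,
         excluded = excluded, data = data.frame(log_conc = x, log_ratio = y)),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Double-log binding fit: Kb = %.4g M^-1, n = %.3f, R^2 = %.4f\n",
              x$kb_M_inv, x$n_sites, x$r_squared))
  if (!is.na(x$temperature_K))
    cat(sprintf("  T = %.2f K\n", x$temperature_K))
  if (nrow(x$excluded) > 0)
    cat(sprintf("  %d point(s) excluded (F0 - F <= 0)\n", nrow(x$excluded)))
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) {
  c(log10_kb = log10(object$kb_M_inv), n_sites = object$n_sites)
}

#' @export
predict.binding_fit <- function(object, conc_M = NULL, ...) {
  lq <- if (is.null(conc_M)) object$data$log_conc else log10(conc_M)
  log10(object$kb_M_inv) + object$n_sites * lq
}

#' @export
residuals.binding_fit <- function(object, ...) {
  object$data$log_ratio - predict(object)
}

#' @export
summary.binding_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  %d points fitted, residual sd = %.3g (log10 units)\n",
              nrow(object$data), stats::sd(residuals(object))))
  invisible(object)
}

#' @export
plot.binding_fit <- function(x, ...) {
  graphics::plot(x$data$log_conc, x$data$log_ratio,
                 xlab = expression(log[10] * "[Q]"),
                 ylab = expression(log[10] * ((F[0] - F) / F)),
                 main = "Double-log binding plot", ...)
  graphics::abline(log10(x$kb_M_inv), x$n_sites, col = "firebrick")
  invisible(x)
}

#' Classify binding cooperativity from the site exponent
#'
#' The double-log slope n measures cooperativity: n above 1 indicates
#' cooperative binding, below 1 anticooperative, and n near 1 independent
#' 1:1 binding.
#'
#' @param fit A \code{\link{fit_double_log}} result (or a bare n value).
#' @param tol Half-width of the independence band around n = 1.
#' @return One of \code{"cooperative"}, \code{"independent"},
#'   \code{"anticooperative"}.
#' @export
classify_cooperativity <- function(fit, tol = 0.05) {
  n <- if (inherits(fit, "binding_fit")) fit$n_sites else as.numeric(fit)
  if (n > 1 + tol) "cooperative"
  else if (n < 1 - tol) "anticooperative"
  else "independent"
}
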