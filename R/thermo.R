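# Gas constant, J mol^-1 K^-1
GAS_CONSTANT <- 8.314

#' Van't Hoff analysis of temperature-resolved binding constants
#'
#' Ordinary least squares of ln Kb on 1/T. For the linear van't Hoff model
#' ln K = -dH/(R T) + dS/R, the slope gives the enthalpy change
#' dH = -R * slope and the intercept the entropy change dS = R * intercept;
#' the free-energy change at each input temperature follows from the fitted
#' line as dG = dH - T dS. dH is assumed temperature-independent over the
#' studied range.
#'
#' @param kb_by_temperature Named numeric vector (or list) mapping absolute
#'   temperature in K (names) to binding constants in M^-1; >= 3 distinct
#'   temperatures, all Kb > 0.
#' @return An object of class \code{"vant_hoff"} with elements
#'   \code{delta_h_kj_mol}, \code{delta_s_j_mol_k}, \code{delta_g_kj_mol}
#'   (named by temperature), \code{delta_g_obs_kj_mol} (diagnostic
#'   -RT ln Kb(observed)), \code{r_squared}, \code{gas_constant},
#'   \code{data}.
#' @export
fit_vant_hoff <- function(kb_by_temperature) {
  kb <- unlist(kb_by_temperature)
  temps <- as.numeric(names(kb))
  if (length(kb) < 3)
    stop("need binding constants at >= 3 temperatures", call. = FALSE)
  if (anyNA(temps)) stop("temperatures (names) must be numeric K",
                         call. = FALSE)
  if (anyDuplicated(temps)) stop("duplicate temperatures", call. = FALSE)
  if (any(kb <= 0)) stop("all Kb must be > 0", call. = FALSE)
  if (any(temps <= 0)) stop("temperatures must be > 0 K", call. = FALSE)
  o <- order(temps)
  temps <- temps[o]; kb <- kb[o]
  x <- 1 / temps
  y <- log(kb)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  dh <- -GAS_CONSTANT * slope / 1000          # kJ mol^-1
  ds <- GAS_CONSTANT * intercept              # J mol^-1 K^-1
  dg <- compute_gibbs(dh, ds, temps)
  names(dg) <- temps
  dg_obs <- -GAS_CONSTANT * temps * y / 1000
  names(dg_obs) <- temps
  r2 <- r_squared_about_mean(y, stats::fitted(fit))
  structure(
    list(delta_h_kj_mol = dh, delta_s_j_mol_k = ds,
         delta_g_kj_mol = dg, delta_g_obs_kj_mol = dg_obs,
         r_squared = max(0, min(1, r2)), gas_constant = GAS_CONSTANT,
         data = data.frame(temperature_K = temps, kb_M_inv = kb,
                           inv_T = x, ln_kb = y)),
    class = "vant_hoff"
  )
}

#' @export
print.vant_hoff <- function(x, ...) {
  cat(sprintf(
    "van't Hoff fit: dH = %.2f kJ mol^-1, dS = %.2f J mol^-1 K^-1, R^2 = %.4f\n",
    x$delta_h_kj_mol, x$delta_s_j_mol_k, x$r_squared))
  for (i in seq_along(x$delta_g_kj_mol))
    cat(sprintf("  dG(%s K) = %.2f kJ mol^-1\n",
                names(x$delta_g_kj_mol)[i], x$delta_g_kj_mol[i]))
  invisible(x)
}

#' @export
coef.vant_hoff <- function(object, ...) {
  c(delta_h_kj_mol = object$delta_h_kj_mol,
    delta_s_j_mol_k = object$delta_s_j_mol_k)
}

#' @export
predict.vant_hoff <- function(object, temperature_K = object$data$temperature_K,
                              ...) {
  # fitted ln Kb at the requested temperatures
  dh_j <- object$delta_h_kj_mol * 1000
  (-dh_j / temperature_K + object$delta_s_j_mol_k) / object$gas_constant
}

#' @export
residuals.vant_hoff <- function(object, ...) {
  object$data$ln_kb - predict(object)
}

#' @export
summary.vant_hoff <- function(object, ...) {
  print(object)
  cat(sprintf("  %d temperatures, %.2f-%.2f K\n", nrow(object$data),
              min(object$data$temperature_K), max(object$data$temperature_K)))
  invisible(object)
}

#' @export
plot.vant_hoff <- function(x, ...) {
  graphics::plot(x$data$inv_T, x$data$ln_kb, xlab = "1/T (K^-1)",
                 ylab = expression(ln ~ K[b]), main = "van't Hoff plot", ...)
  graphics::abline(x$delta_s_j_mol_k / x$gas_constant,
                   -x$delta_h_kj_mol * 1000 / x$gas_constant,
                   col = "darkgreen")
  invisible(x)
}

#' Gibbs free-energy change
#'
#' dG = dH - T dS with units reconciled (dH in kJ mol^-1, dS in
#' J mol^-1 K^-1, output in kJ mol^-1).
#'
#' @param delta_h_kj_mol Enthalpy change (kJ mol^-1).
#' @param delta_s_j_mol_k Entropy change (J mol^-1 K^-1).
#' @param temperature_K Absolute temperature(s), > 0.
#' @return Free-energy change(s) in kJ mol^-1.
#' @export
compute_gibbs <- function(delta_h_kj_mol, delta_s_j_mol_k, temperature_K) {
  if (any(temperature_K <= 0))
    stop("temperature_K must be > 0", call. = FALSE)
  delta_h_kj_mol - temperature_K * delta_s_j_mol_k / 1000
}

#' Classify the dominant binding forces from thermodynamic signs
#'
#' The sign pattern of dH and dS indicates the dominant interaction:
#' positive dH and dS point to hydrophobic forces, negative dH and dS to
#' hydrogen bonding and van der Waals contacts, and near-zero dH to
#' electrostatic interactions.
#'
#' @param delta_h_kj_mol Enthalpy change (kJ mol^-1).
#' @param delta_s_j_mol_k Entropy change (J mol^-1 K^-1).
#' @param h_zero_band_kj_mol Half-width of the "very low or zero" dH band
#'   (kJ mol^-1).
#' @return One of \code{"hydrophobic"}, \code{"hbond_vdw"},
#'   \code{"electrostatic"}, \code{"mixed"}.
#' @export
classify_binding_forces <- function(delta_h_kj_mol, delta_s_j_mol_k,
                                    h_zero_band_kj_mol = 2) {
  band <- h_zero_band_kj_mol
  if (abs(delta_h_kj_mol) <= band) "electrostatic"
  else if (delta_h_kj_mol > band && delta_s_j_mol_k > 0) "hydrophobic"
  else if (delta_h_kj_mol < -band && delta_s_j_mol_k < 0) "hbond_vdw"
  else "mixed"
}
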