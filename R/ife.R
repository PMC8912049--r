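#' Interpolate absorbance at a wavelength
#'
#' Linear interpolation between the bracketing grid points; querying outside
#' the grid range is an error.
#'
#' @param spectrum An \code{\link{absorbance_spectrum}}.
#' @param wavelength_nm Query wavelength (nm), within the grid range.
#' @return Absorbance (AU) at the query wavelength.
#' @export
absorbance_at <- function(spectrum, wavelength_nm) {
  stopifnot(inherits(spectrum, "absorbance_spectrum"))
  wl <- spectrum$wavelengths_nm
  if (wavelength_nm < wl[1] || wavelength_nm > wl[length(wl)])
    stop(sprintf("wavelength %g nm outside grid range [%g, %g]",
                 wavelength_nm, wl[1], wl[length(wl)]), call. = FALSE)
  stats::approx(wl, spectrum$absorbance_au, xout = wavelength_nm)$y
}

#' Pointwise difference of two absorbance spectra
#'
#' Mixture minus reference, used to expose ligand-induced changes
#' (hyper-/hypochromism) against the free-protein baseline. Grids must be
#' identical.
#'
#' @param mixture,reference \code{\link{absorbance_spectrum}} objects on the
#'   same wavelength grid.
#' @return An \code{\link{absorbance_spectrum}} of the differences.
#' @export
difference_spectrum <- function(mixture, reference) {
  stopifnot(inherits(mixture, "absorbance_spectrum"),
            inherits(reference, "absorbance_spectrum"))
  if (length(mixture$wavelengths_nm) != length(reference$wavelengths_nm) ||
      any(mixture$wavelengths_nm != reference$wavelengths_nm))
    stop("wavelength grids differ between mixture and reference",
         call. = FALSE)
  absorbance_spectrum(mixture$wavelengths_nm,
                      mixture$absorbance_au - reference$absorbance_au,
                      label = "difference")
}

#' Classify the direction of an absorbance shift
#'
#' Given difference spectra ordered by increasing ligand concentration,
#' calls the shift at a probe wavelength hyperchromic when the difference
#' absorbance rises monotonically with concentration beyond tolerance,
#' hypochromic when it falls, and none otherwise.
#'
#' @param series_of_differences List of >= 2 \code{absorbance_spectrum}
#'   difference spectra, ordered by ligand concentration.
#' @param probe_nm Probe wavelength (nm), within all grids.
#' @param tol Absolute tolerance (AU) below which steps count as flat.
#' @return One of \code{"hyperchromic"}, \code{"hypochromic"}, \code{"none"}.
#' @export
classify_absorbance_shift <- function(series_of_differences, probe_nm,
                                      tol = 1e-4) {
  if (length(series_of_differences) < 2)
    stop("need at least 2 difference spectra", call. = FALSE)
  a <- vapply(series_of_differences, absorbance_at, numeric(1), probe_nm)
  d <- diff(a)
  if (all(d > tol)) "hyperchromic"
  else if (all(d < -tol)) "hypochromic"
  else "none"
}

#' Inner-filter-effect correction of a titration series
#'
#' Attenuation of excitation and emission light by absorbing species in the
#' cuvette deflates recorded intensities and inflates apparent quenching.
#' The standard half-path correction multiplies every recorded intensity by
#' 10^((A_ex + A_em)/2), using the sample absorbance at the excitation and
#' read-emission wavelengths stored on each titration point.
#'
#' A warning flag is set on points where A_ex + A_em > 0.3, where the
#' correction becomes sensitive to cuvette geometry; the correction is still
#' applied. Correcting an already corrected series is an error (applying the
#' factor twice would square it).
#'
#' @param series A \code{\link{titration_series}} whose points carry
#'   \code{a_ex} and \code{a_em}.
#' @return A list with elements \code{series} (the corrected series, input
#'   left unmodified) and \code{records} (a data frame with one row per
#'   point: \code{quencher_conc_M}, \code{a_ex}, \code{a_em}, \code{factor},
#'   \code{warning_flag}).
#' @export
correct_inner_filter <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  if (series$corrected)
    stop("series is already inner-filter corrected", call. = FALSE)
  recs <- lapply(seq_along(series$points), function(i) {
    p <- series$points[[i]]
    if (is.na(p$a_ex) || is.na(p$a_em))
      stop(sprintf("point %d: missing a_ex/a_em, cannot correct", i),
           call. = FALSE)
    factor <- 10^((p$a_ex + p$a_em) / 2)
    data.frame(quencher_conc_M = p$quencher_conc_M, a_ex = p$a_ex,
               a_em = p$a_em, factor = factor,
               warning_flag = (p$a_ex + p$a_em) > 0.3)
  })
  records <- do.call(rbind, recs)
  new_points <- lapply(seq_along(series$points), function(i) {
    p <- series$points[[i]]
    em <- p$emission
    titration_point(p$quencher_conc_M,
                    emission_spectrum(em$excitation_nm, em$wavelengths_nm,
                                      em$intensity_au * records$factor[i]),
                    a_ex = p$a_ex, a_em = p$a_em)
  })
  corrected <- titration_series(series$protein_conc_M, series$temperature_K,
                                series$excitation_nm, new_points,
                                marker = series$marker, corrected = TRUE)
  list(series = corrected, records = records)
}
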