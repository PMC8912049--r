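#' Construct an absorbance spectrum
#'
#' An absorbance spectrum is a wavelength grid (nm, strictly increasing)
#' paired with unitless absorbance values, as produced by a UV-vis
#' spectrophotometer.
#'
#' @param wavelengths_nm Numeric vector of wavelengths in nm, strictly
#'   increasing, length >= 2.
#' @param absorbance_au Numeric vector of absorbance values (AU), same length.
#' @param label Optional free-text label.
#' @return An object of class \code{"absorbance_spectrum"}.
#' @export
absorbance_spectrum <- function(wavelengths_nm, absorbance_au, label = "") {
  check_grid(wavelengths_nm, absorbance_au, "absorbance_au")
  structure(
    list(wavelengths_nm = as.numeric(wavelengths_nm),
         absorbance_au = as.numeric(absorbance_au),
         label = as.character(label)[1]),
    class = "absorbance_spectrum"
  )
}

#' Construct a fluorescence emission spectrum
#'
#' @param excitation_nm Excitation wavelength (nm).
#' @param wavelengths_nm Emission wavelength grid (nm), strictly increasing.
#' @param intensity_au Nonnegative emission intensities (arbitrary units).
#' @return An object of class \code{"emission_spectrum"}.
#' @export
emission_spectrum <- function(excitation_nm, wavelengths_nm, intensity_au) {
  check_grid(wavelengths_nm, intensity_au, "intensity_au")
  if (any(intensity_au < 0))
    stop("intensity_au: intensities must be >= 0", call. = FALSE)
  if (!is.numeric(excitation_nm) || length(excitation_nm) != 1 ||
      !is.finite(excitation_nm) || excitation_nm <= 0)
    stop("excitation_nm must be a single positive number", call. = FALSE)
  structure(
    list(excitation_nm = as.numeric(excitation_nm),
         wavelengths_nm = as.numeric(wavelengths_nm),
         intensity_au = as.numeric(intensity_au)),
    class = "emission_spectrum"
  )
}

#' Construct a far-UV circular dichroism spectrum
#'
#' Observed ellipticity in millidegrees over a far-UV grid, together with
#' the sample metadata (molar protein concentration, path length, residue
#' count) needed to convert to mean residue ellipticity.
#'
#' @param wavelengths_nm Wavelength grid (nm), strictly increasing.
#' @param ellipticity_mdeg Observed ellipticity (millidegrees).
#' @param protein_conc_M Molar protein concentration, > 0.
#' @param path_cm Cuvette path length in cm, > 0.
#' @param n_residues Number of amino-acid residues (585 for HSA), >= 1.
#' @return An object of class \code{"cd_spectrum"}.
#' @export
cd_spectrum <- function(wavelengths_nm, ellipticity_mdeg, protein_conc_M,
                        path_cm, n_residues) {
  check_grid(wavelengths_nm, ellipticity_mdeg, "ellipticity_mdeg")
  if (protein_conc_M <= 0) stop("protein_conc_M must be > 0", call. = FALSE)
  if (path_cm <= 0) stop("path_cm must be > 0", call. = FALSE)
  if (n_residues < 1) stop("n_residues must be >= 1", call. = FALSE)
  structure(
    list(wavelengths_nm = as.numeric(wavelengths_nm),
         ellipticity_mdeg = as.numeric(ellipticity_mdeg),
         protein_conc_M = as.numeric(protein_conc_M),
         path_cm = as.numeric(path_cm),
         n_residues = as.integer(n_residues)),
    class = "cd_spectrum"
  )
}

# Shared grid validation: equal lengths, >= 2 points, strictly increasing
# wavelengths, all finite.
check_grid <- function(wavelengths_nm, values, value_name) {
  if (length(wavelengths_nm) != length(values))
    stop(sprintf("wavelengths_nm and %s must have equal length", value_name),
         call. = FALSE)
  if (length(wavelengths_nm) < 2)
    stop("spectrum needs at least 2 points", call. = FALSE)
  if (!all(is.finite(wavelengths_nm)) || !all(is.finite(values)))
    stop(sprintf("wavelengths_nm and %s must be finite", value_name),
         call. = FALSE)
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelengths_nm must be strictly increasing", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.absorbance_spectrum <- function(x, ...) {
  cat(sprintf("Absorbance spectrum%s: %d points, %.1f-%.1f nm, max A = %.4g\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm), max(x$absorbance_au)))
  invisible(x)
}

#' @export
print.emission_spectrum <- function(x, ...) {
  i <- which.max(x$intensity_au)
  cat(sprintf(
    "Emission spectrum: ex %.0f nm, %d points, peak %.4g au at %.1f nm\n",
    x$excitation_nm, length(x$wavelengths_nm), x$intensity_au[i],
    x$wavelengths_nm[i]))
  invisible(x)
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat(sprintf(
    "CD spectrum: %d points, %.1f-%.1f nm, [P] = %.3g M, path %.3g cm, %d residues\n",
    length(x$wavelengths_nm), min(x$wavelengths_nm), max(x$wavelengths_nm),
    x$protein_conc_M, x$path_cm, x$n_residues))
  invisible(x)
}

#' Read a two-column spectrum CSV
#'
#' The on-disk format is a plain two-column CSV (wavelength_nm, value) with
#' an optional single header row. Rows are sorted by ascending wavelength on
#' load; duplicate wavelengths are an error.
#'
#' @param path File path.
#' @param kind One of \code{"absorbance"}, \code{"emission"}, \code{"cd"}.
#' @param ... Extra fields required by the kind: \code{excitation_nm} for
#'   emission; \code{protein_conc_M}, \code{path_cm}, \code{n_residues} for cd.
#' @return A spectrum object of the requested kind.
#' @export
read_spectrum_csv <- function(path, kind = c("absorbance", "emission", "cd"),
                              ...) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*[-+0-9.]", first)
  df <- utils::read.csv(path, header = has_header,
                        col.names = c("wavelength", "value"))
  if (nrow(df) < 2) stop("spectrum CSV needs at least 2 rows: ", path,
                         call. = FALSE)
  if (!is.numeric(df$wavelength) || !is.numeric(df$value) ||
      anyNA(df$wavelength) || anyNA(df$value))
    stop("non-numeric rows in spectrum CSV: ", path, call. = FALSE)
  o <- order(df$wavelength)
  df <- df[o, ]
  if (anyDuplicated(df$wavelength))
    stop("duplicate wavelengths in spectrum CSV: ", path, call. = FALSE)
  extra <- list(...)
  switch(kind,
    absorbance = absorbance_spectrum(df$wavelength, df$value,
                                     label = basename(path)),
    emission = emission_spectrum(extra$excitation_nm, df$wavelength, df$value),
    cd = cd_spectrum(df$wavelength, df$value,
                     protein_conc_M = extra$protein_conc_M,
                     path_cm = extra$path_cm,
                     n_residues = extra$n_residues)
  )
}

#' Write a spectrum to a two-column CSV
#'
#' @param x A spectrum object.
#' @param path Destination file.
#' @return Invisibly, \code{path}.
#' @export
write_spectrum_csv <- function(x, path) {
  values <- if (inherits(x, "absorbance_spectrum")) x$absorbance_au
            else if (inherits(x, "emission_spectrum")) x$intensity_au
            else if (inherits(x, "cd_spectrum")) x$ellipticity_mdeg
            else stop("not a spectrum object", call. = FALSE)
  lines <- c("wavelength_nm,value",
             sprintf("%.12g,%.12g", x$wavelengths_nm, values))
  writeLines(lines, path)
  invisible(path)
}
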