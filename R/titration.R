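#' Construct a titration point
#'
#' One point of a fluorescence titration: the quencher (ligand) molar
#' concentration, the measured emission spectrum, and the sample absorbance
#' at the excitation and read-emission wavelengths used for inner-filter
#' correction.
#'
#' @param quencher_conc_M Quencher molar concentration, >= 0.
#' @param emission An \code{\link{emission_spectrum}}.
#' @param a_ex Absorbance at the excitation wavelength (AU), >= 0.
#' @param a_em Absorbance at the read emission wavelength (AU), >= 0.
#' @return An object of class \code{"titration_point"}.
#' @export
titration_point <- function(quencher_conc_M, emission, a_ex = NA_real_,
                            a_em = NA_real_) {
  if (!inherits(emission, "emission_spectrum"))
    stop("emission must be an emission_spectrum", call. = FALSE)
  if (quencher_conc_M < 0)
    stop("quencher_conc_M must be >= 0", call. = FALSE)
  if (!is.na(a_ex) && a_ex < 0) stop("a_ex must be >= 0", call. = FALSE)
  if (!is.na(a_em) && a_em < 0) stop("a_em must be >= 0", call. = FALSE)
  structure(
    list(quencher_conc_M = as.numeric(quencher_conc_M), emission = emission,
         a_ex = as.numeric(a_ex), a_em = as.numeric(a_em)),
    class = "titration_point"
  )
}

#' Construct a fluorescence titration series
#'
#' A titration at one temperature and one excitation wavelength: a fixed
#' protein concentration with emission spectra recorded at increasing
#' quencher concentrations. The first point must have zero quencher (it
#' defines F0). Points are sorted by concentration on construction.
#'
#' @param protein_conc_M Molar protein concentration.
#' @param temperature_K Absolute temperature (K).
#' @param excitation_nm Excitation wavelength (nm).
#' @param points List of \code{\link{titration_point}} objects.
#' @param marker Optional site-marker metadata: a list with elements
#'   \code{name} (character) and \code{conc_M} (molar concentration).
#' @param corrected Logical; \code{TRUE} once inner-filter corrected.
#' @return An object of class \code{"titration_series"}.
#' @export
titration_series <- function(protein_conc_M, temperature_K, excitation_nm,
                             points, marker = NULL, corrected = FALSE) {
  if (length(points) < 1) stop("points: need at least one titration point",
                               call. = FALSE)
  if (!all(vapply(points, inherits, logical(1), "titration_point")))
    stop("points must all be titration_point objects", call. = FALSE)
  concs <- vapply(points, function(p) p$quencher_conc_M, numeric(1))
  points <- points[order(concs)]
  concs <- sort(concs)
  if (concs[1] != 0)
    stop("points: first point must have quencher_conc_M = 0 (defines F0)",
         call. = FALSE)
  if (any(diff(concs) <= 0))
    stop("points: quencher concentrations must be distinct", call. = FALSE)
  grid0 <- points[[1]]$emission$wavelengths_nm
  for (i in seq_along(points)) {
    em <- points[[i]]$emission
    if (em$excitation_nm != excitation_nm)
      stop(sprintf("points: point %d excitation_nm (%g) differs from series (%g)",
                   i, em$excitation_nm, excitation_nm), call. = FALSE)
    if (!identical(length(em$wavelengths_nm), length(grid0)) ||
        any(em$wavelengths_nm != grid0))
      stop(sprintf("points: point %d emission grid differs from point 1", i),
           call. = FALSE)
  }
  if (!is.null(marker)) {
    if (is.null(marker$name) || is.null(marker$conc_M))
      stop("marker must have elements name and conc_M", call. = FALSE)
    marker <- list(name = as.character(marker$name),
                   conc_M = as.numeric(marker$conc_M))
  }
  if (protein_conc_M <= 0) stop("protein_conc_M must be > 0", call. = FALSE)
  if (temperature_K <= 0) stop("temperature_K must be > 0", call. = FALSE)
  structure(
    list(protein_conc_M = as.numeric(protein_conc_M),
         temperature_K = as.numeric(temperature_K),
         excitation_nm = as.numeric(excitation_nm),
         points = points, marker = marker, corrected = isTRUE(corrected)),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  concs <- vapply(x$points, function(p) p$quencher_conc_M, numeric(1))
  cat(sprintf(
    "Titration series: %d points, [Q] %.3g-%.3g M, [P] = %.3g M, T = %.2f K, ex %.0f nm%s%s\n",
    length(x$points), min(concs), max(concs), x$protein_conc_M,
    x$temperature_K, x$excitation_nm,
    if (!is.null(x$marker))
      sprintf(", marker %s at %.3g M", x$marker$name, x$marker$conc_M) else "",
    if (x$corrected) " (IFE-corrected)" else ""))
  invisible(x)
}

#' Load a titration series from a manifest
#'
#' The manifest is a YAML (or JSON) file naming per-point spectrum CSVs and
#' carrying the series metadata. Concentrations may be declared in µM
#' (\code{units: conc: uM}) and temperatures in Celsius
#' (\code{units: temperature: C}); both are converted to molar / kelvin on
#' load. Points are sorted by quencher concentration.
#'
#' @param manifest_path Path to the manifest file.
#' @return A validated \code{\link{titration_series}}.
#' @export
load_titration_series <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  m <- yaml::read_yaml(manifest_path)
  dir <- dirname(manifest_path)
  conc_unit <- tolower(if (!is.null(m$units$conc)) m$units$conc else "M")
  temp_unit <- toupper(if (!is.null(m$units$temperature)) m$units$temperature
                       else "K")
  conc_scale <- switch(conc_unit, "um" = 1e-6, "m" = 1,
                       stop("unknown conc unit: ", conc_unit, call. = FALSE))
  if (is.null(m$protein_conc)) stop("manifest missing protein_conc",
                                    call. = FALSE)
  if (is.null(m$temperature)) stop("manifest missing temperature",
                                   call. = FALSE)
  if (is.null(m$excitation_nm)) stop("manifest missing excitation_nm",
                                     call. = FALSE)
  if (is.null(m$points) || length(m$points) == 0)
    stop("manifest missing points", call. = FALSE)
  temperature_K <- if (temp_unit == "C") m$temperature + 273.15
                   else m$temperature
  points <- lapply(seq_along(m$points), function(i) {
    p <- m$points[[i]]
    if (is.null(p$conc))
      stop(sprintf("points[%d]: missing conc", i), call. = FALSE)
    if (is.null(p$spectrum_file))
      stop(sprintf("points[%d]: missing spectrum_file", i), call. = FALSE)
    f <- file.path(dir, p$spectrum_file)
    if (!file.exists(f))
      stop(sprintf("points[%d]: spectrum file not found: %s", i, f),
           call. = FALSE)
    em <- read_spectrum_csv(f, kind = "emission",
                            excitation_nm = m$excitation_nm)
    titration_point(p$conc * conc_scale, em,
                    a_ex = if (is.null(p$a_ex)) NA_real_ else p$a_ex,
                    a_em = if (is.null(p$a_em)) NA_real_ else p$a_em)
  })
  marker <- if (!is.null(m$marker))
    list(name = m$marker$name, conc_M = m$marker$conc * conc_scale)
  series <- titration_series(
    protein_conc_M = m$protein_conc * conc_scale,
    temperature_K = temperature_K,
    excitation_nm = m$excitation_nm,
    points = points, marker = marker,
    corrected = isTRUE(m$corrected))
  if (length(series$points) != length(m$points))
    stop("point count changed during load", call. = FALSE)  # never silently drop
  series
}

#' Save a titration series as manifest + per-point CSVs
#'
#' Writes one emission CSV per point plus \code{manifest.yml} in
#' \code{dir_path}. Concentrations and temperature are written in molar and
#' kelvin so a save/load round trip is numerically exact to formatting
#' precision (12 significant digits).
#'
#' @param series A \code{\link{titration_series}}.
#' @param dir_path Destination directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
save_titration_series <- function(series, dir_path) {
  stopifnot(inherits(series, "titration_series"))
  if (!dir.exists(dir_path))
    dir.create(dir_path, recursive = TRUE)
  if (!dir.exists(dir_path))
    stop("cannot create directory: ", dir_path, call. = FALSE)
  num <- function(x) if (is.na(x)) NULL else as.numeric(sprintf("%.12g", x))
  pts <- lapply(seq_along(series$points), function(i) {
    p <- series$points[[i]]
    f <- sprintf("point_%02d.csv", i)
    write_spectrum_csv(p$emission, file.path(dir_path, f))
    c(list(conc = num(p$quencher_conc_M), spectrum_file = f),
      if (!is.na(p$a_ex)) list(a_ex = num(p$a_ex)),
      if (!is.na(p$a_em)) list(a_em = num(p$a_em)))
  })
  m <- c(list(
    protein_conc = num(series$protein_conc_M),
    temperature = num(series$temperature_K),
    excitation_nm = num(series$excitation_nm),
    units = list(conc = "M", temperature = "K"),
    corrected = series$corrected,
    points = pts),
    if (!is.null(series$marker))
      list(marker = list(name = series$marker$name,
                         conc = num(series$marker$conc_M))))
  manifest_path <- file.path(dir_path, "manifest.yml")
  yaml::write_yaml(m, manifest_path, precision = 12)
  invisible(manifest_path)
}
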