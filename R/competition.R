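#' Site-marker competition analysis
#'
#' Compares quenching and binding fits of a ligand titration with and
#' without a pre-bound site marker (e.g. warfarin for serum-albumin drug
#' site 1, ibuprofen for site 2). Each series is inner-filter corrected
#' (unless already corrected), fitted with the Stern-Volmer and double-log
#' models, and the relative drop of the binding constant against the
#' marker-free baseline is tabulated.
#'
#' @param baseline_series Marker-free \code{\link{titration_series}}.
#' @param marker_series List of \code{titration_series} measured in the
#'   presence of the site marker; each must carry marker metadata and share
#'   protein concentration, temperature and excitation wavelength with the
#'   baseline.
#' @param tau0_s Fluorophore lifetime for Kq (s).
#' @param displacement_threshold Relative Kb drop at the highest marker
#'   concentration that calls a shared/proximal site.
#' @return An object of class \code{"competition_table"}: \code{marker_name},
#'   \code{baseline} (list with \code{sv} and \code{binding} fits),
#'   \code{rows} (data frame: \code{marker_conc_M}, \code{ksv_M_inv},
#'   \code{kb_M_inv}, \code{n_sites}, \code{relative_change_kb}),
#'   \code{fits} (per-row fit objects), \code{assignment}.
#' @export
run_competition_analysis <- function(baseline_series, marker_series,
                                     tau0_s = 5.7e-9,
                                     displacement_threshold = 0.30) {
  stopifnot(inherits(baseline_series, "titration_series"))
  if (length(marker_series) < 1)
    stop("need at least one marker series", call. = FALSE)
  fit_one <- function(series) {
    if (!series$corrected) series <- correct_inner_filter(series)$series
    pairs <- extract_intensities(series)
    list(sv = fit_stern_volmer(pairs, tau0_s = tau0_s,
                               temperature_K = series$temperature_K,
                               excitation_nm = series$excitation_nm),
         binding = fit_double_log(pairs,
                                  temperature_K = series$temperature_K))
  }
  marker_names <- character(0)
  for (i in seq_along(marker_series)) {
    s <- marker_series[[i]]
    if (is.null(s$marker))
      stop(sprintf("marker series %d: missing marker metadata", i),
           call. = FALSE)
    if (s$protein_conc_M != baseline_series$protein_conc_M)
      stop(sprintf("marker series %d: protein_conc_M differs from baseline", i),
           call. = FALSE)
    if (s$temperature_K != baseline_series$temperature_K)
      stop(sprintf("marker series %d: temperature_K differs from baseline", i),
           call. = FALSE)
    if (s$excitation_nm != baseline_series$excitation_nm)
      stop(sprintf("marker series %d: excitation_nm differs from baseline", i),
           call. = FALSE)
    marker_names <- c(marker_names, s$marker$name)
  }
  if (length(unique(marker_names)) > 1)
    stop("all marker series must use the same marker", call. = FALSE)

  baseline <- fit_one(baseline_series)
  concs <- vapply(marker_series, function(s) s$marker$conc_M, numeric(1))
  o <- order(concs)
  marker_series <- marker_series[o]
  fits <- lapply(marker_series, fit_one)
  rows <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(
      marker_conc_M = marker_series[[i]]$marker$conc_M,
      ksv_M_inv = f$sv$ksv_M_inv,
      kb_M_inv = f$binding$kb_M_inv,
      n_sites = f$binding$n_sites,
      relative_change_kb =
        (baseline$binding$kb_M_inv - f$binding$kb_M_inv) /
        baseline$binding$kb_M_inv)
  }))
  tab <- structure(
    list(marker_name = marker_names[1], baseline = baseline, rows = rows,
         fits = fits, assignment = NA_character_),
    class = "competition_table")
  tab$assignment <- assign_binding_site(tab, displacement_threshold)
  tab
}

#' Assign the ligand binding site from a competition table
#'
#' \code{"shared_or_proximal"} when the relative Kb drop at the highest
#' marker concentration reaches the displacement threshold (inclusive);
#' \code{"independent"} when every absolute relative change stays below it;
#' \code{"inconclusive"} otherwise (mixed or non-monotone displacement).
#'
#' @param table A \code{\link{run_competition_analysis}} result.
#' @param displacement_threshold Relative Kb change threshold.
#' @return The assignment string.
#' @export
assign_binding_site <- function(table, displacement_threshold = 0.30) {
  stopifnot(inherits(table, "competition_table"))
  rc <- table$rows$relative_change_kb
  if (length(rc) < 1) stop("competition table has no rows", call. = FALSE)
  if (rc[length(rc)] >= displacement_threshold) "shared_or_proximal"
  else if (all(abs(rc) < displacement_threshold)) "independent"
  else "inconclusive"
}

#' @export
print.competition_table <- function(x, ...) {
  cat(sprintf("Site-marker competition: %s\n", x$marker_name))
  cat(sprintf("  baseline: Ksv = %.4g M^-1, Kb = %.4g M^-1, n = %.3f\n",
              x$baseline$sv$ksv_M_inv, x$baseline$binding$kb_M_inv,
              x$baseline$binding$n_sites))
  print(x$rows, row.names = FALSE)
  cat(sprintf("  assignment: %s\n", x$assignment))
  invisible(x)
}
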