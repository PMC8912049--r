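#' Ground truth for the synthetic titration generator
#'
#' Collects the true parameter values a simulated titration is generated
#' from, so downstream fits can be checked against a known answer.
#'
#' @param ksv_M_inv True Stern-Volmer constant (M^-1), >= 0.
#' @param kb_M_inv True binding constant (M^-1), >= 0.
#' @param n_sites True binding-site exponent, > 0.
#' @param f0_peak_au Unquenched peak intensity (arbitrary units).
#' @param noise_sd_au Additive Gaussian noise standard deviation (au).
#' @param ife_enabled Apply the inner-filter attenuation to recorded
#'   intensities?
#' @param seed Integer RNG seed.
#' @return An object of class \code{"ground_truth"}.
#' @export
ground_truth <- function(ksv_M_inv = 430, kb_M_inv = 820, n_sites = 1.1,
                         f0_peak_au = 1000, noise_sd_au = 0,
                         ife_enabled = FALSE, seed = 1L) {
  if (ksv_M_inv < 0) stop("ksv_M_inv must be >= 0", call. = FALSE)
  if (kb_M_inv < 0) stop("kb_M_inv must be >= 0", call. = FALSE)
  if (n_sites <= 0) stop("n_sites must be > 0", call. = FALSE)
  if (noise_sd_au < 0) stop("noise_sd_au must be >= 0", call. = FALSE)
  structure(
    list(ksv_M_inv = ksv_M_inv, kb_M_inv = kb_M_inv, n_sites = n_sites,
         f0_peak_au = f0_peak_au, noise_sd_au = noise_sd_au,
         ife_enabled = isTRUE(ife_enabled), seed = as.integer(seed)),
    class = "ground_truth"
  )
}

#' Default gemcitabine-like absorbance bands
#'
#' Two Gaussian bands reproducing the qualitative shape of the drug's UV
#' spectrum: strong absorption from 200-280 nm falling to negligible values
#' past 300 nm. Amplitudes are molar absorptivities (M^-1 cm^-1) scaled so
#' 100 uM gives A of about 1 at the 268 nm maximum.
#'
#' @return A list of bands, each \code{list(center_nm, width_nm,
#'   molar_absorptivity)}.
#' @export
gemcitabine_bands <- function() {
  list(list(center_nm = 232, width_nm = 12, molar_absorptivity = 9000),
       list(center_nm = 268, width_nm = 13, molar_absorptivity = 10000))
}

#' Simulate a ligand absorbance spectrum
#'
#' Beer-Lambert model: absorbance is concentration times a sum of Gaussian
#' bands, hence exactly linear in concentration.
#'
#' @param conc_M Molar ligand concentration, >= 0.
#' @param band_params List of bands as in \code{\link{gemcitabine_bands}}.
#' @param wavelengths_nm Output grid (nm).
#' @return An \code{\link{absorbance_spectrum}}.
#' @export
simulate_ligand_absorbance <- function(conc_M,
                                       band_params = gemcitabine_bands(),
                                       wavelengths_nm = seq(200, 400, by = 1)) {
  if (conc_M < 0) stop("conc_M must be >= 0", call. = FALSE)
  a <- ligand_epsilon(wavelengths_nm, band_params) * conc_M
  absorbance_spectrum(wavelengths_nm, a,
                      label = sprintf("ligand %.3g M", conc_M))
}

# Molar absorptivity (M^-1 cm^-1) of the band model at given wavelengths.
ligand_epsilon <- function(wavelengths_nm, band_params) {
  eps <- numeric(length(wavelengths_nm))
  for (b in band_params) {
    if (b$width_nm <= 0) stop("band width_nm must be > 0", call. = FALSE)
    eps <- eps + b$molar_absorptivity *
      exp(-(wavelengths_nm - b$center_nm)^2 / (2 * b$width_nm^2))
  }
  eps
}

# Tryptophan-like emission band: unimodal Gaussian peaked at 340 nm.
emission_band_shape <- function(wavelengths_nm, peak_nm = 340, sd_nm = 12) {
  exp(-(wavelengths_nm - peak_nm)^2 / (2 * sd_nm^2))
}

#' Simulate a fluorescence emission titration
#'
#' Generates a full titration series with known ground truth. The true
#' (pre-artifact) peak intensity follows the chosen quenching model:
#' \code{"stern_volmer"} gives F = F0 / (1 + Ksv[Q]); \code{"double_log"}
#' gives (F0 - F)/F = Kb[Q]^n, i.e. F = F0 / (1 + Kb[Q]^n). If
#' \code{gt$ife_enabled}, recorded intensities are attenuated by
#' 10^(-(A_ex + A_em)/2) with absorbances from the ligand band model, and
#' those absorbances are stored on each point. Additive Gaussian noise
#' (sd \code{gt$noise_sd_au}, truncated at zero) is applied last.
#'
#' @param gt A \code{\link{ground_truth}}.
#' @param quencher_concs_M Increasing molar concentrations starting at 0.
#' @param excitation_nm Excitation wavelength (nm).
#' @param model Generating model, \code{"stern_volmer"} or
#'   \code{"double_log"}.
#' @param band_params Ligand absorbance bands (for the inner-filter
#'   artifact).
#' @param protein_conc_M Protein concentration stamped on the series.
#' @param temperature_K Temperature stamped on the series.
#' @param emission_grid_nm Emission wavelength grid.
#' @param marker Optional marker metadata passed through to the series.
#' @return A \code{\link{titration_series}}.
#' @export
simulate_emission_titration <- function(gt, quencher_concs_M,
                                        excitation_nm = 295,
                                        model = c("stern_volmer",
                                                  "double_log"),
                                        band_params = gemcitabine_bands(),
                                        protein_conc_M = 3e-6,
                                        temperature_K = 293.15,
                                        emission_grid_nm = seq(300, 450,
                                                               by = 1),
                                        marker = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  model <- match.arg(model)
  q <- as.numeric(quencher_concs_M)
  if (q[1] != 0) stop("first quencher concentration must be 0", call. = FALSE)
  if (any(diff(q) <= 0)) stop("quencher concentrations must be increasing",
                              call. = FALSE)
  shape <- emission_band_shape(emission_grid_nm)
  read_nm <- 340
  set.seed(gt$seed)
  points <- lapply(q, function(conc) {
    f_peak <- switch(model,
      stern_volmer = gt$f0_peak_au / (1 + gt$ksv_M_inv * conc),
      double_log = gt$f0_peak_au / (1 + gt$kb_M_inv * conc^gt$n_sites))
    a_ex <- ligand_epsilon(excitation_nm, band_params) * conc
    a_em <- ligand_epsilon(read_nm, band_params) * conc
    intens <- f_peak * shape
    if (gt$ife_enabled) intens <- intens * 10^(-(a_ex + a_em) / 2)
    if (gt$noise_sd_au > 0)
      intens <- pmax(0, intens + stats::rnorm(length(intens),
                                              sd = gt$noise_sd_au))
    titration_point(conc,
                    emission_spectrum(excitation_nm, emission_grid_nm, intens),
                    a_ex = a_ex, a_em = a_em)
  })
  titration_series(protein_conc_M, temperature_K, excitation_nm, points,
                   marker = marker)
}

#' Simulate titrations across temperatures
#'
#' One titration series per temperature, each generated from its own ground
#' truth, for quenching-mechanism and van't Hoff analyses.
#'
#' @param gt_per_T Named list mapping temperature (K, as names) to
#'   \code{\link{ground_truth}} objects; at least 2 distinct temperatures.
#' @param quencher_concs_M Concentration design shared by all series.
#' @param excitation_nm Excitation wavelength.
#' @param model Generating model (see
#'   \code{\link{simulate_emission_titration}}).
#' @param ... Further arguments passed to
#'   \code{\link{simulate_emission_titration}}.
#' @return A list of \code{\link{titration_series}}, one per temperature.
#' @export
simulate_temperature_series <- function(gt_per_T, quencher_concs_M,
                                        excitation_nm = 295,
                                        model = "stern_volmer", ...) {
  temps <- as.numeric(names(gt_per_T))
  if (length(temps) < 2)
    stop("need at least 2 temperatures", call. = FALSE)
  if (anyNA(temps)) stop("gt_per_T names must be numeric temperatures (K)",
                         call. = FALSE)
  if (anyDuplicated(temps)) stop("duplicate temperatures", call. = FALSE)
  lapply(seq_along(temps), function(i)
    simulate_emission_titration(gt_per_T[[i]], quencher_concs_M,
                                excitation_nm = excitation_nm, model = model,
                                temperature_K = temps[i], ...))
}

# CD basis spectra in mean-residue-ellipticity units (deg cm^2 dmol^-1).
# Both bases are pinned exactly at 208 nm (helix -33000, coil -4000), the
# anchors of estimate_helicity, so a fraction-weighted mixture has a 208 nm
# MRE exactly linear in helix fraction.
cd_helix_basis <- function(wl) {
  b222 <- -30000 * exp(-(wl - 222)^2 / (2 * 7^2))
  at208 <- -30000 * exp(-(208 - 222)^2 / (2 * 7^2))
  b208 <- (-33000 - at208) * exp(-(wl - 208)^2 / (2 * 6^2))
  b208 + b222
}

cd_coil_basis <- function(wl) {
  scale <- -4000 / exp(-(208 - 198)^2 / (2 * 9^2))
  scale * exp(-(wl - 198)^2 / (2 * 9^2))
}

#' Simulate a far-UV CD spectrum with known helicity
#'
#' Ellipticity is a helix-fraction-weighted mixture of an alpha-helix basis
#' (negative minima at 208 and 222 nm) and a disordered-coil basis, scaled
#' so that \code{\link{estimate_helicity}} applied to the noiseless output
#' returns the input fraction exactly.
#'
#' @param helix_fraction Alpha-helix fraction in [0, 1].
#' @param protein_conc_M Molar protein concentration.
#' @param path_cm Path length (cm).
#' @param n_residues Residue count.
#' @param noise_sd_mdeg Additive Gaussian noise sd (millidegrees).
#' @param seed Integer RNG seed.
#' @param wavelengths_nm Output grid (nm), must cover 208 nm.
#' @return A \code{\link{cd_spectrum}}.
#' @export
simulate_cd_spectrum <- function(helix_fraction, protein_conc_M = 3e-6,
                                 path_cm = 0.1, n_residues = 585,
                                 noise_sd_mdeg = 0, seed = 1L,
                                 wavelengths_nm = seq(200, 250, by = 0.5)) {
  if (helix_fraction < 0 || helix_fraction > 1)
    stop("helix_fraction must be in [0, 1]", call. = FALSE)
  mre <- helix_fraction * cd_helix_basis(wavelengths_nm) +
    (1 - helix_fraction) * cd_coil_basis(wavelengths_nm)
  theta <- mre * 10 * protein_conc_M * path_cm * n_residues
  if (noise_sd_mdeg > 0) {
    set.seed(seed)
    theta <- theta + stats::rnorm(length(theta), sd = noise_sd_mdeg)
  }
  cd_spectrum(wavelengths_nm, theta, protein_conc_M, path_cm, n_residues)
}
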