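test_that("spectrum constructors enforce grid invariants", {
  expect_s3_class(absorbance_spectrum(200:210, rep(0.1, 11)),
                  "absorbance_spectrum")
  expect_error(absorbance_spectrum(200:210, rep(0.1, 10)), "equal length")
  expect_error(absorbance_spectrum(c(200, 200, 201), rep(0.1, 3)),
               "strictly increasing")
  expect_error(absorbance_spectrum(c(210, 205, 200), rep(0.1, 3)),
               "strictly increasing")
  expect_error(absorbance_spectrum(200, 0.1), "at least 2")
  expect_error(absorbance_spectrum(c(200, 210), c(0.1, NA)), "finite")
  expect_error(emission_spectrum(295, 300:310, c(rep(1, 10), -1)), ">= 0")
  expect_error(cd_spectrum(200:250, rep(-1, 51), protein_conc_M = 0,
                           path_cm = 0.1, n_residues = 585), "> 0")
  expect_error(cd_spectrum(200:250, rep(-1, 51), protein_conc_M = 3e-6,
                           path_cm = -1, n_residues = 585), "> 0")
})

test_that("spectrum CSV reader validates and normalizes", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,value", "200,0.5", "210,0.3", "220,0.1"), f)
  sp <- read_spectrum_csv(f, "absorbance")
  expect_equal(sp$wavelengths_nm, c(200, 210, 220))
  expect_equal(sp$absorbance_au, c(0.5, 0.3, 0.1))

  # headerless and descending files load the same, sorted ascending
  writeLines(c("220,0.1", "210,0.3", "200,0.5"), f)
  sp2 <- read_spectrum_csv(f, "absorbance")
  expect_equal(sp2$wavelengths_nm, sp$wavelengths_nm)
  expect_equal(sp2$absorbance_au, sp$absorbance_au)

  writeLines(c("200,0.5", "200,0.3", "220,0.1"), f)
  expect_error(read_spectrum_csv(f, "absorbance"), "duplicate")
  writeLines("200,0.5", f)
  expect_error(read_spectrum_csv(f, "absorbance"), "at least 2")
  writeLines(c("200,0.5", "oops,0.3"), f)
  expect_error(read_spectrum_csv(f, "absorbance"), "non-numeric")
})

test_that("titration series sorts points and enforces the F0 anchor", {
  em <- function() emission_spectrum(295, 300:400, rep(1, 101))
  pts <- lapply(c(100e-6, 0, 50e-6), titration_point, emission = em())
  s <- titration_series(3e-6, 293.15, 295, pts)
  expect_equal(vapply(s$points, function(p) p$quencher_conc_M, numeric(1)),
               c(0, 50e-6, 100e-6))

  expect_error(titration_series(3e-6, 293.15, 295,
                                list(titration_point(10e-6, em()))),
               "quencher_conc_M = 0")
  pts2 <- list(titration_point(0, em()),
               titration_point(10e-6,
                               emission_spectrum(295, 300:410, rep(1, 111))))
  expect_error(titration_series(3e-6, 293.15, 295, pts2), "grid differs")
  pts3 <- list(titration_point(0, em()),
               titration_point(10e-6, emission_spectrum(280, 300:400,
                                                        rep(1, 101))))
  expect_error(titration_series(3e-6, 293.15, 295, pts3), "excitation_nm")
})

test_that("manifest save/load round trip preserves all numeric fields", {
  series <- sim_series(ksv_M_inv = 430, noise_sd_au = 0.5, seed = 3,
                       ife_enabled = TRUE)
  series$marker <- list(name = "warfarin", conc_M = 1e-5)
  d <- withr::local_tempdir()
  mp <- save_titration_series(series, d)
  back <- load_titration_series(mp)

  expect_equal(back$protein_conc_M, series$protein_conc_M, tolerance = 1e-9)
  expect_equal(back$temperature_K, series$temperature_K, tolerance = 1e-9)
  expect_equal(back$excitation_nm, series$excitation_nm)
  expect_equal(length(back$points), length(series$points))
  expect_equal(back$marker$name, "warfarin")
  expect_equal(back$marker$conc_M, 1e-5, tolerance = 1e-9)
  for (i in seq_along(series$points)) {
    expect_equal(back$points[[i]]$quencher_conc_M,
                 series$points[[i]]$quencher_conc_M, tolerance = 1e-9)
    expect_equal(back$points[[i]]$a_ex, series$points[[i]]$a_ex,
                 tolerance = 1e-9)
    expect_equal(back$points[[i]]$emission$intensity_au,
                 series$points[[i]]$emission$intensity_au, tolerance = 1e-9)
  }

  # save -> load -> save is byte-identical under the fixed numeric format
  d2 <- withr::local_tempdir()
  mp2 <- save_titration_series(back, d2)
  expect_identical(readLines(mp), readLines(mp2))
  for (f in list.files(d, pattern = "csv$"))
    expect_identical(readLines(file.path(d, f)), readLines(file.path(d2, f)))
})

test_that("manifests convert declared uM/Celsius units on load", {
  d <- withr::local_tempdir()
  for (i in 1:3)
    writeLines(c("wavelength_nm,value", "300,1", "340,5", "400,1"),
               file.path(d, sprintf("p%d.csv", i)))
  yaml::write_yaml(list(
    protein_conc = 3, temperature = 20, excitation_nm = 295,
    units = list(conc = "uM", temperature = "C"),
    points = list(
      list(conc = 200, spectrum_file = "p3.csv"),  # out of order on purpose
      list(conc = 0, spectrum_file = "p1.csv"),
      list(conc = 100, spectrum_file = "p2.csv"))),
    file.path(d, "m.yml"))
  s <- load_titration_series(file.path(d, "m.yml"))
  expect_equal(s$protein_conc_M, 3e-6)
  expect_equal(s$temperature_K, 293.15)
  expect_equal(vapply(s$points, function(p) p$quencher_conc_M, numeric(1)),
               c(0, 1e-4, 2e-4))
})

test_that("manifest loader names the offending field on errors", {
  d <- withr::local_tempdir()
  writeLines(c("300,1", "340,5", "400,1"), file.path(d, "p1.csv"))
  yaml::write_yaml(list(
    protein_conc = 3e-6, temperature = 293.15, excitation_nm = 295,
    points = list(list(conc = 0, spectrum_file = "p1.csv"),
                  list(conc = 1e-5, spectrum_file = "missing.csv"))),
    file.path(d, "m.yml"))
  expect_error(load_titration_series(file.path(d, "m.yml")),
               "points\\[2\\].*missing.csv")
  expect_error(load_titration_series(file.path(d, "nothere.yml")),
               "manifest not found")

  writeLines(c("300,1", "350,5", "400,1"), file.path(d, "p2.csv"))
  yaml::write_yaml(list(
    protein_conc = 3e-6, temperature = 293.15, excitation_nm = 295,
    points = list(list(conc = 0, spectrum_file = "p1.csv"),
                  list(conc = 1e-5, spectrum_file = "p2.csv"))),
    file.path(d, "m2.yml"))
  expect_error(load_titration_series(file.path(d, "m2.yml")), "grid differs")
})
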