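test_that("intensity extraction reads the F0 peak by default", {
  s <- sim_series(ksv_M_inv = 430)
  p <- extract_intensities(s)
  expect_equal(attr(p, "read_nm"), 340)
  expect_equal(p$conc_M[1], 0)
  expect_equal(nrow(p), length(study_concs))

  p350 <- extract_intensities(s, read_nm = 350)
  shape <- exp(-(350 - 340)^2 / (2 * 12^2)) / 1  # band shape ratio
  expect_equal(p350$F, p$F * shape, tolerance = 1e-9)
  expect_error(extract_intensities(s, read_nm = 600), "outside")

  # negative quenching (F > F0) passes through unclipped
  em0 <- emission_spectrum(295, 300:400, rep(100, 101))
  em1 <- emission_spectrum(295, 300:400, rep(120, 101))
  s2 <- titration_series(3e-6, 293.15, 295,
                         list(titration_point(0, em0),
                              titration_point(1e-5, em1)))
  expect_equal(extract_intensities(s2)$F, c(100, 120))
})

test_that("integrated-area mode scales with the band area", {
  s <- sim_series(ksv_M_inv = 430)
  peak <- extract_intensities(s)
  area <- extract_intensities(s, integrate = TRUE)
  # same quenching ratios whichever readout is used (shape is conc-invariant)
  expect_equal(area$F / area$F[1], peak$F / peak$F[1], tolerance = 1e-9)
  expect_gt(area$F[1], peak$F[1])  # area across a >1 nm-wide band
})

test_that("Stern-Volmer fit recovers exact synthetic constants", {
  fit <- fit_stern_volmer(sv_pairs(430))
  expect_equal(fit$ksv_M_inv, 430, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$kq_M_inv_s_inv, 430 / 5.7e-9, tolerance = 1e-12)
  # Kq * tau0 == Ksv identity to machine precision
  expect_equal(fit$kq_M_inv_s_inv * fit$tau0_s, fit$ksv_M_inv,
               tolerance = 1e-15)

  flat <- fit_stern_volmer(data.frame(conc_M = c(0, 1e-5, 2e-5),
                                      F = c(500, 500, 500)))
  expect_equal(flat$ksv_M_inv, 0, tolerance = 1e-8)

  expect_error(fit_stern_volmer(sv_pairs(430)[1:2, ]), "at least 3")
  bad <- sv_pairs(430); bad$F[3] <- 0
  expect_error(fit_stern_volmer(bad), "> 0")
  noF0 <- sv_pairs(430)[-1, ]
  expect_error(fit_stern_volmer(noF0), "\\[Q\\] = 0")
})

test_that("fixed-one intercept mode constrains the line through (0, 1)", {
  pairs <- sv_pairs(430)
  pairs$F <- pairs$F * c(1, 1.01, 0.99, 1.005, 0.995)  # mild scatter
  free <- suppressWarnings(fit_stern_volmer(pairs))
  fixed <- fit_stern_volmer(pairs, intercept_mode = "fixed_one")
  expect_equal(fixed$intercept, 1)
  expect_false(isTRUE(all.equal(free$intercept, 1)))
  # constrained slope equals the analytic through-origin OLS on (x, y-1)
  y <- pairs$F[1] / pairs$F - 1
  x <- pairs$conc_M
  expect_equal(fixed$ksv_M_inv, sum(x * y) / sum(x^2), tolerance = 1e-12)
})

test_that("free-intercept fits flag intercepts deviating from 1 by > 5%", {
  pairs <- sv_pairs(430)
  pairs$F[-1] <- pairs$F[-1] * 0.8  # shifts the ratio intercept up ~10%
  expect_warning(fit_stern_volmer(pairs), "deviates")
  expect_silent(fit_stern_volmer(sv_pairs(430)))
})

test_that("OLS matches the brute-force grid-search oracle", {
  set.seed(42)
  for (rep in 1:4) {
    n <- sample(4:6, 1)
    x <- sort(c(0, runif(n - 1, 1e-6, 3e-4)))
    f0 <- 1000
    F <- f0 / (1 + 450 * x) + c(0, rnorm(n - 1, sd = 3))
    F[1] <- f0
    pairs <- data.frame(conc_M = x, F = F)
    fit <- suppressWarnings(fit_stern_volmer(pairs))
    oracle <- ols_grid_oracle(x, f0 / F)
    expect_equal(fit$ksv_M_inv, unname(oracle["b"]),
                 tolerance = 1e-6)
    expect_equal(fit$intercept, unname(oracle["a"]), tolerance = 1e-6)
  }
  # and for the double-log regression on its log-log design
  pairs <- dl_pairs(820, 1.1)
  pairs$F[-1] <- pairs$F[-1] + rnorm(10, sd = 0.5)
  pairs <- pairs[c(1:6), ]
  fit <- fit_double_log(pairs)
  oracle <- ols_grid_oracle(fit$data$log_conc, fit$data$log_ratio)
  expect_equal(log10(fit$kb_M_inv), unname(oracle["a"]), tolerance = 1e-6)
  expect_equal(fit$n_sites, unname(oracle["b"]), tolerance = 1e-6)
})

test_that("adding an exactly consistent point leaves the fit unchanged", {
  pairs <- sv_pairs(430)
  fit1 <- fit_stern_volmer(pairs)
  extra <- data.frame(conc_M = 3e-4, F = 1000 / (1 + 430 * 3e-4))
  fit2 <- fit_stern_volmer(rbind(pairs, extra))
  expect_equal(fit2$ksv_M_inv, fit1$ksv_M_inv, tolerance = 1e-8)
})

test_that("quenching mechanism classification covers all branches", {
  mk <- function(ksv, T) {
    f <- fit_stern_volmer(sv_pairs(ksv), temperature_K = T)
    f
  }
  # the dynamic pattern: Ksv rising with temperature, Kq ~ 1e10-1e11
  temps <- c(293.15, 303.15, 313.15, 323.15)
  dyn <- classify_mechanism(Map(mk, c(430, 450, 580, 590), temps))
  expect_equal(dyn$label, "dynamic")
  expect_equal(dyn$ksv_trend, 1L)
  expect_equal(dyn$kq_magnitude_ratio, 590 / 5.7e-9 / 1e10,
               tolerance = 1e-9)

  sta <- classify_mechanism(Map(mk, c(600, 500, 400), temps[1:3]))
  expect_equal(sta$label, "static")
  expect_equal(sta$ksv_trend, -1L)

  ind <- classify_mechanism(Map(mk, c(500, 700, 600), temps[1:3]))
  expect_equal(ind$label, "indeterminate")
  expect_equal(ind$ksv_trend, 0L)

  # a rising trend but enormous Kq still reads static
  huge <- Map(function(k, T) fit_stern_volmer(sv_pairs(k), tau0_s = 1e-13,
                                              temperature_K = T),
              c(430, 450, 580), temps[1:3])
  expect_equal(classify_mechanism(huge)$label, "static")

  # a tie within 2% does not break the dynamic call
  tied <- classify_mechanism(Map(mk, c(430, 429, 580), temps[1:3]))
  expect_equal(tied$label, "dynamic")

  expect_error(classify_mechanism(Map(mk, c(430, 450), temps[1:2])),
               ">= 3")
  expect_error(classify_mechanism(Map(mk, c(1, 2, 3),
                                      c(293.15, 293.15, 303.15))),
               "distinct")
})

test_that("double-log fit recovers (Kb, n) exactly on constructed data", {
  f1 <- fit_double_log(dl_pairs(820, 1))
  expect_equal(f1$kb_M_inv, 820, tolerance = 1e-6)
  expect_equal(f1$n_sites, 1, tolerance = 1e-6)
  expect_equal(f1$r_squared, 1, tolerance = 1e-9)

  f2 <- fit_double_log(dl_pairs(820, 1.1))
  expect_equal(f2$kb_M_inv, 820, tolerance = 1e-6)
  expect_equal(f2$n_sites, 1.1, tolerance = 1e-6)
})

test_that("unusable double-log points are excluded and reported, not clamped", {
  pairs <- dl_pairs(820, 1)
  pairs$F[2] <- pairs$F[1] + 5   # F > F0: log undefined
  pairs$F[3] <- pairs$F[1]       # F == F0: log undefined
  fit <- fit_double_log(pairs)
  expect_equal(nrow(fit$excluded), 2)
  expect_equal(fit$excluded$conc_M, pairs$conc_M[2:3])
  expect_equal(nrow(fit$data), nrow(pairs) - 3)

  few <- dl_pairs(820, 1, concs = c(0, 1e-5, 2e-5, 3e-5))
  few$F[2:3] <- few$F[1]
  expect_error(fit_double_log(few), "usable")
  expect_error(fit_double_log(dl_pairs(820, 1)[-1, ]), "\\[Q\\] = 0")
})

test_that("cooperativity classification brackets n = 1", {
  expect_equal(classify_cooperativity(1.1), "cooperative")
  expect_equal(classify_cooperativity(1.00), "independent")
  expect_equal(classify_cooperativity(0.8), "anticooperative")
  expect_equal(classify_cooperativity(1.04), "independent")
  expect_equal(classify_cooperativity(fit_double_log(dl_pairs(820, 1.1))),
               "cooperative")
})

test_that("replicate-scale noisy series recover Kb within 15%", {
  errs <- vapply(1:20, function(s) {
    gt <- ground_truth(kb_M_inv = 820, n_sites = 1.1,
                       noise_sd_au = replicate_noise_au, ife_enabled = TRUE,
                       seed = s)
    ser <- simulate_emission_titration(gt, study_concs,
                                       model = "double_log")
    fit <- fit_double_log(
      extract_intensities(correct_inner_filter(ser)$series))
    abs(fit$kb_M_inv - 820) / 820
  }, numeric(1))
  expect_lt(stats::median(errs), 0.15)
})
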