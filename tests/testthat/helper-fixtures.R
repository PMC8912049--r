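# Shared fixtures and independent oracles for the test suite.

# Brute-force OLS oracle: minimizes the residual sum of squares of
# y ~ a + b x by iterative grid refinement, independent of lm(). The search
# runs on centered x (y ~ c + b (x - xbar)), where the two parameters are
# orthogonal and the quadratic SSE valley is axis-aligned, so grid zooming
# converges; the intercept is mapped back as a = c - b xbar.
ols_grid_oracle <- function(x, y, n_zoom = 80, grid_n = 15) {
  xbar <- mean(x)
  xc <- x - xbar
  b0 <- (max(y) - min(y)) / (max(x) - min(x))
  best <- c(c = mean(y), b = 0)
  c_half <- diff(range(y)) + 1
  b_half <- 2 * abs(b0) + 1
  for (k in seq_len(n_zoom)) {
    cs <- seq(best["c"] - c_half, best["c"] + c_half, length.out = grid_n)
    bs <- seq(best["b"] - b_half, best["b"] + b_half, length.out = grid_n)
    sse <- outer(cs, bs, function(cc, bb)
      vapply(seq_along(cc), function(i)
        sum((y - cc[i] - bb[i] * xc)^2), numeric(1)))
    idx <- arrayInd(which.min(sse), dim(sse))
    best <- c(c = cs[idx[1]], b = bs[idx[2]])
    c_half <- c_half * 2.2 / (grid_n - 1)
    b_half <- b_half * 2.2 / (grid_n - 1)
  }
  c(a = unname(best["c"] - best["b"] * xbar), b = unname(best["b"]))
}

# Exact Stern-Volmer intensity pairs: F0/F = 1 + ksv [Q].
sv_pairs <- function(ksv, concs = c(0, 50, 100, 150, 200) * 1e-6,
                     f0 = 1000) {
  data.frame(conc_M = concs, F = f0 / (1 + ksv * concs))
}

# Exact double-log intensity pairs: (F0 - F)/F = kb [Q]^n.
dl_pairs <- function(kb, n = 1, concs = seq(0, 200e-6, by = 20e-6),
                     f0 = 1000) {
  data.frame(conc_M = concs, F = f0 / (1 + kb * concs^n))
}

# The titration design used throughout: 0-200 uM in 20 uM steps (11 points).
study_concs <- seq(0, 200e-6, by = 20e-6)

# Intensity noise level reproducing the replicate-to-replicate binding
# constant spread seen in repeated titrations (a few percent cv on Kb).
replicate_noise_au <- 0.05

# Quick synthetic series wrapper.
sim_series <- function(..., concs = study_concs) {
  simulate_emission_titration(ground_truth(...), concs)
}
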