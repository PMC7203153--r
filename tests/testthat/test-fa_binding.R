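make_conc <- function() c(0, 10^seq(0, log10(1500), length.out = 12))

test_that("blank correction subtracts channel-wise, floors and invalidates", {
  pts <- data.frame(I_par = c(10, 5, 1), I_perp = c(6, 4, 1),
                    blank_par = c(2, 0, 3), blank_perp = c(2, 0, 3))
  cc <- blank_correct(pts)
  expect_equal(cc$I_par, c(8, 5, 0))
  expect_equal(cc$I_perp, c(4, 4, 0))
  expect_equal(cc$valid, c(TRUE, TRUE, FALSE))
  expect_error(blank_correct(data.frame(I_par = -1, I_perp = 0,
                                        blank_par = 0, blank_perp = 0)),
               "non-negative")
})

test_that("anisotropy formula hits its analytic extremes and scale invariance", {
  expect_equal(compute_anisotropy(1, 1), 0)
  expect_equal(compute_anisotropy(2, 1), 0.25)
  expect_equal(compute_anisotropy(1, 0), 1)
  expect_equal(compute_anisotropy(0, 1), -0.5)
  expect_true(is.na(compute_anisotropy(0, 0)))
  # invariant under common scaling of both channels
  set.seed(3)
  for (i in 1:20) {
    ip <- runif(1, 0.1, 5); iq <- runif(1, 0.1, 5); c0 <- runif(1, 0.1, 10)
    expect_equal(compute_anisotropy(c0 * ip, c0 * iq),
                 compute_anisotropy(ip, iq), tolerance = 1e-12)
  }
  # G factor rebalances the perpendicular channel
  expect_equal(compute_anisotropy(2, 1, g_factor = 2), 0)
})

test_that("baseline transform shifts min to zero, preserves shape, idempotent", {
  cv <- anisotropy_curve("p", c(0, 10, 100), c(0.05, 0.05, 0.09))
  tr <- baseline_transform(cv)
  expect_equal(tr$r, c(0, 0, 0.04))
  expect_true(tr$transformed)
  expect_equal(diff(tr$r), diff(cv$r))
  expect_equal(baseline_transform(tr)$r, tr$r)
})

test_that("noiseless 4PL curves are recovered to 1e-6 with R^2 = 1", {
  conc <- make_conc()
  truth <- list(y0 = 0.01, bmax = 0.05, kd = 500, h = 1)
  y <- truth$y0 + truth$bmax / (1 + (truth$kd / pmax(conc, 1e-300))^truth$h)
  y[conc == 0] <- truth$y0
  fit <- fit_4pl(anisotropy_curve("p", conc, y))
  expect_equal(fit$y0, truth$y0, tolerance = 1e-6)
  expect_equal(fit$bmax, truth$bmax, tolerance = 1e-6)
  expect_equal(fit$kd_uM, truth$kd, tolerance = 1e-6)
  expect_equal(fit$hill, truth$h, tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-10)
  expect_true(fit$reliable)
  # half-saturation: at c = K_D the response sits at y0 + B_max/2 (any h)
  for (h in c(0.7, 1, 2)) {
    yh <- truth$y0 + truth$bmax / (1 + (truth$kd / pmax(conc, 1e-300))^h)
    yh[conc == 0] <- truth$y0
    at_kd <- truth$y0 + truth$bmax /
      (1 + (truth$kd / truth$kd)^h)
    expect_equal(at_kd, truth$y0 + truth$bmax / 2)
    fith <- fit_4pl(anisotropy_curve("p", conc, yh))
    expect_equal(fith$hill, h, tolerance = 1e-5)
  }
})

test_that("fitted K_D is invariant to scaling and shifting anisotropies", {
  conc <- make_conc()
  y <- 0.02 + 0.05 / (1 + (400 / pmax(conc, 1e-300)))
  y[conc == 0] <- 0.02
  base <- fit_4pl(anisotropy_curve("p", conc, y))
  shifted <- fit_4pl(anisotropy_curve("p", conc, y - min(y)))
  scaled <- fit_4pl(anisotropy_curve("p", conc, y * 3))
  expect_equal(shifted$kd_uM, base$kd_uM, tolerance = 1e-6)
  expect_equal(scaled$kd_uM, base$kd_uM, tolerance = 1e-6)
  expect_equal(scaled$bmax, 3 * base$bmax, tolerance = 1e-6)
})

test_that("binding potential equals the numeric initial slope for h = 1", {
  conc <- make_conc()
  y <- 0.01 + 0.05 / (1 + (500 / pmax(conc, 1e-300)))
  y[conc == 0] <- 0.01
  fit <- fit_4pl(anisotropy_curve("p", conc, y))
  # finite-difference slope of the fitted curve at c -> 0, per mM
  eps <- 1e-4
  num_slope <- 1000 * (0.01 + 0.05 / (1 + 500 / eps) - 0.01) / eps
  expect_equal(binding_potential(fit), num_slope, tolerance = 0.01)
  expect_equal(binding_potential(fake_fit(0.5, 0.05, bmax = 0.05)), 0.1)
  expect_equal(binding_potential(fake_fit(0.5, 0.05, bmax = 0)), 0)
})

test_that("reliability flag implements the SE > value exclusion rule", {
  expect_false(flag_reliability(fake_fit(0.405, 13.896)))   # SE >> K_D
  expect_true(flag_reliability(fake_fit(0.521, 0.077)))     # SE < K_D
  expect_true(flag_reliability(fake_fit(0.5, 0.5)))         # boundary kept
  expect_false(flag_reliability(fake_fit(0.5, 0.05, bmax = 0.01,
                                         se_bmax = 0.02)))  # SE_Bmax > B_max
})

test_that("flat curves and sparse titrations are flagged, not fatal", {
  conc <- make_conc()
  flat <- fit_4pl(anisotropy_curve("p", conc, rep(0.02, length(conc))))
  expect_lt(abs(flat$bmax), 1e-3)
  expect_false(flat$reliable)
  expect_warning(fit_4pl(anisotropy_curve("p", c(0, 10, 20, 30),
                                          c(0, 0.01, 0.02, 0.025))),
                 "under-determined")
})

test_that("titration processing wires blanks, anisotropy and transform", {
  truth <- data.frame(peptide_id = "p1", y0 = 0.02, bmax = 0.05,
                      kd_uM = 500, hill = 1)
  sim <- gen_titration(titration_sim_spec(truth, noise_sd = 0,
                                          viscosity_artifact = TRUE))
  curves <- process_titration(sim$titrations, transform = FALSE)
  model_r <- function(conc) {
    y <- 0.02 + 0.05 / (1 + (500 / pmax(conc, 1e-300)))
    y[conc == 0] <- 0.02
    y
  }
  expect_equal(curves$p1$r, model_r(curves$p1$conc), tolerance = 1e-12)
  # without the blank correction the artifact biases high concentrations
  raw <- sim$titrations
  r_raw <- compute_anisotropy(raw$I_par, raw$I_perp)
  expect_gt(max(abs(r_raw - model_r(raw$conc_uM))), 0.01)
})

test_that("Monte-Carlo recovery: low bias and calibrated SEs across the K_D range", {
  set.seed(501)
  n_curves <- 200
  kds <- 10^runif(n_curves, log10(100), log10(1200))
  truth <- data.frame(peptide_id = sprintf("mc%03d", seq_len(n_curves)),
                      y0 = 0.01, bmax = 0.05, kd_uM = kds, hill = 1)
  sim <- gen_titration(titration_sim_spec(truth, noise_sd = 0.03,
                                          seed = 502))
  curves <- process_titration(sim$titrations)
  fits <- fa_fit_table(curves)
  fits <- fits[match(truth$peptide_id, fits$peptide_id), ]
  rel_bias <- (fits$kd_mM * 1000 - kds) / kds
  expect_lt(abs(median(rel_bias)), 0.05)
  covered <- abs(fits$kd_mM * 1000 - kds) <= 2 * fits$se_kd_mM * 1000
  expect_gte(mean(covered, na.rm = TRUE), 0.80)
  # slope recovered within +-0.2 of truth (median)
  expect_lt(abs(median(fits$hill) - 1), 0.2)
})
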