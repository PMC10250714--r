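test_that("the 18-point 3-fold series bottoms out near 2.1e-12 M", {
  ds <- make_dilution_series(2.7e-4, 3, 18)
  expect_length(ds$concentrations, 18)
  expect_true(all(diff(ds$concentrations) < 0))
  expect_equal(min(ds$concentrations), 2.1e-12, tolerance = 0.005)
  # algebraic identity: min * factor^(n-1) recovers the start
  expect_equal(min(ds$concentrations) * 3^17, 2.7e-4, tolerance = 1e-12)
  expect_equal(make_dilution_series(1, 2, 2)$concentrations, c(1, 0.5))
  expect_error(make_dilution_series(-1, 3, 18), "positive")
  expect_error(make_dilution_series(1, 1, 18), "exceed 1")
  expect_error(make_dilution_series(1, 3, 1), "at least 2")
})

test_that("the one-site total binding model has the defining landmarks", {
  expect_equal(saturation_model(1e-7, kd = 1e-7, bmax = 80), 40)
  expect_equal(saturation_model(0, kd = 1e-7, bmax = 80, background = 7), 7)
  expect_equal(saturation_model(1e-2, kd = 1e-7, bmax = 80),
               80, tolerance = 1e-4)
  # the nonspecific term is linear in concentration
  expect_equal(saturation_model(2e-6, 1e-7, 0, ns_slope = 5e6),
               2 * saturation_model(1e-6, 1e-7, 0, ns_slope = 5e6))
})

test_that("the competition model midpoint sits at the Cheng-Prusoff IC50", {
  ki <- 1.1e-9; hot <- 1e-7; hot_kd <- 9.5e-8
  ic50 <- ki * (1 + hot / hot_kd)  # independent arithmetic
  expect_equal(competition_model(log10(ic50), ki, 100, 0, hot, hot_kd), 50)
  expect_equal(competition_model(-20, ki, 100, 0, hot, hot_kd),
               100, tolerance = 1e-6)
  expect_equal(competition_model(2, ki, 100, 0, hot, hot_kd),
               0, tolerance = 1e-6)
})

test_that("noiseless saturation data are recovered almost exactly", {
  ds <- make_dilution_series(2.7e-4, 3, 18)
  obs <- data.frame(conc = ds$concentrations,
                    signal = saturation_model(ds$concentrations,
                                              kd = 1e-7, bmax = 100))
  fit <- fit_saturation(obs)
  expect_equal(fit$kd, 1e-7, tolerance = 1e-3)
  expect_equal(fit$bmax, 100, tolerance = 1e-3)
  expect_lt(fit$rss, 1e-10 * 100^2)
  expect_true(fit$ci95["kd", "low"] <= fit$kd &&
                fit$kd <= fit$ci95["kd", "high"])
})

test_that("the saturation fit lands on the grid-search minimum", {
  ds <- make_dilution_series(1e-5, 3, 12)
  obs <- data.frame(conc = ds$concentrations,
                    signal = saturation_model(ds$concentrations,
                                              kd = 2e-7, bmax = 60))
  fit <- fit_saturation(obs)
  kd_grid <- 10^seq(-8, -6, length.out = 81)
  bmax_grid <- seq(30, 90, length.out = 121)
  rss <- outer(kd_grid, bmax_grid, Vectorize(function(kd, bm)
    sum((obs$signal - saturation_model(obs$conc, kd, bm))^2)))
  best <- which(rss == min(rss), arr.ind = TRUE)[1, ]
  # within one grid step of the exhaustive minimum
  expect_lt(abs(log10(fit$kd) - log10(kd_grid[best[1]])), 0.026)
  expect_lt(abs(fit$bmax - bmax_grid[best[2]]), 0.51)
})

test_that("noiseless competition data recover Ki and the identity holds", {
  ds <- make_dilution_series(2.7e-4, 3, 18)
  hot <- 1e-7; hot_kd <- 9.5e-8
  obs <- data.frame(conc = ds$concentrations,
                    signal = competition_model(log10(ds$concentrations),
                                               ki = 1e-9, top = 100,
                                               bottom = 0, hot_conc = hot,
                                               hot_kd = hot_kd))
  fit <- fit_competition(obs, hot_conc = hot, hot_kd = hot_kd)
  expect_equal(fit$ki, 1e-9, tolerance = 1e-3)
  expect_equal(fit$top, 100, tolerance = 1e-3)
  expect_equal(fit$ic50, fit$ki * (1 + hot / hot_kd), tolerance = 1e-9)
})

test_that("flat curves raise the no-displacement error", {
  ds <- make_dilution_series(2.7e-4, 3, 18)
  set.seed(31)
  flat <- do.call(rbind, lapply(1:3, function(r)
    data.frame(conc = ds$concentrations,
               signal = 100 + rnorm(18, 0, 2), replicate = r)))
  expect_error(fit_competition(flat, hot_conc = 1e-7, hot_kd = 9.5e-8),
               "no displacement")
})

test_that("millipolarization normalization maps extremes to 0 and 100", {
  obs <- data.frame(conc = c(1, 2, 3), signal = c(10, 20, 30))
  expect_equal(normalize_mp(obs)$signal, c(0, 50, 100))
  # idempotent
  expect_equal(normalize_mp(normalize_mp(obs))$signal, c(0, 50, 100))
  set.seed(32)
  r <- data.frame(conc = 1:10, signal = rnorm(10),
                  replicate = rep(1:2, each = 5))
  nm <- normalize_mp(r)
  for (k in 1:2) {
    s <- nm$signal[nm$replicate == k]
    expect_equal(min(s), 0)
    expect_equal(max(s), 100)
  }
  expect_error(normalize_mp(data.frame(conc = 1:3, signal = rep(5, 3))),
               "constant")
})

test_that("fitted-plateau normalization recovers the model scale", {
  ds <- make_dilution_series(2.7e-4, 3, 18)
  # raw mP on an arbitrary scale: plateaus at 250 and 130
  raw <- data.frame(conc = ds$concentrations,
                    signal = competition_model(log10(ds$concentrations),
                                               1e-9, 250, 130, 1e-7,
                                               9.5e-8))
  nm <- normalize_mp(raw, method = "fitted")
  expect_equal(max(nm$signal), 100, tolerance = 1e-2)
  expect_equal(min(nm$signal), 0, tolerance = 1e-2)
})

test_that("simulated binding observations follow the requested design", {
  ds <- make_dilution_series(2.7e-4, 3, 18)
  pars <- list(ki = 1e-9, top = 100, bottom = 0, hot_conc = 1e-7,
               hot_kd = 9.5e-8)
  clean <- gen_binding(pars, ds, n_replicates = 3, noise_frac = 0,
                       seed = 5)
  expect_equal(nrow(clean), 54)
  expect_equal(clean$signal[clean$replicate == 1],
               competition_model(log10(ds$concentrations), 1e-9, 100, 0,
                                 1e-7, 9.5e-8))
  noisy <- gen_binding(pars, ds, n_replicates = 50, noise_frac = 0.05,
                       seed = 6)
  resid <- noisy$signal - rep(clean$signal[clean$replicate == 1], 50)
  expect_equal(sd(resid), 5, tolerance = 0.1)  # 5% of the 0-100 range
  expect_equal(gen_binding(pars, ds, seed = 7),
               gen_binding(pars, ds, seed = 7))
})
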