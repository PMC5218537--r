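test_that("Hill curve evaluates the inhibition formula exactly", {
  p <- hill_params(0, 100, ic50 = 1, h = -1)
  expect_equal(hill_response(p, 1), 50)                 # E(IC50) = midpoint
  expect_equal(hill_response(p, 2), 100 / 11, tolerance = 1e-12)
  expect_equal(hill_response(p, 0), 100 / 1.1, tolerance = 1e-12)

  # midpoint identity holds for arbitrary parameters
  set.seed(9)
  for (i in 1:10) {
    q <- hill_params(runif(1, -5, 5), runif(1, 10, 80),
                     runif(1, 0.1, 10), runif(1, -3, -0.5))
    expect_equal(hill_response(q, q$ic50), (q$emin + q$emax) / 2, tolerance = 1e-12)
  }

  # monotone decreasing in concentration for h < 0, Emax > Emin
  conc <- seq(0, 20, by = 0.25)
  expect_true(all(diff(hill_response(p, conc)) < 0))
  expect_error(hill_params(0, 10, ic50 = -1, h = -1), "positive")
})

test_that("noiseless data are recovered exactly", {
  set.seed(33)
  for (i in 1:20) {
    ic50 <- runif(1, 0.1, 10); h <- runif(1, -3, -0.5)
    truth <- hill_params(runif(1, 0, 5), runif(1, 20, 60), ic50, h)
    conc <- informative_conc(ic50, h)
    fit <- fit_hill(conc, hill_response(truth, conc))
    expect_lt(fit$rss, 1e-12)
    expect_equal(fit$params$ic50, truth$ic50, tolerance = 1e-6)
    expect_equal(fit$params$h, truth$h, tolerance = 1e-6)
    expect_equal(fit$params$emin, truth$emin, tolerance = 1e-6)
    expect_equal(fit$params$emax, truth$emax, tolerance = 1e-6)
  }
})

test_that("fit preconditions and fixed parameters are honoured", {
  p <- hill_params(0, 100, 1, -1)
  expect_error(fit_hill(c(0, 1, 2), hill_response(p, c(0, 1, 2))), "underdetermined")
  expect_error(fit_hill(c(0, 1, 1.1, 1.2, 1.3), rep(1, 5)), "concentration range")

  conc <- c(0, 0.25, 0.5, 1, 2, 4, 8)
  fit <- fit_hill(conc, hill_response(p, conc), fixed = list(emin = 0))
  expect_equal(fit$params$emin, 0)
  expect_equal(fit$params$ic50, 1, tolerance = 1e-6)
  expect_equal(fit$df, length(conc) - 3L)
  expect_true(is.na(fit$se[["emin"]]))
})

test_that("fit agrees with a dense grid-search oracle on noisy data", {
  pre <- hill_presets()$wt_mgatp
  dat <- simulate_dose_response(pre$params, pre$concentrations, n_cells = 4, seed = 11)
  fit <- fit_hill(dat$concentration_mM, dat$response_pApF)
  lic50_range <- log10(c(1.5, 6)); h_range <- c(-3, -0.8)
  pass1 <- grid_hill_fit(dat$concentration_mM, dat$response_pApF,
                         lic50_range, h_range)
  # the optimizer must be at least as good as every grid node
  expect_lte(fit$rss, pass1$rss + 1e-9)
  # refine the grid around the first-pass optimum; the basin centre and the
  # optimizer should then agree to the refined resolution
  dl <- diff(lic50_range) / 120; dh <- diff(h_range) / 120
  pass2 <- grid_hill_fit(dat$concentration_mM, dat$response_pApF,
                         log10(pass1$ic50) + c(-6, 6) * dl,
                         pass1$h + c(-6, 6) * dh, n_grid = 121)
  expect_lt(abs(log10(fit$params$ic50) - log10(pass2$ic50)), 2 * 12 * dl / 120 + 1e-9)
  expect_lt(abs(fit$params$h - pass2$h), 2 * 12 * dh / 120 + 1e-9)
})

test_that("noisy replicates recover the generating IC50 and slope", {
  pre <- hill_presets()$wt_mgatp
  ic50s <- hs <- numeric(10)
  for (i in 1:10) {
    dat <- simulate_dose_response(pre$params, pre$concentrations, n_cells = 5,
                                  seed = 400 + i)
    fit <- fit_hill(dat$concentration_mM, dat$response_pApF)
    ic50s[i] <- fit$params$ic50; hs[i] <- fit$params$h
  }
  expect_lt(abs(stats::median(ic50s) - pre$params$ic50) / pre$params$ic50, 0.10)
  expect_lt(abs(stats::median(hs) - pre$params$h) / abs(pre$params$h), 0.10)
})

test_that("extra sum-of-squares F test contracts hold", {
  pre <- hill_presets()$wt_mgatp
  dat <- simulate_dose_response(pre$params, pre$concentrations, n_cells = 5, seed = 3)

  # identical datasets: SS_null = SS_full, F = 0, p = 1
  same <- compare_curves(dat$concentration_mM, dat$response_pApF,
                         dat$concentration_mM, dat$response_pApF)
  expect_equal(same$F, 0, tolerance = 1e-6)
  expect_equal(same$p_value, 1, tolerance = 1e-6)
  expect_equal(same$df_num, 4L)
  expect_equal(same$df_den, 2L * nrow(dat) - 8L)
  expect_gte(same$ss_null, same$ss_full * (1 - 1e-9))

  # the 6-parameter nested variant also satisfies nesting
  alt <- compare_curves(dat$concentration_mM, dat$response_pApF,
                        dat$concentration_mM, dat$response_pApF,
                        mode = "ic50-and-slope-shared")
  expect_equal(alt$df_num, 2L)
  expect_gte(alt$ss_null, alt$ss_full * (1 - 1e-9))

  # noiseless identical data: residual SS at round-off scale, p near 1
  conc <- pre$concentrations
  resp <- hill_response(pre$params, conc)
  clean <- compare_curves(conc, resp, conc, resp)
  expect_lt(clean$ss_full, 1e-12)
  expect_gt(clean$p_value, 0.9)
})

test_that("clearly different curves are detected with high power", {
  pre <- hill_presets()
  ps <- numeric(10)
  for (i in 1:10) {
    a <- simulate_dose_response(pre$wt_mgatp$params, pre$wt_mgatp$concentrations,
                                5, seed = 500 + i)
    b <- simulate_dose_response(pre$mut_mgatp$params, pre$mut_mgatp$concentrations,
                                5, seed = 600 + i)
    ps[i] <- compare_curves(a$concentration_mM, a$response_pApF,
                            b$concentration_mM, b$response_pApF)$p_value
  }
  expect_true(all(ps <= 0.05))
})
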