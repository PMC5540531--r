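test_that("decompose_mortality matches hand arithmetic and conserves", {
  # all never smokers: decomposition is the population rate
  d <- decompose_mortality(0.01, 0, 0, 2, 1.5)
  expect_equal(d$m_never, 0.01)
  # no excess risk: all three rates equal
  d <- decompose_mortality(0.01, 0.3, 0.2, 1, 1)
  expect_equal(unlist(d), c(m_never = 0.01, m_current = 0.01,
                            m_former = 0.01))
  # hand evaluation with conservation check
  d <- decompose_mortality(0.01, 0.2, 0.1, 2, 1.5)
  expect_equal(d$m_never, 0.008)
  expect_equal(d$m_current, 0.016)
  expect_equal(d$m_former, 0.012)
  expect_equal(0.7 * d$m_never + 0.2 * d$m_current + 0.1 * d$m_former, 0.01)
  expect_error(decompose_mortality(-0.01, 0, 0, 2, 1.5), "nonnegative")
  expect_warning(decompose_mortality(0.01, 0.2, 0.1, 0.8, 1.5), "below 1")
})

test_that("mortality decomposition conserves over random valid inputs", {
  set.seed(42)
  for (i in 1:200) {
    p <- as.numeric(rmultinom(1, 1000, runif(3))) / 1000
    m <- runif(1, 0, 0.2)
    rr_c <- runif(1, 1, 4); rr_f <- runif(1, 1, 3)
    d <- decompose_mortality(m, p[2], p[3], rr_c, rr_f)
    expect_equal(p[1] * d$m_never + p[2] * d$m_current + p[3] * d$m_former,
                 m, tolerance = 1e-10)
  }
})

test_that("step_cohort applies survival then flows in the documented order", {
  # identity under zero flows and zero mortality
  out <- step_cohort(c(never = 10, current = 5, former = 2), 0, 0, 0, 0, 0)
  expect_equal(out, c(never = 10, current = 5, former = 2))
  # extreme initiation moves every never smoker in one step
  out <- step_cohort(c(never = 10, current = 0, former = 0), 1, 0, 0, 0, 0)
  expect_equal(out, c(never = 0, current = 10, former = 0))
  # spreadsheet-style oracle: survival first, then simultaneous flows
  cnt <- c(never = 700, current = 200, former = 100)
  out <- step_cohort(cnt, 0.05, 0.1, 0.008, 0.016, 0.012)
  n <- 700 * exp(-0.008); c_ <- 200 * exp(-0.016); f <- 100 * exp(-0.012)
  expect_equal(unname(out),
               c(n - 0.05 * n, c_ + 0.05 * n - 0.1 * c_, f + 0.1 * c_),
               tolerance = 1e-12)
  # person conservation at zero mortality
  out <- step_cohort(cnt, 0.05, 0.1, 0, 0, 0)
  expect_equal(sum(out), sum(cnt), tolerance = 1e-9)
})

test_that("simulate_prevalence matches the straight-loop reference simulator", {
  tt <- tiny_truth()
  ini <- tt$initial_prev
  ini[c("never", "current", "former")] <-
    1000 * ini[c("never", "current", "former")]
  sim <- simulate_prevalence(ini, tt$flows, tt$lifetable, tt$rrs, NULL,
                             years = 12)
  ref <- reference_simulate(ini, tt$flows, tt$lifetable, tt$rrs, 12)
  for (y in c(0, 5, 12)) {
    sl <- sim[sim$year == y, ]
    sl <- sl[order(sl$age_low), ]
    expect_equal(as.matrix(sl[, c("n_never", "n_current", "n_former")]),
                 ref[[y + 1]], tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("prevalence stays constant without flows or differential mortality", {
  sch <- age_scheme(c(30, 40), sexes = "male")
  lt <- sch; lt$mortality_rate <- 0.01; lt$life_expectancy <- 40
  rrs <- sch; rrs$rr_current <- 1; rrs$rr_former <- 1
  flows <- sch; flows$signed_parameter <- 0
  ini <- sch; ini$never <- c(700, 600); ini$current <- c(200, 250)
  ini$former <- c(100, 150)
  sim <- simulate_prevalence(ini, flows, lt, rrs, NULL, years = 10)
  # uniform mortality and aging mix bands, but band-specific prevalence can
  # only drift through aging; with equal prevalence it must stay constant
  ini2 <- ini; ini2$never <- c(700, 700); ini2$current <- c(200, 200)
  ini2$former <- c(100, 100)
  sim2 <- simulate_prevalence(ini2, flows, lt, rrs, NULL, years = 10)
  expect_equal(sim2$current, rep(0.2, nrow(sim2)), tolerance = 1e-12)
  # simplex closure everywhere
  expect_equal(sim$never + sim$current + sim$former,
               rep(1, nrow(sim)), tolerance = 1e-12)
})

test_that("differential smoker mortality depletes current prevalence with age", {
  sch <- age_scheme(50, sexes = "male")  # one open-ended cohort band
  lt <- sch; lt$mortality_rate <- 0.02; lt$life_expectancy <- 25
  rrs <- sch; rrs$rr_current <- 2.5; rrs$rr_former <- 1.2
  flows <- sch; flows$signed_parameter <- 0
  ini <- sch; ini$never <- 600; ini$current <- 300; ini$former <- 100
  sim <- simulate_prevalence(ini, flows, lt, rrs, NULL, years = 20)
  cur <- sim$current[order(sim$year)]
  expect_true(all(diff(cur) < 0))
})

test_that("raising cessation never raises later current-smoker prevalence", {
  tt <- tiny_truth()
  ini <- tt$initial_prev
  ini[c("never", "current", "former")] <-
    1000 * ini[c("never", "current", "former")]
  fl_hi <- tt$flows
  fl_hi$signed_parameter <- pmax(fl_hi$signed_parameter, 0) + 0.05
  sim_lo <- simulate_prevalence(ini, tt$flows, tt$lifetable, tt$rrs, NULL, 15)
  sim_hi <- simulate_prevalence(ini, fl_hi, tt$lifetable, tt$rrs, NULL, 15)
  expect_true(all(sim_hi$current <= sim_lo$current + 1e-12))
})

test_that("calibration recovers rates on noiseless data and respects weights", {
  tt <- tiny_truth()
  panel <- tiny_panel(tt, noiseless = TRUE)
  fit <- suppressWarnings(
    calibrate_rates(panel, tt$lifetable, tt$rrs, n_starts = 3, seed = 7))
  expect_equal(fit$flows$signed_parameter, tt$flows$signed_parameter,
               tolerance = 1e-6)
  expect_true(all(fit$convergence == 0))
  # the optimum cannot be worse than the generating parameters
  obj_truth <- tobaccoCEA:::calibration_objective(
    tt$flows$signed_parameter,
    as.matrix(1000 * tt$initial_prev[, c("never", "current", "former")]),
    list(list(current = panel$current[panel$year == 2000],
              former = panel$former[panel$year == 2000]),
         list(current = panel$current[panel$year == 2010],
              former = panel$former[panel$year == 2010])),
    list(rep(1, 4), rep(1, 4)),
    tt$lifetable$mortality_rate, tt$rrs$rr_current, tt$rrs$rr_former,
    tt$scheme$age_high - tt$scheme$age_low, 10, c(1, 11))
  expect_lte(fit$objective_by_sex[["male"]], obj_truth + 1e-8)
})

test_that("stationary observations with no differentials calibrate to zero flows", {
  sch <- age_scheme(c(30, 40), sexes = "male")
  lt <- sch; lt$mortality_rate <- 0.01; lt$life_expectancy <- 40
  rrs <- sch; rrs$rr_current <- 1; rrs$rr_former <- 1
  panel <- rbind(
    data.frame(sch, year = 2000, never = 0.7, current = 0.2, former = 0.1),
    data.frame(sch, year = 2010, never = 0.7, current = 0.2, former = 0.1))
  fit <- suppressWarnings(calibrate_rates(panel, lt, rrs, n_starts = 2))
  expect_equal(fit$flows$signed_parameter, c(0, 0), tolerance = 1e-5)
})

test_that("near-zero observation weight makes the fit ignore that observation", {
  tt <- tiny_truth()
  panel <- tiny_panel(tt, noiseless = TRUE)
  # corrupt one 2010 observation but give it negligible weight
  bad <- panel
  i <- which(bad$year == 2010 & bad$age_low == 40)
  bad$current[i] <- pmin(bad$current[i] + 0.3, 1)
  bad$never[i] <- 1 - bad$current[i] - bad$former[i]
  bad$n_eff[i] <- 1e-9
  fit_clean <- suppressWarnings(
    calibrate_rates(panel, tt$lifetable, tt$rrs, n_starts = 2, seed = 3))
  fit_bad <- suppressWarnings(
    calibrate_rates(bad, tt$lifetable, tt$rrs, n_starts = 2, seed = 3))
  expect_equal(fit_bad$flows$signed_parameter,
               fit_clean$flows$signed_parameter, tolerance = 1e-3)
})

test_that("bootstrap is reproducible and reports spread of the right order", {
  tt <- tiny_truth()
  panel <- tiny_panel(tt, n = 500, seed = 2)
  b1 <- suppressWarnings(bootstrap_rates(panel, tt$lifetable, tt$rrs,
                                         n_iter = 20, seed = 11))
  b2 <- suppressWarnings(bootstrap_rates(panel, tt$lifetable, tt$rrs,
                                         n_iter = 20, seed = 11))
  expect_identical(b1$draws, b2$draws)
  expect_equal(b1$n_failed, 0L)
  expect_true(all(is.finite(b1$sd$sd)) && all(b1$sd$sd > 0))
  # means should sit near the base-case fit
  expect_equal(b1$mean$signed_parameter, b1$base$flows$signed_parameter,
               tolerance = 0.05)
})

test_that("bootstrap spread matches a nested-simulation sampling oracle", {
  # survey size large enough that both signed parameters sit many sampling
  # SDs away from the initiation/cessation kink at zero, where the signed
  # parameterisation makes the estimator regular
  tt <- tiny_truth()
  # fix the mortality RRs (no CI columns) so the bootstrap varies only the
  # survey sampling noise that the oracle below reproduces
  rrs_fixed <- tt$rrs[, c("sex", "age_low", "age_high", "rr_current",
                          "rr_former")]
  n_obs <- 3000
  panel <- tiny_panel(tt, n = n_obs, seed = 4)
  boot <- suppressWarnings(bootstrap_rates(panel, tt$lifetable, rrs_fixed,
                                           n_iter = 200, seed = 13))
  # oracle: the true sampling SD of the estimator under multinomial noise,
  # from independent replicate panels calibrated one by one
  reps <- vapply(1:100, function(k) {
    p <- tiny_panel(tt, n = n_obs, seed = 1000 + k)
    fit <- suppressWarnings(calibrate_rates(p, tt$lifetable, tt$rrs,
                                            n_starts = 2, seed = k))
    fit$flows$signed_parameter
  }, numeric(2))
  sd_true <- apply(reps, 1, sd)
  expect_true(all(abs(boot$sd$sd - sd_true) / sd_true < 0.25))
})
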