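test_that("or_to_rr agrees with brute-force 2x2 table reconstruction", {
  expect_equal(or_to_rr(1, 0.37), 1)
  expect_equal(or_to_rr(2, 1e-9), 2, tolerance = 1e-6)
  expect_equal(or_to_rr(2, 0.2), 2 / 1.2, tolerance = 1e-12)
  # brute force: given p0 and OR, exposed odds = OR * p0/(1-p0)
  for (or in c(0.3, 0.67, 1.5, 2.29, 5)) {
    for (p0 in c(0.01, 0.2, 0.5, 0.9)) {
      odds1 <- or * p0 / (1 - p0)
      p1 <- odds1 / (1 + odds1)
      expect_equal(or_to_rr(or, p0), p1 / p0, tolerance = 1e-12)
    }
  }
  expect_error(or_to_rr(2, 1), "baseline_risk")
})

test_that("tax-to-price algebra follows the retail price identity", {
  expect_equal(price_change_from_tax(0.3, 0.3), 0)
  expect_equal(price_change_from_tax(0.20, 0.50), 0.6)
  # identity check: p1 = p0 (1 - t0) / (1 - t1)
  p0 <- 100; t0 <- 0.2; t1 <- 0.5
  p1 <- p0 * (1 - t0) / (1 - t1)
  expect_equal(price_change_from_tax(t0, t1), (p1 - p0) / p0,
               tolerance = 1e-12)
  expect_equal(price_change_from_tax(0.2, 0.5, pass_through = 0), 0)
  expect_error(price_change_from_tax(0.2, 1), "below 1")
})

test_that("apply_effects with no effects reproduces the base trajectory", {
  tt <- tiny_truth()
  ini <- tt$initial_prev
  ini[c("never", "current", "former")] <-
    1000 * ini[c("never", "current", "former")]
  empty <- data.frame(intervention = character(), target = character(),
                      measure = character(), value = numeric(),
                      sex = character())
  base <- simulate_prevalence(ini, tt$flows, tt$lifetable, tt$rrs, NULL, 15)
  scen <- apply_effects(ini, tt$flows, tt$lifetable, tt$rrs, NULL, empty,
                        horizon = 10, years = 15)
  expect_equal(scen$current, base$current, tolerance = 1e-12)
  expect_equal(scen$n_never, base$n_never, tolerance = 1e-9)
})

test_that("flow-rate effects multiply during the horizon and revert after", {
  sch <- age_scheme(30, sexes = "male")
  lt <- sch; lt$mortality_rate <- 0; lt$life_expectancy <- 50
  rrs <- sch; rrs$rr_current <- 1; rrs$rr_former <- 1
  flows <- sch; flows$signed_parameter <- 0.05  # cessation
  ini <- sch; ini$never <- 500; ini$current <- 400; ini$former <- 100
  eff <- data.frame(intervention = "x", target = "cessation",
                    measure = "relative_risk", value = 2, sex = "all")
  scen <- apply_effects(ini, flows, lt, rrs, NULL, eff, horizon = 10,
                        years = 14)
  # no mortality, open-ended single band: current depletes at the cessation
  # rate exactly; 10% during the horizon, 5% after
  cur <- scen$n_current[order(scen$year)]
  expect_equal(cur[2] / cur[1], 0.9, tolerance = 1e-12)
  expect_equal(cur[11] / cur[10], 0.9, tolerance = 1e-12)
  expect_equal(cur[12] / cur[11], 0.95, tolerance = 1e-12)
  expect_equal(cur[14] / cur[13], 0.95, tolerance = 1e-12)
})

test_that("prevalence effects move current smokers to former, on the simplex", {
  tt <- tiny_truth()
  ini <- tt$initial_prev
  ini[c("never", "current", "former")] <-
    1000 * ini[c("never", "current", "former")]
  eff <- data.frame(intervention = "ban", target = "prevalence",
                    measure = "relative_reduction", value = 0.04,
                    sex = "all")
  base <- simulate_prevalence(ini, tt$flows, tt$lifetable, tt$rrs, NULL, 10)
  scen <- apply_effects(ini, tt$flows, tt$lifetable, tt$rrs, NULL, eff,
                        horizon = 10, years = 10)
  b0 <- base[base$year == 0, ]; s0 <- scen[scen$year == 0, ]
  expect_equal(s0$n_current, 0.96 * b0$n_current, tolerance = 1e-12)
  expect_equal(s0$n_never, b0$n_never, tolerance = 1e-12)
  expect_equal(s0$n_former, b0$n_former + 0.04 * b0$n_current,
               tolerance = 1e-12)
  expect_equal(scen$never + scen$current + scen$former,
               rep(1, nrow(scen)), tolerance = 1e-12)
})

test_that("price elasticities scale flows and prevalence as stated", {
  sch <- age_scheme(30, sexes = "male")
  lt <- sch; lt$mortality_rate <- 0; lt$life_expectancy <- 50
  rrs <- sch; rrs$rr_current <- 1; rrs$rr_former <- 1
  flows <- sch; flows$signed_parameter <- -0.1  # initiation
  ini <- sch; ini$never <- 800; ini$current <- 150; ini$former <- 50
  eff <- data.frame(
    intervention = rep("tax", 3),
    target = c("prevalence", "initiation", "cessation"),
    measure = "price_elasticity",
    value = c(-0.88, -1.175, 0), sex = "all")
  scen <- apply_effects(ini, flows, lt, rrs, NULL, eff, price_change = 0.1,
                        horizon = 10, years = 10)
  s0 <- scen[scen$year == 0, ]
  expect_equal(s0$n_current, 150 * (1 - 0.088), tolerance = 1e-12)
  # initiation scaled by 1 + (-1.175)(0.1) = 0.8825
  s1 <- scen[scen$year == 1, ]
  expect_equal(s1$n_never, s0$n_never * (1 - 0.1 * 0.8825),
               tolerance = 1e-12)
  expect_error(
    apply_effects(ini, flows, lt, rrs, NULL, eff, price_change = NULL,
                  horizon = 10, years = 5), "price change")
})

test_that("monotone comparative statics of initiation and cessation effects", {
  tt <- tiny_truth()
  ini <- tt$initial_prev
  ini[c("never", "current", "former")] <-
    1000 * ini[c("never", "current", "former")]
  base <- simulate_prevalence(ini, tt$flows, tt$lifetable, tt$rrs, NULL, 20)
  for (eff in list(
    data.frame(intervention = "a", target = "initiation",
               measure = "relative_risk", value = 0.7, sex = "all"),
    data.frame(intervention = "b", target = "cessation",
               measure = "relative_risk", value = 1.8, sex = "all"))) {
    scen <- apply_effects(ini, tt$flows, tt$lifetable, tt$rrs, NULL, eff,
                          horizon = 10, years = 20)
    expect_true(all(scen$current <= base$current + 1e-12))
  }
})

test_that("sex-specific effect rows apply only to that sex", {
  tr <- truth_fixture()
  ini <- initial_counts(tr)
  eff <- data.frame(intervention = "sfp", target = "initiation",
                    measure = "relative_risk", value = 0.5, sex = "male")
  base <- simulate_prevalence(ini, tr$flows, tr$lifetable_survey,
                              tr$mortality_rrs, tr$demo, 10)
  scen <- apply_effects(ini, tr$flows, tr$lifetable_survey, tr$mortality_rrs,
                        tr$demo, eff, horizon = 10, years = 10)
  f_base <- base[base$sex == "female", ]
  f_scen <- scen[scen$sex == "female", ]
  expect_equal(f_scen$n_current, f_base$n_current, tolerance = 1e-12)
  m_base <- base[base$sex == "male" & base$year == 10, ]
  m_scen <- scen[scen$sex == "male" & scen$year == 10, ]
  expect_true(any(m_scen$n_current < m_base$n_current - 1e-9))
})
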