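test_that("static regimes enforce design feasibility", {
  expect_equal(static_regime("BUP")$stage2, "BUP_HIGH")
  expect_equal(static_regime("PAR")$stage2, "PAR_HIGH")
  expect_error(static_regime("BUP", "PAR_HIGH"), "forces escalation")
  expect_error(static_regime("PBO"), "needs")
  expect_error(static_regime("XYZ"), "one of")
})

test_that("IPWE reduces to the sample mean when everyone follows the regime", {
  withr::with_seed(131, {
    n <- 200
    d <- tibble::tibble(
      Trt1 = "PBO",
      RESPONSE1 = rbinom(n, 1, 0.4),
      SUMD2 = runif(n, 0, 15)
    )
    d$Trt2 <- ifelse(d$RESPONSE1 == 0, "BUP_HIGH", NA)
    v <- ipwe(d, static_regime("PBO", "BUP_HIGH"))
    expect_equal(v$estimate, mean(d$SUMD2))
  })
})

test_that("IPWE equals the brute-force stratified weighted mean", {
  cohort <- simulate_cohort(gen_config(n = 3000, seed = 132), mask = FALSE)
  v <- ipwe(cohort, static_regime("PBO", "PAR_HIGH"))

  # independent oracle: explicit strata and weights
  p_pbo <- mean(cohort$Trt1 == "PBO")
  pnr <- cohort$Trt1 == "PBO" & cohort$RESPONSE1 == 0
  p_par <- mean(cohort$Trt2[pnr] == "PAR_HIGH")
  resp <- cohort[cohort$Trt1 == "PBO" & cohort$RESPONSE1 == 1, ]
  cons <- cohort[pnr & cohort$Trt2 == "PAR_HIGH", ]
  num <- sum(resp$SUMD2) / p_pbo + sum(cons$SUMD2) / (p_pbo * p_par)
  den <- nrow(resp) / p_pbo + nrow(cons) / (p_pbo * p_par)
  expect_equal(v$estimate, num / den, tolerance = 1e-10)
})

test_that("IPWE is invariant to rescaled propensities and errors sensibly", {
  cohort <- simulate_cohort(gen_config(n = 2000, seed = 133), mask = FALSE)
  emp <- ipwe(cohort, static_regime("BUP"))
  # design override with the same relative stage-1 shares
  des <- ipwe(cohort, static_regime("BUP"),
              propensities = list(
                stage1 = prop.table(table(factor(cohort$Trt1,
                                                 levels = c("BUP", "PAR", "PBO")))),
                stage2_bup = 0.5))
  expect_equal(emp$estimate, des$estimate, tolerance = 1e-10)

  none <- cohort[cohort$Trt1 != "PAR", ]
  expect_error(ipwe(none, static_regime("PAR")), "consistent")
})

test_that("IPWE matches the generator-truth value of a static regime", {
  cfg <- gen_config(n = 10000, seed = 134)
  cohort <- simulate_cohort(cfg, mask = FALSE)
  est <- ipwe(cohort, static_regime("PBO", "BUP_HIGH"))
  truth <- true_regime_value(cfg, static_regime("PBO", "BUP_HIGH"),
                             n_sim = 1e5, seed = 135)
  tol <- 3 * sqrt(est$std.error^2 + truth$se^2)
  expect_lt(abs(est$estimate - truth$value), tol)
})

test_that("the fitted regime's true value does not exceed any static regime's", {
  cfg <- gen_config(n = 6000, seed = 136)
  cohort <- simulate_cohort(cfg, mask = FALSE)
  fit <- fit_qlearning(cohort)
  vals <- vapply(table4_regimes(fit), function(r) {
    tv <- true_regime_value(cfg, r, n_sim = 4e4, seed = 137)
    tv$value
  }, numeric(1))
  se <- 22 / sqrt(4e4)  # conservative MC scale bound
  expect_true(all(vals[["Estimated DTR"]] <= vals[-1] + 2 * se))
})

test_that("compare_regimes produces the five-row comparison with nested intervals", {
  cohort <- simulate_cohort(gen_config(n = 1500, seed = 138), mask = FALSE)
  fit <- fit_qlearning(cohort)
  tab <- compare_regimes(cohort, table4_regimes(fit), B = 40, seed = 139)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$regime[1], "Estimated DTR")
  expect_true(all(tab$conf.low <= tab$estimate & tab$estimate <= tab$conf.high))

  dup <- compare_regimes(cohort,
                         list(a = static_regime("BUP"),
                              b = static_regime("BUP")),
                         B = 25, seed = 140)
  expect_equal(dup$estimate[1], dup$estimate[2])
  expect_equal(dup$conf.low[1], dup$conf.low[2])

  wide <- compare_regimes(cohort, list(a = static_regime("BUP")),
                          B = 30, level = 0.95, seed = 141)
  narrow <- compare_regimes(cohort, list(a = static_regime("BUP")),
                            B = 30, level = 0.80, seed = 141)
  expect_lte(wide$conf.low, narrow$conf.low)
  expect_gte(wide$conf.high, narrow$conf.high)
})

test_that("estimated-regime consistency uses the averaged rule at both stages", {
  cohort <- simulate_cohort(gen_config(n = 800, seed = 142), mask = FALSE)
  fit <- published_fit()
  v <- ipwe(cohort, fit)
  d1 <- decide(fit, cohort, stage = 1)
  d2 <- decide(fit, cohort, stage = 2)
  cons <- cohort$Trt1 == d1
  pnr <- cohort$Trt1 == "PBO" & cohort$RESPONSE1 == 0
  cons[pnr] <- cons[pnr] & cohort$Trt2[pnr] == d2[pnr]
  expect_gt(sum(cons), 0)
  # weights: manual normalized mean over the consistent set
  p1 <- prop.table(table(factor(cohort$Trt1, levels = c("BUP", "PAR", "PBO"))))
  p2 <- mean(cohort$Trt2[pnr] == "BUP_HIGH")
  w <- 1 / as.numeric(p1[cohort$Trt1])
  w[pnr] <- w[pnr] / ifelse(cohort$Trt2[pnr] == "BUP_HIGH", p2, 1 - p2)
  expect_equal(v$estimate, sum(w[cons] * cohort$SUMD2[cons]) / sum(w[cons]),
               tolerance = 1e-10)
})
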