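test_that("moment-matched truncated normals hit the printed mean and SD", {
  for (mg in default_baseline_marginals()[c("AGE", "SUMD0", "SUMM0")]) {
    par <- qsmart:::.tnorm_solve(mg$mean, mg$sd, mg$lo, mg$hi)
    mm <- qsmart:::.tnorm_moments(par[1], par[2], mg$lo, mg$hi)
    expect_equal(unname(mm["mean"]), mg$mean, tolerance = 1e-4)
    expect_equal(unname(mm["sd"]), mg$sd, tolerance = 1e-4)
  }
})

test_that("generation is deterministic given the seed", {
  a <- simulate_cohort(gen_config(n = 80, seed = 123))
  b <- simulate_cohort(gen_config(n = 80, seed = 123))
  attributes(a) <- attributes(b) <- NULL
  expect_identical(a, b)
})

test_that("stage-1 allocation follows the configured probabilities", {
  base <- sample_baseline(gen_config(n = 400, seed = 2))
  all_bup <- assign_stage1(base, c(1, 0, 0), seed = 3)
  expect_true(all(all_bup$Trt1 == "BUP"))
  expect_error(assign_stage1(base, c(0.5, 0.5, 0.5)), "summing to 1")

  big <- assign_stage1(sample_baseline(gen_config(n = 20000, seed = 4)),
                       seed = 5)
  frac <- prop.table(table(big$Trt1))
  se <- sqrt(0.512 * 0.488 / 20000)
  expect_lt(abs(frac[["PBO"]] - 0.512), 4 * se)
})

test_that("baseline marginals track the published table at moderate n", {
  b <- sample_baseline(gen_config(n = 20000, seed = 9))
  expect_lt(abs(mean(b$AGE) - 40.59), 4 * 11.74 / sqrt(20000))
  expect_lt(abs(mean(b$SUMM0) - 1.19), 4 * 1.09 / sqrt(20000))
  pr <- prop.table(table(b$PRONSET))
  expect_lt(abs(pr[["remission"]] - 0.459), 4 * sqrt(0.459 * 0.541 / 20000))
  expect_true(all(b$AGE >= 18 & b$AGE <= 77))
  expect_true(all(b$SUMD0 >= 0.75 & b$SUMD0 <= 18))
})

test_that("null treatment effects and vanishing noise reduce SUMD1 to its baseline terms", {
  cfg <- gen_config(n = 300, seed = 21)
  cfg$stage1_coeffs$sumd1[c("A11", "A12")] <- 0
  cfg$noise_sd_stage1[["sumd1"]] <- 1e-9
  b <- assign_stage1(sample_baseline(cfg, seed = 22), seed = 23)
  s <- simulate_stage1(b, cfg, seed = 24)
  enc <- encode_model_terms(b)
  expected <- qsmart:::.lp(enc, cfg$stage1_coeffs$sumd1)
  expect_equal(s$SUMD1, pmin(pmax(expected, 0), 22), tolerance = 1e-6)
})

test_that("responder fraction rises as stage-1 noise shrinks under a strong drug effect", {
  mk <- function(noise) {
    cfg <- gen_config(n = 6000, seed = 31)
    cfg$stage1_coeffs$sumd1[c("A11", "A12")] <- -6
    cfg$noise_sd_stage1[["sumd1"]] <- noise
    s <- simulate_stage1(assign_stage1(sample_baseline(cfg, seed = 32),
                                       seed = 33),
                         cfg, seed = 34)
    mean(s$RESPONSE1[s$Trt1 != "PBO"])
  }
  expect_gt(mk(0.2), mk(6))
})

test_that("stage-2 design: escalation is deterministic, placebo non-responders randomized", {
  cohort <- simulate_cohort(gen_config(n = 2000, seed = 41), mask = FALSE)
  resp <- cohort$RESPONSE1 == 1
  expect_true(all(is.na(cohort$Trt2[resp])))
  expect_true(all(cohort$Trt2[!resp & cohort$Trt1 == "PAR"] == "PAR_HIGH"))
  expect_true(all(cohort$Trt2[!resp & cohort$Trt1 == "BUP"] == "BUP_HIGH"))
  pnr <- cohort$Trt2[!resp & cohort$Trt1 == "PBO"]
  expect_setequal(unique(pnr), c("BUP_HIGH", "PAR_HIGH"))
  p <- mean(pnr == "BUP_HIGH")
  expect_lt(abs(p - 0.5), 4 * sqrt(0.25 / length(pnr)))
})

test_that("configured stage-2 truth switches optimal drug at SUMM1 = 1.18/0.77", {
  cfg <- gen_config()
  contrast <- function(summ1, side3) {
    enc <- tibble::tibble(SUMM1 = summ1, SUMD1 = 5, SIDE3 = side3, A2 = 1)
    qsmart:::.lp(enc, cfg$stage2_coeffs) -
      qsmart:::.lp(dplyr::mutate(enc, A2 = 0), cfg$stage2_coeffs)
  }
  cross <- 1.18 / 0.77
  expect_lt(contrast(cross - 0.01, 0), 0)  # BUP_HIGH better just below
  expect_gt(contrast(cross + 0.01, 0), 0)  # PAR_HIGH better just above
  expect_gt(contrast(0, 1), 0)             # sedation flips it at any low SUMM1
})

test_that("missingness mechanism hits the requested rates and MAR structure", {
  cohort <- simulate_cohort(gen_config(n = 4000, seed = 51), mask = FALSE)

  none <- impose_missingness(cohort, c(SUMM1 = 0), seed = 52)
  expect_identical(none$SUMM1, cohort$SUMM1)

  masked <- impose_missingness(cohort, c(SUMM1 = 0.3), mar = FALSE, seed = 53)
  expect_lt(abs(mean(is.na(masked$SUMM1)) - 0.3), 4 * sqrt(0.21 / 4000))

  # MCAR: missingness independent of AGE; MAR: positively age-dependent
  mcar <- glm(is.na(masked$SUMM1) ~ cohort$AGE, family = binomial())
  expect_lt(abs(coef(mcar)[2]), 3 * summary(mcar)$coefficients[2, 2])
  masked_mar <- impose_missingness(cohort, c(SUMM1 = 0.3), mar = TRUE, seed = 54)
  mar_fit <- glm(is.na(masked_mar$SUMM1) ~ cohort$AGE, family = binomial())
  expect_gt(coef(mar_fit)[2], 3 * summary(mar_fit)$coefficients[2, 2])

  expect_error(impose_missingness(cohort, c(SUMM1 = 1.2)), "\\[0, 1\\]")
})

test_that("generated cohorts always validate and keep the pre-mask truth", {
  cohort <- simulate_cohort(gen_config(n = 250, seed = 61))
  truth <- attr(cohort, "complete")
  expect_false(anyNA(truth$SUMD1))
  obs <- !is.na(cohort$SUMD1)
  expect_identical(cohort$SUMD1[obs], truth$SUMD1[obs])
})
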