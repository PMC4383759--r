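test_that("noiseless stage-2 outcomes are interpolated to machine precision", {
  cohort <- simulate_cohort(gen_config(n = 1500, seed = 71), mask = FALSE)
  enc <- encode_model_terms(cohort)
  truth <- gen_config()$stage2_coeffs
  pnr <- enc$Trt1 == "PBO" & enc$RESPONSE1 == 0
  cohort$SUMD2[pnr] <- qsmart:::.lp(enc[pnr, ], truth)
  fit <- fit_stage2(cohort)
  got <- c(fit$beta20, fit$beta21)
  expect_equal(unname(got),
               unname(truth[c("(Intercept)", "SUMM1", "SUMD1", "SIDE3",
                              "A2", "A2:SUMM1", "A2:SIDE3")]),
               tolerance = 1e-8)
})

test_that("stage-2 fit ignores drug-arm and responder rows entirely", {
  cohort <- simulate_cohort(gen_config(n = 1200, seed = 72), mask = FALSE)
  fit1 <- fit_stage2(cohort)
  perturbed <- cohort
  other <- !(perturbed$Trt1 == "PBO" & perturbed$RESPONSE1 == 0)
  perturbed$SUMD2[other] <- pmin(22, perturbed$SUMD2[other] + 7)
  perturbed$SUMM1[other] <- 0
  fit2 <- fit_stage2(perturbed)
  expect_identical(fit1$coef, fit2$coef)
})

test_that("stage-2 fit errors on rank deficiency and tiny subsets", {
  cohort <- simulate_cohort(gen_config(n = 800, seed = 73), mask = FALSE)
  cohort$SIDE3 <- 0L  # constant column, collinear with intercept
  expect_error(fit_stage2(cohort), "SIDE3")
  small <- cohort[cohort$Trt1 == "PBO" & cohort$RESPONSE1 == 0, ][1:6, ]
  expect_error(fit_stage2(small, stage2_terms()), "Too few rows")
})

test_that("pseudo-outcome follows the indicator algebra of backward induction", {
  cohort <- simulate_cohort(gen_config(n = 1000, seed = 74), mask = FALSE)
  fit <- fit_stage2(cohort)
  ps <- pseudo_outcome(cohort, fit)
  enc <- encode_model_terms(cohort)

  other <- !(enc$Trt1 == "PBO" & enc$RESPONSE1 == 0)
  expect_identical(ps[other], cohort$SUMD2[other])

  pnr <- which(!other)
  sub <- enc[pnr, ]
  X20 <- qsmart:::.design(sub, fit$terms$h20)
  X21 <- qsmart:::.design(sub, fit$terms$h21)
  q_par <- drop(X20 %*% fit$beta20)            # a2 = 0 arm
  q_bup <- q_par + drop(X21 %*% fit$beta21)    # a2 = 1 arm
  expect_equal(ps[pnr], pmin(q_par, q_bup))
  expect_true(all(ps[pnr] <= pmax(q_par, q_bup) + 1e-12))
  pos <- drop(X21 %*% fit$beta21) > 0
  expect_equal(ps[pnr][pos], q_par[pos])
})

test_that("full shrinkage collapses the pseudo-outcome to the regular part", {
  cohort <- simulate_cohort(gen_config(n = 1000, seed = 75), mask = FALSE)
  fit <- fit_stage2(cohort)
  ps <- pseudo_outcome(cohort, fit, shrink = 1e6)
  enc <- encode_model_terms(cohort)
  pnr <- which(enc$Trt1 == "PBO" & enc$RESPONSE1 == 0)
  X20 <- qsmart:::.design(enc[pnr, ], fit$terms$h20)
  expect_equal(ps[pnr], drop(X20 %*% fit$beta20))
})

test_that("stage-1 fit is replication-invariant and null effects vanish", {
  cohort <- simulate_cohort(gen_config(n = 900, seed = 76), mask = FALSE)
  s2 <- fit_stage2(cohort)
  ps <- pseudo_outcome(cohort, s2)
  f1 <- fit_stage1(cohort, ps)
  doubled <- dplyr::bind_rows(cohort, cohort)
  f1d <- fit_stage1(doubled, c(ps, ps))
  expect_equal(f1$coef, f1d$coef, tolerance = 1e-10)

  # operation-level null: response unrelated to treatment
  cfg <- gen_config(n = 8000, seed = 77)
  coh <- simulate_cohort(cfg, mask = FALSE)
  encn <- encode_model_terms(coh)
  ynull <- 3 + 0.3 * encn$SUMD0 + rnorm(nrow(coh))
  fnull <- fit_stage1(coh, ynull)
  se <- sqrt(fnull$sigma2 * diag(fnull$xtx_inv))
  trt_terms <- grepl("^A1", names(fnull$coef))
  expect_true(all(abs(fnull$coef[trt_terms]) < 4 * se[trt_terms]))
})

test_that("fitted regime matches brute-force dynamic programming on the discrete toy", {
  toy <- make_toy_cohort(n = 4000, seed = 81)
  fit <- fit_qlearning(toy, stage1 = toy_stage1_terms(),
                       stage2 = toy_stage2_terms())
  oracle <- dp_oracle(toy)

  s2grid <- tibble::tibble(SUMM1 = oracle$stage2$SUMM1,
                           SIDE3 = oracle$stage2$SIDE3,
                           Trt1 = "PBO", RESPONSE1 = 0L)
  expect_equal(decide(fit, s2grid, stage = 2), oracle$stage2$rec)

  s1grid <- tibble::tibble(PRONSET = oracle$stage1$PRONSET)
  expect_equal(decide(fit, s1grid, stage = 1), oracle$stage1$rec)
})

test_that("flipping the outcome sign flips every decision", {
  toy <- make_toy_cohort(n = 3000, seed = 82)
  fit <- fit_qlearning(toy, stage1 = toy_stage1_terms(),
                       stage2 = toy_stage2_terms())
  flipped <- toy
  flipped$SUMD2 <- -toy$SUMD2
  fit_f <- fit_qlearning(flipped, stage1 = toy_stage1_terms(),
                         stage2 = toy_stage2_terms())
  grid <- tibble::tibble(SUMM1 = c(0L, 0L, 1L, 1L), SIDE3 = c(0L, 1L, 0L, 1L),
                         Trt1 = "PBO", RESPONSE1 = 0L)
  d1 <- decide(fit, grid, stage = 2)
  d2 <- decide(fit_f, grid, stage = 2)
  expect_true(all(d1 != d2))
})

test_that("decide() reproduces hand-derived rules at the published point estimates", {
  fit <- published_fit()

  # stage 2: contrast = -1.18 + 0.77 SUMM1 + 1.82 SIDE3; BUP_HIGH iff < 0
  grid <- tibble::tibble(
    SUMM1 = c(1.0, 2.0, 0.5, 1.52, 1.54),
    SIDE3 = c(0L, 0L, 1L, 0L, 0L),
    SUMD1 = 5, Trt1 = "PBO", RESPONSE1 = 0L
  )
  expect_equal(decide(fit, grid, stage = 2),
               c("BUP_HIGH", "PAR_HIGH", "PAR_HIGH", "BUP_HIGH", "PAR_HIGH"))

  # singleton feasible sets bypass the model; responders get no decision
  other <- tibble::tibble(SUMM1 = 1, SUMD1 = 5, SIDE3 = 0L,
                          Trt1 = c("BUP", "PAR", "PBO"),
                          RESPONSE1 = c(0L, 0L, 1L))
  expect_equal(decide(fit, other, stage = 2),
               c("BUP_HIGH", "PAR_HIGH", NA))

  # stage 1, hand-computed from the printed coefficients:
  # hypomanic at 50: BUP contrast +0.08, PAR contrast +0.85 -> placebo
  # hypomanic at 30: BUP contrast -0.12 -> Bupropion
  # remission at 30: BUP -0.59, PAR +0.62 -> Bupropion
  s1 <- tibble::tibble(AGE = c(50, 30, 30),
                       PRONSET = c("hypomanic", "hypomanic", "remission"),
                       SUMM0 = 1.19, SUMD0 = 7.47)
  expect_equal(decide(fit, s1, stage = 1), c("PBO", "BUP", "BUP"))

  expect_error(decide(fit, dplyr::mutate(s1, AGE = NA), stage = 1), "Missing")
})

test_that("tidy and glance summarize a fit", {
  toy <- make_toy_cohort(n = 2000, seed = 83)
  fit <- fit_qlearning(toy, stage1 = toy_stage1_terms(),
                       stage2 = toy_stage2_terms())
  td <- tidy(fit)
  expect_true(all(c("stage", "term", "estimate") %in% names(td)))
  expect_setequal(unique(td$stage), c(1L, 2L))
  gl <- glance(fit)
  expect_equal(gl$m, 1)
  expect_equal(gl$n, 2000)
})
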