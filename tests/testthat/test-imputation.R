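test_that("complete data pass through imputation untouched", {
  cohort <- simulate_cohort(gen_config(n = 150, seed = 91), mask = FALSE)
  imps <- impute_cohort(cohort, m = 3, seed = 92)
  expect_s3_class(imps, "imputation_set")
  expect_length(imps$cohorts, 3)
  for (l in 1:3) expect_identical(imps$cohorts[[l]], cohort)
})

test_that("observed cells are never altered and PMM draws only donor values", {
  cohort <- simulate_cohort(gen_config(n = 500, seed = 93))
  specs <- list(SUMD1 = c("SUMD0", "SUMM0", "Trt1", "SUMD2"),
                SUMM1 = c("SUMM0", "SUMD0", "Trt1"),
                HINCOME = c("EMPLOY", "EDUCATE"),
                EDUCATE = c("HINCOME", "EMPLOY"),
                EMPLOY = c("AGE",  "HINCOME"),
                MARSTAT = c("AGE", "GENDER"),
                MEDINS = c("AGE", "EMPLOY"),
                PRONSET = c("SUMM0", "SUMD0"))
  imps <- impute_cohort(cohort, m = 2, seed = 94, sweeps = 3, specs = specs)
  for (l in 1:2) {
    comp <- imps$cohorts[[l]]
    expect_false(anyNA(comp[setdiff(names(comp), "Trt2")]))
    for (v in c("SUMD1", "SUMM1", "PRONSET")) {
      obs <- !is.na(cohort[[v]])
      expect_identical(comp[[v]][obs], cohort[[v]][obs])
      # PMM / categorical draws come from the observed support
      expect_true(all(comp[[v]][!obs] %in% cohort[[v]][obs]))
    }
  }
})

test_that("multiple imputations differ somewhere and are seed-deterministic", {
  cohort <- simulate_cohort(gen_config(n = 300, seed = 95))
  specs <- list(SUMD1 = c("SUMD0", "Trt1", "SUMD2"),
                SUMM1 = c("SUMM0", "Trt1"),
                HINCOME = "EMPLOY", EDUCATE = "HINCOME", EMPLOY = "AGE",
                MARSTAT = "AGE", MEDINS = "AGE", PRONSET = "SUMM0")
  a <- impute_cohort(cohort, m = 2, seed = 96, sweeps = 2, specs = specs)
  expect_false(identical(a$cohorts[[1]]$SUMD1, a$cohorts[[2]]$SUMD1))
  b <- impute_cohort(cohort, m = 2, seed = 96, sweeps = 2, specs = specs)
  expect_identical(a$cohorts, b$cohorts)
})

test_that("fully missing columns are rejected", {
  cohort <- simulate_cohort(gen_config(n = 60, seed = 97), mask = FALSE)
  cohort$SUMM1 <- NA_real_
  expect_error(impute_cohort(cohort, m = 1), "entirely missing")
})

test_that("forward stepwise finds true conditional predictors and rejects noise", {
  withr::with_seed(98, {
    n <- 1500
    d <- tibble::tibble(
      x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
      linear = NA_real_, noise = rnorm(n)
    )
    d$linear <- 2 * d$x1  # exact function of one candidate
    sel <- select_conditional_predictors(d, "linear",
                                         candidates = c("x1", "x2", "x3"))
    expect_equal(sel[1], "x1")
    sel_noise <- select_conditional_predictors(d, "noise",
                                               candidates = c("x1", "x2", "x3"))
    expect_length(sel_noise, 0)
  })
})

test_that("selection errors without complete cases", {
  d <- tibble::tibble(y = c(NA, 1, 2, NA), x = c(1, NA, NA, 2))
  expect_error(select_conditional_predictors(d, "y", candidates = "x"),
               "complete cases")
})

test_that("imputation recovers pre-masking means under MAR", {
  cfg <- gen_config(n = 1200, seed = 99)
  cohort <- simulate_cohort(cfg)
  truth <- attr(cohort, "complete")
  specs <- list(SUMD1 = c("AGE", "SUMD0", "SUMM0", "Trt1", "SUMD2"),
                SUMM1 = c("AGE", "SUMM0", "Trt1"),
                HINCOME = c("AGE", "EMPLOY"), EDUCATE = c("AGE", "HINCOME"),
                EMPLOY = c("AGE", "HINCOME"), MARSTAT = c("AGE", "GENDER"),
                MEDINS = c("AGE", "EMPLOY"), PRONSET = c("AGE", "SUMM0"))
  imps <- impute_cohort(cohort, m = 5, seed = 100, sweeps = 5, specs = specs)
  for (v in c("SUMD1", "SUMM1")) {
    n_mis <- sum(is.na(cohort[[v]]))
    pooled <- mean(vapply(imps$cohorts, function(cc) mean(cc[[v]]), 0))
    tol <- 3 * sd(truth[[v]]) / sqrt(n_mis)
    expect_lt(abs(pooled - mean(truth[[v]])), tol)
  }
})
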