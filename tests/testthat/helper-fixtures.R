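# Shared fixtures: a discrete toy SMART for dynamic-programming oracle checks,
# and a constructor for dtr_fit objects with hand-set coefficients.

# Discrete toy cohort: binary SUMM1 and SIDE3, trinary PRONSET, uniform
# three-arm stage 1, Bernoulli response, 1:1 stage-2 randomization of placebo
# non-responders. Cell-mean outcome structure so saturated working models are
# correctly specified.
make_toy_cohort <- function(n = 5000, seed = 1) {
  withr::with_seed(seed, {
    pron <- sample(c("remission", "hypomanic", "mixed"), n, replace = TRUE)
    trt1 <- sample(c("BUP", "PAR", "PBO"), n, replace = TRUE)
    resp <- rbinom(n, 1, ifelse(pron == "remission", 0.5, 0.35))
    summ1 <- rbinom(n, 1, 0.5)
    side3 <- rbinom(n, 1, 0.3)
    trt2 <- rep(NA_character_, n)
    trt2[resp == 0 & trt1 == "BUP"] <- "BUP_HIGH"
    trt2[resp == 0 & trt1 == "PAR"] <- "PAR_HIGH"
    pnr <- which(resp == 0 & trt1 == "PBO")
    trt2[pnr] <- sample(c("BUP_HIGH", "PAR_HIGH"), length(pnr), replace = TRUE)
    a2 <- as.integer(trt2 == "BUP_HIGH")
    # outcome: arbitrary but fixed cell means + noise
    mu <- 5 + 0.8 * (pron == "remission") - 1.2 * (pron == "hypomanic") +
      0.9 * (trt1 == "BUP") - 0.7 * (trt1 == "PAR") + 0.6 * summ1
    is_pnr <- seq_len(n) %in% pnr
    mu[is_pnr] <- 4 + 1.1 * summ1[is_pnr] - 0.8 * side3[is_pnr] +
      a2[is_pnr] * (-1 + 1.6 * summ1[is_pnr] + 0.9 * side3[is_pnr] -
                      0.8 * summ1[is_pnr] * side3[is_pnr])
    y <- mu + rnorm(n)
    tibble::tibble(SUMM1 = summ1, SIDE3 = side3, PRONSET = pron,
                   Trt1 = trt1, RESPONSE1 = resp, Trt2 = trt2, SUMD2 = y)
  })
}

toy_stage2_terms <- function() {
  stage2_terms(h20 = c("SUMM1", "SIDE3", "SUMM1:SIDE3"),
               h21 = c("SUMM1", "SIDE3", "SUMM1:SIDE3"))
}

toy_stage1_terms <- function() {
  stage1_terms(h10 = c("PRONSET1", "PRONSET2"),
               h11 = c("PRONSET1", "PRONSET2"),
               h12 = c("PRONSET1", "PRONSET2"))
}

# Brute-force dynamic programming on the discrete toy: empirical cell means,
# no regression anywhere. Returns the optimal rule on every history cell.
dp_oracle <- function(toy) {
  pnr <- toy[toy$Trt1 == "PBO" & toy$RESPONSE1 == 0, ]
  pnr$a2 <- as.integer(pnr$Trt2 == "BUP_HIGH")
  s2_cells <- expand.grid(SUMM1 = 0:1, SIDE3 = 0:1)
  s2_cells$rec <- NA_character_
  s2_cells$qmin <- NA_real_
  for (i in seq_len(nrow(s2_cells))) {
    cell <- pnr[pnr$SUMM1 == s2_cells$SUMM1[i] & pnr$SIDE3 == s2_cells$SIDE3[i], ]
    q0 <- mean(cell$SUMD2[cell$a2 == 0])
    q1 <- mean(cell$SUMD2[cell$a2 == 1])
    s2_cells$rec[i] <- if (q1 < q0) "BUP_HIGH" else "PAR_HIGH"
    s2_cells$qmin[i] <- min(q0, q1)
  }
  # pseudo-outcome: plug in the cell-minimum for placebo non-responders
  ps <- toy$SUMD2
  for (i in seq_len(nrow(s2_cells))) {
    sel <- toy$Trt1 == "PBO" & toy$RESPONSE1 == 0 &
      toy$SUMM1 == s2_cells$SUMM1[i] & toy$SIDE3 == s2_cells$SIDE3[i]
    ps[sel] <- s2_cells$qmin[i]
  }
  s1_cells <- data.frame(PRONSET = c("remission", "hypomanic", "mixed"))
  s1_cells$rec <- NA_character_
  for (i in seq_len(nrow(s1_cells))) {
    q <- vapply(c(BUP = "BUP", PAR = "PAR", PBO = "PBO"), function(a) {
      mean(ps[toy$PRONSET == s1_cells$PRONSET[i] & toy$Trt1 == a])
    }, numeric(1))
    best <- names(q)[q == min(q)]
    s1_cells$rec[i] <- if ("PBO" %in% best) "PBO" else
      if ("PAR" %in% best) "PAR" else "BUP"
  }
  list(stage2 = s2_cells, stage1 = s1_cells)
}

# dtr_fit with hand-set coefficients (single "imputation")
manual_fit <- function(beta20, beta21, beta10, beta11, beta12,
                       s2 = stage2_terms(), s1 = stage1_terms()) {
  structure(
    list(
      stage2_fits = list(structure(
        list(terms = s2, beta20 = beta20, beta21 = beta21,
             coef = c(beta20, beta21)), class = "stage2_fit")),
      stage1_fits = list(structure(
        list(terms = s1, beta10 = beta10, beta11 = beta11, beta12 = beta12,
             coef = c(beta10, beta11, beta12)), class = "stage1_fit")),
      stage1_terms = s1, stage2_terms = s2, m = 1, n = NA_integer_
    ),
    class = "dtr_fit"
  )
}

# published point estimates as a manual fit (Q-function tables)
published_fit <- function() {
  manual_fit(
    beta20 = c("(Intercept)" = 2.21, SUMM1 = 0.18, SUMD1 = 0.50, SIDE3 = -0.41),
    beta21 = c("(Intercept)" = -1.18, SUMM1 = 0.77, SIDE3 = 1.82),
    beta10 = c("(Intercept)" = 1.57, AGE = 0.02, SUMM0 = 0.48, SUMD0 = 0.20,
               PRONSET1 = -0.42, PRONSET2 = -0.86),
    beta11 = c("(Intercept)" = -1.55, AGE = 0.01, PRONSET1 = 0.66,
               PRONSET2 = 1.13),
    beta12 = c("(Intercept)" = 0.73, AGE = -0.03, PRONSET1 = 0.79,
               PRONSET2 = 1.62)
  )
}
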