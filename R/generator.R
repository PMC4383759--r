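# Synthetic SMART cohort generator. Emulates the two-stage acute
# bipolar-depression design: baseline covariates drawn to match the published
# cohort marginals, a three-arm stage-1 randomization, a 50%-improvement
# responder rule with a (hypo)mania override, re-randomization of placebo
# non-responders only, and a continuous 12-week depression outcome (lower is
# better). Generative coefficients default to the published fitted Q-function
# forms so that downstream parameter-recovery tests are anchored to printed
# numbers; the generative truth (pre-masking data, branch models) is retained
# so every pipeline stage can be checked against it.

# ---- truncated normal utilities ------------------------------------------

.rtnorm <- function(n, mu, sigma, lo, hi) {
  mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n)
  u <- runif(n)
  out <- numeric(n)
  # work in whichever tail keeps the interval probabilities representable
  low_side <- mu <= (lo + hi) / 2
  if (any(low_side)) {
    i <- which(low_side)
    pl <- pnorm(lo, mu[i], sigma[i], lower.tail = FALSE)
    ph <- pnorm(hi, mu[i], sigma[i], lower.tail = FALSE)
    out[i] <- qnorm(pl + u[i] * (ph - pl), mu[i], sigma[i],
                    lower.tail = FALSE)
  }
  if (any(!low_side)) {
    i <- which(!low_side)
    pl <- pnorm(lo, mu[i], sigma[i])
    ph <- pnorm(hi, mu[i], sigma[i])
    out[i] <- qnorm(pl + u[i] * (ph - pl), mu[i], sigma[i])
  }
  pmin(pmax(out, lo), hi)
}

.tnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  m <- mu + sigma * (dnorm(a) - dnorm(b)) / z
  v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
                    ((dnorm(a) - dnorm(b)) / z)^2)
  c(mean = unname(m), sd = unname(sqrt(v)))
}

# solve for (mu, sigma) so the truncated normal on [lo, hi] has the target
# mean and sd; the printed mean/SD plus range are the only constraints the
# source table provides
.tnorm_solve <- function(mean, sd, lo, hi) {
  obj <- function(p) {
    mm <- .tnorm_moments(p[1], exp(p[2]), lo, hi)
    (mm[1] - mean)^2 + (mm[2] - sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# ---- default configuration ------------------------------------------------

#' Default baseline marginals of the synthetic cohort
#'
#' Numeric variables carry a printed mean, SD and range and are sampled from a
#' moment-matched truncated normal; categorical variables carry printed level
#' frequencies. Binary codings: RACE = 1 white, HINCOME = 1 income >= $40k,
#' EMPLOY = 1 employed, EDUCATE = 1 technical school or above, MEDINS = 1
#' insured, BITYPE = 1 bipolar type I, SIDEx = 1 side effect present.
#'
#' @return Named list of per-variable marginal parameters.
#' @export
default_baseline_marginals <- function() {
  list(
    AGE    = list(type = "numeric", mean = 40.59, sd = 11.74, lo = 18, hi = 77),
    SUMD0  = list(type = "numeric", mean = 7.47, sd = 2.30, lo = 0.75, hi = 18),
    SUMM0  = list(type = "numeric", mean = 1.19, sd = 1.09, lo = 0, hi = 7),
    RACE   = list(type = "binary", p = 0.904),
    GENDER = list(type = "categorical", levels = .GENDER_LEVELS,
                  p = c(0.43, 0.56, 0.01)),
    MARSTAT = list(type = "categorical", levels = .MARSTAT_LEVELS,
                   p = c(0.356, 0.338, 0.306)),
    HINCOME = list(type = "binary", p = 0.415),
    EMPLOY  = list(type = "binary", p = 0.469),
    EDUCATE = list(type = "binary", p = 0.47),
    MEDINS  = list(type = "binary", p = 0.728),
    BITYPE  = list(type = "binary", p = 0.704),
    PRONSET = list(type = "categorical", levels = .PRONSET_LEVELS,
                   p = c(0.459, 0.332, 0.209)),
    SIDE1 = list(type = "binary", p = 0.269),
    SIDE2 = list(type = "binary", p = 0.211),
    SIDE3 = list(type = "binary", p = 0.171),
    SIDE4 = list(type = "binary", p = 0.057),
    SIDE5 = list(type = "binary", p = 0.120),
    SIDE6 = list(type = "binary", p = 0.137),
    SIDE7 = list(type = "binary", p = 0.143),
    SIDE8 = list(type = "binary", p = 0.097),
    SIDE9 = list(type = "binary", p = 0.126)
  )
}

# intermediate-outcome intercepts below were calibrated once by simulation so
# the default marginals of SUMD1 and SUMM1 match their printed mean values
.default_stage1_coeffs <- function() {
  list(
    sumd1 = c("(Intercept)" = -0.7, SUMD0 = 0.5, SUMM0 = 0.3,
              PRONSET1 = -0.5, PRONSET2 = 0.3, A11 = -1.0, A12 = -1.0),
    summ1 = c("(Intercept)" = -3.0, SUMM0 = 1.8, A11 = 0.3, A12 = 0.3),
    mania = c("(Intercept)" = -2.5, SUMM0 = 0.4, A11 = 0.6, A12 = 0.6)
  )
}

# stage-2 outcome branch (placebo non-responders): the published second-stage
# Q-function point estimates
.default_stage2_coeffs <- function() {
  c("(Intercept)" = 2.21, SUMM1 = 0.18, SUMD1 = 0.50, SIDE3 = -0.41,
    A2 = -1.18, "A2:SUMM1" = 0.77, "A2:SIDE3" = 1.82)
}

# outcome branch for everyone else (responders and drug-arm non-responders):
# the published first-stage Q-function point estimates
.default_y_other_coeffs <- function() {
  c("(Intercept)" = 1.57, AGE = 0.02, SUMM0 = 0.48, SUMD0 = 0.20,
    PRONSET1 = -0.42, PRONSET2 = -0.86,
    A11 = -1.55, "A11:AGE" = 0.01, "A11:PRONSET1" = 0.66, "A11:PRONSET2" = 1.13,
    A12 = 0.73, "A12:AGE" = -0.03, "A12:PRONSET1" = 0.79, "A12:PRONSET2" = 1.62)
}

.default_missing_rates <- function() {
  c(SUMD1 = 0.28, SUMM1 = 0.28, HINCOME = 0.15, EDUCATE = 0.15,
    EMPLOY = 0.15, MARSTAT = 0.15, MEDINS = 0.15, PRONSET = 0.10)
}

#' Generator configuration
#'
#' Bundles every knob of the synthetic cohort generator. Defaults reproduce
#' the published cohort: n = 365, stage-1 allocation frequencies
#' (0.233, 0.255, 0.512) over (BUP, PAR, PBO), baseline marginals from the
#' published candidate-predictor table, and outcome branch coefficients equal
#' to the published fitted Q-function point estimates.
#'
#' @param n Number of subjects.
#' @param seed Integer seed; every sampling step is deterministic given it.
#' @param stage1_probs Probability 3-vector over (BUP, PAR, PBO).
#' @param baseline_marginals Per-variable marginal parameters; see
#'   [default_baseline_marginals()].
#' @param stage1_coeffs Named list with elements `sumd1`, `summ1` (linear
#'   models for the intermediate scores) and `mania` (logistic model for the
#'   (hypo)mania indicator).
#' @param stage2_coeffs Linear outcome model for placebo non-responders, in
#'   the second-stage Q-function terms.
#' @param y_other_coeffs Linear outcome model for all other subjects.
#' @param noise_sd_stage1 Named vector `c(sumd1 = , summ1 = )`, residual SDs
#'   of the intermediate-score models (points).
#' @param noise_sd_y Residual SD of the 12-week outcome (points).
#' @param missing_rates Named per-column masking probabilities.
#' @param mar If `TRUE` (default) masking probability depends on the
#'   always-observed AGE and stage-1 arm (missing at random); if `FALSE`
#'   masking is completely at random.
#' @return An object of class `qsmart_config`.
#' @export
gen_config <- function(n = 365,
                       seed = NULL,
                       stage1_probs = c(BUP = 0.233, PAR = 0.255, PBO = 0.512),
                       baseline_marginals = default_baseline_marginals(),
                       stage1_coeffs = .default_stage1_coeffs(),
                       stage2_coeffs = .default_stage2_coeffs(),
                       y_other_coeffs = .default_y_other_coeffs(),
                       noise_sd_stage1 = c(sumd1 = 4.0, summ1 = 1.05),
                       noise_sd_y = 2.5,
                       missing_rates = .default_missing_rates(),
                       mar = TRUE) {
  if (n < 1) abort("`n` must be at least 1.")
  if (length(stage1_probs) != 3 || any(stage1_probs < 0) ||
      abs(sum(stage1_probs) - 1) > 1e-8) {
    abort("`stage1_probs` must be a non-negative 3-vector summing to 1.")
  }
  if (any(missing_rates < 0 | missing_rates > 1)) {
    abort("`missing_rates` must lie in [0, 1].")
  }
  for (v in c("AGE", "SUMD0", "SUMM0")) {
    mg <- baseline_marginals[[v]]
    if (mg$mean < mg$lo || mg$mean > mg$hi) {
      abort(paste0("Marginal mean of ", v, " lies outside its range."))
    }
  }
  structure(
    list(n = n, seed = seed,
         stage1_probs = setNames(as.numeric(stage1_probs), .TRT1),
         baseline_marginals = baseline_marginals,
         stage1_coeffs = stage1_coeffs,
         stage2_coeffs = stage2_coeffs,
         y_other_coeffs = y_other_coeffs,
         noise_sd_stage1 = noise_sd_stage1,
         noise_sd_y = noise_sd_y,
         missing_rates = missing_rates,
         mar = mar),
    class = "qsmart_config"
  )
}

# evaluate a named linear predictor on encoded data; "A:B" terms are products
.lp <- function(data, coefs) {
  out <- rep(0, nrow(data))
  for (nm in names(coefs)) {
    if (nm == "(Intercept)") {
      out <- out + coefs[[nm]]
    } else if (grepl(":", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      x <- rep(1, nrow(data))
      for (p in parts) x <- x * data[[p]]
      out <- out + coefs[[nm]] * x
    } else {
      out <- out + coefs[[nm]] * data[[nm]]
    }
  }
  out
}

.with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# ---- sampling stages -------------------------------------------------------

#' Sample baseline covariates
#'
#' Numeric variables are drawn from a truncated normal on the printed range
#' whose parameters are moment-matched so the *truncated* distribution has the
#' printed mean and SD; categorical variables are drawn at the printed level
#' frequencies. Side-effect indicators are sampled independently.
#'
#' @param config A [gen_config()] object.
#' @param seed Optional seed overriding `config$seed`.
#' @return Tibble with one baseline row per subject.
#' @export
sample_baseline <- function(config, seed = config$seed) {
  n <- config$n
  .with_seed(seed, {
    out <- tibble::tibble(id = seq_len(n))
    for (v in names(config$baseline_marginals)) {
      mg <- config$baseline_marginals[[v]]
      out[[v]] <- switch(mg$type,
        numeric = {
          par <- .tnorm_solve(mg$mean, mg$sd, mg$lo, mg$hi)
          .rtnorm(n, par[1], par[2], mg$lo, mg$hi)
        },
        binary = rbinom(n, 1, mg$p),
        categorical = sample(mg$levels, n, replace = TRUE, prob = mg$p)
      )
    }
    out[, intersect(.COHORT_COLS, names(out))]
  })
}

#' Assign stage-1 treatment
#'
#' Independent categorical draws over (BUP, PAR, PBO). The default allocation
#' probabilities are the empirical stage-1 frequencies of the published
#' cohort, (0.233, 0.255, 0.512).
#'
#' @param data Baseline cohort tibble.
#' @param stage1_probs Probability 3-vector over (BUP, PAR, PBO).
#' @param seed Optional seed.
#' @return `data` with a `Trt1` column appended.
#' @export
assign_stage1 <- function(data,
                          stage1_probs = c(BUP = 0.233, PAR = 0.255, PBO = 0.512),
                          seed = NULL) {
  if (length(stage1_probs) != 3 || any(stage1_probs < 0) ||
      abs(sum(stage1_probs) - 1) > 1e-8) {
    abort("`stage1_probs` must be a non-negative 3-vector summing to 1.")
  }
  .with_seed(seed, {
    data$Trt1 <- sample(.TRT1, nrow(data), replace = TRUE, prob = stage1_probs)
    data
  })
}

#' Simulate intermediate (end-of-stage-1) outcomes
#'
#' SUMD1 and SUMM1 are linear in baseline scores, prior-episode dummies and
#' treatment dummies plus Gaussian noise, truncated to the score ranges
#' ([0, 22] and [0, 16]); the (hypo)mania indicator is Bernoulli with a
#' logistic model; responder status follows [classify_response()].
#'
#' @param data Cohort with baseline and `Trt1`.
#' @param config A [gen_config()] object.
#' @param seed Optional seed.
#' @return `data` with `SUMD1`, `SUMM1`, `MANIA1`, `RESPONSE1` appended.
#' @export
simulate_stage1 <- function(data, config, seed = NULL) {
  enc <- encode_model_terms(data)
  .with_seed(seed, {
    n <- nrow(enc)
    mu_d <- .lp(enc, config$stage1_coeffs$sumd1)
    mu_m <- .lp(enc, config$stage1_coeffs$summ1)
    data$SUMD1 <- .rtnorm(n, mu_d, config$noise_sd_stage1[["sumd1"]], 0, 22)
    data$SUMM1 <- .rtnorm(n, mu_m, config$noise_sd_stage1[["summ1"]], 0, 16)
    data$MANIA1 <- rbinom(n, 1, plogis(.lp(enc, config$stage1_coeffs$mania)))
    data$RESPONSE1 <- classify_response(data$SUMD0, data$SUMD1, data$MANIA1)
    data
  })
}

#' Assign stage-2 treatment and simulate the distal outcome
#'
#' Placebo non-responders are randomized 1:1 to the two high-dose drugs and
#' their outcome follows the stage-2 branch model (`stage2_coeffs`); drug
#' non-responders escalate their own drug deterministically; responders get no
#' stage-2 treatment. Everyone outside the placebo non-responder stratum draws
#' their outcome from the `y_other_coeffs` branch. Outcomes are truncated to
#' [0, 22]; lower is better.
#'
#' @param data Cohort with stage-1 fields.
#' @param config A [gen_config()] object.
#' @param seed Optional seed.
#' @return `data` with `Trt2` and `SUMD2` appended.
#' @export
assign_stage2_and_outcome <- function(data, config, seed = NULL) {
  .with_seed(seed, {
    n <- nrow(data)
    nonresp <- data$RESPONSE1 == 0
    data$Trt2 <- NA_character_
    data$Trt2[nonresp & data$Trt1 == "BUP"] <- "BUP_HIGH"
    data$Trt2[nonresp & data$Trt1 == "PAR"] <- "PAR_HIGH"
    pnr <- which(nonresp & data$Trt1 == "PBO")
    data$Trt2[pnr] <- sample(.TRT2, length(pnr), replace = TRUE)

    enc <- encode_model_terms(data)
    mu <- .lp(enc, config$y_other_coeffs)
    mu[pnr] <- .lp(enc[pnr, , drop = FALSE], config$stage2_coeffs)
    data$SUMD2 <- .rtnorm(n, mu, config$noise_sd_y, 0, 22)
    data
  })
}

#' Impose missingness masks on a cohort
#'
#' Sets masked cells to `NA`. Under the MAR mechanism the per-column masking
#' probability is a logistic function of the always-observed AGE (standardized)
#' and the placebo indicator, with the intercept calibrated so the empirical
#' marginal rate matches the requested rate; under MCAR the probability is
#' constant. The unmasked cohort is retained in the `"complete"` attribute as
#' the generative truth for downstream checks.
#'
#' @param data Complete cohort tibble.
#' @param missing_rates Named per-column masking probabilities.
#' @param mar Logical; MAR (default) or MCAR mechanism.
#' @param seed Optional seed.
#' @return Masked cohort with attributes `complete` and `masked_cols`.
#' @export
impose_missingness <- function(data, missing_rates = .default_missing_rates(),
                               mar = TRUE, seed = NULL) {
  if (any(missing_rates < 0 | missing_rates > 1)) {
    abort("`missing_rates` must lie in [0, 1].")
  }
  complete <- data
  .with_seed(seed, {
    z_age <- as.numeric(scale(data$AGE))
    pbo <- as.numeric(data$Trt1 == "PBO")
    score <- if (mar) 0.4 * z_age + 0.4 * pbo else rep(0, nrow(data))
    for (v in names(missing_rates)) {
      rate <- missing_rates[[v]]
      if (rate == 0) next
      if (rate == 1) {
        data[[v]] <- NA
        next
      }
      # calibrate the intercept on the realized scores
      a <- uniroot(function(a) mean(plogis(a + score)) - rate,
                   interval = c(-20, 20))$root
      mask <- runif(nrow(data)) < plogis(a + score)
      data[[v]][mask] <- NA
    }
    attr(data, "complete") <- complete
    attr(data, "masked_cols") <- names(missing_rates)[missing_rates > 0]
    data
  })
}

#' Simulate a complete synthetic SMART cohort
#'
#' Runs baseline sampling, stage-1 randomization, intermediate outcomes,
#' stage-2 assignment and the distal outcome, then (optionally) imposes
#' missingness. The generator-internal `MANIA1` column is dropped from the
#' returned cohort (it exists only to compute responder status) but is kept in
#' the `"complete"` truth attribute.
#'
#' @param config A [gen_config()] object.
#' @param mask Impose the configured missingness (default `TRUE`).
#' @return Cohort tibble in the subject-level schema, with attributes
#'   `complete` (pre-masking data) and `config`.
#' @export
simulate_cohort <- function(config = gen_config(), mask = TRUE) {
  .with_seed(config$seed, {
    out <- sample_baseline(config, seed = NULL)
    out <- assign_stage1(out, config$stage1_probs)
    out <- simulate_stage1(out, config)
    out <- assign_stage2_and_outcome(out, config)
    truth <- out
    out$MANIA1 <- NULL
    out <- out[, .COHORT_COLS]
    if (mask && any(config$missing_rates > 0)) {
      out <- impose_missingness(out, config$missing_rates, mar = config$mar)
    }
    attr(out, "complete") <- truth
    attr(out, "config") <- config
    validate_cohort(out)
    out
  })
}

# ---- generator truth oracle ------------------------------------------------

#' Monte-Carlo value of a regime under the generative truth
#'
#' Simulates a large cohort in which treatments are *forced* to follow the
#' regime (rather than randomized) and returns the mean outcome. This is the
#' generator-truth oracle: it never touches the estimation pipeline, so it can
#' serve as an independent reference for inverse-probability-weighted
#' estimates and for regret comparisons of fitted regimes.
#'
#' @param config A [gen_config()] object.
#' @param regime A [static_regime()] or a fitted regime from
#'   [fit_qlearning()].
#' @param n_sim Number of simulated subjects.
#' @param seed Optional seed.
#' @return Tibble with columns `value` (mean outcome, points), `se`
#'   (Monte-Carlo standard error) and `n`.
#' @export
true_regime_value <- function(config, regime, n_sim = 1e5, seed = NULL) {
  .with_seed(seed, {
    cfg <- config
    cfg$n <- n_sim
    base <- sample_baseline(cfg, seed = NULL)
    if (inherits(regime, "static_regime")) {
      base$Trt1 <- regime$stage1
    } else if (inherits(regime, "dtr_fit")) {
      base$Trt1 <- decide(regime, base, stage = 1)
    } else {
      abort("`regime` must be a static_regime or dtr_fit object.")
    }
    sim <- simulate_stage1(base, cfg)
    nonresp <- sim$RESPONSE1 == 0
    sim$Trt2 <- NA_character_
    sim$Trt2[nonresp & sim$Trt1 == "BUP"] <- "BUP_HIGH"
    sim$Trt2[nonresp & sim$Trt1 == "PAR"] <- "PAR_HIGH"
    pnr <- which(nonresp & sim$Trt1 == "PBO")
    if (length(pnr) > 0) {
      if (inherits(regime, "static_regime")) {
        sim$Trt2[pnr] <- regime$stage2
      } else {
        sim$Trt2[pnr] <- decide(regime, sim[pnr, , drop = FALSE], stage = 2)
      }
    }
    enc <- encode_model_terms(sim)
    mu <- .lp(enc, cfg$y_other_coeffs)
    mu[pnr] <- .lp(enc[pnr, , drop = FALSE], cfg$stage2_coeffs)
    y <- .rtnorm(nrow(sim), mu, cfg$noise_sd_y, 0, 22)
    tibble::tibble(value = mean(y), se = sd(y) / sqrt(length(y)),
                   n = length(y))
  })
}
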