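# Inverse-probability-weighted estimation of regime values. A subject is
# regime-consistent when the observed treatments equal the regime's
# recommendations at every decision actually made; weights are the inverse
# randomization probabilities (stage-1 arm, and the stage-2 randomization for
# placebo non-responders — responders and drug-arm non-responders have no
# second randomization, so they contribute only the stage-1 factor). The
# estimator is the normalized (Hajek) weighted mean, which is bounded by the
# observed outcome range.

#' Define a static treatment regime
#'
#' A fixed first-line treatment plus, where a second randomized decision
#' exists (placebo non-responders), a fixed second-line treatment. Drug-arm
#' non-responders always escalate their own drug, so `stage2` is implied for
#' `stage1 = "BUP"` or `"PAR"` and must be supplied (one of `"BUP_HIGH"`,
#' `"PAR_HIGH"`) for `stage1 = "PBO"`.
#'
#' @param stage1 One of `"BUP"`, `"PAR"`, `"PBO"`.
#' @param stage2 Second-line treatment for re-randomized subjects; implied
#'   for drug first lines.
#' @return A `static_regime` object.
#' @examples
#' static_regime("PBO", "BUP_HIGH")
#' static_regime("BUP")  # escalation to BUP_HIGH is implied
#' @export
static_regime <- function(stage1, stage2 = NULL) {
  if (!stage1 %in% .TRT1) abort("`stage1` must be one of BUP, PAR, PBO.")
  implied <- switch(stage1, BUP = "BUP_HIGH", PAR = "PAR_HIGH", PBO = NULL)
  if (is.null(implied)) {
    if (is.null(stage2) || !stage2 %in% .TRT2) {
      abort("A placebo first line needs `stage2` in {BUP_HIGH, PAR_HIGH}.")
    }
  } else {
    if (!is.null(stage2) && stage2 != implied) {
      abort(paste0("stage1 = ", stage1, " forces escalation to ", implied, "."))
    }
    stage2 <- implied
  }
  structure(list(stage1 = stage1, stage2 = stage2), class = "static_regime")
}

#' @export
print.static_regime <- function(x, ...) {
  cat("Static regime: (", x$stage1, ", ", x$stage2, ")\n", sep = "")
  invisible(x)
}

# per-subject regime recommendations (stage-1 vector, stage-2 vector)
.regime_recommendations <- function(data, regime) {
  if (inherits(regime, "static_regime")) {
    pi1 <- rep(regime$stage1, nrow(data))
    pi2 <- rep(NA_character_, nrow(data))
    nonresp <- !is.na(data$RESPONSE1) & data$RESPONSE1 == 0
    pi2[nonresp & pi1 == "BUP"] <- "BUP_HIGH"
    pi2[nonresp & pi1 == "PAR"] <- "PAR_HIGH"
    pi2[nonresp & pi1 == "PBO"] <- regime$stage2
    list(pi1 = pi1, pi2 = pi2)
  } else if (inherits(regime, "dtr_fit")) {
    pi1 <- decide(regime, data, stage = 1)
    pi2 <- decide(regime, data, stage = 2)
    list(pi1 = pi1, pi2 = pi2)
  } else {
    abort("`regime` must be a static_regime or a dtr_fit.")
  }
}

# consistency indicator: observed treatments match recommendations at every
# decision actually made under the observed path
.regime_consistent <- function(data, rec) {
  c1 <- data$Trt1 == rec$pi1
  pnr <- !is.na(data$RESPONSE1) & data$RESPONSE1 == 0 & data$Trt1 == "PBO"
  c2 <- rep(TRUE, nrow(data))
  c2[pnr] <- data$Trt2[pnr] == rec$pi2[pnr]
  c1 & c2
}

.ipwe_point <- function(data, regime, propensities = NULL) {
  rec <- .regime_recommendations(data, regime)
  consistent <- .regime_consistent(data, rec)
  if (!any(consistent)) abort("No subject is consistent with this regime.")

  if (is.null(propensities)) {
    p1 <- prop.table(table(factor(data$Trt1, levels = .TRT1)))
    pnr <- !is.na(data$RESPONSE1) & data$RESPONSE1 == 0 & data$Trt1 == "PBO"
    p2bup <- mean(data$Trt2[pnr] == "BUP_HIGH")
  } else {
    p1 <- propensities$stage1[.TRT1]
    p2bup <- propensities$stage2_bup
    pnr <- !is.na(data$RESPONSE1) & data$RESPONSE1 == 0 & data$Trt1 == "PBO"
  }
  w <- 1 / as.numeric(p1[data$Trt1])
  w[pnr] <- w[pnr] / ifelse(data$Trt2[pnr] == "BUP_HIGH", p2bup, 1 - p2bup)
  if (any(consistent & !is.finite(w))) {
    abort("A regime-consistent subject has zero estimated propensity.")
  }
  wc <- w * consistent
  mu <- sum(wc * data$SUMD2) / sum(wc)
  list(point = mu,
       se = sqrt(sum((wc * (data$SUMD2 - mu))^2)) / sum(wc),
       n_effective = sum(wc)^2 / sum(wc^2))
}

#' Inverse-probability-weighted value of a regime
#'
#' Normalized (Hajek) weighted mean of the 12-week outcome over
#' regime-consistent subjects. Propensities default to empirical per-stage
#' frequencies (stage-1 arm shares overall; stage-2 shares among placebo
#' non-responders); pass `propensities = list(stage1 = c(BUP=, PAR=, PBO=),
#' stage2_bup = )` to use known design probabilities instead.
#'
#' @param data Complete cohort tibble (generator output or one imputed
#'   dataset).
#' @param regime A [static_regime()] or fitted [fit_qlearning()] regime.
#' @param propensities Optional known randomization probabilities.
#' @return One-row tibble: `estimate` (points, lower is better), `std.error`
#'   (linearization SE), `n_effective` (Kish effective weighted count).
#' @export
ipwe <- function(data, regime, propensities = NULL) {
  res <- .ipwe_point(tibble::as_tibble(data), regime, propensities)
  tibble::tibble(estimate = res$point, std.error = res$se,
                 n_effective = res$n_effective)
}

#' Compare regime values with common bootstrap resamples
#'
#' IPWE point estimates for each regime plus percentile bootstrap intervals
#' computed on a single shared set of subject resamples, so differences
#' between rows are comparable. The default regime list mirrors the published
#' comparison: the estimated regime (when supplied) and the four static
#' regimes.
#'
#' @param data Complete cohort tibble.
#' @param regimes Named list of regimes ([static_regime()] or `dtr_fit`).
#'   See [table4_regimes()] for the standard five-row layout.
#' @param B Bootstrap replicates.
#' @param level Confidence level (default 0.90).
#' @param propensities Optional known randomization probabilities (otherwise
#'   re-estimated empirically inside every resample).
#' @param seed Optional seed.
#' @return A tibble of class `regime_values`: `regime`, `estimate`,
#'   `conf.low`, `conf.high`, `n_effective`.
#' @export
compare_regimes <- function(data, regimes, B = 200, level = 0.90,
                            propensities = NULL, seed = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(names(regimes)) || any(names(regimes) == "")) {
    abort("`regimes` must be a named list.")
  }
  n <- nrow(data)
  .with_seed(seed, {
    pts <- lapply(regimes, function(r) .ipwe_point(data, r, propensities))
    reps <- matrix(NA_real_, nrow = B, ncol = length(regimes),
                   dimnames = list(NULL, names(regimes)))
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      dat_b <- data[idx, , drop = FALSE]
      for (j in seq_along(regimes)) {
        reps[b, j] <- tryCatch(
          .ipwe_point(dat_b, regimes[[j]], propensities)$point,
          error = function(e) NA_real_)
      }
    }
    alpha <- (1 - level) / 2
    out <- tibble::tibble(
      regime = names(regimes),
      estimate = unname(vapply(pts, `[[`, 0, "point")),
      conf.low = unname(apply(reps, 2, quantile, probs = alpha, na.rm = TRUE,
                              names = FALSE, type = 1)),
      conf.high = unname(apply(reps, 2, quantile, probs = 1 - alpha,
                               na.rm = TRUE, names = FALSE, type = 1)),
      n_effective = unname(vapply(pts, `[[`, 0, "n_effective"))
    )
    attr(out, "replicates") <- reps
    attr(out, "level") <- level
    class(out) <- c("regime_values", class(out))
    out
  })
}

#' Standard five-regime comparison list
#'
#' The estimated regime (if a fit is supplied) followed by the four static
#' regimes: (Bupropion, high-dose Bupropion), (Paroxetine, high-dose
#' Paroxetine), (placebo, high-dose Bupropion), (placebo, high-dose
#' Paroxetine).
#'
#' @param fit Optional `dtr_fit` for the estimated-regime row.
#' @return Named list of regimes.
#' @export
table4_regimes <- function(fit = NULL) {
  out <- list(
    "(BUP, BUP_HIGH)" = static_regime("BUP"),
    "(PAR, PAR_HIGH)" = static_regime("PAR"),
    "(PBO, BUP_HIGH)" = static_regime("PBO", "BUP_HIGH"),
    "(PBO, PAR_HIGH)" = static_regime("PBO", "PAR_HIGH")
  )
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "dtr_fit"))
    out <- c(list("Estimated DTR" = fit), out)
  }
  out
}
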