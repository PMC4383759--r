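# Nonparametric bootstrap confidence intervals for the Q-function
# coefficients. Subjects are resampled with replacement and the whole
# estimation pipeline (imputation, when the data carry missingness, then
# backward-induction Q-learning) is re-run on each replicate; intervals are
# percentile intervals. Term specifications are frozen: variable selection is
# done once on the original data, never inside replicates, so the intervals
# refer to the single selected model.
#
# The stage-1 estimand is non-regular: the pseudo-outcome takes a minimum
# over stage-2 treatments, which is non-smooth where the stage-2 contrast is
# near zero. The optional soft-threshold correction shrinks each subject's
# estimated contrast c toward zero by the factor (1 - lambda/c^2)+ with
# lambda = Var(c) * z^2 before the minimum is taken, suppressing the
# contribution of subjects whose contrast is statistically indistinguishable
# from zero.

# fast complete-data Q-learning refit used inside bootstrap replicates:
# design matrices are built once on the full cohort and re-indexed
.qfit_prepare <- function(data, stage1, stage2) {
  enc <- encode_model_terms(data)
  list(
    X20 = .design(enc, stage2$h20),
    X21 = .design(enc, stage2$h21),
    X10 = .design(enc, stage1$h10),
    X11 = .design(enc, stage1$h11),
    X12 = .design(enc, stage1$h12),
    A2 = enc$A2, A11 = enc$A11, A12 = enc$A12,
    y = enc$SUMD2,
    pnr = !is.na(enc$Trt1) & enc$Trt1 == "PBO" &
      !is.na(enc$RESPONSE1) & enc$RESPONSE1 == 0,
    s2names = c(colnames(.design(enc[0, ], stage2$h20)), "A2",
                paste0("A2:", stage2$h21, recycle0 = TRUE)),
    s1names = c(colnames(.design(enc[0, ], stage1$h10)),
                "A11", paste0("A11:", stage1$h11, recycle0 = TRUE),
                "A12", paste0("A12:", stage1$h12, recycle0 = TRUE))
  )
}

.qfit_coefs <- function(prep, idx, shrink = NULL) {
  pnr <- prep$pnr[idx]
  r2 <- idx[pnr & !is.na(prep$A2[idx])]
  k2 <- ncol(prep$X20) + ncol(prep$X21)
  if (length(r2) < k2 + 2) return(NULL)
  X2 <- cbind(prep$X20[r2, , drop = FALSE],
              prep$A2[r2] * prep$X21[r2, , drop = FALSE])
  f2 <- stats::lm.fit(X2, prep$y[r2])
  if (f2$rank < k2) return(NULL)
  beta <- f2$coefficients
  b20 <- beta[seq_len(ncol(prep$X20))]
  b21 <- beta[(ncol(prep$X20) + 1):k2]

  ps <- prep$y[idx]
  rows <- which(pnr)
  if (length(rows) > 0) {
    Xp0 <- prep$X20[idx[rows], , drop = FALSE]
    Xp1 <- prep$X21[idx[rows], , drop = FALSE]
    cont <- drop(Xp1 %*% b21)
    if (!is.null(shrink)) {
      sigma2 <- sum(f2$residuals^2) / (length(r2) - k2)
      xtx_inv <- chol2inv(qr.R(f2$qr))[order(f2$qr$pivot),
                                       order(f2$qr$pivot), drop = FALSE]
      i21 <- (ncol(prep$X20) + 1):k2
      Sigma <- sigma2 * xtx_inv[i21, i21, drop = FALSE]
      v <- rowSums((Xp1 %*% Sigma) * Xp1)
      cont <- cont * pmax(0, 1 - (v * shrink^2) / cont^2)
    }
    ps[rows] <- drop(Xp0 %*% b20) + pmin(0, cont)
  }

  X1 <- cbind(prep$X10[idx, , drop = FALSE],
              prep$A11[idx] * prep$X11[idx, , drop = FALSE],
              prep$A12[idx] * prep$X12[idx, , drop = FALSE])
  f1 <- stats::lm.fit(X1, ps)
  if (f1$rank < ncol(X1)) return(NULL)
  setNames(c(beta, f1$coefficients),
           c(paste0("s2:", prep$s2names), paste0("s1:", prep$s1names)))
}

# replicate coefficients via the general path (with imputation)
.qfit_coefs_mi <- function(data, idx, stage1, stage2, m, sweeps, specs,
                           pmm_donors) {
  dat_b <- data[idx, , drop = FALSE]
  imps <- impute_cohort(dat_b, m = m, sweeps = sweeps, specs = specs,
                        pmm_donors = pmm_donors)
  fit <- tryCatch(fit_qlearning(imps, stage1, stage2),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  td <- tidy(fit)
  setNames(td$estimate, paste0("s", td$stage, ":", td$term))
}

#' Bootstrap confidence intervals for Q-function coefficients
#'
#' Resamples subjects with replacement, re-runs the estimation pipeline on
#' each replicate (imputing first when the data contain missingness) and
#' returns percentile intervals for every stage-1 and stage-2 coefficient.
#' Replicates whose placebo non-responder subset is too small or rank
#' deficient are dropped and counted; more than 10% dropped is an error.
#'
#' @param data Cohort tibble (with or without missingness).
#' @param stage1,stage2 Frozen term specifications ([stage1_terms()],
#'   [stage2_terms()]); selection is never redone inside replicates.
#' @param B Number of bootstrap replicates (>= 2).
#' @param level Confidence level in (0, 1); default 0.90.
#' @param correction `"none"` or `"soft_threshold"` (non-regularity
#'   correction of the stage-1 pseudo-outcome; see the package vignette).
#' @param m Imputations per replicate when the data have missingness
#'   (default 5, a deliberately reduced count for tractability).
#' @param sweeps Chained-equation sweeps per imputation inside replicates.
#' @param impute_specs Optional frozen predictor specs for imputation inside
#'   replicates; defaults to specs selected once on the original data.
#' @param pmm_donors PMM donor-pool size.
#' @param seed Optional seed; identical seed and config give identical
#'   intervals.
#' @return Tibble with columns `stage`, `term`, `estimate`, `conf.low`,
#'   `conf.high` plus attributes `replicates` (coefficient matrix),
#'   `dropped`, `level`, `correction`.
#' @export
bootstrap_ci <- function(data, stage1 = stage1_terms(),
                         stage2 = stage2_terms(), B = 200, level = 0.90,
                         correction = c("none", "soft_threshold"),
                         m = 5, sweeps = 5, impute_specs = NULL,
                         pmm_donors = 5, seed = NULL) {
  correction <- match.arg(correction)
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  if (B < 2) abort("`B` must be at least 2.")
  data <- tibble::as_tibble(data)
  core <- setdiff(names(data), c("id", "Trt2"))
  has_na <- any(vapply(data[core], anyNA, logical(1)))
  n <- nrow(data)
  shrink <- if (correction == "soft_threshold") qnorm(1 - (1 - level) / 2) else NULL

  .with_seed(seed, {
    if (has_na) {
      if (is.null(impute_specs)) {
        incomplete <- core[vapply(data[core], anyNA, logical(1))]
        impute_specs <- lapply(setNames(incomplete, incomplete), function(v) {
          select_conditional_predictors(data, v)
        })
      }
      imps0 <- impute_cohort(data, m = m, sweeps = sweeps,
                             specs = impute_specs, pmm_donors = pmm_donors)
      fit0 <- fit_qlearning(imps0, stage1, stage2)
      td <- tidy(fit0)
      point <- setNames(td$estimate, paste0("s", td$stage, ":", td$term))
    } else {
      prep <- .qfit_prepare(data, stage1, stage2)
      point <- .qfit_coefs(prep, seq_len(n), shrink = shrink)
      if (is.null(point)) abort("Point estimate could not be computed (degenerate stage-2 subset).")
    }

    reps <- matrix(NA_real_, nrow = B, ncol = length(point),
                   dimnames = list(NULL, names(point)))
    dropped <- 0L
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      cf <- if (has_na) {
        .qfit_coefs_mi(data, idx, stage1, stage2, m, sweeps, impute_specs,
                       pmm_donors)
      } else {
        .qfit_coefs(prep, idx, shrink = shrink)
      }
      if (is.null(cf)) dropped <- dropped + 1L else reps[b, ] <- cf[names(point)]
    }
    if (dropped > 0.10 * B) {
      abort(paste0(dropped, " of ", B,
                   " replicates degenerate (> 10%); cohort too small for the bootstrap."))
    }
    reps <- reps[stats::complete.cases(reps), , drop = FALSE]
    alpha <- (1 - level) / 2
    # inverse-ECDF percentile ends: at B = 2 this degenerates to min/max
    lo <- apply(reps, 2, quantile, probs = alpha, names = FALSE, type = 1)
    hi <- apply(reps, 2, quantile, probs = 1 - alpha, names = FALSE, type = 1)
    out <- tibble::tibble(
      stage = as.integer(sub("^s(\\d).*", "\\1", names(point))),
      term = sub("^s\\d:", "", names(point)),
      estimate = unname(point),
      conf.low = unname(lo),
      conf.high = unname(hi)
    )
    attr(out, "replicates") <- reps
    attr(out, "dropped") <- dropped
    attr(out, "level") <- level
    attr(out, "correction") <- correction
    out
  })
}
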