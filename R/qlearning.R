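# Backward-induction Q-learning with linear working models for the two-stage
# SMART design. Stage 2 is fit by OLS on placebo non-responders only (the only
# subjects re-randomized); the pseudo-outcome substitutes, for those subjects,
# the best achievable predicted stage-2 outcome; stage 1 is fit by OLS of the
# pseudo-outcome on all subjects. With multiply imputed data the decision rule
# is the argmin of the Q-functions averaged over imputations.

#' Stage-2 working-model term specification
#'
#' Term lists for the second-stage Q-function
#' \eqn{Q_2(h_2, a_2) = h_{20}^T \beta_{20} + a_2 h_{21}^T \beta_{21}}, where
#' `a2 = 1` codes high-dose Bupropion and `a2 = 0` high-dose Paroxetine. The
#' intercept is implicit in both lists (so `h21 = character(0)` still includes
#' the `A2` main effect). Defaults are the published selected model.
#'
#' @param h20 Character vector of main-effect terms.
#' @param h21 Character vector of treatment-interaction terms.
#' @return A named list with elements `h20`, `h21`.
#' @export
stage2_terms <- function(h20 = c("SUMM1", "SUMD1", "SIDE3"),
                         h21 = c("SUMM1", "SIDE3")) {
  list(h20 = h20, h21 = h21)
}

#' Stage-1 working-model term specification
#'
#' Term lists for the first-stage Q-function
#' \eqn{Q_1(h_1, a_1) = h_{10}^T \beta_{10} + a_{11} h_{11}^T \beta_{11} +
#' a_{12} h_{12}^T \beta_{12}}, with `a11 = 1` iff Bupropion and `a12 = 1` iff
#' Paroxetine (placebo is the reference). Intercepts are implicit in all three
#' lists. Defaults are the published selected model.
#'
#' @param h10 Main-effect terms.
#' @param h11 Terms interacting with the Bupropion dummy.
#' @param h12 Terms interacting with the Paroxetine dummy.
#' @return A named list with elements `h10`, `h11`, `h12`.
#' @export
stage1_terms <- function(h10 = c("AGE", "SUMM0", "SUMD0", "PRONSET1", "PRONSET2"),
                         h11 = c("AGE", "PRONSET1", "PRONSET2"),
                         h12 = c("AGE", "PRONSET1", "PRONSET2")) {
  list(h10 = h10, h11 = h11, h12 = h12)
}

# design-matrix column for a term; "A:B" terms are products of encoded columns
.term_col <- function(enc, term) {
  if (grepl(":", term, fixed = TRUE)) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    x <- rep(1, nrow(enc))
    for (p in parts) {
      if (is.null(enc[[p]])) abort(paste0("Unknown term column: ", p))
      x <- x * enc[[p]]
    }
    x
  } else {
    if (is.null(enc[[term]])) abort(paste0("Unknown term column: ", term))
    enc[[term]]
  }
}

.design <- function(enc, terms) {
  X <- matrix(1, nrow = nrow(enc), ncol = 1 + length(terms),
              dimnames = list(NULL, c("(Intercept)", terms)))
  for (j in seq_along(terms)) X[, j + 1] <- .term_col(enc, terms[[j]])
  X
}

# OLS with rank check; returns coefficients, residual variance and the
# unscaled inverse Gram matrix
.fit_ols <- function(X, y, context = "regression") {
  if (nrow(X) < ncol(X) + 2) {
    abort(paste0("Too few rows (", nrow(X), ") to fit ", context,
                 " with ", ncol(X), " coefficients."))
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    abort(paste0("Rank-deficient design in ", context, "; collinear term(s): ",
                 paste(dropped, collapse = ", ")))
  }
  beta <- qr.coef(qrx, y)
  res <- y - drop(X %*% beta)
  df <- nrow(X) - ncol(X)
  R <- qr.R(qrx)
  xtx_inv <- chol2inv(R)[order(qrx$pivot), order(qrx$pivot), drop = FALSE]
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  list(coef = beta, sigma2 = sum(res^2) / df, rss = sum(res^2),
       xtx_inv = xtx_inv, n = nrow(X), k = ncol(X))
}

# rows entering the stage-2 regression: placebo non-responders with observed
# stage-2 treatment and outcome
.stage2_rows <- function(enc) {
  which(!is.na(enc$Trt1) & enc$Trt1 == "PBO" &
          !is.na(enc$RESPONSE1) & enc$RESPONSE1 == 0 &
          !is.na(enc$A2) & !is.na(enc$SUMD2))
}

#' Fit the second-stage Q-function
#'
#' OLS of the 12-week outcome on `[h20 terms, a2 * h21 terms]` over placebo
#' non-responders only — the one stratum re-randomized at stage 2. Rows in
#' other arms or responders never enter the fit.
#'
#' @param data Complete (or imputed) cohort tibble.
#' @param terms A [stage2_terms()] specification.
#' @return A `stage2_fit` object: coefficient vectors `beta20`/`beta21`,
#'   residual variance, the unscaled coefficient covariance, and the subset
#'   size `n`.
#' @export
fit_stage2 <- function(data, terms = stage2_terms()) {
  enc <- encode_model_terms(data)
  rows <- .stage2_rows(enc)
  sub <- enc[rows, , drop = FALSE]
  X20 <- .design(sub, terms$h20)
  X21 <- .design(sub, terms$h21)
  X <- cbind(X20, sub$A2 * X21)
  colnames(X) <- c(colnames(X20),
                   c("A2", paste0("A2:", terms$h21, recycle0 = TRUE)))
  fit <- .fit_ols(X, sub$SUMD2, context = "the stage-2 Q-model")
  k20 <- ncol(X20)
  structure(
    list(terms = terms,
         coef = fit$coef,
         beta20 = fit$coef[seq_len(k20)],
         beta21 = fit$coef[(k20 + 1):length(fit$coef)],
         sigma2 = fit$sigma2, rss = fit$rss, xtx_inv = fit$xtx_inv,
         n = fit$n, k = fit$k),
    class = "stage2_fit"
  )
}

# a2-contrast h21' beta21 per row, and its estimated variance if requested
.stage2_contrast <- function(fit, enc, se = FALSE) {
  X21 <- .design(enc, fit$terms$h21)
  cont <- drop(X21 %*% fit$beta21)
  if (!se) return(list(contrast = cont))
  idx <- (length(fit$beta20) + 1):length(fit$coef)
  Sigma <- fit$sigma2 * fit$xtx_inv[idx, idx, drop = FALSE]
  v <- rowSums((X21 %*% Sigma) * X21)
  list(contrast = cont, var = v)
}

#' Construct the stage-1 pseudo-outcome
#'
#' For placebo non-responders the pseudo-outcome is the minimum of the fitted
#' stage-2 Q-function over the two feasible high-dose treatments,
#' \eqn{h_{20}^T \hat\beta_{20} + \min(0, h_{21}^T \hat\beta_{21})}; everyone
#' else (responders in any arm and drug-arm non-responders, whose dose
#' escalation is deterministic, not a decision) contributes their observed
#' outcome.
#'
#' @param data Complete (or imputed) cohort tibble.
#' @param fit A `stage2_fit` object.
#' @param shrink Optional per-row shrinkage of the a2-contrast used by the
#'   non-regularity correction: when a positive `shrink` is supplied, the
#'   contrast `c` is replaced by `c * max(0, 1 - lambda / c^2)` with
#'   `lambda = Var(c) * shrink^2` before taking the minimum.
#' @return Numeric vector of pseudo-outcomes, one per row of `data`.
#' @export
pseudo_outcome <- function(data, fit, shrink = NULL) {
  enc <- encode_model_terms(data)
  rows <- which(!is.na(enc$Trt1) & enc$Trt1 == "PBO" &
                  !is.na(enc$RESPONSE1) & enc$RESPONSE1 == 0)
  out <- enc$SUMD2
  if (length(rows) == 0) return(out)
  sub <- enc[rows, , drop = FALSE]
  X20 <- .design(sub, fit$terms$h20)
  cs <- .stage2_contrast(fit, sub, se = !is.null(shrink))
  cont <- cs$contrast
  if (!is.null(shrink)) {
    lambda <- cs$var * shrink^2
    cont <- cont * pmax(0, 1 - lambda / cont^2)
  }
  out[rows] <- drop(X20 %*% fit$beta20) + pmin(0, cont)
  out
}

#' Fit the first-stage Q-function
#'
#' OLS of the pseudo-outcome on
#' `[h10 terms, a11 * h11 terms, a12 * h12 terms]` over all subjects.
#'
#' @param data Complete (or imputed) cohort tibble.
#' @param pseudo Pseudo-outcome vector from [pseudo_outcome()].
#' @param terms A [stage1_terms()] specification.
#' @return A `stage1_fit` object with coefficient vectors `beta10`, `beta11`,
#'   `beta12`.
#' @export
fit_stage1 <- function(data, pseudo, terms = stage1_terms()) {
  enc <- encode_model_terms(data)
  keep <- which(!is.na(pseudo))
  sub <- enc[keep, , drop = FALSE]
  X10 <- .design(sub, terms$h10)
  X11 <- .design(sub, terms$h11)
  X12 <- .design(sub, terms$h12)
  X <- cbind(X10, sub$A11 * X11, sub$A12 * X12)
  colnames(X) <- c(colnames(X10),
                   c("A11", paste0("A11:", terms$h11, recycle0 = TRUE)),
                   c("A12", paste0("A12:", terms$h12, recycle0 = TRUE)))
  fit <- .fit_ols(X, pseudo[keep], context = "the stage-1 Q-model")
  k10 <- ncol(X10)
  k11 <- ncol(X11)
  structure(
    list(terms = terms,
         coef = fit$coef,
         beta10 = fit$coef[seq_len(k10)],
         beta11 = fit$coef[k10 + seq_len(k11)],
         beta12 = fit$coef[(k10 + k11 + 1):length(fit$coef)],
         sigma2 = fit$sigma2, rss = fit$rss, xtx_inv = fit$xtx_inv,
         n = fit$n, k = fit$k),
    class = "stage1_fit"
  )
}

#' Fit a two-stage Q-learning regime
#'
#' Runs the backward induction (stage-2 fit, pseudo-outcome, stage-1 fit) on a
#' single complete cohort or on every completed dataset of an imputation set.
#' The resulting decision rule is the argmin of the Q-functions averaged over
#' the fitted models, the standard pooling rule for multiply imputed data.
#'
#' @param data A complete cohort tibble or an `imputation_set` from
#'   [impute_cohort()].
#' @param stage1 A [stage1_terms()] specification.
#' @param stage2 A [stage2_terms()] specification.
#' @return A `dtr_fit` object holding per-imputation `stage1_fit` and
#'   `stage2_fit` lists and the term specifications.
#' @export
fit_qlearning <- function(data, stage1 = stage1_terms(),
                          stage2 = stage2_terms()) {
  cohorts <- if (inherits(data, "imputation_set")) data$cohorts else list(data)
  s2 <- vector("list", length(cohorts))
  s1 <- vector("list", length(cohorts))
  for (l in seq_along(cohorts)) {
    s2[[l]] <- fit_stage2(cohorts[[l]], stage2)
    ps <- pseudo_outcome(cohorts[[l]], s2[[l]])
    s1[[l]] <- fit_stage1(cohorts[[l]], ps, stage1)
  }
  structure(
    list(stage1_fits = s1, stage2_fits = s2,
         stage1_terms = stage1, stage2_terms = stage2,
         m = length(cohorts), n = nrow(cohorts[[1]])),
    class = "dtr_fit"
  )
}

#' Recommend treatment from a fitted regime
#'
#' Returns the treatment minimizing the imputation-averaged Q-function over
#' the feasible set of each history. At stage 2, subjects whose feasible set
#' is a singleton (drug-arm non-responders) get that treatment without
#' evaluating the model, and responders (empty feasible set) get `NA`. Ties
#' are broken deterministically toward placebo at stage 1 and toward
#' high-dose Paroxetine at stage 2. Histories with missing values in required
#' terms raise an error.
#'
#' @param object A `dtr_fit`.
#' @param newdata Tibble of histories; stage 2 additionally requires `Trt1`
#'   and `RESPONSE1`.
#' @param stage Decision stage, 1 or 2.
#' @return Character vector of recommended treatments.
#' @export
decide <- function(object, newdata, stage) {
  stopifnot(inherits(object, "dtr_fit"))
  enc <- encode_model_terms(newdata)
  if (stage == 1) {
    tm <- object$stage1_terms
    need <- unique(unlist(strsplit(c(tm$h10, tm$h11, tm$h12), ":", fixed = TRUE)))
    if (anyNA(enc[, need])) {
      abort("Missing values in stage-1 history terms; impute before deciding.")
    }
    X10 <- .design(enc, tm$h10)
    X11 <- .design(enc, tm$h11)
    X12 <- .design(enc, tm$h12)
    base <- rep(0, nrow(enc)); cb <- rep(0, nrow(enc)); cp <- rep(0, nrow(enc))
    for (f in object$stage1_fits) {
      base <- base + drop(X10 %*% f$beta10)
      cb <- cb + drop(X11 %*% f$beta11)
      cp <- cp + drop(X12 %*% f$beta12)
    }
    # base cancels in the argmin; contrasts are vs placebo
    cb <- cb / object$m
    cp <- cp / object$m
    q <- cbind(BUP = cb, PAR = cp, PBO = 0)
    apply(q, 1, function(r) {
      best <- names(r)[r == min(r)]
      if ("PBO" %in% best) "PBO" else if ("PAR" %in% best) "PAR" else "BUP"
    })
  } else if (stage == 2) {
    if (is.null(enc$Trt1) || is.null(enc$RESPONSE1) ||
        anyNA(enc$Trt1) || anyNA(enc$RESPONSE1)) {
      abort("Stage-2 decisions need complete `Trt1` and `RESPONSE1`.")
    }
    out <- rep(NA_character_, nrow(enc))
    out[enc$RESPONSE1 == 0 & enc$Trt1 == "BUP"] <- "BUP_HIGH"
    out[enc$RESPONSE1 == 0 & enc$Trt1 == "PAR"] <- "PAR_HIGH"
    pnr <- which(enc$RESPONSE1 == 0 & enc$Trt1 == "PBO")
    if (length(pnr) > 0) {
      tm <- object$stage2_terms
      need <- unique(unlist(strsplit(tm$h21, ":", fixed = TRUE)))
      sub <- enc[pnr, , drop = FALSE]
      if (length(need) > 0 && anyNA(sub[, need])) {
        abort("Missing values in stage-2 history terms; impute before deciding.")
      }
      cont <- rep(0, length(pnr))
      for (f in object$stage2_fits) {
        cont <- cont + .stage2_contrast(f, sub)$contrast
      }
      # A2 = 1 is BUP_HIGH; tie (contrast 0) goes to PAR_HIGH
      out[pnr] <- ifelse(cont / object$m < 0, "BUP_HIGH", "PAR_HIGH")
    }
    out
  } else {
    abort("`stage` must be 1 or 2.")
  }
}

#' @export
print.dtr_fit <- function(x, ...) {
  cat("Two-stage Q-learning fit (", x$m, " imputation(s), n = ", x$n, ")\n",
      sep = "")
  cat("Stage 2 (placebo non-responders, n = ",
      round(mean(vapply(x$stage2_fits, `[[`, 0, "n"))), "):\n", sep = "")
  s2 <- colMeans(do.call(rbind, lapply(x$stage2_fits, `[[`, "coef")))
  print(round(s2, 3))
  cat("Stage 1 (all subjects):\n")
  s1 <- colMeans(do.call(rbind, lapply(x$stage1_fits, `[[`, "coef")))
  print(round(s1, 3))
  invisible(x)
}

#' Tidy a fitted regime
#'
#' @param x A `dtr_fit`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient: `stage`, `term`, `estimate`
#'   (imputation-averaged).
#' @method tidy dtr_fit
#' @export
tidy.dtr_fit <- function(x, ...) {
  s2 <- colMeans(do.call(rbind, lapply(x$stage2_fits, `[[`, "coef")))
  s1 <- colMeans(do.call(rbind, lapply(x$stage1_fits, `[[`, "coef")))
  dplyr::bind_rows(
    tibble::tibble(stage = 2L, term = names(s2), estimate = unname(s2)),
    tibble::tibble(stage = 1L, term = names(s1), estimate = unname(s1))
  )
}

#' Glance at a fitted regime
#'
#' @param x A `dtr_fit`.
#' @param ... Unused.
#' @return One-row tibble: `m`, `n`, `n_stage2` (mean stage-2 subset size),
#'   `sigma_stage2`, `sigma_stage1` (mean residual SDs).
#' @method glance dtr_fit
#' @export
glance.dtr_fit <- function(x, ...) {
  tibble::tibble(
    m = x$m, n = x$n,
    n_stage2 = mean(vapply(x$stage2_fits, `[[`, 0, "n")),
    sigma_stage2 = mean(sqrt(vapply(x$stage2_fits, `[[`, 0, "sigma2"))),
    sigma_stage1 = mean(sqrt(vapply(x$stage1_fits, `[[`, 0, "sigma2")))
  )
}
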