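# Multiple imputation by chained equations. Conditional models per variable:
# predictive mean matching (PMM) for continuous targets, logistic regression
# for binary targets, multinomial logistic for 3-level categoricals. Predictors
# of each conditional model are chosen by forward stepwise BIC on complete
# cases. Parameter draws use the Bayesian linear/ML sampling distribution under
# flat priors, so imputations are proper (they carry between-imputation
# variance).

.col_family <- function(x) {
  if (is.character(x)) return("multinomial")
  ux <- unique(x[!is.na(x)])
  if (all(ux %in% c(0, 1))) "logistic" else "pmm"
}

.gaussian_bic <- function(rss, n, k) n * log(rss / n) + k * log(n)

# fit one conditional model family on a data frame and return BIC
.cond_bic <- function(df, target, family) {
  n <- nrow(df)
  if (family == "pmm") {
    fit <- lm(stats::reformulate(".", response = target), data = df)
    k <- sum(!is.na(coef(fit)))
    .gaussian_bic(sum(stats::residuals(fit)^2), n, k + 1)
  } else if (family == "logistic") {
    fit <- suppressWarnings(
      glm(stats::reformulate(".", response = target), data = df,
          family = binomial()))
    fit$deviance + sum(!is.na(coef(fit))) * log(n)
  } else {
    fit <- nnet::multinom(stats::reformulate(".", response = target),
                          data = df, trace = FALSE)
    fit$deviance + length(coef(fit)) * log(n)
  }
}

#' Select predictors for a conditional imputation model
#'
#' Forward stepwise selection on complete cases: starting from the
#' intercept-only model, repeatedly add the candidate that most decreases the
#' BIC of the conditional model for `target`, stopping when no addition
#' decreases it. The model family follows the column type (continuous,
#' binary, or categorical).
#'
#' @param data Cohort tibble (may contain missingness).
#' @param target Column to be imputed.
#' @param candidates Candidate predictor columns; defaults to every schema
#'   column except `id`, `Trt2` (structurally missing for responders) and the
#'   target itself.
#' @return Character vector of selected predictors (possibly empty).
#' @export
select_conditional_predictors <- function(data, target, candidates = NULL) {
  if (is.null(candidates)) {
    candidates <- setdiff(intersect(.COHORT_COLS, names(data)),
                          c("id", "Trt2", target))
  }
  candidates <- setdiff(candidates, target)
  df <- as.data.frame(data[, c(target, candidates)])
  for (v in names(df)) if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < length(candidates) + 5) {
    abort(paste0("Too few complete cases (", nrow(df),
                 ") to select predictors for ", target,
                 "; fall back to marginal imputation."))
  }
  family <- .col_family(data[[target]])

  selected <- character(0)
  best <- .cond_bic(df[, target, drop = FALSE], target, family)
  repeat {
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0) break
    scores <- vapply(remaining, function(v) {
      tryCatch(.cond_bic(df[, c(target, selected, v), drop = FALSE],
                         target, family),
               error = function(e) Inf)
    }, numeric(1))
    if (min(scores) >= best) break
    pick <- remaining[which.min(scores)]
    selected <- c(selected, pick)
    best <- min(scores)
  }
  selected
}

# ---- conditional draws -----------------------------------------------------

# Bayesian linear model draw + predictive mean matching against observed donors
.draw_pmm <- function(y_obs, X_obs, X_mis, donors) {
  qrx <- qr(X_obs)
  keep <- qrx$pivot[seq_len(qrx$rank)]
  X_obs <- X_obs[, keep, drop = FALSE]
  X_mis <- X_mis[, keep, drop = FALSE]
  qrx <- qr(X_obs)
  beta_hat <- qr.coef(qrx, y_obs)
  res <- y_obs - drop(X_obs %*% beta_hat)
  df <- max(nrow(X_obs) - ncol(X_obs), 1)
  sigma2_star <- sum(res^2) / rchisq(1, df)
  R <- qr.R(qrx)
  # beta* ~ N(beta_hat, sigma2* (X'X)^-1); (X'X)^-1 = R^-1 R^-T
  u <- backsolve(R, rnorm(ncol(X_obs)))
  beta_star <- beta_hat[qrx$pivot] + sqrt(sigma2_star) * u
  beta_star <- beta_star[order(qrx$pivot)]
  pred_obs <- drop(X_obs %*% beta_hat)
  pred_mis <- drop(X_mis %*% beta_star)

  ord <- order(pred_obs)
  po <- pred_obs[ord]
  yo <- y_obs[ord]
  n_obs <- length(po)
  vapply(pred_mis, function(p) {
    i <- findInterval(p, po)
    lo <- max(1, i - donors)
    hi <- min(n_obs, i + donors)
    idx <- lo:hi
    d <- abs(po[idx] - p)
    pool <- idx[order(d)][seq_len(min(donors, length(idx)))]
    yo[sample(pool, 1)]
  }, numeric(1))
}

.draw_logistic <- function(y_obs, X_obs, X_mis) {
  fit <- suppressWarnings(glm.fit(X_obs, y_obs, family = binomial()))
  beta_hat <- coef(fit)
  ok <- !is.na(beta_hat)
  # asymptotic posterior draw: N(beta_hat, (X'WX)^-1)
  w <- fit$weights
  XtWX <- crossprod(X_obs[, ok, drop = FALSE] * sqrt(w))
  V <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  beta_star <- beta_hat[ok]
  if (!is.null(V)) {
    beta_star <- beta_star + drop(t(chol(V)) %*% rnorm(sum(ok)))
  }
  p <- plogis(drop(X_mis[, ok, drop = FALSE] %*% beta_star))
  rbinom(length(p), 1, p)
}

.draw_multinomial <- function(y_obs, df_obs, df_mis) {
  lev <- sort(unique(y_obs))
  if (length(lev) == 1) return(rep(lev, nrow(df_mis)))
  df_obs$.y <- factor(y_obs, levels = lev)
  fit <- nnet::multinom(.y ~ ., data = df_obs, trace = FALSE)
  # approximate posterior draw of the coefficient vector
  th <- coef(fit)
  V <- tryCatch(vcov(fit), error = function(e) NULL)
  if (!is.null(V) && all(is.finite(V))) {
    thv <- if (is.matrix(th)) as.vector(t(th)) else th
    draw <- tryCatch(thv + drop(t(chol(V + diag(1e-10, nrow(V)))) %*%
                                  rnorm(length(thv))),
                     error = function(e) thv)
    if (is.matrix(th)) {
      th2 <- matrix(draw, nrow = nrow(th), byrow = TRUE,
                    dimnames = dimnames(th))
      # rebuild probabilities manually from the drawn coefficients
      mm <- stats::model.matrix(stats::delete.response(stats::terms(fit)),
                                data = df_mis)
      eta <- mm %*% t(th2)
      pr <- cbind(1, exp(eta))
      pr <- pr / rowSums(pr)
    } else {
      mm <- stats::model.matrix(stats::delete.response(stats::terms(fit)),
                                data = df_mis)
      eta <- drop(mm %*% draw)
      pr <- cbind(1 - plogis(eta), plogis(eta))
    }
  } else {
    pr <- predict(fit, newdata = df_mis, type = "probs")
    if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)
  }
  lev[apply(pr, 1, function(p) sample(length(lev), 1, prob = pmax(p, 0)))]
}

# ---- chained equations -----------------------------------------------------

.model_frame <- function(data, predictors) {
  df <- as.data.frame(data[, predictors, drop = FALSE])
  for (v in names(df)) if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  df
}

#' Impute a cohort by chained equations
#'
#' Produces `m` completed cohorts. Missing cells are initialized by random
#' draws from the observed marginal of each column, then updated over
#' `sweeps` Gibbs-style passes: each incomplete column in turn is regressed on
#' its selected predictors (using current completed values) on the rows where
#' it is observed, parameters are drawn from their sampling distribution under
#' flat priors, and the missing cells are redrawn — via PMM donor matching for
#' continuous columns (imputed values are always observed donor values),
#' Bernoulli draws from a logistic model for binary columns, and categorical
#' draws from a multinomial model otherwise. Chains are independent across
#' imputations and the whole procedure is deterministic given `seed`.
#'
#' @param data Cohort tibble with missingness (`NA` cells).
#' @param m Number of completed datasets.
#' @param seed Optional seed.
#' @param sweeps Chained-equation passes per imputation (default 10).
#' @param specs Optional named list of per-target predictor vectors; by
#'   default predictors are chosen by [select_conditional_predictors()].
#' @param pmm_donors Donor-pool size for PMM (default 5).
#' @return An `imputation_set`: list with `cohorts` (length `m`), `m`,
#'   `specs`, `seed`. Observed cells are bitwise identical to the input in
#'   every completed cohort.
#' @export
impute_cohort <- function(data, m = 25, seed = NULL, sweeps = 10,
                          specs = NULL, pmm_donors = 5) {
  data <- tibble::as_tibble(data)
  core <- setdiff(names(data), c("id", "Trt2"))
  incomplete <- core[vapply(data[core], anyNA, logical(1))]
  fully_missing <- incomplete[vapply(data[incomplete],
                                     function(x) all(is.na(x)), logical(1))]
  if (length(fully_missing) > 0) {
    abort(paste0("Column(s) entirely missing, cannot initialize: ",
                 paste(fully_missing, collapse = ", ")))
  }

  if (length(incomplete) == 0) {
    return(structure(list(cohorts = rep(list(data), m), m = m,
                          specs = list(), seed = seed),
                     class = "imputation_set"))
  }

  # impute the least-missing columns first (their early imputations feed the
  # conditionals of worse columns)
  incomplete <- incomplete[order(vapply(data[incomplete],
                                        function(x) sum(is.na(x)), 0))]

  .with_seed(seed, {
    if (is.null(specs)) {
      specs <- lapply(setNames(incomplete, incomplete), function(v) {
        select_conditional_predictors(data, v)
      })
    }
    families <- vapply(incomplete, function(v) .col_family(data[[v]]),
                       character(1))
    miss_idx <- lapply(setNames(incomplete, incomplete),
                       function(v) which(is.na(data[[v]])))

    cohorts <- vector("list", m)
    for (l in seq_len(m)) {
      cur <- data
      for (v in incomplete) {
        obs <- data[[v]][!is.na(data[[v]])]
        cur[[v]][miss_idx[[v]]] <- sample(obs, length(miss_idx[[v]]),
                                          replace = TRUE)
      }
      for (s in seq_len(sweeps)) {
        for (v in incomplete) {
          mi <- miss_idx[[v]]
          oi <- setdiff(seq_len(nrow(cur)), mi)
          preds <- specs[[v]]
          if (length(preds) == 0) {
            cur[[v]][mi] <- sample(data[[v]][oi], length(mi), replace = TRUE)
            next
          }
          df <- .model_frame(cur, preds)
          fam <- families[[v]]
          if (fam == "multinomial") {
            cur[[v]][mi] <- .draw_multinomial(cur[[v]][oi],
                                              df[oi, , drop = FALSE],
                                              df[mi, , drop = FALSE])
          } else {
            X <- stats::model.matrix(~ ., df)
            if (fam == "pmm") {
              cur[[v]][mi] <- .draw_pmm(cur[[v]][oi], X[oi, , drop = FALSE],
                                        X[mi, , drop = FALSE], pmm_donors)
            } else {
              cur[[v]][mi] <- .draw_logistic(cur[[v]][oi],
                                             X[oi, , drop = FALSE],
                                             X[mi, , drop = FALSE])
            }
          }
        }
      }
      cohorts[[l]] <- cur
    }
    structure(list(cohorts = cohorts, m = m, specs = specs, seed = seed),
              class = "imputation_set")
  })
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("Imputation set: m =", x$m, "completed cohorts of n =",
      nrow(x$cohorts[[1]]), "subjects\n")
  if (length(x$specs) > 0) {
    cat("Imputed columns:", paste(names(x$specs), collapse = ", "), "\n")
  }
  invisible(x)
}
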