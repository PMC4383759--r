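# Two-step forward stepwise model selection: first the stage-2 term set, then
# the stage-1 term set given the selected stage-2 set, each minimizing the BIC
# averaged over the multiply imputed datasets. The base model at each stage is
# intercept + treatment dummies (the fitted published models always contain
# them); a candidate enters as a main effect or as a treatment interaction,
# with interactions admissible only once their main effect is present (weak
# hierarchy).

# Candidate predictors in published-table order. Trinary covariates enter as
# a dummy pair in a single move.
.POOL_TABLE <- list(
  AGE     = "AGE",
  RACE    = "RACE",
  GENDER  = c("GENDER1", "GENDER2"),
  MARSTAT = c("MARSTAT1", "MARSTAT2"),
  HINCOME = "HINCOME",
  EMPLOY  = "EMPLOY",
  EDUCATE = "EDUCATE",
  MEDINS  = "MEDINS",
  BITYPE  = "BITYPE",
  PRONSET = c("PRONSET1", "PRONSET2"),
  SUMD0   = "SUMD0",
  SUMD1   = "SUMD1",
  SUMM0   = "SUMM0",
  SUMM1   = "SUMM1",
  SIDE1   = "SIDE1", SIDE2 = "SIDE2", SIDE3 = "SIDE3", SIDE4 = "SIDE4",
  SIDE5   = "SIDE5", SIDE6 = "SIDE6", SIDE7 = "SIDE7", SIDE8 = "SIDE8",
  SIDE9   = "SIDE9"
)
.STAGE2_ONLY <- c("SUMD1", "SUMM1")

#' Candidate predictor pool for a stage
#'
#' Stage 1 admits baseline covariates only; stage 2 additionally admits the
#' end-of-stage-1 scores SUMD1 and SUMM1. Stage-1 treatment is constant on
#' the stage-2 estimation subset (placebo non-responders), so no
#' Trt1-derived term is estimable there and none is offered. Trinary
#' covariates (GENDER, MARSTAT, PRONSET) move as a dummy pair.
#'
#' @param stage 1 or 2.
#' @param candidates Optional character vector restricting the pool (names
#'   from the candidate table, e.g. `c("SUMM1", "SIDE3")`).
#' @return Named list mapping candidate names to their model term(s), in
#'   table order.
#' @export
candidate_pool <- function(stage, candidates = NULL) {
  if (!stage %in% c(1, 2)) abort("`stage` must be 1 or 2.")
  pool <- .POOL_TABLE
  if (stage == 1) pool <- pool[setdiff(names(pool), .STAGE2_ONLY)]
  if (!is.null(candidates)) {
    unknown <- setdiff(candidates, names(pool))
    if (length(unknown) > 0) {
      abort(paste0("Unknown or inadmissible candidate(s) for stage ", stage,
                   ": ", paste(unknown, collapse = ", ")))
    }
    pool <- pool[names(pool) %in% candidates]
  }
  pool
}

.as_imputation_set <- function(data) {
  if (inherits(data, "imputation_set")) return(data)
  structure(list(cohorts = list(tibble::as_tibble(data)), m = 1,
                 specs = list(), seed = NULL),
            class = "imputation_set")
}

#' BIC averaged over imputed datasets
#'
#' Computes `mean_l [ n_l log(RSS_l / n_l) + k_l log(n_l) ]` for the requested
#' stage's regression fitted on each completed dataset: the stage-2 regression
#' runs on placebo non-responders, and the stage-1 regression runs on all
#' subjects with pseudo-outcomes recomputed per imputation from the supplied
#' stage-2 specification.
#'
#' @param data An `imputation_set` (or single complete cohort).
#' @param spec A [stage2_terms()] or [stage1_terms()] specification matching
#'   `stage`.
#' @param stage 1 or 2.
#' @param stage2_spec The stage-2 specification used to form pseudo-outcomes;
#'   required when `stage = 1`.
#' @return The averaged BIC (scalar).
#' @export
averaged_bic <- function(data, spec, stage, stage2_spec = NULL) {
  imps <- .as_imputation_set(data)
  ns <- vapply(imps$cohorts, nrow, 0)
  if (length(unique(ns)) > 1) {
    abort("Imputed cohorts differ in size; imputation set is inconsistent.")
  }
  if (stage == 1 && is.null(stage2_spec)) {
    abort("Stage-1 scoring needs the selected stage-2 specification (select stage 2 first).")
  }
  bics <- vapply(imps$cohorts, function(cohort) {
    if (stage == 2) {
      f <- fit_stage2(cohort, spec)
    } else {
      f2 <- fit_stage2(cohort, stage2_spec)
      ps <- pseudo_outcome(cohort, f2)
      f <- fit_stage1(cohort, ps, spec)
    }
    f$n * log(f$rss / f$n) + f$k * log(f$n)
  }, numeric(1))
  mean(bics)
}

# enumerate admissible moves given the current spec; order = pool order with
# the main-effect move before the interaction move(s) of the same candidate
.moves <- function(spec, stage, pool) {
  moves <- list()
  for (cand in names(pool)) {
    terms <- pool[[cand]]
    if (stage == 2) {
      if (!all(terms %in% spec$h20)) {
        moves[[length(moves) + 1]] <-
          list(label = paste0(cand, " (main)"),
               spec = within_spec(spec, "h20", terms))
      } else if (!all(terms %in% spec$h21)) {
        moves[[length(moves) + 1]] <-
          list(label = paste0("A2:", cand),
               spec = within_spec(spec, "h21", terms))
      }
    } else {
      if (!all(terms %in% spec$h10)) {
        moves[[length(moves) + 1]] <-
          list(label = paste0(cand, " (main)"),
               spec = within_spec(spec, "h10", terms))
      } else {
        if (!all(terms %in% spec$h11)) {
          moves[[length(moves) + 1]] <-
            list(label = paste0("A11:", cand),
                 spec = within_spec(spec, "h11", terms))
        }
        if (!all(terms %in% spec$h12)) {
          moves[[length(moves) + 1]] <-
            list(label = paste0("A12:", cand),
                 spec = within_spec(spec, "h12", terms))
        }
      }
    }
  }
  moves
}

within_spec <- function(spec, slot, terms) {
  spec[[slot]] <- c(spec[[slot]], setdiff(terms, spec[[slot]]))
  spec
}

#' Forward stepwise selection of Q-function terms
#'
#' Greedy search from the base model (intercept plus treatment dummies): at
#' each step the single admissible move — a candidate's main effect, or a
#' treatment interaction once its main effect is present — that most
#' decreases the imputation-averaged BIC is added; the search stops when no
#' move decreases it. Stage 1 must be selected *after* stage 2, whose
#' specification fixes the pseudo-outcomes. Equal-BIC ties go to the earlier
#' candidate in table order (mains before interactions).
#'
#' @param data An `imputation_set` (or single complete cohort).
#' @param stage 1 or 2.
#' @param pool A [candidate_pool()]; defaults to the full pool for `stage`.
#' @param stage2_spec Selected stage-2 specification; required when
#'   `stage = 1`.
#' @return The selected specification ([stage2_terms()] or [stage1_terms()]
#'   shaped), with a `trace` attribute recording each move and the averaged
#'   BIC before/after.
#' @export
stepwise_select <- function(data, stage, pool = candidate_pool(stage),
                            stage2_spec = NULL) {
  if (stage == 1 && is.null(stage2_spec)) {
    abort("Stage-1 selection requires the already-selected stage-2 specification.")
  }
  imps <- .as_imputation_set(data)
  spec <- if (stage == 2) {
    list(h20 = character(0), h21 = character(0))
  } else {
    list(h10 = character(0), h11 = character(0), h12 = character(0))
  }
  best <- averaged_bic(imps, spec, stage, stage2_spec)
  trace <- list(list(move = "<base>", bic = best))
  repeat {
    moves <- .moves(spec, stage, pool)
    if (length(moves) == 0) break
    scores <- vapply(moves, function(mv) {
      tryCatch(averaged_bic(imps, mv$spec, stage, stage2_spec),
               error = function(e) Inf)
    }, numeric(1))
    if (min(scores) >= best) break
    pick <- which.min(scores)  # first minimum = table-order tie-break
    trace[[length(trace) + 1]] <- list(move = moves[[pick]]$label,
                                       bic = scores[pick])
    spec <- moves[[pick]]$spec
    best <- scores[pick]
  }
  attr(spec, "trace") <- dplyr::bind_rows(lapply(trace, tibble::as_tibble))
  spec
}
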