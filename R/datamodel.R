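# Core trajectory schema and feasibility logic of the two-stage SMART design:
# three first-line arms (BUP, PAR, PBO); responders are never re-randomized;
# placebo non-responders are randomized between the two high-dose drugs; drug
# non-responders escalate their own drug deterministically.

# canonical column order of the subject-level CSV schema
.COHORT_COLS <- c(
  "id", "AGE", "RACE", "GENDER", "MARSTAT", "HINCOME", "EMPLOY", "EDUCATE",
  "MEDINS", "BITYPE", "PRONSET", "SUMD0", "SUMM0",
  paste0("SIDE", 1:9),
  "Trt1", "SUMD1", "SUMM1", "RESPONSE1", "Trt2", "SUMD2"
)

.GENDER_LEVELS  <- c("male", "female", "transgender")
.MARSTAT_LEVELS <- c("never", "married", "separated")
.PRONSET_LEVELS <- c("remission", "hypomanic", "mixed")

#' Feasible treatments at a decision stage
#'
#' Returns the set of treatments actually available under the trial design.
#' At stage 1 every subject can receive low-dose Bupropion (`"BUP"`), low-dose
#' Paroxetine (`"PAR"`) or placebo (`"PBO"`). At stage 2 responders receive no
#' further randomized treatment (empty set); non-responders on a drug escalate
#' to the high dose of that same drug (singleton set); placebo non-responders
#' may receive either high-dose drug.
#'
#' @param stage Decision stage, 1 or 2.
#' @param a1 Stage-1 treatment (`"BUP"`, `"PAR"` or `"PBO"`); required for
#'   stage 2.
#' @param responder Stage-1 responder status (0/1); required for stage 2.
#' @return Character vector of feasible treatment codes (possibly empty).
#' @examples
#' feasible_treatments(1)
#' feasible_treatments(2, a1 = "PBO", responder = 0)
#' feasible_treatments(2, a1 = "BUP", responder = 1)
#' @export
feasible_treatments <- function(stage, a1 = NULL, responder = NULL) {
  if (!stage %in% c(1, 2)) {
    abort("`stage` must be 1 or 2.")
  }
  if (stage == 1) {
    return(.TRT1)
  }
  if (is.null(a1) || is.null(responder) || !a1 %in% .TRT1 ||
      !responder %in% c(0, 1)) {
    abort("Stage-2 feasibility needs `a1` in {BUP, PAR, PBO} and `responder` in {0, 1}.")
  }
  if (responder == 1) {
    return(character(0))
  }
  switch(a1,
    BUP = "BUP_HIGH",
    PAR = "PAR_HIGH",
    PBO = .TRT2
  )
}

#' Classify end-of-stage-1 response
#'
#' A subject responds when the depression score at the end of stage 1 shows at
#' least a 50% improvement over entry (`sumd1 <= 0.5 * sumd0`, boundary
#' inclusive) and the subject has not met (hypo)mania criteria.
#'
#' @param sumd0 Depression score at entry (points, > 0).
#' @param sumd1 Depression score at the end of stage 1 (points).
#' @param mania_flag 0/1 indicator of (hypo)mania during stage 1.
#' @return Integer vector of responder indicators (1 = responder).
#' @examples
#' classify_response(10, 5, 0)   # exactly 50% improvement counts
#' classify_response(10, 5.1, 0)
#' classify_response(10, 2, 1)   # mania overrides symptomatic response
#' @export
classify_response <- function(sumd0, sumd1, mania_flag) {
  if (any(sumd0 <= 0, na.rm = TRUE)) {
    abort("`sumd0` must be positive: percent improvement is undefined at 0.")
  }
  if (any(!mania_flag %in% c(0, 1), na.rm = TRUE)) {
    abort("`mania_flag` must be 0 or 1.")
  }
  out <- as.integer(sumd1 <= 0.5 * sumd0 & mania_flag == 0)
  out[is.na(sumd0) | is.na(sumd1) | is.na(mania_flag)] <- NA_integer_
  out
}

#' Add model-coding columns to a cohort
#'
#' Adds the dummy codings used by every regression in the package:
#' `PRONSET1` (1 iff prior episode was remission), `PRONSET2` (1 iff
#' (hypo)manic; mixed is the reference), `A11` (1 iff Trt1 = BUP), `A12`
#' (1 iff Trt1 = PAR; placebo is the reference), and `A2` (1 iff
#' Trt2 = BUP_HIGH, 0 iff PAR_HIGH, NA when no stage-2 treatment). The other
#' trinary covariates get dummy pairs with the first printed level as
#' reference: `GENDER1`/`GENDER2` (female, transgender vs male) and
#' `MARSTAT1`/`MARSTAT2` (married, separated vs never married).
#'
#' @param data Cohort data frame.
#' @return The input as a tibble with the coding columns appended.
#' @export
encode_model_terms <- function(data) {
  out <- tibble::as_tibble(data)
  if ("PRONSET" %in% names(out)) {
    out$PRONSET1 <- as.integer(out$PRONSET == "remission")
    out$PRONSET2 <- as.integer(out$PRONSET == "hypomanic")
  }
  if ("GENDER" %in% names(out)) {
    out$GENDER1 <- as.integer(out$GENDER == "female")
    out$GENDER2 <- as.integer(out$GENDER == "transgender")
  }
  if ("MARSTAT" %in% names(out)) {
    out$MARSTAT1 <- as.integer(out$MARSTAT == "married")
    out$MARSTAT2 <- as.integer(out$MARSTAT == "separated")
  }
  if ("Trt1" %in% names(out)) {
    out$A11 <- as.integer(out$Trt1 == "BUP")
    out$A12 <- as.integer(out$Trt1 == "PAR")
  }
  if ("Trt2" %in% names(out)) {
    out$A2 <- ifelse(is.na(out$Trt2), NA_integer_,
                     as.integer(out$Trt2 == "BUP_HIGH"))
  }
  out
}

#' Validate a cohort against the trial design
#'
#' Checks score ranges, categorical levels, and treatment feasibility: `Trt2`
#' must be absent for responders and must lie in the feasible set implied by
#' `Trt1` for non-responders. Violations raise an error.
#'
#' @param data Cohort data frame in the subject-level schema.
#' @return The validated cohort (invisibly usable in a pipe).
#' @export
validate_cohort <- function(data) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(.COHORT_COLS, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  chk_range <- function(x, lo, hi, nm) {
    bad <- !is.na(x) & (x < lo | x > hi)
    if (any(bad)) abort(paste0(nm, " outside [", lo, ", ", hi, "] in ", sum(bad), " row(s)."))
  }
  chk_range(data$SUMD0, 0, 22, "SUMD0")
  chk_range(data$SUMD1, 0, 22, "SUMD1")
  chk_range(data$SUMD2, 0, 22, "SUMD2")
  chk_range(data$SUMM0, 0, 16, "SUMM0")
  chk_range(data$SUMM1, 0, 16, "SUMM1")
  chk_range(data$AGE, 18, Inf, "AGE")
  chk_lev <- function(x, lev, nm) {
    bad <- !is.na(x) & !x %in% lev
    if (any(bad)) abort(paste0(nm, " has values outside {", paste(lev, collapse = ", "), "}."))
  }
  chk_lev(data$PRONSET, .PRONSET_LEVELS, "PRONSET")
  chk_lev(data$GENDER, .GENDER_LEVELS, "GENDER")
  chk_lev(data$MARSTAT, .MARSTAT_LEVELS, "MARSTAT")
  chk_lev(data$Trt1, .TRT1, "Trt1")
  chk_lev(data$Trt2, .TRT2, "Trt2")
  for (v in paste0("SIDE", 1:9)) chk_lev(data[[v]], c(0L, 1L), v)

  # stage-2 feasibility where both Trt1 and responder status are observed
  obs <- !is.na(data$Trt1) & !is.na(data$RESPONSE1)
  resp2 <- obs & data$RESPONSE1 == 1 & !is.na(data$Trt2)
  if (any(resp2)) {
    abort(paste0(sum(resp2), " responder(s) carry a stage-2 treatment; responders are never re-randomized."))
  }
  nonresp <- which(obs & data$RESPONSE1 == 0 & !is.na(data$Trt2))
  for (i in nonresp) {
    feas <- feasible_treatments(2, data$Trt1[i], 0)
    if (!data$Trt2[i] %in% feas) {
      abort(paste0("Row ", i, ": Trt2 = ", data$Trt2[i],
                   " infeasible after Trt1 = ", data$Trt1[i], "."))
    }
  }
  data
}

#' Write a cohort to CSV
#'
#' One row per subject, columns in the canonical schema order; missing cells
#' are written empty. Round-trips exactly through [read_cohort()].
#'
#' @param data Cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(data[, .COHORT_COLS], path, na = "")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' @param path CSV file written by [write_cohort()] (or matching its schema).
#' @param validate Run [validate_cohort()] on load (default `TRUE`).
#' @return A cohort tibble; empty cells become `NA` (the missingness mask).
#' @export
read_cohort <- function(path, validate = TRUE) {
  types <- readr::cols(
    id = readr::col_integer(),
    GENDER = readr::col_character(),
    MARSTAT = readr::col_character(),
    PRONSET = readr::col_character(),
    Trt1 = readr::col_character(),
    Trt2 = readr::col_character(),
    RESPONSE1 = readr::col_integer(),
    .default = readr::col_double()
  )
  out <- readr::read_csv(path, col_types = types, na = "")
  for (v in c("RACE", "HINCOME", "EMPLOY", "EDUCATE", "MEDINS", "BITYPE",
              paste0("SIDE", 1:9))) {
    out[[v]] <- as.integer(out[[v]])
  }
  if (validate) out <- validate_cohort(out)
  out
}
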