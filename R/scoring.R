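# SNS and MSNS-AT scoring -----------------------------------------------

#' Scoring configuration for the SNS components
#'
#' Two admission findings have no printed bin in the original seven-row SNS
#' table: rectal temperature above 37.5 degrees C (hyperthermia) and a
#' respiratory rate below 40/min without apnea or grunting. Both are abnormal
#' but not obviously as severe as the zero-point bins, so each defaults to
#' 1 point and is configurable here.
#'
#' @param hyperthermia_score Points for rectal temperature > 37.5 C (0, 1 or 2).
#' @param low_rate_score Points for the `low_rate_other` respiratory-effort
#'   category (non-apneic rate < 40/min).
#' @return A list of class `sns_config`.
#' @export
#' @examples
#' sns_config()
sns_config <- function(hyperthermia_score = 1L, low_rate_score = 1L) {
  stopifnot(hyperthermia_score %in% 0:2, low_rate_score %in% 0:2)
  structure(list(hyperthermia_score = as.integer(hyperthermia_score),
                 low_rate_score = as.integer(low_rate_score)),
            class = "sns_config")
}

# canonical component ids (CSV column names) and accepted aliases
.sns_components <- c("resp_effort", "heart_rate", "mean_bp", "temp_rectal",
                     "crt_sec", "glucose_first", "spo2")

.sns_aliases <- c(respiratory_effort = "resp_effort",
                  temperature = "temp_rectal",
                  capillary_refill = "crt_sec",
                  blood_glucose = "glucose_first")

.resp_levels <- c("apnea_or_grunting", "tachypnea", "normal", "low_rate_other")

# physiologic sanity ranges; values outside are rejected, never scored
.sns_sanity <- list(heart_rate = c(0, 350),
                    mean_bp = c(0, 200),
                    temp_rectal = c(25, 45),
                    crt_sec = c(0, 60),
                    glucose_first = c(0, 1500),
                    spo2 = c(0, 100))

.canonical_component <- function(component) {
  if (length(component) != 1L || !is.character(component))
    stop("`component` must be a single component id", call. = FALSE)
  if (component %in% names(.sns_aliases)) component <- .sns_aliases[[component]]
  if (!component %in% .sns_components)
    stop("unknown SNS component: '", component, "'", call. = FALSE)
  component
}

#' Score one SNS component
#'
#' Maps a single admission measurement onto its 0/1/2 SNS bin. Printed closed
#' ranges are closed intervals; printed strict bounds are strict; the one
#' overlapping bin edge (36.5 C, printed in both the 1- and 2-point
#' temperature bins) goes to the higher-scoring side, so 36.5 scores 2.
#' Lower scores always mean a more abnormal finding.
#'
#' @param component One of `"resp_effort"`, `"heart_rate"`, `"mean_bp"`,
#'   `"temp_rectal"`, `"crt_sec"`, `"glucose_first"`, `"spo2"` (aliases
#'   `respiratory_effort`, `temperature`, `capillary_refill`, `blood_glucose`
#'   are accepted).
#' @param value The measurement: a category from
#'   `c("apnea_or_grunting", "tachypnea", "normal", "low_rate_other")` for
#'   respiratory effort, otherwise numeric (beats/min, mmHg, degrees C,
#'   seconds, mg/dL, percent).
#' @param config An [sns_config()].
#' @return Integer vector of 0, 1 or 2 points (vectorised over `value`).
#' @export
#' @examples
#' score_sns_component("heart_rate", 120)   # normal range -> 2
#' score_sns_component("spo2", 84)          # < 85 -> 0
#' score_sns_component("blood_glucose", 50) # 40-60 -> 1
score_sns_component <- function(component, value, config = sns_config()) {
  component <- .canonical_component(component)
  if (length(value) == 0L) stop("`value` must be non-empty", call. = FALSE)

  if (component == "resp_effort") {
    value <- as.character(value)
    bad <- !value %in% .resp_levels
    if (any(is.na(value)) || any(bad))
      stop("resp_effort must be one of: ", paste(.resp_levels, collapse = ", "),
           call. = FALSE)
    return(unname(c(apnea_or_grunting = 0L, tachypnea = 1L, normal = 2L,
                    low_rate_other = config$low_rate_score)[value]))
  }

  if (!is.numeric(value) || any(!is.finite(value)))
    stop("non-finite value for component '", component, "'", call. = FALSE)
  rng <- .sns_sanity[[component]]
  if (any(value < rng[1] | value > rng[2]))
    stop("value outside sanity range [", rng[1], ", ", rng[2],
         "] for component '", component, "'", call. = FALSE)

  switch(component,
    heart_rate = ifelse(value < 100, 0L, ifelse(value <= 160, 2L, 1L)),
    mean_bp = ifelse(value < 30, 0L, ifelse(value <= 39, 1L, 2L)),
    temp_rectal = ifelse(value < 36, 0L,
                  ifelse(value < 36.5, 1L,
                  ifelse(value <= 37.5, 2L, config$hyperthermia_score))),
    crt_sec = ifelse(value < 3, 2L, ifelse(value <= 5, 1L, 0L)),
    glucose_first = ifelse(value < 40, 0L, ifelse(value <= 60, 1L, 2L)),
    spo2 = ifelse(value < 85, 0L, ifelse(value <= 92, 1L, 2L)))
}

#' Sick Neonatal Score (SNS)
#'
#' Sum of the seven component scores (respiratory effort, heart rate, mean
#' blood pressure, rectal temperature at admission, capillary refill time,
#' first blood glucose after admission, SpO2 in room air). Range 0-14; lower
#' means sicker. The rectal temperature and first glucose are the canonical
#' inputs; no axillary/random-glucose mode exists.
#'
#' Missing components are an error, never imputed: the score is defined only
#' on a complete admission record.
#'
#' @param vitals A list or data.frame with columns/fields `resp_effort`,
#'   `heart_rate`, `mean_bp`, `temp_rectal`, `crt_sec`, `glucose_first`,
#'   `spo2`.
#' @param config An [sns_config()].
#' @return Integer vector of total scores in 0..14.
#' @export
#' @examples
#' score_sns(list(resp_effort = "normal", heart_rate = 120, mean_bp = 45,
#'                temp_rectal = 37, crt_sec = 2, glucose_first = 80,
#'                spo2 = 98))  # 14
score_sns <- function(vitals, config = sns_config()) {
  missing <- setdiff(.sns_components, names(vitals))
  if (length(missing))
    stop("missing SNS component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  has_na <- vapply(.sns_components, function(cp) anyNA(vitals[[cp]]), logical(1))
  if (any(has_na))
    stop("missing (NA) values in SNS component(s): ",
         paste(.sns_components[has_na], collapse = ", "), call. = FALSE)
  pts <- lapply(.sns_components, function(cp)
    score_sns_component(cp, vitals[[cp]], config))
  as.integer(Reduce(`+`, pts))
}

#' MSNS-AT points for gestational age, birth weight and admission time
#'
#' The additional point tables of the Modified SNS-Admission Time score:
#' gestational age <32 weeks scores 0, 32-36 scores 1, >=37 scores 2;
#' birth weight <1500 g scores 0, 1500-2499 scores 1, >=2500 scores 2;
#' time from birth to admission >=12 h scores 0, 6-12 h scores 1, <6 h
#' scores 3. The admission-time points are deliberately asymmetric (no
#' 2-point bin): early arrival carries the largest protective weight.
#'
#' @param ga_weeks Completed gestational weeks (22-44).
#' @param bw_grams Birth weight in grams (300-6000).
#' @param at_hours Hours from birth to admission (>= 0).
#' @return A data.frame with integer columns `ga_points`, `bw_points`,
#'   `at_points`.
#' @export
#' @examples
#' msnsat_points(38, 3100, 3)  # 2, 2, 3
msnsat_points <- function(ga_weeks, bw_grams, at_hours) {
  if (!is.numeric(ga_weeks) || !is.numeric(bw_grams) || !is.numeric(at_hours))
    stop("ga_weeks, bw_grams and at_hours must be numeric", call. = FALSE)
  if (any(!is.finite(ga_weeks)) || any(!is.finite(bw_grams)) ||
      any(!is.finite(at_hours)))
    stop("non-finite scoring input", call. = FALSE)
  if (any(ga_weeks < 22 | ga_weeks > 44))
    stop("ga_weeks outside [22, 44]", call. = FALSE)
  if (any(bw_grams < 300 | bw_grams > 6000))
    stop("bw_grams outside [300, 6000]", call. = FALSE)
  if (any(at_hours < 0))
    stop("at_hours must be non-negative", call. = FALSE)
  data.frame(
    ga_points = ifelse(ga_weeks < 32, 0L, ifelse(ga_weeks < 37, 1L, 2L)),
    bw_points = ifelse(bw_grams < 1500, 0L, ifelse(bw_grams < 2500, 1L, 2L)),
    at_points = ifelse(at_hours < 6, 3L, ifelse(at_hours < 12, 1L, 0L)))
}

#' Admission-time category
#'
#' Early: admitted < 6 h after birth; intermediate: 6 to < 12 h; late:
#' >= 12 h (the point table's bin edge; the score grants late admissions
#' 0 points).
#'
#' @param at_hours Hours from birth to admission (>= 0).
#' @return Factor with levels `early`, `intermediate`, `late`.
#' @export
at_category <- function(at_hours) {
  if (!is.numeric(at_hours) || any(!is.finite(at_hours)) || any(at_hours < 0))
    stop("at_hours must be non-negative and finite", call. = FALSE)
  factor(ifelse(at_hours < 6, "early",
         ifelse(at_hours < 12, "intermediate", "late")),
         levels = c("early", "intermediate", "late"))
}

#' MSNS-AT risk stratum
#'
#' Three mortality-risk groups by total MSNS-AT score: high risk for scores
#' <= 7, intermediate for 8-15, low for >= 16 (lower scores mean sicker
#' infants).
#'
#' @param msnsat_total Total MSNS-AT score(s), 0-21.
#' @return Factor with levels `high`, `intermediate`, `low`.
#' @export
risk_stratum <- function(msnsat_total) {
  if (!is.numeric(msnsat_total) || any(!is.finite(msnsat_total)) ||
      any(msnsat_total < 0 | msnsat_total > 21))
    stop("msnsat_total must lie in [0, 21]", call. = FALSE)
  factor(ifelse(msnsat_total <= 7, "high",
         ifelse(msnsat_total <= 15, "intermediate", "low")),
         levels = c("high", "intermediate", "low"))
}

#' Score a cohort: full MSNS-AT breakdown
#'
#' Computes, for every record, the seven SNS component points, the SNS total,
#' the gestational-age/birth-weight/admission-time points, the MSNS-AT total
#' (SNS + the three point columns, range 0-21), the admission-time category,
#' the two published cut-off flags (SNS <= 8, MSNS-AT <= 10) and the
#' three-level risk stratum.
#'
#' @param records A cohort data.frame in the [read_cohort()] schema (vital
#'   columns plus `ga_weeks`, `bw_grams`, `at_hours`; `id` optional).
#' @param config An [sns_config()].
#' @param include_at_points If `FALSE`, the admission-time points are dropped
#'   from the total (the score collapses to SNS + GA + BW points); the flags
#'   and stratum are computed from the reduced total. Intended for
#'   sensitivity analyses of the admission-time contribution.
#' @return A data.frame of class `score_breakdown`, one row per record.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_params(n = 5, seed = 1))$records
#' score_msnsat(coh)
score_msnsat <- function(records, config = sns_config(),
                         include_at_points = TRUE) {
  records <- as.data.frame(records)
  needed <- c("ga_weeks", "bw_grams", "at_hours", .sns_components)
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop("missing scoring column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  comp <- vapply(.sns_components, function(cp)
    score_sns_component(cp, records[[cp]], config),
    integer(nrow(records)))
  comp <- matrix(as.integer(comp), ncol = length(.sns_components),
                 dimnames = list(NULL, paste0("pts_", .sns_components)))
  sns_total <- as.integer(rowSums(comp))
  extra <- msnsat_points(records$ga_weeks, records$bw_grams, records$at_hours)
  if (!include_at_points) extra$at_points <- 0L
  msnsat_total <- sns_total + extra$ga_points + extra$bw_points + extra$at_points
  out <- data.frame(
    id = if (!is.null(records$id)) records$id else seq_len(nrow(comp)),
    comp,
    sns_total = sns_total,
    extra,
    msnsat_total = as.integer(msnsat_total),
    at_category = at_category(records$at_hours),
    sns_le8 = sns_total <= 8L,
    msnsat_le10 = msnsat_total <= 10L,
    risk_stratum = risk_stratum(msnsat_total))
  class(out) <- c("score_breakdown", "data.frame")
  out
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat("MSNS-AT score breakdown:", nrow(x), "record(s)\n")
  cat("  SNS total   : median", stats::median(x$sns_total),
      " range", min(x$sns_total), "-", max(x$sns_total), "\n")
  cat("  MSNS-AT     : median", stats::median(x$msnsat_total),
      " range", min(x$msnsat_total), "-", max(x$msnsat_total), "\n")
  cat("  risk strata :", paste(sprintf("%s=%d", levels(x$risk_stratum),
      tabulate(x$risk_stratum, 3L)), collapse = "  "), "\n")
  invisible(x)
}
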