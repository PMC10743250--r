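# Cohort I/O, validation and the end-to-end analysis pipeline -----------

.cohort_columns <- c("id", "ga_weeks", "bw_grams", "sex", "apgar1",
                     "place_of_birth", "at_hours", "eos", "resp_effort",
                     "heart_rate", "mean_bp", "temp_rectal", "crt_sec",
                     "glucose_first", "spo2", "died", "followup_hours")

#' Validate a cohort table
#'
#' Checks the full record schema (demographics, admission vitals, outcome)
#' with row-level diagnostics; any violation aborts with the offending rows
#' named. No imputation is ever attempted.
#'
#' @param records Cohort data.frame.
#' @return The validated data.frame, invisibly, with logical columns coerced.
#' @export
validate_cohort <- function(records) {
  records <- as.data.frame(records)
  missing <- setdiff(.cohort_columns, names(records))
  if (length(missing))
    stop("missing cohort column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (cl in c("eos", "died"))
    records[[cl]] <- as.logical(records[[cl]])

  problems <- character()
  note <- function(rows, what) {
    if (length(rows))
      problems <<- c(problems, sprintf("%s (rows %s)", what,
        paste(utils::head(rows, 5L), collapse = ", ")))
  }
  num_rule <- function(col, lo, hi) {
    v <- records[[col]]
    bad <- which(!is.finite(v) | v < lo | v > hi)
    note(bad, sprintf("%s outside [%s, %s] or missing", col, lo, hi))
  }
  num_rule("ga_weeks", 22, 44)
  num_rule("bw_grams", 300, 6000)
  num_rule("apgar1", 0, 10)
  num_rule("at_hours", 0, Inf)
  num_rule("followup_hours", 0, Inf)
  for (cp in setdiff(.sns_components, "resp_effort"))
    num_rule(cp, .sns_sanity[[cp]][1], .sns_sanity[[cp]][2])
  note(which(!records$resp_effort %in% .resp_levels),
       "invalid resp_effort category")
  note(which(!records$sex %in% c("male", "female")), "invalid sex")
  note(which(!records$place_of_birth %in%
               c("home", "level1", "level2", "level3")),
       "invalid place_of_birth")
  note(which(is.na(records$eos)), "eos not 0/1")
  note(which(is.na(records$died)), "died not 0/1")
  if (length(problems))
    stop("cohort validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  invisible(records)
}

#' Read / write a cohort CSV
#'
#' One header row, UTF-8, '.' decimal separator; booleans as 0/1; categories
#' as literal tokens (`male`/`female`; `home`/`level1`/`level2`/`level3`;
#' respiratory effort `apnea_or_grunting`/`tachypnea`/`normal`/
#' `low_rate_other`).
#'
#' @param path CSV file path.
#' @return `read_cohort`: the validated cohort data.frame.
#' @export
read_cohort <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8")
  validate_cohort(records)
}

#' @rdname read_cohort
#' @param records Cohort data.frame (validated before writing).
#' @export
write_cohort <- function(records, path) {
  records <- validate_cohort(records)
  out <- records[, .cohort_columns]
  out$eos <- as.integer(out$eos)
  out$died <- as.integer(out$died)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Cohort headline summary
#'
#' @param records Cohort data.frame (needs `ga_weeks` and `died`).
#' @return List with `n`, `deaths`, `death_rate_pct` (two decimals),
#'   `preterm`, `preterm_fraction_pct` (one decimal, matching the precision
#'   such cohort shares are conventionally reported at).
#' @export
#' @examples
#' # 20 deaths among 403 admissions, 217 preterm
#' rec <- data.frame(ga_weeks = rep(c(30, 40), c(217, 186)),
#'                   died = rep(c(TRUE, FALSE), c(20, 383)))
#' mortality_summary(rec)
mortality_summary <- function(records) {
  if (!nrow(records)) stop("empty cohort", call. = FALSE)
  n <- nrow(records)
  deaths <- sum(as.logical(records$died))
  preterm <- sum(records$ga_weeks < 37)
  list(n = n, deaths = deaths,
       death_rate_pct = round(100 * deaths / n, 2),
       preterm = preterm,
       preterm_fraction_pct = round(100 * preterm / n, 1))
}

#' Analysis configuration
#'
#' @param at_cutoff Admission-time split (hours) for the dichotomized
#'   survival analysis; default 6.5 (the published Youden-optimal value).
#' @param sns_cutoff SNS flag threshold (score <= cutoff); default 8.
#' @param msnsat_cutoff MSNS-AT flag threshold; default 10.
#' @param strata_edges Increasing pair of MSNS-AT edges for the three risk
#'   strata (high <= first, intermediate to second, low above); default
#'   c(7, 15).
#' @param include_at_points Keep the admission-time points in the MSNS-AT
#'   total (set `FALSE` for the sensitivity analysis that collapses the
#'   score to SNS + GA + BW points).
#' @param sns_config An [sns_config()].
#' @param min_events Minimum number of deaths in a subgroup for Cox/ROC
#'   stages to run (default 2); smaller subgroups are skipped with a logged
#'   warning.
#' @param seed Seed for any resampling step (none is used by the standard
#'   stages; retained for extensions).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(at_cutoff = 6.5, sns_cutoff = 8,
                            msnsat_cutoff = 10, strata_edges = c(7, 15),
                            include_at_points = TRUE,
                            sns_config = msnsat::sns_config(),
                            min_events = 2L, seed = 1L) {
  if (length(strata_edges) != 2 || diff(strata_edges) <= 0)
    stop("strata_edges must be two increasing values", call. = FALSE)
  if (at_cutoff < 0) stop("at_cutoff must be non-negative", call. = FALSE)
  if (sns_cutoff < 0 || sns_cutoff > 14)
    stop("sns_cutoff outside the SNS range", call. = FALSE)
  if (msnsat_cutoff < 0 || msnsat_cutoff > 21)
    stop("msnsat_cutoff outside the MSNS-AT range", call. = FALSE)
  structure(list(at_cutoff = at_cutoff, sns_cutoff = sns_cutoff,
                 msnsat_cutoff = msnsat_cutoff, strata_edges = strata_edges,
                 include_at_points = include_at_points,
                 sns_config = sns_config, min_events = as.integer(min_events),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

# drop constant covariates (e.g. no Apgar<3 infant in a small subgroup),
# recording which were dropped
.usable_covariates <- function(df, names) {
  keep <- names[vapply(names, function(nm)
    diff(range(df[[nm]])) > 0, logical(1))]
  list(keep = keep, dropped = setdiff(names, keep))
}

.analyze_subgroup <- function(df, config, label, warn) {
  deaths <- sum(df$died)
  out <- list(label = label, n = nrow(df), deaths = deaths,
              death_rate_pct = round(100 * deaths / nrow(df), 2))

  num_vars <- c(ga_weeks = "gestational age", bw_grams = "birth weight",
                at_hours = "time to admission", apgar1 = "Apgar 1 min",
                sns_total = "SNS", msnsat_total = "MSNS-AT")
  out$baseline <- do.call(rbind, lapply(names(num_vars), function(v) {
    x <- df[[v]]
    data.frame(variable = v, mean = mean(x), sd = stats::sd(x),
               median = stats::median(x),
               q1 = unname(stats::quantile(x, 0.25)),
               q3 = unname(stats::quantile(x, 0.75)))
  }))

  # survivor vs non-survivor rank comparisons
  if (deaths >= 1 && deaths < nrow(df)) {
    out$comparisons <- do.call(rbind, lapply(names(num_vars), function(v) {
      mw <- mann_whitney_u(df[[v]][!df$died], df[[v]][df$died])
      data.frame(variable = v,
                 median_survivors = stats::median(df[[v]][!df$died]),
                 median_nonsurvivors = stats::median(df[[v]][df$died]),
                 u = mw$statistic, p_value = mw$p_value)
    }))
  } else {
    warn(sprintf("subgroup '%s': no survivor/non-survivor contrast possible",
                 label))
  }

  # categorical associations: OR + chi-square
  flags <- list(male = df$sex == "male", apgar_lt3 = df$apgar1 < 3,
                eos = df$eos, sns_le8 = df$sns_le8,
                msnsat_le10 = df$msnsat_le10)
  out$associations <- do.call(rbind, lapply(names(flags), function(nm) {
    fl <- flags[[nm]]
    tab <- two_by_two(sum(fl & df$died), sum(fl & !df$died),
                      sum(!fl & df$died), sum(!fl & !df$died))
    or <- odds_ratio(tab)
    m <- matrix(c(tab$a, tab$b, tab$c, tab$d), 2, byrow = TRUE)
    p <- tryCatch(chi_square_2xk(m)$p_value, error = function(e) NA_real_)
    data.frame(exposure = nm, a = tab$a, b = tab$b, c = tab$c, d = tab$d,
               odds_ratio = or$odds_ratio, ci_low = or$ci_low,
               ci_high = or$ci_high, chi2_p = p)
  }))

  enough <- deaths >= config$min_events && deaths < nrow(df)
  if (!enough) {
    warn(sprintf(
      "subgroup '%s': only %d event(s); ROC, survival and Cox stages skipped",
      label, deaths))
    return(out)
  }

  out$roc <- list(
    at = roc_curve(df$at_hours, df$died, "higher_is_event"),
    sns = roc_curve(df$sns_total, df$died, "lower_is_event"),
    msnsat = roc_curve(df$msnsat_total, df$died, "lower_is_event"))

  # KM + log-rank on the admission-time split and on the risk strata
  at_grp <- factor(ifelse(df$at_hours > config$at_cutoff,
                          paste0("AT>", config$at_cutoff),
                          paste0("AT<=", config$at_cutoff)))
  out$km_at <- list(fits = km_fit(df$followup_hours, df$died, at_grp))
  out$km_at$logrank <- if (nlevels(droplevels(at_grp)) > 1)
    log_rank(df$followup_hours, df$died, at_grp) else NULL

  strata <- droplevels(df$stratum)
  out$km_strata <- list(fits = km_fit(df$followup_hours, df$died, strata))
  out$km_strata$logrank <- if (nlevels(strata) > 1)
    log_rank(df$followup_hours, df$died, strata) else NULL

  # Cox models and their hazard-probability AUCs
  fit_model <- function(covs, name) {
    use <- .usable_covariates(df, covs)
    if (length(use$dropped))
      warn(sprintf("subgroup '%s', model '%s': constant covariate(s) %s dropped",
                   label, name, paste(use$dropped, collapse = ", ")))
    if (!length(use$keep)) return(NULL)
    fit <- withCallingHandlers(
      cox_fit(df$followup_hours, df$died, df[, use$keep, drop = FALSE]),
      warning = function(w) {
        warn(sprintf("subgroup '%s', model '%s': %s", label, name,
                     conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    fit$auc <- hazard_auc(fit)
    fit
  }
  df$at_gt_cut <- as.numeric(df$at_hours > config$at_cutoff)
  df$apgar_lt3_num <- as.numeric(df$apgar1 < 3)
  df$eos_num <- as.numeric(df$eos)
  adj <- c("ga_weeks", "bw_grams", "at_hours", "apgar_lt3_num", "eos_num")
  out$cox <- list(
    sns_only = fit_model("sns_total", "sns_only"),
    msnsat_only = fit_model("msnsat_total", "msnsat_only"),
    sns_plus_at = fit_model(c("sns_total", "at_gt_cut"), "sns_plus_at"),
    adjusted_sns = fit_model(c("sns_total", adj), "adjusted_sns"),
    adjusted_msnsat = fit_model(c("msnsat_total", adj), "adjusted_msnsat"))

  # Table-8-style adjusted model with risk-stratum indicators (low = ref)
  df$stratum_high <- as.numeric(df$stratum == "high")
  df$stratum_intermediate <- as.numeric(df$stratum == "intermediate")
  out$cox$strata_adjusted <- fit_model(
    c("stratum_high", "stratum_intermediate", "ga_weeks", "bw_grams",
      "apgar1", "apgar_lt3_num", "eos_num", "at_hours"), "strata_adjusted")
  out
}

#' Run the full analysis pipeline
#'
#' Stages, in order: validate the cohort, score every record, split into
#' subgroups (all; preterm < 37 weeks; term >= 37 weeks), survivor vs
#' non-survivor comparisons (Mann-Whitney), categorical associations (odds
#' ratios with Woolf CIs and chi-square p), ROC with Youden cut-offs for
#' admission time and both scores, Kaplan-Meier + log-rank on the
#' admission-time split and the risk strata, Cox models (score-only,
#' score + admission-time indicator, and the adjusted model-comparison pair)
#' each with its hazard-probability AUC, and the adjusted risk-stratum Cox
#' model. Deterministic given the input and configuration. Subgroups with
#' fewer than `min_events` deaths skip the ROC/survival/Cox stages with a
#' logged warning.
#'
#' @param input Cohort CSV path, cohort data.frame, or a
#'   [generate_cohort()] result.
#' @param config An [analysis_config()].
#' @return An `analysis_report`: `schema_version`, `config`, `summary`
#'   ([mortality_summary()]), `scores` (the [score_msnsat()] breakdown),
#'   `subgroups` (all/preterm/term stage outputs) and `warnings`.
#' @export
#' @examples
#' rep <- run_analysis(generate_cohort(cohort_params(n = 300, seed = 7)))
#' rep$summary
run_analysis <- function(input, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  records <- if (is.character(input)) read_cohort(input)
    else if (inherits(input, "synthetic_cohort")) validate_cohort(input$records)
    else validate_cohort(input)

  warnings <- character()
  warn <- function(msg) warnings <<- c(warnings, msg)

  scores <- score_msnsat(records, config = config$sns_config,
                         include_at_points = config$include_at_points)
  df <- cbind(records, scores[, setdiff(names(scores), "id")])
  df$sns_le8 <- df$sns_total <= config$sns_cutoff
  df$msnsat_le10 <- df$msnsat_total <= config$msnsat_cutoff
  e <- config$strata_edges
  df$stratum <- factor(ifelse(df$msnsat_total <= e[1], "high",
                       ifelse(df$msnsat_total <= e[2], "intermediate", "low")),
                       levels = c("high", "intermediate", "low"))

  subgroups <- list(
    all = df,
    preterm = df[df$ga_weeks < 37, , drop = FALSE],
    term = df[df$ga_weeks >= 37, , drop = FALSE])
  results <- lapply(names(subgroups), function(nm) {
    sg <- subgroups[[nm]]
    if (!nrow(sg)) { warn(sprintf("subgroup '%s' is empty", nm)); return(NULL) }
    .analyze_subgroup(sg, config, nm, warn)
  })
  names(results) <- names(subgroups)

  structure(list(schema_version = "1.0", config = config,
                 summary = mortality_summary(records), scores = scores,
                 subgroups = results, warnings = warnings),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  s <- x$summary
  cat("Outborn-neonate mortality analysis (schema", x$schema_version, ")\n")
  cat(sprintf("  n = %d, deaths = %d (%.2f%%), preterm = %d (%.1f%%)\n",
              s$n, s$deaths, s$death_rate_pct, s$preterm,
              s$preterm_fraction_pct))
  for (nm in names(x$subgroups)) {
    sg <- x$subgroups[[nm]]
    if (is.null(sg)) next
    cat(sprintf("  [%s] n = %d, deaths = %d", nm, sg$n, sg$deaths))
    if (!is.null(sg$cox$adjusted_sns) && !is.null(sg$cox$adjusted_msnsat))
      cat(sprintf("; hazard-probability AUC: SNS model %.3f, MSNS-AT model %.3f",
                  sg$cox$adjusted_sns$auc$auc, sg$cox$adjusted_msnsat$auc$auc))
    cat("\n")
  }
  if (length(x$warnings))
    cat("  warnings:", length(x$warnings), "(see $warnings)\n")
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits `report.json` (the full machine-readable report at full precision)
#' plus one CSV per main table analogue: the per-record score breakdown and,
#' per subgroup, the survivor comparison and association tables.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- jsonlite::toJSON(unclass_report(report), auto_unbox = TRUE,
                           digits = NA, force = TRUE, null = "null")
  writeLines(json, file.path(dir, "report.json"))
  utils::write.csv(report$scores, file.path(dir, "scores.csv"),
                   row.names = FALSE)
  for (nm in names(report$subgroups)) {
    sg <- report$subgroups[[nm]]
    if (is.null(sg)) next
    if (!is.null(sg$comparisons))
      utils::write.csv(sg$comparisons,
                       file.path(dir, paste0("comparisons_", nm, ".csv")),
                       row.names = FALSE)
    utils::write.csv(sg$associations,
                     file.path(dir, paste0("associations_", nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

# strip closures/classes so jsonlite can serialize deterministically
unclass_report <- function(x) {
  if (is.function(x)) return(NULL)
  if (is.list(x)) {
    x <- lapply(x, unclass_report)
    attributes(x) <- list(names = names(x))
  }
  x
}
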