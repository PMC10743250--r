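# Kaplan-Meier, log-rank, Cox PH and hazard-probability AUC -------------
#
# Time origin is admission; the event is in-hospital death at
# `followup_hours`, survivors are censored at discharge. At tied times,
# deaths are processed before censorings (both are in the risk set at that
# time; censored subjects leave afterwards).

.check_surv <- function(time, event) {
  if (length(time) != length(event) || anyNA(time) || anyNA(event))
    stop("time and event must be complete and of equal length", call. = FALSE)
  if (any(!is.finite(time)) || any(time < 0))
    stop("times must be non-negative and finite", call. = FALSE)
  as.logical(event)
}

#' Kaplan-Meier product-limit estimate
#'
#' S(t) = prod over event times u <= t of (1 - d(u)/n(u)), where d(u) is the
#' number of deaths at u and n(u) the number still at risk.
#'
#' @param time Follow-up time per subject (hours from admission).
#' @param event Logical death indicator; `FALSE` means censored.
#' @param group Optional grouping labels: returns one fit per group.
#' @return A `km_estimate` (or named list of them): `time` (distinct event
#'   times), `n_risk`, `n_event`, `survival`; or a list per group.
#' @export
#' @examples
#' km_fit(c(1, 2, 3, 4), c(TRUE, TRUE, TRUE, TRUE))$survival  # .75 .5 .25 0
km_fit <- function(time, event, group = NULL) {
  event <- .check_surv(time, event)
  if (!is.null(group)) {
    group <- as.factor(group)
    fits <- lapply(split(seq_along(time), group, drop = TRUE), function(i)
      km_fit(time[i], event[i]))
    return(structure(fits, class = "km_estimate_list"))
  }
  tev <- sort(unique(time[event]))
  n_risk <- vapply(tev, function(u) sum(time >= u), numeric(1))
  n_event <- vapply(tev, function(u) sum(event & time == u), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(time = tev, n_risk = n_risk, n_event = n_event,
                 survival = surv, n = length(time), events = sum(event)),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("Kaplan-Meier estimate:", x$n, "subjects,", x$events, "events\n")
  if (length(x$time))
    print(data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
                     survival = round(x$survival, 4)), row.names = FALSE)
  else cat("  (no events; S(t) = 1 throughout)\n")
  invisible(x)
}

#' Evaluate a Kaplan-Meier estimate at arbitrary times
#'
#' @param km A `km_estimate`. @param t Times to evaluate at.
#' @return S(t), right-continuous step function with S(t) = 1 before the
#'   first event.
#' @export
km_survival_at <- function(km, t) {
  stopifnot(inherits(km, "km_estimate"))
  vapply(t, function(u) {
    i <- sum(km$time <= u)
    if (i == 0) 1 else km$survival[i]
  }, numeric(1))
}

#' Log-rank test
#'
#' Standard observed-minus-expected statistic with hypergeometric variance,
#' summed over distinct event times; chi-square with (groups - 1) degrees of
#' freedom (the last group's redundant coordinate is dropped).
#'
#' @param time,event As in [km_fit()]. @param group Group labels (>= 2 groups).
#' @return A `logrank_result` with `chi2`, `df`, `p_value`, `observed`,
#'   `expected` per group.
#' @export
log_rank <- function(time, event, group) {
  event <- .check_surv(time, event)
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (!any(event)) stop("need at least one event", call. = FALSE)
  tev <- sort(unique(time[event]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (u in tev) {
    at_risk <- time >= u
    n <- sum(at_risk)
    d <- sum(event & time == u)
    ng <- vapply(levels(group), function(g) sum(at_risk & group == g),
                 numeric(1))
    dg <- vapply(levels(group), function(g)
      sum(event & time == u & group == g), numeric(1))
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      vc <- d * (n - d) / (n - 1) *
        (diag(ng / n, k) - tcrossprod(ng / n))
      V <- V + vc
    }
  }
  idx <- seq_len(k - 1L)
  oe <- (O - E)[idx]
  chi2 <- drop(t(oe) %*% solve(V[idx, idx, drop = FALSE], oe))
  structure(list(chi2 = chi2, df = k - 1L,
                 p_value = stats::pchisq(chi2, k - 1L, lower.tail = FALSE),
                 observed = stats::setNames(O, levels(group)),
                 expected = stats::setNames(E, levels(group))),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi2(%d) = %.3f, p = %s\n", x$df, x$chi2,
              format.pval(x$p_value, digits = 4)))
  invisible(x)
}

# Breslow partial log-likelihood, gradient and information, computed by
# cumulative sums over subjects sorted by decreasing time (risk set of an
# event time = everyone with time >= it; tied events share one denominator).
.breslow_quantities <- function(time, event, x, beta) {
  ord <- order(-time)
  t_s <- time[ord]; d_s <- event[ord]; x_s <- x[ord, , drop = FALSE]
  eta <- drop(x_s %*% beta)
  shift <- max(eta)                     # overflow guard
  w <- exp(eta - shift)
  p <- ncol(x)
  S0 <- cumsum(w)
  S1 <- apply(x_s * w, 2L, cumsum)
  if (p == 1L) S1 <- matrix(S1, ncol = 1L)
  # cumulative sum of w_i * x_i x_i', flattened to n x p^2 index pairs
  pair_i <- rep(seq_len(p), times = p)
  pair_j <- rep(seq_len(p), each = p)
  S2 <- apply(x_s[, pair_i, drop = FALSE] * x_s[, pair_j, drop = FALSE] * w,
              2L, cumsum)
  if (length(t_s) == 1L) S2 <- matrix(S2, nrow = 1L)

  loglik <- 0; grad <- numeric(p); info <- matrix(0, p, p)
  ev_times <- unique(t_s[d_s])
  cuts <- vapply(ev_times, function(u) sum(t_s >= u), integer(1))
  for (j in seq_along(ev_times)) {
    u <- ev_times[j]
    cut <- cuts[j]
    at <- which(d_s & t_s == u)
    d <- length(at)
    s0 <- S0[cut]
    s1 <- S1[cut, ]
    s2 <- matrix(S2[cut, ], p, p)
    loglik <- loglik + sum(eta[at]) - d * (log(s0) + shift)
    grad <- grad + colSums(x_s[at, , drop = FALSE]) - d * s1 / s0
    info <- info + d * (s2 / s0 - tcrossprod(s1 / s0))
  }
  list(loglik = loglik, grad = grad, info = info)
}

#' Cox proportional-hazards model (Breslow ties)
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson with
#' step-halving, starting from beta = 0; convergence when the largest
#' coefficient update is below `tol` (default 1e-8) or after `max_iter`
#' iterations. Standard errors come from the observed information at the
#' estimate. Monotone likelihood (complete separation of event risk) is
#' detected by diverging coefficients and reported as `converged = FALSE`
#' with a warning, never silently.
#'
#' @param time,event As in [km_fit()] (at least one event required).
#' @param covariates Numeric matrix or data.frame of covariates (no constant
#'   columns).
#' @param tol,max_iter Newton-Raphson controls.
#' @return A `cox_model`: `coefficients`, `se`, `hazard_ratios` (with 95% CI
#'   columns), `loglik` (null, final), `risk_scores` (per-subject linear
#'   predictor, the "hazard probabilities" used for model comparison),
#'   `converged`, `iter`, `n`, `n_event`, and the training `event` vector.
#' @export
cox_fit <- function(time, event, covariates, tol = 1e-8, max_iter = 100L) {
  event <- .check_surv(time, event)
  if (!any(event)) stop("at least one event is required", call. = FALSE)
  x <- as.matrix(as.data.frame(covariates))
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("non-finite covariate values", call. = FALSE)
  if (nrow(x) != length(time)) stop("covariate rows must match subjects",
                                    call. = FALSE)
  const <- apply(x, 2L, function(col) diff(range(col)) == 0)
  if (any(const))
    stop("constant covariate(s): ", paste(colnames(x)[const], collapse = ", "),
         call. = FALSE)
  # center and scale for numerical stability; transform back afterwards
  ctr <- colMeans(x); scl <- apply(x, 2L, stats::sd)
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  p <- ncol(xs)
  beta <- numeric(p)
  q0 <- .breslow_quantities(time, event, xs, beta)
  loglik0 <- q0$loglik
  loglik <- loglik0
  converged <- FALSE
  diverged <- FALSE
  iter <- 0L
  q <- q0
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(q$info, q$grad), error = function(e) NULL)
    if (is.null(step)) { diverged <- TRUE; break }
    new_beta <- beta + step
    q_new <- .breslow_quantities(time, event, xs, new_beta)
    halvings <- 0L
    while ((!is.finite(q_new$loglik) || q_new$loglik < loglik - 1e-12) &&
           halvings < 30L) {
      step <- step / 2
      new_beta <- beta + step
      q_new <- .breslow_quantities(time, event, xs, new_beta)
      halvings <- halvings + 1L
    }
    delta <- max(abs(new_beta - beta))
    beta <- new_beta; q <- q_new; loglik <- q_new$loglik
    if (max(abs(beta)) > 20) { diverged <- TRUE; break }  # on sd scale
    if (delta < tol) { converged <- TRUE; break }
  }
  if (diverged)
    warning("monotone partial likelihood (complete separation); ",
            "coefficients diverge and the fit is flagged non-converged",
            call. = FALSE)
  cov_s <- tryCatch(solve(q$info), error = function(e) NULL)
  if (is.null(cov_s)) {
    if (!diverged)
      warning("singular information matrix (collinear covariates?); ",
              "standard errors unavailable", call. = FALSE)
    se_s <- rep(NA_real_, p)
    converged <- FALSE
  } else se_s <- sqrt(pmax(0, diag(cov_s)))
  coef <- beta / scl
  se <- se_s / scl
  names(coef) <- names(se) <- colnames(x)
  lp <- drop(x %*% coef)
  hr <- cbind(hr = exp(coef),
              ci_low = exp(coef - 1.96 * se),
              ci_high = exp(coef + 1.96 * se))
  structure(list(coefficients = coef, se = se, hazard_ratios = hr,
                 loglik = c(null = loglik0, final = loglik),
                 risk_scores = lp, converged = converged && !diverged,
                 iter = iter, n = length(time), n_event = sum(event),
                 event = event),
            class = "cox_model")
}

#' @export
print.cox_model <- function(x, digits = 3, ...) {
  cat("Cox proportional-hazards model (Breslow ties):",
      x$n, "subjects,", x$n_event, "events\n")
  tab <- data.frame(coef = round(x$coefficients, digits),
                    se = round(x$se, digits),
                    HR = round(x$hazard_ratios[, "hr"], digits),
                    ci_low = round(x$hazard_ratios[, "ci_low"], digits),
                    ci_high = round(x$hazard_ratios[, "ci_high"], digits))
  print(tab)
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' Hazard-probability AUC of a Cox model
#'
#' The model-comparison device: the ROC AUC of the fitted per-subject risk
#' scores (linear predictor) against the death indicator. Because the AUC is
#' invariant under monotone transforms, using the linear predictor, exp of
#' it, or 1 - S(t*)^exp(lp) all give the identical value. A 95% CI by the
#' Hanley-McNeil method accompanies the estimate.
#'
#' @param model A fitted [cox_fit()] model.
#' @param event Optional event indicator to score against (defaults to the
#'   model's training events).
#' @param risk_scores Optional risk scores (defaults to the model's).
#' @return List with `auc`, `ci_low`, `ci_high`, `se`, and the underlying
#'   `roc` ([roc_curve()] result).
#' @export
hazard_auc <- function(model, event = NULL, risk_scores = NULL) {
  stopifnot(inherits(model, "cox_model"))
  event <- if (is.null(event)) model$event else as.logical(event)
  risk_scores <- if (is.null(risk_scores)) model$risk_scores else risk_scores
  if (!any(event)) stop("no events", call. = FALSE)
  roc <- roc_curve(risk_scores, event, direction = "higher_is_event")
  se <- .hanley_mcneil_se(roc$auc, roc$n_event, roc$n_nonevent)
  list(auc = roc$auc,
       ci_low = max(0, roc$auc - 1.96 * se),
       ci_high = min(1, roc$auc + 1.96 * se),
       se = se, roc = roc)
}
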