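#' Pearson chi-square test of tumor-mutation enrichment
#'
#' Tests whether MVFC-identified tumor mutations are enriched for mutations
#' independently found in tumor tissue, on a pooled 2x2 table (rows:
#' detected in tumor tissue yes/no; columns: MVFC class tumor/nontumor).
#' Pearson X^2 with expected counts from the margins, df = 1, no continuity
#' correction by default.
#'
#' @param table A 2x2 matrix of counts, or a length-4 numeric vector
#'   `c(a, b, c, d)` filled by row.
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return A list of class `mvfc_test`: `statistic`, `df`, `p_value`.
#' @export
chi_square_enrichment <- function(table, correct = FALSE) {
  if (!is.matrix(table)) {
    if (length(table) != 4) stop("table must be 2x2")
    table <- matrix(table, nrow = 2, byrow = TRUE)
  }
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0)) stop("counts must be non-negative")
  if (sum(table) < 1) stop("table must contain at least one observation")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row/column margin: expected counts undefined")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = correct))
  structure(list(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value)),
            class = "mvfc_test")
}

#' @export
print.mvfc_test <- function(x, ...) {
  cat(sprintf("statistic = %.4g", x$statistic))
  if (!is.null(x$df)) cat(sprintf(", df = %g", x$df))
  cat(sprintf(", p = %.4g\n", x$p_value))
  if (!is.null(x$estimate)) {
    cat(sprintf("estimate = %.4g (95%% CI %.4g-%.4g)\n",
                x$estimate, x$ci_lower, x$ci_upper))
  }
  invisible(x)
}

#' Pooled tumor-tissue enrichment table
#'
#' Builds the 2x2 contingency table of (detected in tumor tissue) x (MVFC
#' class) over all evaluable screened mutations, pooled across patients.
#' A mutation counts as in-tissue when its site appears among the same
#' patient's tumor-tissue calls.
#'
#' @param screened Screened mutations from [screen_patient()].
#' @param tissue_calls Tumor-tissue calls from [call_sample_mutations()].
#' @return A 2x2 matrix: rows `in_tissue`/`not_in_tissue`, columns
#'   `tumor`/`nontumor`.
#' @export
enrichment_table <- function(screened, tissue_calls) {
  ev <- screened[screened$mvfc_class %in% c("tumor", "nontumor"), ,
                 drop = FALSE]
  tissue_keys <- paste(tissue_calls$patient_id, .site_key(tissue_calls))
  in_tissue <- paste(ev$patient_id, .site_key(ev)) %in% tissue_keys
  tab <- matrix(c(
    sum(in_tissue & ev$mvfc_class == "tumor"),
    sum(in_tissue & ev$mvfc_class == "nontumor"),
    sum(!in_tissue & ev$mvfc_class == "tumor"),
    sum(!in_tissue & ev$mvfc_class == "nontumor")
  ), nrow = 2, byrow = TRUE,
  dimnames = list(c("in_tissue", "not_in_tissue"), c("tumor", "nontumor")))
  tab
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per group under right censoring, and the
#' two-group log-rank statistic `(sum(O - E))^2 / sum(V)` over event times
#' (df = 1).
#'
#' @param time Follow-up times (days), > 0.
#' @param event Logical/0-1 event indicators.
#' @param group Two-level group labels.
#' @return A list of class `mvfc_test`: `statistic`, `df`, `p_value`, and
#'   `curves` (data.frame `group`, `time`, `n_risk`, `n_event`, `surv`).
#' @export
km_logrank <- function(time, event, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (any(time <= 0)) stop("times must be > 0")
  event <- as.logical(event)
  if (sum(event) == 0) stop("no events in either group")
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(
    group = sub("^group=", "", strata),
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    surv = fit$surv, stringsAsFactors = FALSE
  )
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
  stat <- unname(sd$chisq)
  structure(list(statistic = stat, df = 1L,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 curves = curves),
            class = "mvfc_test")
}

#' Cox proportional-hazards regression
#'
#' Fits Cox regression on relapse-free survival by partial-likelihood
#' maximization with the Efron tie approximation, either one covariate at a
#' time (`mode = "univariate"`) or jointly (`"multivariate"`). Reports the
#' hazard ratio with Wald 95% confidence interval and p-value per covariate.
#'
#' @param data data.frame containing `time`, `event` and the covariates.
#' @param covariates Character vector of covariate column names.
#' @param mode `"univariate"` or `"multivariate"`.
#' @return A data.frame with one row per (model) coefficient: `term`,
#'   `coef`, `hr`, `se`, `ci_lower`, `ci_upper`, `p_value`, `n`, `n_events`,
#'   and `flagged` (TRUE for non-finite/monotone-likelihood estimates).
#' @export
cox_fit <- function(data, covariates,
                    mode = c("multivariate", "univariate")) {
  mode <- match.arg(mode)
  if (!all(c("time", "event") %in% names(data))) {
    stop("data must contain columns time and event")
  }
  if (sum(data$event) < 2) stop("at least 2 events required")
  fit_one <- function(covs) {
    fml <- stats::as.formula(paste(
      "survival::Surv(time, event) ~",
      paste(sprintf("`%s`", covs), collapse = " + ")
    ))
    fit <- survival::coxph(fml, data = data, ties = "efron",
                           control = survival::coxph.control(
                             eps = 1e-12, toler.chol = 1e-14,
                             iter.max = 100))
    s <- summary(fit)
    co <- s$coefficients
    flagged <- !is.finite(co[, "coef"]) | !is.finite(co[, "se(coef)"]) |
      abs(co[, "coef"]) > 15
    data.frame(
      term = rownames(co),
      coef = co[, "coef"],
      hr = exp(co[, "coef"]),
      se = co[, "se(coef)"],
      ci_lower = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
      ci_upper = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
      p_value = co[, "Pr(>|z|)"],
      n = s$n, n_events = s$nevent, flagged = flagged,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  if (mode == "multivariate") {
    fit_one(covariates)
  } else {
    do.call(rbind, lapply(covariates, fit_one))
  }
}

# outcome status at a horizon: 1 = recurrence by t, 0 = event-free beyond t,
# NA = censored before t (status unknown)
.horizon_status <- function(time, event, horizon) {
  status <- rep(NA_real_, length(time))
  status[event & time <= horizon] <- 1
  status[time > horizon] <- 0
  status
}

#' Fixed-horizon ROC AUC for early recurrence
#'
#' AUC of a marker for discriminating patients who recur on or before the
#' horizon (cases) from patients still event-free beyond it (controls),
#' using the rank (Mann-Whitney) formulation with midrank tie handling.
#' Patients censored before the horizon have unknown status and are
#' excluded. For a binary marker this equals (sensitivity + specificity)/2.
#'
#' @param marker Numeric or logical marker values (higher = higher risk).
#' @param time Follow-up times (days).
#' @param event Logical/0-1 event indicators.
#' @param horizon Horizon in days (default 183, i.e. six months).
#' @return A list of class `mvfc_test`: `estimate` (AUC), `n_cases`,
#'   `n_controls`.
#' @export
fixed_horizon_roc <- function(marker, time, event, horizon = 183) {
  status <- .horizon_status(time, as.logical(event), horizon)
  keep <- !is.na(status) & !is.na(marker)
  marker <- as.numeric(marker[keep])
  status <- status[keep]
  n1 <- sum(status == 1)
  n0 <- sum(status == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both recurrence classes must be present at the horizon")
  }
  r <- rank(marker)
  auc <- (sum(r[status == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(estimate = auc, n_cases = n1, n_controls = n0,
                 statistic = auc, p_value = NA_real_),
            class = "mvfc_test")
}

# left-continuous KM censoring-survival lookup: G(t-) when lag, else G(t)
.km_censor <- function(time, event) {
  cens_fit <- survival::survfit(
    survival::Surv(time, !as.logical(event)) ~ 1
  )
  function(t, lag = FALSE) {
    tt <- if (lag) t - sqrt(.Machine$double.eps) * max(1, t) else t
    idx <- findInterval(tt, cens_fit$time)
    g <- c(1, cens_fit$surv)[idx + 1]
    g
  }
}

#' Time-dependent ROC AUC (cumulative cases, dynamic controls)
#'
#' Estimates AUC(t) for the cumulative-case/dynamic-control definition:
#' cases are patients with an event by time t, controls patients still at
#' risk beyond t. Censoring is handled by inverse-probability-of-censoring
#' weights from the Kaplan-Meier estimator of the censoring distribution
#' (cases weighted by 1/G(T-), controls by 1/G(t)). Without censoring the
#' estimate reduces exactly to [fixed_horizon_roc()] at each horizon.
#'
#' @param marker Numeric or logical marker values (higher = higher risk).
#'   For the combined marker, pass the binary OR of the single markers.
#' @param time Follow-up times (days).
#' @param event Logical/0-1 event indicators.
#' @param times Horizons (days) at which to estimate AUC(t), e.g.
#'   `c(183, 365, 730)`.
#' @return A data.frame: `time`, `auc` (NA when no events precede `t`),
#'   `n_cases`, `n_controls`.
#' @export
time_dependent_roc <- function(marker, time, event,
                               times = c(183, 365, 730)) {
  event <- as.logical(event)
  marker <- as.numeric(marker)
  keep <- !is.na(marker)
  marker <- marker[keep]; time <- time[keep]; event <- event[keep]
  G <- .km_censor(time, event)
  out <- data.frame(time = times, auc = NA_real_,
                    n_cases = NA_integer_, n_controls = NA_integer_)
  for (i in seq_along(times)) {
    t0 <- times[i]
    case <- event & time <= t0
    ctrl <- time > t0
    out$n_cases[i] <- sum(case)
    out$n_controls[i] <- sum(ctrl)
    if (!any(case) || !any(ctrl)) next
    w_case <- 1 / G(time[case], lag = TRUE)
    w_ctrl <- rep(1 / G(t0), sum(ctrl))
    if (any(!is.finite(w_case)) || any(!is.finite(w_ctrl))) {
      w_case[!is.finite(w_case)] <- 0
    }
    cmp <- outer(marker[case], marker[ctrl],
                 function(a, b) (a > b) + 0.5 * (a == b))
    wts <- outer(w_case, w_ctrl)
    out$auc[i] <- sum(cmp * wts) / sum(wts)
  }
  out
}
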