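# Claims-derived clinical endpoints and survival statistics.
#
# Time-on-treatment (TOT) is the interval between the first and last drug
# administrations in the claims stream. Overall survival uses a recorded
# death date when present; otherwise a claims gap of more than 100 days
# before the data refresh is presumed death (imputed at the last claim,
# the latest evidence of being alive), and contact within 100 days of the
# refresh is censoring. Cases with TOT below 21 days are excluded from
# survival analyses as poor-quality data. Kaplan-Meier estimation, the
# log-rank test and Cox proportional-hazards fits are delegated to the
# survival package.

check_outcome <- function(outcome) {
  with(outcome, {
    if (any(first_admin_day > last_admin_day) ||
        any(last_admin_day > last_claim_day) ||
        any(last_claim_day > refresh_day)) {
      stopf("outcome day indices violate first <= last admin <= last claim <= refresh")
    }
    if (any(!is.na(death_day) & death_day < first_admin_day)) {
      stopf("death_day before first administration")
    }
  })
  invisible(outcome)
}

#' Time-on-treatment from an outcome record
#'
#' @param outcome data.frame of outcome records (see [simulate_outcomes()]).
#' @return integer days: `last_admin_day - first_admin_day`.
#' @export
derive_tot <- function(outcome) {
  check_outcome(outcome)
  outcome$last_admin_day - outcome$first_admin_day
}

#' Overall survival time and event from claims
#'
#' A recorded death date takes precedence (event at
#' `death_day - first_admin_day`). Otherwise, a gap of strictly more than
#' 100 days between the last claim and the claims refresh is presumed
#' death, imputed at the last claim day; contact within 100 days of the
#' refresh is censoring at the last claim day.
#'
#' @param outcome data.frame of outcome records.
#' @param gap_days presumed-death claims-gap threshold (default 100).
#' @return data.frame with `time` (days from first administration) and
#'   `event` (1 = death, observed or presumed; 0 = censored).
#' @export
derive_os <- function(outcome, gap_days = 100L) {
  check_outcome(outcome)
  gap <- outcome$refresh_day - outcome$last_claim_day
  presumed <- gap > gap_days
  time <- ifelse(!is.na(outcome$death_day),
                 outcome$death_day - outcome$first_admin_day,
                 outcome$last_claim_day - outcome$first_admin_day)
  event <- ifelse(!is.na(outcome$death_day), 1L, ifelse(presumed, 1L, 0L))
  data.frame(time = as.numeric(time), event = as.integer(event))
}

#' Build survival records for a grouped analysis
#'
#' @param time follow-up in days (non-negative; zero times are nudged to
#'   half a day so the product-limit estimator is defined).
#' @param event 1 = observed, 0 = censored.
#' @param group two-level factor (biomarker-negative level first: it is the
#'   Cox reference).
#' @param endpoint `"TOT"` or `"OS"`.
#' @param case_id optional ids.
#' @return data.frame of class `survival_records`.
#' @export
survival_records <- function(time, event, group, endpoint = c("OS", "TOT"),
                             case_id = NULL) {
  endpoint <- match.arg(endpoint)
  if (any(!is.finite(time)) || any(time < 0)) stopf("times must be non-negative")
  if (any(is.na(group))) stopf("group must be non-missing")
  time <- ifelse(time == 0, 0.5, time)
  group <- if (is.factor(group)) group else
    factor(group, levels = c("negative", "positive"))
  out <- data.frame(case_id = case_id %||% seq_along(time), time = time,
                    event = as.integer(event), group = group,
                    endpoint = endpoint)
  class(out) <- c("survival_records", "data.frame")
  out
}

#' Exclude records with short time-on-treatment
#'
#' Removes cases with TOT strictly below `min_days` (default 21), the
#' poor-data-quality filter applied before survival analyses.
#'
#' @param records a data.frame carrying a `tot` column, or a vector of TOT
#'   days alongside `records`.
#' @param tot TOT days aligned with `records` (used when `records` has no
#'   `tot` column).
#' @param min_days exclusion threshold.
#' @return the filtered records; the number removed is reported via
#'   `message()`.
#' @export
filter_min_tot <- function(records, tot = records$tot, min_days = 21L) {
  if (is.null(tot)) stopf("TOT values required")
  keep <- tot >= min_days
  n_rm <- sum(!keep)
  if (n_rm > 0) message(sprintf("excluded %d case(s) with TOT < %d days", n_rm, min_days))
  records[keep, , drop = FALSE]
}

#' Kaplan-Meier curve
#'
#' Product-limit estimate of the survival function; censored cases leave
#' the risk set without dropping the curve.
#'
#' @param records survival records (single group; use `group` columns with
#'   [km_plot()] for stratified curves).
#' @param conf confidence level for the point-wise band.
#' @return data.frame with `time`, `n_risk`, `n_event`, `surv`, `lower`,
#'   `upper`.
#' @export
km_curve <- function(records, conf = 0.95) {
  if (nrow(records) < 1) stopf("need at least one record")
  if (any(records$time <= 0)) stopf("times must be positive")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = records,
                          conf.int = conf)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             surv = sf$surv, lower = sf$lower, upper = sf$upper)
}

#' Log-rank test between two groups
#'
#' @param group_a,group_b survival records of the two arms, or a single
#'   `survival_records` data.frame with a two-level `group` in `group_a`.
#' @return list with `statistic` (1-df chi-square) and `p`.
#' @export
logrank <- function(group_a, group_b = NULL) {
  records <- if (is.null(group_b)) {
    group_a
  } else {
    rbind(transform(group_a[, c("time", "event")], group = "a"),
          transform(group_b[, c("time", "event")], group = "b"))
  }
  if (length(unique(records$group)) != 2) stopf("need two non-empty groups")
  if (sum(records$event) == 0) stopf("log-rank requires at least one event")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = records)
  list(statistic = sd_$chisq, p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards hazard ratio
#'
#' Fits a single binary group covariate by partial-likelihood maximisation
#' with Breslow tie handling (Efron available via `ties`), reporting the
#' hazard ratio of the positive group against the negative reference with
#' a Wald confidence interval on the log scale. A monotone likelihood
#' (infinite estimate) is reported as an explicit error, never a silent
#' estimate.
#'
#' @param records a `survival_records` data.frame with a two-level `group`.
#' @param conf confidence level.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return list with `hr`, `ci`, `p`, `n`, `n_events`.
#' @export
cox_hr <- function(records, conf = 0.95, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (length(unique(records$group)) != 2) stopf("need a binary group covariate")
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ group, data = records,
                    ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        stopf("Cox fit did not converge (monotone likelihood?)")
      }
      suppressWarnings(survival::coxph(survival::Surv(time, event) ~ group,
                                       data = records, ties = ties))
    })
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  if (!is.finite(beta) || !is.finite(se) || se > 100) {
    stopf("Cox fit did not converge (monotone likelihood?)")
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(hr = exp(beta), ci = exp(c(beta - z * se, beta + z * se)),
       p = 2 * stats::pnorm(-abs(beta / se)),
       n = fit$n, n_events = fit$nevent)
}

#' Survival stratification by actual or predicted biomarker status
#'
#' Builds OS (or TOT) survival records for a cohort, groups them by either
#' the true label or model-predicted status (pooled cross-fold test
#' probabilities thresholded at `threshold`), applies the 21-day TOT
#' exclusion, and reports KM curves per group, the log-rank test and the
#' Cox hazard ratio (negative group as reference).
#'
#' @param cohort a `synth_cohort`.
#' @param predictions optional prediction records; when given, groups come
#'   from `probability >= threshold`, otherwise from the true status.
#' @param endpoint `"OS"` or `"TOT"`.
#' @param threshold probability cut for predicted-positive (default 0.5).
#' @param min_tot_days TOT exclusion threshold.
#' @return list with `records`, `km` (per-group curves), `logrank`, `cox`.
#' @export
survival_by_status <- function(cohort, predictions = NULL,
                               endpoint = c("OS", "TOT"), threshold = 0.5,
                               min_tot_days = 21L) {
  endpoint <- match.arg(endpoint)
  outcome <- do.call(rbind, lapply(cohort$cases, `[[`, "outcome"))
  ids <- names(cohort$cases)
  status <- if (is.null(predictions)) {
    case_labels(cohort)
  } else {
    s <- stats::setNames(as.integer(predictions$probability >= threshold),
                         predictions$case_id)
    keep <- ids %in% names(s)
    ids <- ids[keep]; outcome <- outcome[keep, , drop = FALSE]
    s[ids]
  }
  tot <- derive_tot(outcome)
  surv <- if (endpoint == "OS") derive_os(outcome) else
    data.frame(time = as.numeric(tot),
               event = as.integer(outcome$last_claim_day > outcome$last_admin_day |
                                    !is.na(outcome$death_day)))
  rec <- survival_records(surv$time, surv$event,
                          factor(ifelse(status == 1, "positive", "negative"),
                                 levels = c("negative", "positive")),
                          endpoint = endpoint, case_id = ids)
  rec$tot <- tot
  rec <- filter_min_tot(rec)
  km <- lapply(split(rec, rec$group, drop = TRUE), km_curve)
  list(records = rec, km = km, logrank = logrank(rec), cox = cox_hr(rec))
}

#' Kaplan-Meier plot with confidence bands
#'
#' @param records a `survival_records` data.frame with a `group` column.
#' @param file optional PNG path; when given the plot is written to file.
#' @param main plot title.
#' @return invisibly, the per-group KM curves.
#' @export
km_plot <- function(records, file = NULL, main = "") {
  curves <- lapply(split(records, records$group), km_curve)
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 480)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(NULL, xlim = c(0, max(records$time)), ylim = c(0, 1),
                 xlab = "days", ylab = "survival", main = main)
  cols <- c("#1b9e77", "#d95f02")
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    if (nrow(cv) == 0) next
    tt <- c(0, rep(cv$time, each = 2))
    ss <- c(1, 1, rep(cv$surv, each = 2)[-(2 * nrow(cv))])
    graphics::lines(tt, ss, col = cols[i], lwd = 2)
    graphics::polygon(c(cv$time, rev(cv$time)),
                      c(cv$lower, rev(cv$upper)),
                      col = grDevices::adjustcolor(cols[i], 0.2), border = NA)
  }
  graphics::legend("topright", legend = names(curves), col = cols, lwd = 2)
  invisible(curves)
}
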