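# Survival evaluation: Kaplan-Meier, log-rank, multivariate Cox with
# backward selection, IPCW time-dependent ROC, activity correlations.

#' Two-group log-rank test
#'
#' @param group Character/factor vector with exactly two non-empty groups.
#' @param time Survival times, positive.
#' @param event Event indicator (0/1), at least one event.
#' @return List `chi2`, `p` (1 df chi-square), `n` per group.
#' @export
logrank_test <- function(group, time, event) {
  group <- as.character(group)
  tab <- table(group)
  if (length(tab) != 2L || any(tab == 0L)) {
    stop("log-rank test needs exactly two non-empty groups")
  }
  if (sum(event) < 1L) stop("log-rank test needs at least one event")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi2 <- unname(fit$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
       n = as.integer(tab))
}

#' Kaplan-Meier curve
#'
#' Product-limit estimate for one group of subjects. The median survival
#' is the earliest observed time with S(t) <= 0.5, `NA` when the curve
#' never reaches 0.5.
#'
#' @param time Survival times.
#' @param event Event indicator (0/1).
#' @return List of class `km_curve`: `time`, `surv`, `n_risk`, `n_event`,
#'   `median`.
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) >= 1L, length(time) == length(event))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- fit$time[fit$surv <= 0.5]
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event,
                 median = if (length(med)) med[1L] else NA_real_),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> ", length(x$time), " time point(s); median ",
      if (is.na(x$median)) "not reached" else x$median, "\n", sep = "")
  invisible(x)
}

#' Multivariate Cox regression with backward stepwise selection
#'
#' Starts from all supplied covariates, repeatedly refits after dropping
#' the covariate with the largest Wald p exceeding `alpha`, and stops when
#' every retained covariate has p <= `alpha`. Rows with missing covariate
#' values are dropped (complete-case analysis; the number dropped is
#' messaged). Covariates must be numeric or two-level factors so each
#' contributes a single coefficient. Non-convergent terms are dropped
#' with a warning.
#'
#' @param covariates Data.frame of covariates, rows aligned to `time`.
#' @param time,event Survival data.
#' @param alpha Stay threshold on the Wald p (default 0.05).
#' @return Data.frame of retained terms: `term, beta, hr, ci_low, ci_high,
#'   p`; zero rows if nothing survives.
#' @export
multivariate_cox_backward <- function(covariates, time, event, alpha = 0.05) {
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(time))
  cc <- stats::complete.cases(covariates)
  if (any(!cc)) {
    message("dropping ", sum(!cc), " subject(s) with missing covariates")
    covariates <- covariates[cc, , drop = FALSE]
    time <- time[cc]; event <- event[cc]
  }
  terms <- colnames(covariates)
  result <- NULL
  while (length(terms)) {
    df <- covariates[, terms, drop = FALSE]
    fit <- tryCatch(
      withCallingHandlers(
        survival::coxph(survival::Surv(time, event) ~ ., data = df),
        warning = function(w) {
          if (grepl("converge|infinite|singular", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }),
      error = function(e) NULL)
    if (is.null(fit) || any(is.na(stats::coef(fit)))) {
      bad <- if (is.null(fit)) terms[length(terms)] else {
        nm <- names(stats::coef(fit))[is.na(stats::coef(fit))][1L]
        terms[which.max(vapply(terms, function(t) grepl(t, nm, fixed = TRUE),
                               logical(1)))]
      }
      warning("covariate '", bad, "' dropped: model did not converge")
      terms <- setdiff(terms, bad)
      next
    }
    sm <- summary(fit)$coefficients
    # map coefficient rows back to covariate columns (2-level factors give
    # one coefficient whose name is prefixed by the column name)
    pvals <- vapply(terms, function(t) {
      rows <- which(startsWith(rownames(sm), t))
      min(sm[rows, "Pr(>|z|)"])
    }, numeric(1))
    if (max(pvals) > alpha && length(terms) > 0L) {
      terms <- setdiff(terms, names(which.max(pvals)))
      if (!length(terms)) { result <- NULL; break }
      next
    }
    ci <- exp(stats::confint(fit))
    result <- data.frame(
      term = rownames(sm), beta = sm[, "coef"], hr = exp(sm[, "coef"]),
      ci_low = ci[, 1L], ci_high = ci[, 2L], p = sm[, "Pr(>|z|)"],
      stringsAsFactors = FALSE, row.names = NULL)
    break
  }
  if (is.null(result)) {
    result <- data.frame(term = character(0), beta = numeric(0),
                         hr = numeric(0), ci_low = numeric(0),
                         ci_high = numeric(0), p = numeric(0))
  }
  result
}

# Censoring-survival left limit G(t-) via reverse Kaplan-Meier.
censoring_km <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  function(t, left = FALSE) {
    vapply(t, function(ti) {
      keep <- if (left) fit$time < ti else fit$time <= ti
      if (!any(keep)) 1 else min(fit$surv[keep], na.rm = TRUE)
    }, numeric(1))
  }
}

#' Time-dependent ROC AUC (cumulative cases / dynamic controls)
#'
#' AUC at a fixed horizon using cumulative cases (event by the horizon)
#' versus dynamic controls (still at risk past the horizon), weighted by
#' inverse probability of censoring (reverse Kaplan-Meier). With no
#' censoring before the horizon all weights coincide and the estimator
#' reduces to the plain Mann-Whitney statistic of scores, cases versus
#' controls.
#'
#' @param scores Risk scores (higher = worse prognosis).
#' @param time,event Survival data aligned to scores.
#' @param horizon Evaluation time (months), inside the observed range.
#' @return List `auc`, `horizon`, `n_cases`, `n_controls`.
#' @export
td_roc <- function(scores, time, event, horizon) {
  stopifnot(length(scores) == length(time))
  case <- time <= horizon & event == 1
  ctrl <- time > horizon
  if (!any(case)) stop("no cases (events before the horizon)")
  if (!any(ctrl)) stop("no controls (subjects past the horizon)")
  G <- censoring_km(time, event)
  w_case <- 1 / G(time[case], left = TRUE)
  w_ctrl <- rep(1 / G(horizon), sum(ctrl))
  sc <- scores[case]; sx <- scores[ctrl]
  cmp <- outer(sc, sx, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- sum((w_case %o% w_ctrl) * cmp) / (sum(w_case) * sum(w_ctrl))
  list(auc = auc, horizon = horizon, n_cases = sum(case), n_controls = sum(ctrl))
}

#' Compare two time-dependent AUCs on the same subjects
#'
#' Paired normal test on the IPCW AUC difference: the AUC difference of
#' the two markers is bootstrapped over subjects (same resamples for both
#' markers), its standard error estimated from the bootstrap spread, and
#' a two-sided normal p-value reported for the observed difference.
#'
#' @param scores_a,scores_b Two risk-score vectors on the same subjects.
#' @param time,event Survival data.
#' @param horizon Evaluation time.
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed Integer seed.
#' @return List `auc_a`, `auc_b`, `diff`, `se`, `p`.
#' @export
compare_auc <- function(scores_a, scores_b, time, event, horizon,
                        n_boot = 200L, seed = NULL) {
  auc_a <- td_roc(scores_a, time, event, horizon)$auc
  auc_b <- td_roc(scores_b, time, event, horizon)$auc
  n <- length(time)
  diffs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      da <- tryCatch(td_roc(scores_a[idx], time[idx], event[idx], horizon)$auc,
                     error = function(e) NA_real_)
      db <- tryCatch(td_roc(scores_b[idx], time[idx], event[idx], horizon)$auc,
                     error = function(e) NA_real_)
      da - db
    }, numeric(1))
  })
  se <- stats::sd(diffs, na.rm = TRUE)
  d <- auc_a - auc_b
  list(auc_a = auc_a, auc_b = auc_b, diff = d, se = se,
       p = 2 * stats::pnorm(-abs(d / se)))
}

#' Pairwise Pearson correlation of subpathway activities
#'
#' @param activity Subpathway-by-sample activity matrix (>= 2 rows).
#' @return Symmetric correlation matrix with unit diagonal; zero-variance
#'   rows give `NA` entries with a warning.
#' @export
activity_correlation <- function(activity) {
  if (nrow(activity) < 2L) stop("need at least two subpathways")
  zero <- row_vars(activity) == 0
  if (any(zero)) {
    warning("zero-variance activity row(s): ",
            paste(rownames(activity)[zero], collapse = ", "),
            "; correlations set to NA")
  }
  r <- suppressWarnings(stats::cor(t(activity)))
  diag(r) <- 1
  r
}

#' Evaluate a risk split within a clinical stratum
#'
#' Subsets the cohort by a predicate over clinical rows, then runs the
#' log-rank test and per-group Kaplan-Meier curves on the stratum.
#'
#' @param risk Risk table (`sample, score, group`), e.g. from
#'   [apply_signature()].
#' @param clinical Clinical data.frame with `sample`, `time_months`,
#'   `event` and covariates.
#' @param predicate Function taking the clinical data.frame and returning
#'   a logical row mask (default: all rows).
#' @return List `n`, `logrank` (see [logrank_test()]), `km` (named list of
#'   [km_curve()] per group).
#' @export
stratified_evaluate <- function(risk, clinical, predicate = function(df) rep(TRUE, nrow(df))) {
  keep <- predicate(clinical)
  stopifnot(is.logical(keep), length(keep) == nrow(clinical))
  sub <- clinical[keep, , drop = FALSE]
  if (!nrow(sub)) stop("empty stratum")
  m <- match(sub$sample, risk$sample)
  if (anyNA(m)) stop("stratum sample(s) missing from the risk table")
  grp <- risk$group[m]
  res <- logrank_test(grp, sub$time_months, sub$event)
  km <- lapply(split(seq_len(nrow(sub)), grp), function(i) {
    km_curve(sub$time_months[i], sub$event[i])
  })
  list(n = nrow(sub), logrank = res, km = km)
}
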