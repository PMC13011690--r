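# Risk-stratified survival decision support: dichotomize patients by their
# stacking score, then Kaplan-Meier curves, log-rank tests and Cox models,
# including the adjuvant-therapy (POAT) contrasts within each risk group.

#' Stratify patients by model score
#'
#' @param scores probabilities in `[0, 1]`.
#' @param cutoff risk cutoff (default 0.53); a score equal to the cutoff is
#'   high risk.
#' @return factor with levels `low`, `high`.
#' @export
stratify_by_score <- function(scores, cutoff = 0.53) {
  check_prob(scores, "scores")
  factor(ifelse(scores >= cutoff, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier curves and log-rank test across strata
#'
#' @param records data.frame with columns `time` (months, > 0), `event`
#'   (0/1) and the grouping column.
#' @param group_field name of the grouping column.
#' @param ties Cox tie handling for the accompanying hazard ratio
#'   (`"breslow"` default, `"efron"` optional).
#' @return a `strata_comparison`: per-stratum `survfit` curves, log-rank
#'   statistic and p-value, and the hazard ratio (second level vs first)
#'   with 95% Wald CI.
#' @export
km_logrank <- function(records, group_field = "risk_group",
                       ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (!all(c("time", "event", group_field) %in% names(records))) {
    stop("records need `time`, `event` and `", group_field, "`", call. = FALSE)
  }
  if (any(records$time <= 0)) stop("survival times must be positive", call. = FALSE)
  if (sum(records$event) < 1L) stop("no events observed", call. = FALSE)
  g <- factor(records[[group_field]])
  if (any(table(g) == 0L)) stop("empty stratum", call. = FALSE)
  df <- data.frame(time = records$time, event = records$event, g = g)
  fit <- survival::survfit(survival::Surv(time, event) ~ g, data = df)
  lr <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  p <- pchisq(lr$chisq, df = length(lr$n) - 1L, lower.tail = FALSE)
  hr <- rep(NA_real_, 3L)
  if (nlevels(g) == 2L) {
    cx <- survival::coxph(survival::Surv(time, event) ~ g, data = df,
                          ties = ties)
    est <- unname(coef(cx)[1L]); se <- sqrt(diag(cx$var))[1L]
    hr <- exp(c(est, est - 1.96 * se, est + 1.96 * se))
  }
  structure(list(survfit = fit, logrank_chisq = unname(lr$chisq),
                 logrank_p = p, hr = hr[1L], hr_ci = hr[2:3],
                 n = table(g)),
            class = "strata_comparison")
}

#' @export
print.strata_comparison <- function(x, ...) {
  cat(sprintf("log-rank chi-square %.3f, p = %.4g\n", x$logrank_chisq,
              x$logrank_p))
  if (is.finite(x$hr)) {
    cat(sprintf("HR = %.3f [%.3f-%.3f]\n", x$hr, x$hr_ci[1L], x$hr_ci[2L]))
  }
  invisible(x)
}

#' Multivariable Cox model
#'
#' Partial-likelihood fit with Breslow tie handling (Efron optional) and
#' Wald confidence intervals. Warns when events are scarce relative to the
#' number of terms (fewer than five events per term).
#'
#' @param records data.frame with `time`, `event` and the model terms.
#' @param terms character vector of covariate names.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return data.frame (term, coef, hr, lower, upper, se, z, p).
#' @export
cox_fit <- function(records, terms, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event") %in% names(records)),
            all(terms %in% names(records)))
  n_events <- sum(records$event)
  if (n_events < 5L * length(terms)) {
    warning(sprintf("only %d events for %d terms (< 5 per term)", n_events,
                    length(terms)), call. = FALSE)
  }
  x <- as.matrix(records[, terms, drop = FALSE])
  if (qr(cbind(1, x))$rank < ncol(x) + 1L) {
    stop("rank-deficient covariates", call. = FALSE)
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(terms, collapse = " + ")))
  cx <- survival::coxph(fml, data = records, ties = ties)
  if (!is.null(cx$info) && any(!is.finite(coef(cx)))) {
    stop("Cox model failed to converge", call. = FALSE)
  }
  est <- coef(cx); se <- sqrt(diag(cx$var))
  data.frame(term = names(est), coef = unname(est), hr = exp(unname(est)),
             lower = exp(unname(est - 1.96 * se)),
             upper = exp(unname(est + 1.96 * se)),
             se = unname(se), z = unname(est / se),
             p = 2 * pnorm(-abs(unname(est / se))))
}

#' Adjuvant-therapy benefit by risk group
#'
#' Within each risk group, contrasts patients who did and did not receive
#' postoperative adjuvant therapy: Kaplan-Meier curves, a log-rank test and
#' the Cox hazard ratio of treatment. Groups with an empty treatment arm
#' are skipped with a warning.
#'
#' @param records data.frame with `time`, `event`, `poat` (0/1) and
#'   `risk_group` (`low`/`high`).
#' @param ties Cox tie handling.
#' @return named list (one entry per risk group) of `strata_comparison`s
#'   for the POAT contrast.
#' @export
poat_benefit_analysis <- function(records, ties = "breslow") {
  stopifnot(all(c("time", "event", "poat", "risk_group") %in% names(records)))
  out <- list()
  for (grp in levels(factor(records$risk_group))) {
    sub <- records[records$risk_group == grp, ]
    if (length(unique(sub$poat)) < 2L) {
      warning("risk group '", grp, "' has an empty treatment arm; skipped",
              call. = FALSE)
      next
    }
    if (sum(sub$event) < 1L) {
      warning("risk group '", grp, "' has no events; skipped", call. = FALSE)
      next
    }
    out[[grp]] <- km_logrank(sub, group_field = "poat", ties = ties)
  }
  out
}

#' Survival records of a cohort as an analysis table
#'
#' Collects each patient's follow-up time, event indicator, adjuvant-therapy
#' flag and label into a data.frame; when model scores are supplied the
#' table also carries the score and the derived risk group.
#'
#' @param cohort a `nodebag_cohort` generated with survival enabled.
#' @param scores optional per-patient probabilities aligned with the cohort.
#' @param cutoff risk cutoff passed to [stratify_by_score()].
#' @return data.frame with columns `patient_id`, `time`, `event`, `poat`,
#'   `lnm_label`, and optionally `score` and `risk_group`.
#' @export
survival_records <- function(cohort, scores = NULL, cutoff = 0.53) {
  keep <- !vapply(cohort, function(p) is.null(p$survival), logical(1L))
  df <- do.call(rbind, lapply(cohort[keep], function(p) {
    data.frame(patient_id = p$patient_id, time = p$survival$time,
               event = p$survival$event, poat = p$survival$poat,
               lnm_label = p$lnm_label)
  }))
  if (!is.null(scores)) {
    df$score <- scores[keep]
    df$risk_group <- stratify_by_score(df$score, cutoff)
  }
  df
}
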