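# End-to-end orchestration: cohort generation -> base models -> MIL ->
# stacking -> evaluation -> risk-stratified survival, with a structured,
# reproducible run report. All randomness flows from one global seed.

#' Pipeline configuration
#'
#' Collects every stage's constants in one place: 7:3 label-stratified
#' training/validation split, 5-fold CV, mediastinal window (350/40 HU),
#' 1 x 1 x 5 mm target spacing, 224-pixel patches, 2-voxel dilation,
#' Spearman 0.9 / ICC 0.75 selection thresholds, and the 0.53 stacking risk
#' cutoff. `reference_cutoffs` stores reference per-model operating
#' cutoffs as metadata only; every run recomputes its own Youden cutoffs.
#'
#' @param cohort a [cohort_config()] for the synthetic cohort.
#' @param split training fraction (default 0.7).
#' @param n_folds CV folds (default 5).
#' @param stacking_cutoff risk-stratification cutoff (default 0.53).
#' @param spearman_threshold,icc_threshold selection thresholds.
#' @param imaging imaging constants, see [imaging_config()].
#' @param mil_overrides named list of [mil_config()] overrides for both MIL
#'   models.
#' @param seed global seed.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            split = 0.7, n_folds = 5L,
                            stacking_cutoff = 0.53,
                            spearman_threshold = 0.9, icc_threshold = 0.75,
                            imaging = imaging_config(),
                            mil_overrides = list(), seed = 1L) {
  structure(list(
    cohort = cohort, split = split, n_folds = as.integer(n_folds),
    stacking_cutoff = stacking_cutoff,
    spearman_threshold = spearman_threshold, icc_threshold = icc_threshold,
    imaging = imaging, mil_overrides = mil_overrides,
    reference_cutoffs = c(Stacking = 0.530, MILDL = 0.550, MILRad = 0.500,
                          TumorDL = 0.484, TumorRad = 0.526,
                          Clinical = 0.400, LLNRad = 0.322),
    seed = as.integer(seed)), class = "pipeline_config")
}

clinical_df <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p) {
    data.frame(age_ge65 = p$clinical$age_ge65, male = p$clinical$male,
               site = p$clinical$site, t_stage = p$clinical$t_stage,
               tumor_length = p$clinical$tumor_length,
               lnm = p$lnm_label)
  }))
}

#' Percentage of a count, printed-table style
#'
#' @param n count.
#' @param total denominator.
#' @return `100 * n / total` rounded to two decimals.
#' @export
count_percent <- function(n, total) round(100 * n / total, 2)

#' Baseline characteristics summary
#'
#' Per-variable counts and percentages (two decimals) for one or more
#' cohorts; with several cohorts, a chi-square comparison p-value for each
#' categorical variable and a Kruskal-Wallis p-value for tumor length.
#'
#' @param cohorts a `nodebag_cohort` or a named list of them.
#' @return data.frame (variable, level, cohort, n, pct) with attribute
#'   `p_values` when more than one cohort is supplied and attribute
#'   `continuous` carrying mean and sd of tumor length per cohort.
#' @export
cohort_summary <- function(cohorts) {
  if (inherits(cohorts, "nodebag_cohort")) cohorts <- list(cohort = cohorts)
  if (!length(cohorts) || !length(cohorts[[1L]])) {
    stop("empty cohort", call. = FALSE)
  }
  dfs <- lapply(cohorts, clinical_df)
  vars <- list(
    age = function(d) factor(ifelse(d$age_ge65 == 1, ">=65", "<65"),
                             levels = c("<65", ">=65")),
    sex = function(d) factor(ifelse(d$male == 1, "male", "female"),
                             levels = c("male", "female")),
    site = function(d) factor(d$site, levels = c("upper", "middle", "lower")),
    t_stage = function(d) factor(paste0("T", d$t_stage),
                                 levels = paste0("T", 1:4)),
    lnm = function(d) factor(ifelse(d$lnm == 1, "yes", "no"),
                             levels = c("no", "yes")))
  rows <- list()
  for (v in names(vars)) {
    for (ci in seq_along(dfs)) {
      f <- vars[[v]](dfs[[ci]])
      tb <- table(f)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = names(tb), cohort = names(cohorts)[ci],
        n = as.integer(tb), pct = count_percent(as.integer(tb), length(f)))
    }
  }
  out <- do.call(rbind, rows)
  cont <- do.call(rbind, lapply(seq_along(dfs), function(ci) {
    data.frame(cohort = names(cohorts)[ci],
               mean = mean(dfs[[ci]]$tumor_length),
               sd = sd(dfs[[ci]]$tumor_length))
  }))
  attr(out, "continuous") <- cont
  if (length(dfs) > 1L) {
    pooled <- do.call(rbind, lapply(seq_along(dfs), function(ci) {
      cbind(dfs[[ci]], .cohort = names(cohorts)[ci])
    }))
    pv <- c(vapply(names(vars), function(v) {
      suppressWarnings(chisq.test(table(vars[[v]](pooled),
                                        pooled$.cohort))$p.value)
    }, numeric(1L)),
    tumor_length = kruskal.test(pooled$tumor_length,
                                factor(pooled$.cohort))$p.value)
    attr(out, "p_values") <- pv
  }
  out
}

#' Run the full prediction pipeline on a synthetic cohort
#'
#' Generates the cohort, splits it 7:3 with label stratification, fits the
#' five base models plus the largest-node baseline on the training split,
#' builds out-of-fold meta-features and the stacking model, evaluates all
#' seven models on the held-out split at training-derived Youden cutoffs,
#' and runs the risk-stratified adjuvant-therapy survival analysis using
#' the stacking scores (out-of-fold for training patients).
#'
#' @param config a [pipeline_config()].
#' @return a `run_report`: `models` (7 evaluation reports), `val_scores`,
#'   `cutoffs`, `summary`, `survival`, `attention`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- generate_cohort(config$cohort)
  y <- cohort_labels(cohort)
  n <- length(cohort)
  fold2 <- stratified_folds(y, 10L, derive_seed(config$seed, "split"))
  tr_idx <- which(fold2 <= round(10 * config$split))
  va_idx <- setdiff(seq_len(n), tr_idx)
  train <- cohort[tr_idx]; class(train) <- class(cohort)
  val <- cohort[va_idx]; class(val) <- class(cohort)

  base <- fit_base_models(train, seed = derive_seed(config$seed, "base"),
                          mil_overrides = config$mil_overrides)
  lln <- fit_submodel(submodel_spec("LLNRad",
                                    seed = derive_seed(config$seed, "lln")),
                      train)
  meta <- oof_probabilities(train, n_folds = config$n_folds,
                            seed = derive_seed(config$seed, "oof"),
                            mil_overrides = config$mil_overrides)
  stack <- fit_stacking(meta, y[tr_idx], n_folds = config$n_folds,
                        seed = derive_seed(config$seed, "stack"))

  train_scores <- c(
    list(Stacking = predict_meta(stack, strip_meta(meta))),
    lapply(setNames(STACK_COLUMNS, STACK_COLUMNS), function(nm) {
      predict_base(base[[nm]], train, nm)
    }),
    list(LLNRad = predict(lln, train)))
  val_scores <- c(
    list(Stacking = predict_stacking(stack, base, val)),
    lapply(setNames(STACK_COLUMNS, STACK_COLUMNS), function(nm) {
      predict_base(base[[nm]], val, nm)
    }),
    list(LLNRad = predict(lln, val)))
  roster <- c("Stacking", STACK_COLUMNS, "LLNRad")
  cutoffs <- vapply(roster, function(nm) {
    as.numeric(youden_cutoff(train_scores[[nm]], y[tr_idx]))
  }, numeric(1L))
  models <- lapply(setNames(roster, roster), function(nm) {
    evaluate_model(val_scores[[nm]], y[va_idx], cutoff = cutoffs[[nm]])
  })

  surv_block <- NULL
  if (!is.null(config$cohort$survival)) {
    all_scores <- numeric(n)
    all_scores[tr_idx] <- train_scores$Stacking
    all_scores[va_idx] <- val_scores$Stacking
    rec <- survival_records(cohort, all_scores, config$stacking_cutoff)
    strat <- tryCatch(km_logrank(rec, "risk_group"), error = function(e) e)
    poat <- tryCatch(suppressWarnings(poat_benefit_analysis(rec)),
                     error = function(e) e)
    surv_block <- list(records = rec, stratification = strat, poat = poat)
  }

  att <- attention_report(base$MILRad, cohort_bags(val, "radiomic"))

  structure(list(
    models = models, val_scores = val_scores, train_scores = train_scores,
    cutoffs = cutoffs, labels = list(train = y[tr_idx], val = y[va_idx]),
    summary = cohort_summary(list(training = train, validation = val)),
    survival = surv_block, attention = att,
    base_models = base, lln_model = lln, stacking = stack,
    manifest = list(seed = config$seed, n_patients = n,
                    n_train = length(tr_idx), n_val = length(va_idx),
                    reference_cutoffs = config$reference_cutoffs,
                    timestamp = NULL)),
    class = "run_report")
}

strip_meta <- function(meta) {
  x <- unclass(meta)
  attr(x, "fold") <- NULL
  attr(x, "provenance") <- NULL
  x
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d): %d train / %d validation patients\n",
              x$manifest$seed, x$manifest$n_train, x$manifest$n_val))
  for (nm in names(x$models)) {
    r <- x$models[[nm]]
    cat(sprintf("  %-9s AUC %.3f (%.3f-%.3f), cutoff %.3f\n", nm,
                r$roc$auc, r$roc$ci[1L], r$roc$ci[2L], x$cutoffs[[nm]]))
  }
  if (!is.null(x$survival) && inherits(x$survival$stratification,
                                       "strata_comparison")) {
    s <- x$survival$stratification
    cat(sprintf("  risk stratification: HR %.3f [%.3f-%.3f], log-rank p %.4g\n",
                s$hr, s$hr_ci[1L], s$hr_ci[2L], s$logrank_p))
  }
  invisible(x)
}
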