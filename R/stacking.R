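# Decision-level (late) fusion: the five base-model probabilities
# (MILDL, MILRad, TumorDL, TumorRad, Clinical) form the meta-features of an
# SVM stacking learner. Meta-training rows are produced out-of-fold so no
# patient's label can leak into its own meta-features; LLNRad is a
# comparison baseline and is not part of the stack.

STACK_COLUMNS <- c("MILDL", "MILRad", "TumorDL", "TumorRad", "Clinical")

cohort_bags <- function(cohort, view = c("radiomic", "deep")) {
  view <- match.arg(view)
  lapply(cohort, function(p) {
    mil_bag(if (view == "radiomic") p$node_features else p$node_deep_features,
            p$lnm_label, p$patient_id)
  })
}

#' Fit the five base models on a training cohort
#'
#' @param cohort training `nodebag_cohort`.
#' @param seed integer seed; each base model derives its own stream.
#' @param mil_overrides named list of [mil_config()] arguments applied to
#'   both MIL models (e.g. `list(max_epochs = 100)`).
#' @return named list of fitted models (`MILDL`, `MILRad`, `TumorDL`,
#'   `TumorRad`, `Clinical`).
#' @export
fit_base_models <- function(cohort, seed = 1L, mil_overrides = list()) {
  mk_mil <- function(dim, tag) {
    do.call(mil_config, c(list(input_dim = dim,
                               seed = derive_seed(seed, tag)),
                          mil_overrides))
  }
  d_rad <- ncol(cohort[[1L]]$node_features)
  d_deep <- ncol(cohort[[1L]]$node_deep_features)
  list(
    MILDL = train_mil(cohort_bags(cohort, "deep"), mk_mil(d_deep, "mildl")),
    MILRad = train_mil(cohort_bags(cohort, "radiomic"), mk_mil(d_rad, "milrad")),
    TumorDL = fit_submodel(submodel_spec("TumorDL",
                                         seed = derive_seed(seed, "tumordl")),
                           cohort),
    TumorRad = fit_submodel(submodel_spec("TumorRad",
                                          seed = derive_seed(seed, "tumorrad")),
                            cohort),
    Clinical = fit_submodel(submodel_spec("Clinical",
                                          seed = derive_seed(seed, "clinical")),
                            cohort)
  )
}

predict_base <- function(model, cohort, name) {
  if (inherits(model, "mil_net")) {
    view <- if (name == "MILDL") "deep" else "radiomic"
    predict(model, cohort_bags(cohort, view))
  } else {
    predict(model, cohort)
  }
}

#' Out-of-fold base-model probabilities for meta-training
#'
#' Splits the training cohort into label-stratified folds; each patient's
#' five base-model probabilities come from models fitted without that
#' patient's fold. If a fold draw leaves a fold single-class, the folds are
#' redrawn with a shifted seed (logged as a message).
#'
#' @param cohort training `nodebag_cohort`.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed.
#' @param mil_overrides passed to [fit_base_models()].
#' @return a `meta_feature_table`: matrix n x 5 with columns
#'   `MILDL, MILRad, TumorDL, TumorRad, Clinical`, attribute
#'   `provenance = "oof"` and the fold assignment.
#' @export
oof_probabilities <- function(cohort, n_folds = 5L, seed = 1L,
                              mil_overrides = list()) {
  y <- cohort_labels(cohort)
  fold <- stratified_folds(y, n_folds, derive_seed(seed, "folds"))
  tries <- 0L
  while (any(vapply(seq_len(n_folds), function(f) {
    length(unique(y[fold != f])) < 2L || !sum(fold == f)
  }, logical(1L))) && tries < 10L) {
    tries <- tries + 1L
    message("refolding: a fold was single-class")
    fold <- stratified_folds(y, n_folds, derive_seed(seed, paste0("refold", tries)))
  }
  meta <- matrix(NA_real_, length(cohort), length(STACK_COLUMNS),
                 dimnames = list(vapply(cohort, `[[`, character(1L), "patient_id"),
                                 STACK_COLUMNS))
  for (f in seq_len(n_folds)) {
    tr <- cohort[fold != f]
    class(tr) <- class(cohort)
    models <- fit_base_models(tr, seed = derive_seed(seed, paste0("fold", f)),
                              mil_overrides = mil_overrides)
    te <- cohort[fold == f]
    class(te) <- class(cohort)
    for (nm in STACK_COLUMNS) {
      meta[fold == f, nm] <- predict_base(models[[nm]], te, nm)
    }
  }
  attr(meta, "provenance") <- "oof"
  attr(meta, "fold") <- fold
  class(meta) <- c("meta_feature_table", class(meta))
  meta
}

#' Fit the SVM stacking meta-learner
#'
#' Requires out-of-fold meta-features (leakage guard). Hyperparameters are
#' tuned by stratified 5-fold CV on the meta-features.
#'
#' @param meta a `meta_feature_table` from [oof_probabilities()] (or a
#'   matrix with the five named columns and `provenance` attribute "oof").
#' @param labels binary labels aligned with `meta` rows.
#' @param n_folds,seed CV controls.
#' @return a `stacking_model`.
#' @export
fit_stacking <- function(meta, labels, n_folds = 5L, seed = 1L) {
  if (!identical(attr(meta, "provenance"), "oof")) {
    stop("meta-features must be out-of-fold (leakage guard)", call. = FALSE)
  }
  if (!identical(colnames(meta), STACK_COLUMNS)) {
    stop("meta table must have exactly the columns ",
         paste(STACK_COLUMNS, collapse = ", "), call. = FALSE)
  }
  check_prob(as.numeric(meta), "meta probabilities")
  x <- unclass(meta)
  attr(x, "provenance") <- NULL; attr(x, "fold") <- NULL
  y <- as.integer(labels)
  foldid <- stratified_folds(y, n_folds, derive_seed(seed, "stackgrid"))
  grid <- rbind(
    expand.grid(kernel = "linear", cost = c(0.01, 0.1, 1, 10, 100),
                gamma = NA, stringsAsFactors = FALSE),
    expand.grid(kernel = "radial", cost = c(0.01, 0.1, 1, 10, 100),
                gamma = c(NA, 0.01, 0.1), stringsAsFactors = FALSE))
  grid$auc <- vapply(seq_len(nrow(grid)), function(i) {
    svm_cv_auc(x, y, grid$kernel[i], grid$cost[i], grid$gamma[i],
               foldid, derive_seed(seed, "stacksvm"))
  }, numeric(1L))
  best <- grid[which.max(grid$auc), ]
  fit <- with_seed(derive_seed(seed, "stackfinal"), e1071::svm(
    x, factor(y, levels = c(0, 1)), kernel = best$kernel, cost = best$cost,
    gamma = if (is.na(best$gamma)) 1 / ncol(x) else best$gamma,
    probability = TRUE, scale = FALSE))
  structure(list(fit = fit, best = best, cv_grid = grid,
                 fold = attr(meta, "fold"), columns = STACK_COLUMNS),
            class = "stacking_model")
}

#' Stacking prediction for new patients
#'
#' Scores patients with the full-training base models, assembles the
#' five-column meta-feature row in the fixed column order, and applies the
#' meta-learner.
#'
#' @param stack a `stacking_model`.
#' @param base_models named list from [fit_base_models()] (fitted on the
#'   full training cohort).
#' @param cohort patients to score.
#' @return probability per patient, in `[0, 1]`.
#' @export
predict_stacking <- function(stack, base_models, cohort) {
  missing_m <- setdiff(STACK_COLUMNS, names(base_models))
  if (length(missing_m)) {
    stop("missing base model(s): ", paste(missing_m, collapse = ", "),
         call. = FALSE)
  }
  meta <- vapply(STACK_COLUMNS, function(nm) {
    predict_base(base_models[[nm]], cohort, nm)
  }, numeric(length(cohort)))
  if (length(cohort) == 1L) meta <- matrix(meta, 1L,
                                           dimnames = list(NULL, STACK_COLUMNS))
  predict_meta(stack, meta)
}

#' @rdname predict_stacking
#' @param meta a matrix with exactly the five named columns in order.
#' @export
predict_meta <- function(stack, meta) {
  if (!identical(colnames(meta), stack$columns)) {
    stop("meta columns must be exactly ",
         paste(stack$columns, collapse = ", "), " in that order",
         call. = FALSE)
  }
  pr <- predict(stack$fit, unclass(meta)[, , drop = FALSE], probability = TRUE)
  unname(attr(pr, "probabilities")[, "1"])
}

#' @export
print.stacking_model <- function(x, ...) {
  cat(sprintf("Stacking SVM over (%s): %s kernel, cost %.2g, CV AUC %.3f\n",
              paste(x$columns, collapse = ", "), x$best$kernel, x$best$cost,
              x$best$auc))
  invisible(x)
}
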