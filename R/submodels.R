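# Single-source base models: TumorRad, TumorDL, LLNRad, Clinical.
# Each is a scaler / LASSO-selector / SVM stack emitting a per-patient
# probability of lymph-node metastasis. Deep-feature models skip z-scoring.

#' Submodel specification
#'
#' @param name one of `"TumorRad"`, `"TumorDL"`, `"LLNRad"`, `"Clinical"`.
#' @param zscore apply z-score normalization (forced OFF for TumorDL —
#'   deep features are never z-scored).
#' @param lasso apply LASSO feature selection.
#' @param cost_grid,gamma_grid SVM hyperparameter grids; `NA` in
#'   `gamma_grid` means the 1/d auto-scale.
#' @param n_folds CV folds for the grid search (default 5).
#' @param seed integer seed.
#' @return a `submodel_spec`.
#' @export
submodel_spec <- function(name = c("TumorRad", "TumorDL", "LLNRad", "Clinical"),
                          zscore = NULL, lasso = TRUE,
                          cost_grid = c(0.01, 0.1, 1, 10, 100),
                          gamma_grid = c(NA, 0.01, 0.1),
                          n_folds = 5L, seed = 1L) {
  name <- match.arg(name)
  if (is.null(zscore)) zscore <- name != "TumorDL"
  if (name == "TumorDL" && isTRUE(zscore)) {
    stop("TumorDL consumes deep features, which are never z-scored", call. = FALSE)
  }
  structure(list(name = name, zscore = zscore, lasso = lasso,
                 cost_grid = cost_grid, gamma_grid = gamma_grid,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "submodel_spec")
}

#' Largest lymph node of a patient
#'
#' @param patient a patient record with `node_sizes` (tabular path) or a
#'   list of mask volumes.
#' @return index of the node with maximal size; ties go to the lowest index.
#' @export
largest_node_of <- function(patient) {
  sizes <- patient$node_sizes
  if (is.null(sizes) || !length(sizes)) stop("patient has no nodes", call. = FALSE)
  which.max(sizes)  # which.max returns the first (lowest) index on ties
}

#' Clinical covariate design matrix
#'
#' Encoding: age >= 65 binary, sex binary, primary site one-hot
#' (upper/middle/lower), T stage ordinal 1-4, tumor length in cm.
#'
#' @param cohort a `nodebag_cohort`.
#' @return numeric matrix, one row per patient.
#' @export
clinical_matrix <- function(cohort) {
  m <- do.call(rbind, lapply(cohort, function(p) {
    cl <- p$clinical
    c(age_ge65 = cl$age_ge65, male = cl$male,
      site_upper = as.integer(cl$site == "upper"),
      site_middle = as.integer(cl$site == "middle"),
      site_lower = as.integer(cl$site == "lower"),
      t_stage = cl$t_stage, tumor_length = cl$tumor_length)
  }))
  rownames(m) <- vapply(cohort, function(p) p$patient_id, character(1L))
  m
}

# Per-patient feature matrix for a submodel source.
submodel_matrix <- function(cohort, name) {
  switch(name,
         TumorRad = t(vapply(cohort, function(p) p$tumor_features,
                             cohort[[1L]]$tumor_features)),
         TumorDL = t(vapply(cohort, function(p) p$tumor_deep_features,
                            cohort[[1L]]$tumor_deep_features)),
         LLNRad = t(vapply(cohort, function(p) {
           p$node_features[largest_node_of(p), ]
         }, cohort[[1L]]$node_features[1L, ])),
         Clinical = clinical_matrix(cohort),
         stop("unknown submodel source: ", name, call. = FALSE))
}

svm_cv_auc <- function(x, y, kernel, cost, gamma, foldid, seed) {
  scores <- rep(NA_real_, length(y))
  for (f in sort(unique(foldid))) {
    tr <- foldid != f
    if (length(unique(y[tr])) < 2L) return(NA_real_)
    fit <- with_seed(seed + f, e1071::svm(
      x[tr, , drop = FALSE], factor(y[tr], levels = c(0, 1)),
      kernel = kernel, cost = cost,
      gamma = if (is.na(gamma)) 1 / ncol(x) else gamma,
      probability = TRUE, scale = FALSE))
    pr <- predict(fit, x[!tr, , drop = FALSE], probability = TRUE)
    scores[!tr] <- attr(pr, "probabilities")[, "1"]
  }
  auc_mw(scores, y)
}

#' Fit a single-source base model
#'
#' Optional z-scoring and LASSO selection (both fitted on the training
#' cohort only), followed by an SVM whose kernel/cost/width are chosen by
#' stratified 5-fold cross-validation maximizing AUC. Probabilities come
#' from Platt-style sigmoid calibration.
#'
#' @param spec a [submodel_spec()].
#' @param cohort training `nodebag_cohort` (both classes present).
#' @return a fitted `submodel` with frozen feature list and CV summary.
#' @export
fit_submodel <- function(spec, cohort) {
  stopifnot(inherits(spec, "submodel_spec"))
  x <- submodel_matrix(cohort, spec$name)
  if (is.null(colnames(x))) colnames(x) <- sprintf("x%03d", seq_len(ncol(x)))
  y <- cohort_labels(cohort)
  if (length(unique(y)) < 2L) stop("both classes required", call. = FALSE)
  scaler <- NULL
  xm <- x
  if (spec$zscore) {
    scaler <- zscore_fit(x)
    xm <- zscore_apply(x, scaler)
  }
  medians <- apply(xm, 2L, median)
  feats <- colnames(xm)
  if (spec$lasso && ncol(xm) > 2L) {
    sel <- lasso_select(xm, y, n_folds = spec$n_folds,
                        seed = derive_seed(spec$seed, "lasso"))
    if (length(sel) >= 1L) feats <- as.character(sel)
  }
  xs <- xm[, feats, drop = FALSE]
  foldid <- stratified_folds(y, spec$n_folds, derive_seed(spec$seed, "grid"))
  grid <- rbind(
    expand.grid(kernel = "linear", cost = spec$cost_grid, gamma = NA,
                stringsAsFactors = FALSE),
    expand.grid(kernel = "radial", cost = spec$cost_grid,
                gamma = spec$gamma_grid, stringsAsFactors = FALSE))
  if (!nrow(grid)) stop("empty hyperparameter grid", call. = FALSE)
  grid$auc <- vapply(seq_len(nrow(grid)), function(i) {
    svm_cv_auc(xs, y, grid$kernel[i], grid$cost[i], grid$gamma[i],
               foldid, derive_seed(spec$seed, "svm"))
  }, numeric(1L))
  best <- grid[which.max(grid$auc), ]  # first max: deterministic tie-break
  fit <- with_seed(derive_seed(spec$seed, "final"), e1071::svm(
    xs, factor(y, levels = c(0, 1)), kernel = best$kernel, cost = best$cost,
    gamma = if (is.na(best$gamma)) 1 / ncol(xs) else best$gamma,
    probability = TRUE, scale = FALSE))
  structure(list(spec = spec, scaler = scaler, features = feats,
                 impute = medians[feats], fit = fit, cv_grid = grid,
                 best = best,
                 train_ids = vapply(cohort, function(p) p$patient_id,
                                    character(1L))),
            class = "submodel")
}

#' @export
predict.submodel <- function(object, cohort, ...) {
  x <- submodel_matrix(cohort, object$spec$name)
  if (is.null(colnames(x))) colnames(x) <- sprintf("x%03d", seq_len(ncol(x)))
  xm <- if (!is.null(object$scaler)) zscore_apply(x, object$scaler) else x
  missing_f <- setdiff(object$features, colnames(xm))
  if (length(missing_f)) {
    stop("unknown feature names at predict time: ",
         paste(head(missing_f, 5L), collapse = ", "), call. = FALSE)
  }
  xs <- xm[, object$features, drop = FALSE]
  # training-cohort median imputation for missing covariates
  if (any(is.na(xs))) {
    for (j in seq_len(ncol(xs))) {
      nas <- is.na(xs[, j])
      if (any(nas)) xs[nas, j] <- object$impute[j]
    }
  }
  pr <- predict(object$fit, xs, probability = TRUE)
  unname(attr(pr, "probabilities")[, "1"])
}

#' @export
print.submodel <- function(x, ...) {
  cat(sprintf("%s submodel: %d features, SVM %s (cost %.2g%s), CV AUC %.3f\n",
              x$spec$name, length(x$features), x$best$kernel, x$best$cost,
              if (is.na(x$best$gamma)) "" else sprintf(", gamma %.2g", x$best$gamma),
              x$best$auc))
  invisible(x)
}
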