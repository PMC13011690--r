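# The feature-reduction chain: z-scoring (training cohort only), Spearman
# redundancy filter, ICC stability filter, and cross-validated LASSO
# selection. Each stage returns a subset of its input features.

#' Fit / apply z-score normalization
#'
#' Means and standard deviations are learned on the training table only;
#' the population standard deviation (denominator n) is used by default.
#' Constant features are dropped with a warning.
#'
#' @param table numeric matrix or data.frame (rows = patients).
#' @param population use denominator n (default) rather than n - 1.
#' @return `zscore_fit()`: a `scaler_params` object; `zscore_apply()`: the
#'   standardized matrix restricted to retained features.
#' @export
zscore_fit <- function(table, population = TRUE) {
  x <- as.matrix(table)
  if (nrow(x) < 2L) stop("need at least 2 rows to fit a scaler", call. = FALSE)
  mu <- colMeans(x)
  s <- apply(x, 2L, function(v) {
    sqrt(mean((v - mean(v))^2) * if (population) 1 else length(v) / (length(v) - 1))
  })
  keep <- s > 0
  if (any(!keep)) {
    warning(sprintf("dropping %d constant feature(s): %s", sum(!keep),
                    paste(head(colnames(x)[!keep], 5L), collapse = ", ")),
            call. = FALSE)
  }
  structure(list(mean = mu[keep], sd = s[keep],
                 features = colnames(x)[keep],
                 dropped = colnames(x)[!keep]),
            class = "scaler_params")
}

#' @rdname zscore_fit
#' @param params a `scaler_params` from [zscore_fit()].
#' @export
zscore_apply <- function(table, params) {
  stopifnot(inherits(params, "scaler_params"))
  x <- as.matrix(table)
  missing_f <- setdiff(params$features, colnames(x))
  if (length(missing_f)) {
    stop("features absent from table: ", paste(head(missing_f, 5L), collapse = ", "),
         call. = FALSE)
  }
  x <- x[, params$features, drop = FALSE]
  sweep(sweep(x, 2L, params$mean), 2L, params$sd, `/`)
}

#' Spearman redundancy filter
#'
#' Removes one feature of every pair whose |Spearman rho| exceeds the
#' threshold: offending pairs are processed in descending |rho|, the member
#' with the higher mean absolute correlation against the currently retained
#' features is removed, and mean absolute correlations are recomputed after
#' each removal. On ties (e.g. exact duplicates) the feature later in
#' catalog order is removed.
#'
#' @param table numeric matrix (rows = patients, columns = features).
#' @param threshold correlation threshold (default 0.9).
#' @return character vector of retained feature names, in input order; the
#'   removal log is attached as attribute `removals`.
#' @export
spearman_redundancy_filter <- function(table, threshold = 0.9) {
  x <- as.matrix(table)
  nm <- colnames(x)
  if (is.null(nm)) nm <- colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  if (ncol(x) < 2L) return(nm)
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  rho[is.na(rho)] <- 0
  keep <- rep(TRUE, ncol(x))
  removals <- list()
  repeat {
    sub <- abs(rho[keep, keep, drop = FALSE])
    diag(sub) <- 0
    if (!any(sub > threshold)) break
    # worst offending pair among retained features
    w <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    ki <- which(keep)
    a <- ki[w[1L]]; b <- ki[w[2L]]
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    others <- setdiff(ki, c(a, b))
    mac <- function(f) if (length(others)) mean(abs(rho[f, others])) else 0
    drop_f <- if (mac(a) > mac(b)) a else b  # tie -> later catalog position
    keep[drop_f] <- FALSE
    removals[[length(removals) + 1L]] <-
      data.frame(removed = nm[drop_f], partner = nm[c(a, b)[c(a, b) != drop_f]],
                 rho = rho[a, b])
  }
  out <- nm[keep]
  attr(out, "removals") <- if (length(removals)) do.call(rbind, removals) else NULL
  out
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single rater, computed from
#' the ANOVA mean squares of a subjects x raters table.
#'
#' @param measurements numeric matrix, rows = subjects, columns = raters
#'   (here: the two delineation replicates).
#' @return the ICC(2,1) estimate.
#' @export
icc21 <- function(measurements) {
  x <- as.matrix(measurements)
  n <- nrow(x); k <- ncol(x)
  if (n < 3L) stop("ICC needs at least 3 subjects", call. = FALSE)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)            # between subjects
  msc <- n * sum((col_m - grand)^2) / (k - 1)            # between raters
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' ICC stability filter
#'
#' Keeps features whose test-retest ICC(2,1) across two delineation
#' replicates exceeds the threshold.
#'
#' @param rep1,rep2 aligned numeric matrices (same subjects and features).
#' @param threshold ICC threshold (default 0.75).
#' @return retained feature names with per-feature ICCs as attribute `icc`.
#' @export
icc_filter <- function(rep1, rep2, threshold = 0.75) {
  r1 <- as.matrix(rep1); r2 <- as.matrix(rep2)
  if (!identical(dim(r1), dim(r2)) ||
      !identical(colnames(r1), colnames(r2))) {
    stop("replicate tables must share subjects and features", call. = FALSE)
  }
  iccs <- vapply(seq_len(ncol(r1)), function(j) {
    if (stats::sd(r1[, j]) == 0 && stats::sd(r2[, j]) == 0 &&
        all(r1[, j] == r2[, j])) return(1)
    icc21(cbind(r1[, j], r2[, j]))
  }, numeric(1L))
  names(iccs) <- colnames(r1)
  out <- colnames(r1)[iccs > threshold]
  attr(out, "icc") <- iccs
  out
}

#' Cross-validated LASSO feature selection
#'
#' Logistic LASSO with the penalty chosen by minimum mean cross-validated
#' deviance over label-stratified folds; returns the features with nonzero
#' coefficients at that penalty.
#'
#' @param table standardized numeric matrix.
#' @param labels binary vector with both classes present.
#' @param n_folds number of CV folds (default 5).
#' @param seed integer seed controlling the folds.
#' @return selected feature names; the fitted `cv.glmnet` object is attached
#'   as attribute `fit`.
#' @export
lasso_select <- function(table, labels, n_folds = 5L, seed = 1L) {
  x <- as.matrix(table)
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("labels must contain both classes", call. = FALSE)
  foldid <- stratified_folds(y, n_folds, seed)
  fit <- with_seed(seed, glmnet::cv.glmnet(x, y, family = "binomial",
                                           type.measure = "deviance",
                                           foldid = foldid,
                                           standardize = FALSE))
  beta <- as.matrix(coef(fit, s = "lambda.min"))[-1L, 1L]
  out <- colnames(x)[beta != 0]
  attr(out, "fit") <- fit
  out
}

#' Run the full feature-reduction chain
#'
#' z-score (fit on training rows), Spearman redundancy filter, optional ICC
#' stability filter, then LASSO. Each stage sees only the survivors of the
#' previous one; the report records survivors after every stage.
#'
#' @param table training feature matrix.
#' @param labels binary training labels.
#' @param rep1,rep2 optional delineation replicate tables for the ICC stage.
#' @param spearman_threshold,icc_threshold stage thresholds (0.9, 0.75).
#' @param n_folds,seed LASSO CV controls.
#' @return list with `features` (final selection), `scaler`, and `report`
#'   (survivors after each stage).
#' @export
select_features <- function(table, labels, rep1 = NULL, rep2 = NULL,
                            spearman_threshold = 0.9, icc_threshold = 0.75,
                            n_folds = 5L, seed = 1L) {
  scaler <- zscore_fit(table)
  z <- zscore_apply(table, scaler)
  s1 <- spearman_redundancy_filter(z, threshold = spearman_threshold)
  survivors <- list(zscore = scaler$features, spearman = as.character(s1))
  cur <- as.character(s1)
  if (!is.null(rep1) && !is.null(rep2)) {
    common <- intersect(cur, colnames(as.matrix(rep1)))
    kept <- icc_filter(as.matrix(rep1)[, common, drop = FALSE],
                       as.matrix(rep2)[, common, drop = FALSE],
                       threshold = icc_threshold)
    cur <- intersect(cur, as.character(kept))
    survivors$icc <- cur
  }
  sel <- lasso_select(z[, cur, drop = FALSE], labels, n_folds = n_folds,
                      seed = seed)
  survivors$lasso <- as.character(sel)
  list(features = as.character(sel), scaler = scaler, report = survivors)
}
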