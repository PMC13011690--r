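#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov coef glm kruskal.test median pchisq pnorm predict
#'   quantile rbinom rnorm rpois runif sd setNames var chisq.test qnorm
#'   binomial cor rexp complete.cases
#' @importFrom utils read.csv write.csv head tail
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

# Evaluate expr under a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream tag, staying in
# 32-bit integer range.
derive_seed <- function(seed, tag) {
  s <- (as.double(seed) * 48271 + sum(utf8ToInt(as.character(tag))) * 9973) %% 2147483629
  as.integer(s)
}

# Stratified fold assignment: every fold gets both classes when feasible.
stratified_folds <- function(labels, n_folds, seed) {
  stopifnot(n_folds >= 2L)
  labels <- as.integer(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
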