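# Deep-feature extractor contract. The pipeline consumes 512-dimensional
# pooled representations of lesion patches through a pluggable extractor
# object; the built-in extractor is a documented deterministic stub (seeded
# random projection of an average-pooled patch followed by a tanh
# nonlinearity). An adapter implementing the same contract can wrap a
# pretrained 18-layer residual network's final pooling layer. Deep features
# are intentionally never z-score normalized downstream.

#' Deterministic stub deep-feature extractor
#'
#' Average-pools each 224x224 channel to `pool x pool`, flattens the three
#' channels, applies a fixed seeded Gaussian random projection to 512
#' dimensions and a tanh nonlinearity. Identical patches always map to
#' identical vectors.
#'
#' @param seed seed of the fixed projection.
#' @param pool pooled spatial size per channel (default 16).
#' @param n_features output dimension (default 512, the pooled width of the
#'   reference CNN backbone).
#' @return a `deep_extractor` object with fields `extract`, `name`,
#'   `deterministic`, `n_features`.
#' @export
stub_deep_extractor <- function(seed = 20240101, pool = 16L,
                                n_features = 512L) {
  in_dim <- 3L * pool * pool
  W <- with_seed(seed, matrix(rnorm(in_dim * n_features, sd = 1 / sqrt(in_dim)),
                              in_dim, n_features))
  b <- with_seed(seed + 1L, rnorm(n_features, sd = 0.1))
  extract <- function(patch) {
    stopifnot(inherits(patch, "patch_triplet"))
    ch <- patch$channels
    pooled <- vapply(1:3, function(k) {
      as.numeric(avg_pool2d(ch[k, , ], pool))
    }, numeric(pool * pool))
    as.numeric(tanh(matrix(as.numeric(pooled), 1L) %*% W + b))
  }
  structure(list(extract = extract, name = "stub-randproj",
                 deterministic = TRUE, n_features = as.integer(n_features)),
            class = "deep_extractor")
}

avg_pool2d <- function(mat, out) {
  n <- nrow(mat)
  stopifnot(n == ncol(mat))
  edges <- floor(seq(0L, n, length.out = out + 1L))
  sapply(seq_len(out), function(j) {
    cols <- (edges[j] + 1L):edges[j + 1L]
    vapply(seq_len(out), function(i) {
      mean(mat[(edges[i] + 1L):edges[i + 1L], cols])
    }, numeric(1L))
  })
}

#' Extract deep features from a patch through an extractor contract
#'
#' @param patch a `patch_triplet` from [extract_patch()].
#' @param extractor a `deep_extractor` (default: the deterministic stub).
#' @return named numeric vector of length `extractor$n_features` tagged with
#'   family `"deep"`; these values bypass z-scoring downstream.
#' @export
extract_deep_features <- function(patch, extractor = stub_deep_extractor()) {
  stopifnot(inherits(extractor, "deep_extractor"))
  v <- extractor$extract(patch)
  if (length(v) != extractor$n_features) {
    stop(sprintf("extractor '%s' returned %d values, contract requires %d",
                 extractor$name, length(v), extractor$n_features),
         call. = FALSE)
  }
  names(v) <- sprintf("deep%03d", seq_along(v))
  attr(v, "families") <- rep("deep", length(v))
  v
}
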