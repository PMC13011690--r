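# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition (pair enumeration, exhaustive
# threshold search, ANOVA tables) rather than calling package internals.

# AUC by direct enumeration of all positive-negative pairs, ties = 1/2.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Youden cutoff by exhaustive enumeration of observed thresholds.
youden_bruteforce <- function(scores, labels) {
  best_j <- -Inf
  best_c <- Inf
  for (ct in sort(unique(scores))) {
    sens <- mean(scores[labels == 1] >= ct)
    spec <- mean(scores[labels == 0] < ct)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_c <- ct
    }
  }
  best_c
}

# Normalized symmetric GLCM of a single 2D slice of integer levels by
# direct pair counting.
glcm_bruteforce <- function(slice, ng, dr, dc) {
  counts <- matrix(0, ng, ng)
  nr <- nrow(slice); nc <- ncol(slice)
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    r2 <- r + dr; c2 <- cl + dc
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    a <- slice[r, cl]; b <- slice[r2, c2]
    if (is.na(a) || is.na(b)) next
    counts[a, b] <- counts[a, b] + 1
    counts[b, a] <- counts[b, a] + 1
  }
  counts / sum(counts)
}

# Spearman redundancy filter by direct, stepwise application of the rule,
# recomputing correlations from the data at every step.
spearman_filter_bruteforce <- function(x, threshold = 0.9) {
  kept <- colnames(x)
  repeat {
    rho <- suppressWarnings(stats::cor(x[, kept, drop = FALSE],
                                       method = "spearman"))
    rho[is.na(rho)] <- 0
    diag(rho) <- 0
    if (max(abs(rho)) <= threshold) break
    w <- which(abs(rho) == max(abs(rho)), arr.ind = TRUE)[1, ]
    pair <- sort(kept[w])
    others <- setdiff(kept, pair)
    mac <- vapply(pair, function(f) {
      if (length(others)) mean(abs(rho[f, others])) else 0
    }, numeric(1))
    drop_f <- if (mac[1] > mac[2]) pair[1] else pair[2]
    kept <- setdiff(kept, drop_f)
  }
  kept
}

# ICC(2,1) from the two-way ANOVA table fitted by aov().
icc_aov_oracle <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  long <- data.frame(y = as.vector(tab),
                     subject = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(aov(y ~ subject + rater, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# tiny labeled cohort for fast fits
tiny_cohort <- function(n = 80, seed = 99, survival = NULL) {
  generate_cohort(cohort_config(n_patients = n, seed = seed,
                                survival = survival))
}

fast_mil <- list(max_epochs = 25L, patience = 10L)
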