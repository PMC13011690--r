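test_that("the bag label is exactly the OR of the latent node labels", {
  cohort <- generate_cohort(cohort_config(n_patients = 150L, seed = 3L,
                                          survival = NULL))
  for (p in cohort) {
    expect_identical(p$lnm_label, as.integer(any(p$node_latent_labels == 1L)))
  }
})

test_that("every node-positive bag carries at least one metastatic node", {
  cohort <- generate_cohort(cohort_config(n_patients = 200L, seed = 11L,
                                          survival = NULL))
  pos <- Filter(function(p) p$lnm_label == 1L, cohort)
  expect_gt(length(pos), 0L)
  for (p in pos) expect_gte(sum(p$node_latent_labels), 1L)
  neg <- Filter(function(p) p$lnm_label == 0L, cohort)
  for (p in neg) expect_identical(sum(p$node_latent_labels), 0L)
})

test_that("prevalence and node-count distribution match the configuration", {
  n <- 2000L
  cohort <- generate_cohort(cohort_config(n_patients = n, seed = 7L,
                                          survival = NULL))
  y <- vapply(cohort, function(p) p$lnm_label, integer(1L))
  # exact binomial 99.9% band around 0.62
  band <- qbinom(c(5e-4, 1 - 5e-4), n, 0.62) / n
  expect_gte(mean(y), band[1L])
  expect_lte(mean(y), band[2L])
  nodes <- vapply(cohort, function(p) nrow(p$node_features), integer(1L))
  expect_true(all(nodes >= 1L))
  # mean of 1 + Poisson(7.7) is 8.7 with variance 7.7
  se <- sqrt(7.7 / n)
  expect_lt(abs(mean(nodes) - 8.7), 4 * se)
})

test_that("metastatic nodes are shifted on the informative features only", {
  cfg <- cohort_config(n_patients = 600L, seed = 5L, survival = NULL)
  cohort <- generate_cohort(cfg)
  x <- do.call(rbind, lapply(cohort, `[[`, "node_features"))
  lat <- unlist(lapply(cohort, `[[`, "node_latent_labels"))
  inf_shift <- colMeans(x[lat == 1L, 1:8]) - colMeans(x[lat == 0L, 1:8])
  noise_shift <- colMeans(x[lat == 1L, 9:32]) - colMeans(x[lat == 0L, 9:32])
  expect_true(all(inf_shift > 1.0))       # configured effect 1.5
  expect_true(all(abs(noise_shift) < 0.3))
})

test_that("cohorts are byte-identical for a fixed config and seed", {
  cfg <- cohort_config(n_patients = 40L, seed = 123L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_config(n_patients = 40L, seed = 124L))
  expect_false(identical(a, c2))
})

test_that("cohort generation does not disturb the global RNG stream", {
  set.seed(42L)
  before <- .Random.seed
  invisible(generate_cohort(cohort_config(n_patients = 10L, seed = 9L)))
  expect_identical(before, .Random.seed)
})

test_that("repeat measurements respect the target reliability ordering", {
  rm_hi <- generate_repeat_measurements(400L, 4L, reliability = 0.9, seed = 2L)
  rm_lo <- generate_repeat_measurements(400L, 4L, reliability = 0.3, seed = 2L)
  icc_hi <- vapply(1:4, function(j) icc21(cbind(rm_hi$rep1[, j],
                                                rm_hi$rep2[, j])), numeric(1L))
  icc_lo <- vapply(1:4, function(j) icc21(cbind(rm_lo$rep1[, j],
                                                rm_lo$rep2[, j])), numeric(1L))
  expect_true(all(icc_hi > 0.8))
  expect_true(all(icc_lo < 0.6))
  expect_true(all(icc_hi > icc_lo))
  # zero reliability -> replicates are independent noise
  rm0 <- generate_repeat_measurements(3000L, 1L, reliability = 0, seed = 4L)
  expect_lt(abs(cor(rm0$rep1[, 1L], rm0$rep2[, 1L])), 0.06)
  expect_error(generate_repeat_measurements(10L, 2L, reliability = 1),
               "reliability")
})

test_that("phantom lesions are exact ellipsoid indicators in physical mm", {
  ph <- generate_phantom_case(
    grid_shape = c(20L, 40L, 40L), spacing = c(1, 1, 1),
    lesion_spec = list(list(center = c(10, 20, 20), radii = c(5, 5, 5),
                            intensity = 60, kind = "lymph_node")),
    noise_sd = 0, background = -50, seed = 1L)
  m <- ph$masks[[1L]]$mask
  # voxel count of a radius-5 sphere within 5% of (4/3) pi 125
  expect_lt(abs(sum(m) / ((4 / 3) * pi * 125) - 1), 0.05)
  # noiseless interior voxels equal the lesion intensity exactly
  expect_true(all(ph$volume$intensities[m] == 60))
  expect_true(all(ph$volume$intensities[!m] == -50))
  # anisotropic spacing scales the mask extent per axis
  ph2 <- generate_phantom_case(
    grid_shape = c(10L, 40L, 40L), spacing = c(5, 1, 1),
    lesion_spec = list(list(center = c(20, 20, 20), radii = c(10, 6, 6),
                            intensity = 80)),
    noise_sd = 0)
  sl_extent <- range(which(apply(ph2$masks[[1L]]$mask, 1L, any)))
  expect_equal(sl_extent, c(3L, 7L))  # 20 +/- 10 mm at 5 mm slices
})

test_that("two disjoint phantom lesions yield disjoint masks", {
  ph <- generate_phantom_case(
    grid_shape = c(12L, 50L, 50L), spacing = c(2, 1, 1),
    lesion_spec = list(
      list(center = c(10, 12, 12), radii = c(4, 4, 4), intensity = 70,
           kind = "tumor"),
      list(center = c(12, 35, 35), radii = c(5, 5, 5), intensity = 55)),
    noise_sd = 0)
  expect_length(ph$masks, 2L)
  expect_identical(ph$masks[[1L]]$kind, "tumor")
  expect_identical(ph$masks[[2L]]$kind, "lymph_node")
  expect_false(any(ph$masks[[1L]]$mask & ph$masks[[2L]]$mask))
})

test_that("a lesion extending outside the grid is rejected", {
  expect_error(generate_phantom_case(
    grid_shape = c(10L, 20L, 20L), spacing = c(1, 1, 1),
    lesion_spec = list(list(center = c(5, 2, 10), radii = c(3, 3, 3),
                            intensity = 60))),
    "outside the grid")
})

test_that("survival generator reproduces its own hazard ratios", {
  cohort <- generate_cohort(cohort_config(n_patients = 4000L, seed = 31L))
  rec <- survival_records(cohort)
  # adjuvant therapy hazard in truly node-positive patients: log HR ~ log 0.45
  pos <- rec[rec$lnm_label == 1L, ]
  fit_pos <- cox_fit(pos, "poat")
  expect_lt(abs(fit_pos$coef - log(0.45)), 3 * fit_pos$se)
  # no treatment effect among truly node-negative patients
  neg <- rec[rec$lnm_label == 0L, ]
  fit_neg <- cox_fit(neg, "poat")
  expect_lt(abs(fit_neg$z), 3)
  # node positivity is prognostic among untreated patients (true HR 1.8)
  unt <- rec[rec$poat == 0L, ]
  fit_lnm <- cox_fit(unt, "lnm_label")
  expect_lt(abs(fit_lnm$coef - log(1.8)), 3 * fit_lnm$se)
})

test_that("a cohort round-trips through the plain-text writer", {
  cohort <- generate_cohort(cohort_config(n_patients = 12L, seed = 8L))
  dir <- tempfile("cohort")
  write_cohort(cohort, dir)
  clin <- read.csv(file.path(dir, "clinical.csv"))
  expect_identical(nrow(clin), 12L)
  expect_identical(clin$lnm_label, cohort_labels(cohort))
  nodes <- read.csv(file.path(dir, "node_features.csv"))
  expect_identical(nrow(nodes), sum(vapply(cohort, function(p)
    nrow(p$node_features), integer(1L))))
  expect_equal(nodes$nf01[nodes$patient_id == "P0003"],
               unname(cohort[[3L]]$node_features[, 1L]))
  unlink(dir, recursive = TRUE)
})
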