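# Synthetic cohorts, repeated-delineation tables, and CT phantoms.
#
# The generator emulates the statistical structure the pipeline assumes:
# each patient is a bag of lymph-node feature vectors whose label is the OR
# of latent per-node metastatic states; tumor features and clinical
# covariates carry a weaker association with the bag label; survival times
# follow a proportional-hazards model in which adjuvant therapy helps only
# truly node-positive patients.

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the study conditions the pipeline targets: prevalence of
#' node-positive patients 0.62, about 8.7 visible nodes per patient
#' (1 + Poisson(7.7)), and roughly 30% of nodes metastatic within a positive
#' bag.
#'
#' @param n_patients number of patients to simulate.
#' @param prevalence probability that a patient is node-positive.
#' @param node_count_rate Poisson rate for nodes beyond the mandatory first.
#' @param witness_rate expected fraction of metastatic nodes in a positive
#'   bag; the realized count is a zero-truncated binomial so every positive
#'   bag holds at least one witness.
#' @param instance_dim dimension of the per-node (and tumor) "radiomic"
#'   feature view.
#' @param deep_dim dimension of the per-node (and tumor) "deep" feature view,
#'   a fixed seeded nonlinear projection of the radiomic view plus noise.
#' @param n_informative number of features carrying the metastatic signal.
#' @param effect_size mean shift applied to informative features of
#'   metastatic nodes.
#' @param tumor_effect_size weaker mean shift applied to informative tumor
#'   features of node-positive patients.
#' @param clinical_marginals category probabilities for age/sex/site/T stage
#'   and tumor-length distribution; see [default_clinical_marginals()].
#' @param clinical_assoc logistic-scale tilt coefficients linking covariates
#'   to the label (mild by default so the clinical model is learnable but
#'   weaker than the node-level models).
#' @param survival list of survival-generator settings: Weibull `shape` and
#'   `scale` (months), `hr_positive` (hazard ratio of true node-positive
#'   status), `poat_hr` (treatment hazard multiplier applied only to truly
#'   node-positive patients), `poat_rate` (probability of receiving adjuvant
#'   therapy), `censor_max` (administrative censoring drawn uniform on
#'   (0, censor_max) months). `NULL` disables survival records.
#' @param seed integer seed; the cohort is byte-identical for a fixed
#'   config + seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 300L,
                          prevalence = 0.62,
                          node_count_rate = 7.7,
                          witness_rate = 0.3,
                          instance_dim = 32L,
                          deep_dim = 64L,
                          n_informative = 8L,
                          effect_size = 1.5,
                          tumor_effect_size = 0.8,
                          clinical_marginals = default_clinical_marginals(),
                          clinical_assoc = default_clinical_assoc(),
                          survival = default_survival_config(),
                          seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop("`n_patients` must be a positive integer", call. = FALSE)
  }
  check_prob(prevalence, "prevalence")
  if (node_count_rate <= 0) stop("`node_count_rate` must be > 0", call. = FALSE)
  if (witness_rate <= 0 || witness_rate > 1) {
    stop("`witness_rate` must lie in (0, 1]", call. = FALSE)
  }
  if (instance_dim < n_informative) {
    stop("`instance_dim` must be >= `n_informative`", call. = FALSE)
  }
  cfg <- list(
    n_patients = as.integer(n_patients), prevalence = prevalence,
    node_count_rate = node_count_rate, witness_rate = witness_rate,
    instance_dim = as.integer(instance_dim), deep_dim = as.integer(deep_dim),
    n_informative = as.integer(n_informative), effect_size = effect_size,
    tumor_effect_size = tumor_effect_size,
    clinical_marginals = clinical_marginals, clinical_assoc = clinical_assoc,
    survival = survival, seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  cfg
}

#' Default clinical covariate marginals
#'
#' Marginal distributions of age group, sex, primary tumor site, T stage and
#' tumor length typical of an oesophageal squamous-cell carcinoma cohort.
#' @return named list of category probabilities and length parameters.
#' @export
default_clinical_marginals <- function() {
  list(
    age_ge65 = 0.3563,
    male = 0.8378,
    site = c(upper = 0.2526, middle = 0.5595, lower = 0.1879),
    t_stage = c(0.0770, 0.1889, 0.6324, 0.1016),
    length_mean = 4.19, length_sd = 1.84
  )
}

#' @rdname default_clinical_marginals
#' @export
default_clinical_assoc <- function() {
  list(age_ge65 = 0.6, male = 0.3, site = c(0, 0.4, 0.7),
       t_stage = 0.8, length = 0.7)
}

#' @rdname default_clinical_marginals
#' @export
default_survival_config <- function() {
  list(shape = 1.2, scale = 60, hr_positive = 1.8, poat_hr = 0.45,
       poat_rate = 0.5, censor_max = 150)
}

# Tilt a category probability vector on the logit scale by y-dependent
# coefficients, keeping the marginal mild.
tilt_probs <- function(p, coefs, y, prevalence) {
  w <- p * exp(coefs * (y - prevalence))
  w / sum(w)
}

#' Generate a synthetic patient cohort
#'
#' @param config a [cohort_config()].
#' @return a list of patient records (class `nodebag_cohort`). Each record
#'   holds node feature matrices (radiomic and deep view), per-node latent
#'   metastatic labels and sizes, tumor feature vectors, clinical covariates,
#'   the bag-level metastasis label, and an optional survival record.
#'   The bag label always equals the OR of the latent node labels.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cm <- config$clinical_marginals
  ca <- config$clinical_assoc
  d <- config$instance_dim
  k <- config$n_informative
  # fixed projection defining the "deep" view, derived from the config seed
  proj <- with_seed(derive_seed(config$seed, "deepview"), {
    matrix(rnorm(d * config$deep_dim, sd = 1 / sqrt(d)), d, config$deep_dim)
  })
  with_seed(config$seed, {
    lapply(seq_len(config$n_patients), function(i) {
      y <- rbinom(1L, 1L, config$prevalence)
      n_nodes <- 1L + rpois(1L, config$node_count_rate)
      latent <- integer(n_nodes)
      if (y == 1L) {
        # zero-truncated binomial witness count
        repeat {
          m <- rbinom(1L, n_nodes, config$witness_rate)
          if (m >= 1L) break
        }
        latent[sample.int(n_nodes, m)] <- 1L
      }
      x <- matrix(rnorm(n_nodes * d), n_nodes, d)
      x[latent == 1L, seq_len(k)] <- x[latent == 1L, seq_len(k)] + config$effect_size
      colnames(x) <- sprintf("nf%02d", seq_len(d))
      xd <- tanh(x %*% proj) + matrix(rnorm(n_nodes * config$deep_dim, sd = 0.5),
                                      n_nodes, config$deep_dim)
      colnames(xd) <- sprintf("df%02d", seq_len(config$deep_dim))
      sizes <- exp(rnorm(n_nodes, mean = log(6) + 0.45 * latent, sd = 0.35))
      tf <- rnorm(d)
      if (y == 1L) tf[seq_len(k)] <- tf[seq_len(k)] + config$tumor_effect_size
      names(tf) <- sprintf("tf%02d", seq_len(d))
      tfd <- as.numeric(tanh(matrix(tf, 1L) %*% proj)) +
        rnorm(config$deep_dim, sd = 0.5)
      names(tfd) <- sprintf("td%02d", seq_len(config$deep_dim))
      clin <- list(
        age_ge65 = rbinom(1L, 1L, tilt_probs(
          c(1 - cm$age_ge65, cm$age_ge65), c(0, ca$age_ge65), y,
          config$prevalence)[2L]),
        male = rbinom(1L, 1L, tilt_probs(
          c(1 - cm$male, cm$male), c(0, ca$male), y, config$prevalence)[2L]),
        site = names(cm$site)[sample.int(3L, 1L, prob = tilt_probs(
          cm$site, ca$site, y, config$prevalence))],
        t_stage = sample.int(4L, 1L, prob = tilt_probs(
          cm$t_stage, ca$t_stage * (1:4 - 2.5) / 1.5, y, config$prevalence)),
        tumor_length = max(0.5, rnorm(
          1L, cm$length_mean + ca$length * (y - config$prevalence) * cm$length_sd,
          cm$length_sd))
      )
      surv <- NULL
      if (!is.null(config$survival)) {
        sv <- config$survival
        poat <- rbinom(1L, 1L, sv$poat_rate)
        lp <- log(sv$hr_positive) * y + log(sv$poat_hr) * poat * y
        t_event <- sv$scale * (-log(runif(1L)) / exp(lp))^(1 / sv$shape)
        c_admin <- runif(1L, 0, sv$censor_max)
        surv <- list(time = max(min(t_event, c_admin), 1e-3),
                     event = as.integer(t_event <= c_admin),
                     poat = poat)
      }
      rec <- list(
        patient_id = sprintf("P%04d", i),
        node_features = x, node_deep_features = xd,
        node_sizes = sizes, node_latent_labels = latent,
        tumor_features = tf, tumor_deep_features = tfd,
        clinical = clin, lnm_label = as.integer(max(latent)),
        survival = surv
      )
      class(rec) <- "patient_record"
      rec
    }) -> cohort
    class(cohort) <- c("nodebag_cohort", "list")
    attr(cohort, "config") <- config
    cohort
  })
}

#' @export
print.nodebag_cohort <- function(x, ...) {
  labs <- vapply(x, function(p) p$lnm_label, integer(1L))
  nodes <- vapply(x, function(p) nrow(p$node_features), integer(1L))
  cat(sprintf("Synthetic cohort: %d patients, %.1f%% node-positive, mean %.2f nodes/patient\n",
              length(x), 100 * mean(labs), mean(nodes)))
  invisible(x)
}

#' Bag-level metastasis labels of a cohort
#'
#' @param cohort a `nodebag_cohort`.
#' @return integer vector of 0/1 labels, one per patient.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort, function(p) p$lnm_label, integer(1L))
}

#' Generate aligned repeated-measurement feature tables
#'
#' Produces two delineation replicates per subject with a shared subject
#' effect, noise-calibrated so each feature's population intraclass
#' correlation equals its target: replicate = subject_effect * sqrt(r) +
#' noise * sqrt(1 - r).
#'
#' @param n_subjects number of subjects.
#' @param n_features number of features.
#' @param reliability per-feature target ICC in `[0, 1)`; recycled.
#' @param seed integer seed.
#' @return list with matrices `rep1` and `rep2` (subjects x features).
#' @export
generate_repeat_measurements <- function(n_subjects, n_features, reliability,
                                         seed = 1L) {
  if (any(reliability < 0) || any(reliability >= 1)) {
    stop("`reliability` values must lie in [0, 1)", call. = FALSE)
  }
  r <- rep_len(reliability, n_features)
  with_seed(seed, {
    subj <- matrix(rnorm(n_subjects * n_features), n_subjects, n_features)
    e1 <- matrix(rnorm(n_subjects * n_features), n_subjects, n_features)
    e2 <- matrix(rnorm(n_subjects * n_features), n_subjects, n_features)
    sr <- sqrt(matrix(r, n_subjects, n_features, byrow = TRUE))
    sn <- sqrt(1 - sr^2)
    nm <- sprintf("f%03d", seq_len(n_features))
    rep1 <- subj * sr + e1 * sn
    rep2 <- subj * sr + e2 * sn
    colnames(rep1) <- colnames(rep2) <- nm
    list(rep1 = rep1, rep2 = rep2)
  })
}

#' Generate a phantom CT case with ellipsoidal lesions
#'
#' @param grid_shape integer vector (n_slices, n_rows, n_cols).
#' @param spacing physical voxel size in mm, same axis order as `grid_shape`.
#' @param lesion_spec list of lesions, each a list with `center` (mm,
#'   physical coordinates), `radii` (mm semi-axes), `intensity` (HU), and
#'   `kind` ("tumor" or "lymph_node").
#' @param noise_sd standard deviation of additive Gaussian noise (HU).
#' @param background background intensity in HU.
#' @param seed integer seed for the noise.
#' @return list with an [image_volume()] and a list of [roi_mask()]s, one per
#'   lesion; masks are the exact ellipsoid indicator sets.
#' @export
generate_phantom_case <- function(grid_shape, spacing, lesion_spec,
                                  noise_sd = 0, background = -50, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, length(spacing) == 3L)
  extent <- (grid_shape - 1L) * spacing
  coords <- lapply(1:3, function(a) (seq_len(grid_shape[a]) - 1L) * spacing[a])
  vol <- array(background, dim = grid_shape)
  masks <- vector("list", length(lesion_spec))
  for (li in seq_along(lesion_spec)) {
    ls <- lesion_spec[[li]]
    if (any(ls$center - ls$radii < 0) || any(ls$center + ls$radii > extent)) {
      stop("lesion extends outside the grid", call. = FALSE)
    }
    d1 <- ((coords[[1L]] - ls$center[1L]) / ls$radii[1L])^2
    d2 <- ((coords[[2L]] - ls$center[2L]) / ls$radii[2L])^2
    d3 <- ((coords[[3L]] - ls$center[3L]) / ls$radii[3L])^2
    inside <- outer(outer(d1, d2, `+`), d3, `+`) <= 1
    vol[inside] <- ls$intensity
    masks[[li]] <- roi_mask(inside, kind = if (is.null(ls$kind)) "lymph_node" else ls$kind)
  }
  if (noise_sd > 0) {
    vol <- vol + with_seed(seed, array(rnorm(length(vol), sd = noise_sd),
                                       dim = grid_shape))
  }
  list(volume = image_volume(vol, spacing), masks = masks)
}

#' Write / read a synthetic cohort as plain-text tables
#'
#' Writes one CSV of clinical covariates + label + survival and one
#' long-format CSV per feature view (`patient_id`, `node_index`, features).
#' @param cohort a `nodebag_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  clin <- do.call(rbind, lapply(cohort, function(p) {
    sv <- p$survival
    data.frame(patient_id = p$patient_id,
               age_ge65 = p$clinical$age_ge65, male = p$clinical$male,
               site = p$clinical$site, t_stage = p$clinical$t_stage,
               tumor_length = p$clinical$tumor_length,
               lnm_label = p$lnm_label,
               time = if (is.null(sv)) NA_real_ else sv$time,
               event = if (is.null(sv)) NA_integer_ else sv$event,
               poat = if (is.null(sv)) NA_integer_ else sv$poat)
  }))
  write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  long <- do.call(rbind, lapply(cohort, function(p) {
    data.frame(patient_id = p$patient_id,
               node_index = seq_len(nrow(p$node_features)),
               latent_label = p$node_latent_labels,
               size = p$node_sizes, p$node_features)
  }))
  write.csv(long, file.path(dir, "node_features.csv"), row.names = FALSE)
  tum <- do.call(rbind, lapply(cohort, function(p) {
    data.frame(patient_id = p$patient_id, t(p$tumor_features))
  }))
  write.csv(tum, file.path(dir, "tumor_features.csv"), row.names = FALSE)
  invisible(dir)
}
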