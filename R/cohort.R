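#' Specification of a synthetic patient/control cohort
#'
#' Defines the statistical structure of a simulated cohort: a patient (ID)
#' group carrying planted subtypes with correlated gray-matter reductions and
#' elevated clinical scores, plus a matched healthy-control (HC) reference
#' group. Defaults reproduce the canonical study conditions: 140 patients in
#' two subtypes of 90 and 50, 57 controls, 166 atlas regions, and
#' subtype-specific PSQI/SAS/SDS profiles.
#'
#' Each ID subject carries a latent severity scalar that drives both the
#' gray-matter reduction on that subtype's affected regions and the elevation
#' of the clinical scores, so imaging and clinical differences are coupled
#' within subtype. Regional volumes additionally load on age and total
#' intracranial volume (TIV) so that covariate control in downstream partial
#' correlations is meaningful, and residuals share block-wise correlation to
#' mimic structural covariance.
#'
#' @param n_id Number of patients (default 140).
#' @param n_hc Number of healthy controls (default 57).
#' @param n_roi Number of atlas regions (default 166).
#' @param n_skeleton Number of skeleton-channel features (default 500).
#' @param subtype_fractions Proportions of ID subjects per planted subtype,
#'   summing to 1 (default `c(90, 50) / 140`).
#' @param effect_size Standardized mean gray-matter reduction applied to each
#'   subtype's affected region set (default 1.5).
#' @param affected_roi_fraction Fraction of regions shifted per subtype
#'   (default 0.2).
#' @param clinical_means,clinical_sds K x 3 matrices of per-subtype
#'   (PSQI, SAS, SDS) means and standard deviations.
#' @param hc_clinical_means,hc_clinical_sds Length-3 vectors for the HC group.
#' @param severity_coupling Correlation between the latent severity scalar and
#'   each clinical score within subtype, in `[0, 1)` (default 0.6).
#' @param severity_sd Dispersion of the latent severity scalar around 1
#'   (default 0.3); larger values elongate each subtype along its shift
#'   direction.
#' @param age_mean,age_sd,age_range Per-group age models (named lists with
#'   `id` and `hc` entries); ages are drawn normal and clipped to range.
#' @param p_male Named list with per-group probability of male sex.
#' @param tiv_mean,tiv_sd TIV model in ml.
#' @param noise_cv Coefficient of variation of regional residual noise
#'   (default 0.1): each region's residual SD is `noise_cv` times its mean.
#' @param beta_age,beta_tiv Standardized loadings of age and TIV on every
#'   regional volume.
#' @param n_blocks,block_cor Residual covariance blocks: regions are split into
#'   `n_blocks` contiguous blocks with within-block residual correlation
#'   `block_cor`.
#' @param skeleton_noise_sd Independent noise added to the skeleton channel, in
#'   units of each skeleton feature's projected SD.
#' @param skeleton_projection `"random"` (fixed seeded random nonnegative
#'   projection of the ROI channel) or `"identity"` (skeleton equals the first
#'   `n_skeleton` ROI columns; requires `n_skeleton <= n_roi`).
#' @param seed Integer seed fixing every random draw.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_id = 140L, n_hc = 57L, n_roi = 166L,
                        n_skeleton = 500L,
                        subtype_fractions = c(90, 50) / 140,
                        effect_size = 1.5,
                        affected_roi_fraction = 0.2,
                        clinical_means = rbind(c(13.80, 53.18, 53.72),
                                               c(12.10, 42.16, 44.37)),
                        clinical_sds = rbind(c(2.32, 7.07, 8.22),
                                             c(3.07, 12.13, 13.57)),
                        hc_clinical_means = c(3.56, 38.12, 33.72),
                        hc_clinical_sds = c(1.51, 10.10, 7.31),
                        severity_coupling = 0.6,
                        severity_sd = 0.3,
                        age_mean = list(id = 36.69, hc = 34.75),
                        age_sd = list(id = 11.51, hc = 8.32),
                        age_range = list(id = c(18, 60), hc = c(21, 56)),
                        p_male = list(id = 65 / 140, hc = 36 / 57),
                        tiv_mean = 1450, tiv_sd = 120,
                        noise_cv = 0.1,
                        beta_age = -0.2, beta_tiv = 0.25,
                        n_blocks = 12L, block_cor = 0.3,
                        skeleton_noise_sd = 0.2,
                        skeleton_projection = c("random", "identity"),
                        seed = 1L) {
  skeleton_projection <- match.arg(skeleton_projection)
  spec <- list(
    n_id = as.integer(n_id), n_hc = as.integer(n_hc),
    n_roi = as.integer(n_roi), n_skeleton = as.integer(n_skeleton),
    subtype_fractions = subtype_fractions,
    effect_size = effect_size,
    affected_roi_fraction = affected_roi_fraction,
    clinical_means = as.matrix(clinical_means),
    clinical_sds = as.matrix(clinical_sds),
    hc_clinical_means = hc_clinical_means,
    hc_clinical_sds = hc_clinical_sds,
    severity_coupling = severity_coupling,
    severity_sd = severity_sd,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    p_male = p_male, tiv_mean = tiv_mean, tiv_sd = tiv_sd,
    noise_cv = noise_cv, beta_age = beta_age, beta_tiv = beta_tiv,
    n_blocks = as.integer(n_blocks), block_cor = block_cor,
    skeleton_noise_sd = skeleton_noise_sd,
    skeleton_projection = skeleton_projection,
    seed = as.integer(seed)
  )
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  if (abs(sum(spec$subtype_fractions) - 1) > 1e-12) {
    stop("subtype_fractions must sum to 1 (got ",
         format(sum(spec$subtype_fractions), digits = 15), ")")
  }
  if (any(spec$subtype_fractions < 0)) stop("subtype_fractions must be >= 0")
  if (spec$n_roi < 2L) stop("n_roi must be >= 2")
  if (spec$effect_size < 0) stop("effect_size must be >= 0")
  counts <- c(spec$n_id, spec$n_hc, spec$n_roi, spec$n_skeleton)
  if (any(counts <= 0L)) stop("all cohort counts must be positive")
  k <- length(spec$subtype_fractions)
  if (nrow(spec$clinical_means) < k || nrow(spec$clinical_sds) < k) {
    stop("clinical_means/clinical_sds must have one row per subtype")
  }
  if (spec$severity_coupling < 0 || spec$severity_coupling >= 1) {
    stop("severity_coupling must lie in [0, 1)")
  }
  if (spec$skeleton_projection == "identity" &&
      spec$n_skeleton > spec$n_roi) {
    stop("identity skeleton projection requires n_skeleton <= n_roi")
  }
  invisible(spec)
}

# Deterministic subtype counts honouring the fractions exactly where possible
subtype_counts <- function(n, fractions) {
  cum <- round(cumsum(fractions) * n)
  counts <- diff(c(0L, cum))
  counts[length(counts)] <- n - sum(counts[-length(counts)])
  as.integer(counts)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic cohort with planted subtypes
#'
#' Draws a full cohort table from a [cohort_spec()]: regional gray-matter
#' volumes (positive, mm^3-scaled), a skeleton feature channel, clinical
#' scales (PSQI 0-21, SAS/SDS 25-100) and covariates (age, sex, TIV), with ID
#' subjects carrying a recorded ground-truth subtype. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param skeleton Whether to also derive the skeleton channel (default TRUE).
#' @return An object of class `subject_cohort`: a list with `features`
#'   (subjects x n_roi matrix, columns named by [atlas_labels()]), `skeleton`
#'   (subjects x n_skeleton matrix or NULL), `pheno` (data.frame with
#'   subject_id, group, true_subtype, psqi, sas, sds, age, sex, tiv) and the
#'   generating `spec`. The latent severity scalars are kept in
#'   `attr(cohort, "severity")`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_id = 20, n_hc = 10, n_roi = 12,
#'                                       n_skeleton = 15, seed = 7))
#' table(cohort$pheno$group)
generate_cohort <- function(spec, skeleton = TRUE) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_id + spec$n_hc
  k <- length(spec$subtype_fractions)

  # regional scale: mm^3-level means with proportional residual SD
  mu_r <- stats::runif(spec$n_roi, 2000, 12000)
  sigma_r <- spec$noise_cv * mu_r

  group <- c(rep("ID", spec$n_id), rep("HC", spec$n_hc))
  counts <- subtype_counts(spec$n_id, spec$subtype_fractions)
  true_subtype <- c(rep(seq_len(k), counts), rep(NA_integer_, spec$n_hc))

  grp <- ifelse(group == "ID", "id", "hc")
  age <- stats::rnorm(n, unlist(spec$age_mean[grp]), unlist(spec$age_sd[grp]))
  lo <- vapply(spec$age_range[grp], `[`, numeric(1), 1L)
  hi <- vapply(spec$age_range[grp], `[`, numeric(1), 2L)
  age <- clip(age, lo, hi)
  sex <- ifelse(stats::rbinom(n, 1L, unlist(spec$p_male[grp])) == 1L, "M", "F")
  tiv <- stats::rnorm(n, spec$tiv_mean, spec$tiv_sd)

  z_age <- (age - mean(age)) / stats::sd(age)
  z_tiv <- (tiv - mean(tiv)) / stats::sd(tiv)

  # block-correlated residuals: shared block factor + idiosyncratic noise
  block <- sort(rep(seq_len(spec$n_blocks), length.out = spec$n_roi))
  bfac <- matrix(stats::rnorm(n * spec$n_blocks), n, spec$n_blocks)
  eps <- sqrt(spec$block_cor) * bfac[, block, drop = FALSE] +
    sqrt(1 - spec$block_cor) * matrix(stats::rnorm(n * spec$n_roi), n)

  x <- matrix(mu_r, n, spec$n_roi, byrow = TRUE) +
    outer(spec$beta_age * z_age + spec$beta_tiv * z_tiv, sigma_r) +
    sweep(eps, 2L, sigma_r, `*`)

  # planted subtype shifts, scaled by a per-subject latent severity
  severity <- rep(NA_real_, n)
  severity[group == "ID"] <- pmax(stats::rnorm(spec$n_id, 1, spec$severity_sd), 0.1)
  n_aff <- max(1L, round(spec$affected_roi_fraction * spec$n_roi))
  affected <- lapply(seq_len(k), function(i) sample.int(spec$n_roi, n_aff))
  for (i in which(group == "ID")) {
    rois <- affected[[true_subtype[i]]]
    x[i, rois] <- x[i, rois] -
      spec$effect_size * severity[i] * sigma_r[rois]
  }
  x <- pmax(x, 1)  # volumes strictly positive

  # clinical scores: subtype mean + severity-coupled deviation
  rho <- spec$severity_coupling
  sz <- (severity - 1) / max(spec$severity_sd, 1e-8)
  clin <- matrix(NA_real_, n, 3L,
                 dimnames = list(NULL, c("psqi", "sas", "sds")))
  for (d in 1:3) {
    noise <- stats::rnorm(n)
    for (i in seq_len(n)) {
      if (group[i] == "ID") {
        st <- true_subtype[i]
        clin[i, d] <- spec$clinical_means[st, d] + spec$clinical_sds[st, d] *
          (rho * sz[i] + sqrt(1 - rho^2) * noise[i])
      } else {
        clin[i, d] <- spec$hc_clinical_means[d] +
          spec$hc_clinical_sds[d] * noise[i]
      }
    }
  }
  clin[, "psqi"] <- round(clip(clin[, "psqi"], 0, 21))
  clin[, "sas"] <- clip(clin[, "sas"], 25, 100)
  clin[, "sds"] <- clip(clin[, "sds"], 25, 100)

  ids <- c(sprintf("ID_%03d", seq_len(spec$n_id)),
           sprintf("HC_%03d", seq_len(spec$n_hc)))
  labels <- atlas_labels(spec$n_roi)
  dimnames(x) <- list(ids, labels)
  pheno <- data.frame(
    subject_id = ids, group = group, true_subtype = true_subtype,
    psqi = clin[, "psqi"], sas = clin[, "sas"], sds = clin[, "sds"],
    age = age, sex = sex, tiv = tiv, stringsAsFactors = FALSE
  )
  cohort <- structure(
    list(features = x, skeleton = NULL, pheno = pheno, spec = spec),
    class = "subject_cohort", severity = severity,
    affected_rois = affected
  )
  if (skeleton) cohort <- derive_skeleton_channel(cohort, spec)
  cohort
}

#' Derive the synthetic skeleton feature channel
#'
#' Produces a second feature channel that is correlated with, but not
#' identical to, the ROI channel: a fixed seeded nonnegative random projection
#' of each subject's regional volumes plus independent noise. This stands in
#' for skeletonized gray-matter values sampled on the core of the cortical
#' mantle; any user-supplied per-subject skeleton vector can be used instead.
#'
#' @param cohort A `subject_cohort` with `features` present.
#' @param spec The generating [cohort_spec()] (defaults to `cohort$spec`);
#'   `spec$seed` fixes the projection matrix.
#' @return The cohort with `$skeleton` filled (subjects x n_skeleton).
#' @export
derive_skeleton_channel <- function(cohort, spec = cohort$spec) {
  stopifnot(inherits(cohort, "subject_cohort"), !is.null(cohort$features))
  set.seed(spec$seed + 1L)
  x <- cohort$features
  if (spec$skeleton_projection == "identity") {
    proj <- diag(spec$n_roi)[seq_len(spec$n_skeleton), , drop = FALSE]
  } else {
    proj <- matrix(stats::runif(spec$n_skeleton * spec$n_roi),
                   spec$n_skeleton, spec$n_roi)
    proj <- proj / rowSums(proj)  # each skeleton feature: weighted ROI mean
  }
  skel <- x %*% t(proj)
  if (spec$skeleton_noise_sd > 0) {
    csd <- apply(skel, 2L, stats::sd)
    csd[csd == 0] <- 1
    skel <- skel + matrix(stats::rnorm(length(skel)), nrow(skel)) *
      rep(spec$skeleton_noise_sd * csd, each = nrow(skel))
  }
  dimnames(skel) <- list(rownames(x),
                         sprintf("SK_%04d", seq_len(spec$n_skeleton)))
  cohort$skeleton <- skel
  cohort
}

#' Inject strong edge-level perturbations into selected subjects
#'
#' Engineering helper for validating the individualized differential network
#' pipeline: for a chosen set of disjoint ROI pairs and a chosen set of ID
#' subjects, the two regions of each pair are pushed in opposite directions by
#' `magnitude` residual SDs around the cohort mean, so that adding any chosen
#' subject to the reference group visibly perturbs the correlation on exactly
#' those edges.
#'
#' @param cohort A `subject_cohort`.
#' @param n_edges Number of disjoint ROI-pair edges to perturb.
#' @param n_subjects Number of ID subjects receiving the perturbation.
#' @param magnitude Shift in units of each region's cohort SD (default 6).
#' @param seed Integer seed for edge/subject selection.
#' @return The modified cohort, with the planted edges as an attribute
#'   `"perturbed_edges"` (two-column matrix of ROI indices) and the subject
#'   ids as `"perturbed_subjects"`.
#' @export
inject_edge_perturbations <- function(cohort, n_edges = 30L,
                                      n_subjects = 40L, magnitude = 6,
                                      seed = 1L) {
  stopifnot(inherits(cohort, "subject_cohort"))
  n_roi <- ncol(cohort$features)
  if (2L * n_edges > n_roi) stop("not enough ROIs for disjoint edges")
  set.seed(seed)
  rois <- sample.int(n_roi, 2L * n_edges)
  edges <- cbind(rois[seq_len(n_edges)], rois[n_edges + seq_len(n_edges)])
  edges <- t(apply(edges, 1L, sort))
  id_rows <- which(cohort$pheno$group == "ID")
  if (n_subjects > length(id_rows)) stop("not enough ID subjects")
  subjects <- sort(sample(id_rows, n_subjects))
  mu <- colMeans(cohort$features)
  sdv <- apply(cohort$features, 2L, stats::sd)
  for (e in seq_len(n_edges)) {
    a <- edges[e, 1L]; b <- edges[e, 2L]
    cohort$features[subjects, a] <- mu[a] + magnitude * sdv[a]
    cohort$features[subjects, b] <- pmax(mu[b] - magnitude * sdv[b], 1)
  }
  attr(cohort, "perturbed_edges") <- edges
  attr(cohort, "perturbed_subjects") <- cohort$pheno$subject_id[subjects]
  cohort
}

#' @export
print.subject_cohort <- function(x, ...) {
  cat("subject_cohort:", nrow(x$features), "subjects x",
      ncol(x$features), "ROI features\n")
  cat("  groups:", paste(names(table(x$pheno$group)),
                         table(x$pheno$group), collapse = ", "), "\n")
  if (!is.null(x$skeleton)) {
    cat("  skeleton channel:", ncol(x$skeleton), "features\n")
  }
  if (any(!is.na(x$pheno$true_subtype))) {
    cat("  planted subtypes:",
        paste(table(x$pheno$true_subtype), collapse = "/"), "\n")
  }
  invisible(x)
}
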