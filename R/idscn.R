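#' Partial correlation matrix with covariate control
#'
#' Residualizes every feature column on the covariates (plus an intercept)
#' and returns the Pearson correlation matrix of the residuals. With no
#' covariates this reduces to the plain correlation matrix.
#'
#' @param features S x R matrix (subjects in rows).
#' @param covariates S x P numeric matrix, or NULL.
#' @return Symmetric R x R matrix with unit diagonal.
#' @export
partial_correlation_matrix <- function(features, covariates = NULL) {
  features <- as.matrix(features)
  s <- nrow(features)
  if (is.null(covariates) || length(covariates) == 0L) {
    if (s < 3L) stop("need at least 3 subjects")
    res <- features
  } else {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != s) stop("covariate row count differs")
    if (s <= ncol(covariates) + 2L) {
      stop("too few subjects for ", ncol(covariates), " covariates")
    }
    d <- cbind(1, covariates)
    qd <- qr(d)
    if (qd$rank < ncol(d)) stop("rank-deficient covariate matrix")
    res <- qr.resid(qd, features)
  }
  pcc <- stats::cor(res)
  pcc[is.na(pcc)] <- 0
  pcc <- (pcc + t(pcc)) / 2
  diag(pcc) <- 1
  pcc
}

# Numeric covariate columns used throughout: age, sex (F = 0, M = 1), TIV.
covariate_matrix <- function(pheno) {
  cbind(age = pheno$age,
        sex = as.numeric(pheno$sex == "M"),
        tiv = pheno$tiv)
}

#' Subset a cohort by group or row index
#'
#' @param cohort A `subject_cohort`.
#' @param group Group label(s) to keep (ignored when `rows` given).
#' @param rows Row indices to keep.
#' @return The restricted `subject_cohort`.
#' @export
subset_cohort <- function(cohort, group = NULL, rows = NULL) {
  stopifnot(inherits(cohort, "subject_cohort"))
  if (is.null(rows)) {
    if (is.null(group)) stop("give either group or rows")
    rows <- which(cohort$pheno$group %in% group)
  }
  cohort$features <- cohort$features[rows, , drop = FALSE]
  if (!is.null(cohort$skeleton)) {
    cohort$skeleton <- cohort$skeleton[rows, , drop = FALSE]
  }
  cohort$pheno <- cohort$pheno[rows, , drop = FALSE]
  attr(cohort, "severity") <- attr(cohort, "severity")[rows]
  cohort
}

#' Healthy-reference structural covariance network
#'
#' Partial correlation of regional gray-matter volumes across all region
#' pairs over the healthy-control group, controlling for age, sex and TIV.
#'
#' @param hc_cohort A `subject_cohort` containing HC subjects only.
#' @param covariates Covariate column names drawn from the pheno table
#'   (default age, sex, TIV); set to `NULL` for no control.
#' @return A `reference_network`: `pcc` (R x R), `n_hc`, `covariates`,
#'   `roi_labels`, plus the HC features/covariate matrix needed for
#'   leave-one-in perturbation.
#' @export
build_reference <- function(hc_cohort,
                            covariates = c("age", "sex", "tiv")) {
  stopifnot(inherits(hc_cohort, "subject_cohort"))
  if (any(hc_cohort$pheno$group != "HC")) {
    stop("reference network must be built from HC subjects only")
  }
  n_hc <- nrow(hc_cohort$features)
  if (n_hc <= 5L) stop("need more than 5 HC subjects")
  cov_mat <- if (is.null(covariates)) NULL else {
    covariate_matrix(hc_cohort$pheno)[,
      match(covariates, c("age", "sex", "tiv")), drop = FALSE]
  }
  pcc <- partial_correlation_matrix(hc_cohort$features, cov_mat)
  structure(list(pcc = pcc, n_hc = n_hc, covariates = covariates,
                 roi_labels = colnames(hc_cohort$features),
                 hc_features = hc_cohort$features,
                 hc_covariates = cov_mat),
            class = "reference_network")
}

#' Individualized differential structural covariance network of one subject
#'
#' Adds one subject to the reference group, recomputes the covariate-
#' controlled partial correlation network, and expresses the perturbation of
#' every edge as `delta = PCC_{n+1} - PCC_n` and a Z-score
#' `z = delta / ((1 - PCC_n^2) / (n - 1))` with `n` the reference sample
#' size; two-sided p-values come from the standard normal. Edges where the
#' reference correlation is exactly +/-1 are masked as undefined.
#'
#' @param ref A `reference_network`.
#' @param subject_features Length-R vector of the subject's regional volumes.
#' @param subject_covariates Covariate vector matching `ref$covariates`
#'   (or NULL when the reference was built without covariates).
#' @return A `subject_idscn`: `delta_pcc`, `z`, `p` (symmetric, zero/NA
#'   diagonal).
#' @export
idscn_for_subject <- function(ref, subject_features,
                              subject_covariates = NULL) {
  stopifnot(inherits(ref, "reference_network"))
  r <- ncol(ref$pcc)
  subject_features <- as.numeric(subject_features)
  if (length(subject_features) != r) stop("subject feature length != R")
  feats <- rbind(ref$hc_features, subject_features)
  covs <- NULL
  if (!is.null(ref$hc_covariates)) {
    if (is.null(subject_covariates)) stop("subject covariates required")
    covs <- rbind(ref$hc_covariates, as.numeric(subject_covariates))
  }
  pcc_aug <- partial_correlation_matrix(feats, covs)
  delta <- pcc_aug - ref$pcc
  denom <- (1 - ref$pcc^2) / (ref$n_hc - 1)
  undef <- abs(ref$pcc) >= 1 - 1e-15
  diag(undef) <- TRUE
  if (any(undef & !diag(r))) {
    warning("edges with |reference correlation| = 1 masked as undefined",
            call. = FALSE)
  }
  z <- delta / denom
  z[undef] <- NA_real_
  diag(z) <- 0
  diag(delta) <- 0
  p <- 2 * stats::pnorm(-abs(z))
  diag(p) <- NA_real_
  structure(list(delta_pcc = delta, z = z, p = p),
            class = "subject_idscn")
}

#' Individualized differential networks for every patient
#'
#' Builds the HC reference network and the leave-one-in differential network
#' of every ID subject of a cohort.
#'
#' @param cohort A `subject_cohort` with both groups present.
#' @param covariates Covariate names (default age, sex, TIV).
#' @return An `idscn_set`: `reference` and `subjects` (named list of
#'   `subject_idscn`).
#' @export
idscn_all <- function(cohort, covariates = c("age", "sex", "tiv")) {
  ref <- build_reference(subset_cohort(cohort, group = "HC"),
                         covariates = covariates)
  id_rows <- which(cohort$pheno$group == "ID")
  cov_all <- if (is.null(covariates)) NULL else {
    covariate_matrix(cohort$pheno)[,
      match(covariates, c("age", "sex", "tiv")), drop = FALSE]
  }
  subjects <- lapply(id_rows, function(i) {
    idscn_for_subject(ref, cohort$features[i, ],
                      if (is.null(cov_all)) NULL else cov_all[i, ])
  })
  names(subjects) <- cohort$pheno$subject_id[id_rows]
  structure(list(reference = ref, subjects = subjects),
            class = "idscn_set")
}

#' Significant edges of one individualized network
#'
#' Applies a multiple-comparison correction over the `R(R-1)/2` upper-
#' triangle edges of one subject's p-value matrix and returns the symmetric
#' binary significance matrix. Bonferroni thresholds at `alpha / m`; FDR uses
#' Benjamini-Hochberg.
#'
#' @param idscn A `subject_idscn` (or an R x R p-value matrix).
#' @param alpha Significance level (default 0.05).
#' @param method `"bonferroni"` or `"fdr"`.
#' @return Binary symmetric R x R matrix with zero diagonal.
#' @export
edge_significance <- function(idscn, alpha = 0.05,
                              method = c("bonferroni", "fdr")) {
  method <- match.arg(method)
  p <- if (inherits(idscn, "subject_idscn")) idscn$p else as.matrix(idscn)
  r <- nrow(p)
  ut <- upper.tri(p)
  pv <- p[ut]
  sig_ut <- rep(FALSE, length(pv))
  keep <- is.finite(pv)
  if (method == "bonferroni") {
    sig_ut[keep] <- pv[keep] <= alpha / sum(keep)
  } else {
    sig_ut[keep] <- stats::p.adjust(pv[keep], method = "BH") <= alpha
  }
  sig <- matrix(0, r, r, dimnames = dimnames(p))
  sig[ut] <- as.numeric(sig_ut)
  sig + t(sig)
}

#' Common significantly altered edges across patients
#'
#' Counts, for every edge, the patients whose individualized network flags
#' it as significantly altered, keeps edges altered in at least
#' `min_subjects` patients, ranks by count (ties by mean |z| descending,
#' then lexicographic region index) and truncates to the `top_k` strongest.
#'
#' @param idscns An `idscn_set` or list of `subject_idscn`.
#' @param min_subjects Minimum number of patients an edge must be altered in
#'   (default 33).
#' @param min_fraction Optional fractional alternative: when given,
#'   `min_subjects` is replaced by `ceiling(min_fraction * n_subjects)`.
#' @param top_k Retention cap (default 20).
#' @param alpha,method Passed to [edge_significance()].
#' @return An `edge_summary`: `edges` (data.frame i, j, roi_a, roi_b, count,
#'   mean_abs_z), `z_matrix` (subjects x retained edges), `counts` (R x R
#'   matrix of per-edge alteration counts).
#' @export
top_altered_edges <- function(idscns, min_subjects = 33L,
                              min_fraction = NULL, top_k = 20L,
                              alpha = 0.05,
                              method = c("bonferroni", "fdr")) {
  method <- match.arg(method)
  subjects <- if (inherits(idscns, "idscn_set")) idscns$subjects else idscns
  if (!length(subjects)) stop("need at least one subject")
  if (!is.null(min_fraction)) {
    min_subjects <- ceiling(min_fraction * length(subjects))
  }
  r <- nrow(subjects[[1L]]$z)
  labels <- colnames(subjects[[1L]]$z)
  if (is.null(labels)) labels <- sprintf("ROI_%03d", seq_len(r))
  counts <- matrix(0, r, r)
  zsum <- matrix(0, r, r)
  for (s in subjects) {
    counts <- counts + edge_significance(s, alpha = alpha, method = method)
    zsum <- zsum + abs(ifelse(is.finite(s$z), s$z, 0))
  }
  ut <- which(upper.tri(counts), arr.ind = TRUE)
  cand <- data.frame(i = ut[, 1L], j = ut[, 2L],
                     count = counts[ut],
                     mean_abs_z = zsum[ut] / length(subjects))
  cand <- cand[cand$count >= min_subjects, , drop = FALSE]
  cand <- cand[order(-cand$count, -cand$mean_abs_z, cand$i, cand$j), ,
               drop = FALSE]
  cand <- utils::head(cand, top_k)
  z_matrix <- matrix(NA_real_, length(subjects), nrow(cand),
                     dimnames = list(names(subjects),
                                     paste(labels[cand$i], labels[cand$j],
                                           sep = "--")))
  for (s in seq_along(subjects)) {
    z_matrix[s, ] <- subjects[[s]]$z[cbind(cand$i, cand$j)]
  }
  cand$roi_a <- labels[cand$i]
  cand$roi_b <- labels[cand$j]
  rownames(cand) <- NULL
  structure(list(edges = cand[, c("i", "j", "roi_a", "roi_b", "count",
                                  "mean_abs_z")],
                 z_matrix = z_matrix, counts = counts,
                 min_subjects = min_subjects, top_k = top_k,
                 alpha = alpha, method = method),
            class = "edge_summary")
}

#' K-means clustering on individualized-network edge Z-scores
#'
#' Clusters patients on the Z-scores of the retained common edges and, when
#' reference labels are given, reports the cross-tabulation and adjusted
#' Rand index against them.
#'
#' @param edge_summary An `edge_summary` with a non-empty edge set.
#' @param c Number of clusters (default 2).
#' @param restarts K-means restarts. @param seed Integer seed.
#' @param reference_labels Optional labels (named by subject id) to compare
#'   against.
#' @return List with `labels`, and when reference labels are supplied
#'   `crosstab` and `ari`.
#' @export
idscn_based_clustering <- function(edge_summary, c = 2L, restarts = 50L,
                                   seed = 0L, reference_labels = NULL) {
  stopifnot(inherits(edge_summary, "edge_summary"))
  if (nrow(edge_summary$edges) == 0L) {
    stop("empty retained edge set; nothing to cluster")
  }
  z <- edge_summary$z_matrix
  z[!is.finite(z)] <- 0
  labels <- cluster_latent(z, c, restarts = restarts, seed = seed)
  out <- list(labels = labels)
  if (!is.null(reference_labels)) {
    common <- intersect(names(labels), names(reference_labels))
    out$crosstab <- table(reference = reference_labels[common],
                          idscn = labels[common])
    out$ari <- adjusted_rand_index(reference_labels[common], labels[common])
  }
  out
}
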