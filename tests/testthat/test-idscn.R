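test_that("partial correlation reduces to plain correlation and the
           first-order closed form", {
  set.seed(61)
  x <- matrix(rnorm(80), 20, 4)
  expect_equal(partial_correlation_matrix(x), cor(x), tolerance = 1e-12)
  # first-order closed form with a single covariate z
  z <- rnorm(20)
  xy <- cbind(a = rnorm(20) + z, b = rnorm(20) - 0.5 * z)
  pc <- partial_correlation_matrix(xy, cbind(z))
  r <- cor(cbind(xy, z))
  closed <- (r["a", "b"] - r["a", 3] * r["b", 3]) /
    sqrt((1 - r["a", 3]^2) * (1 - r["b", 3]^2))
  expect_lt(abs(pc["a", "b"] - closed), 1e-10)
  # structural invariants
  expect_identical(pc, t(pc))
  expect_equal(diag(pc), c(a = 1, b = 1))
  # degenerate inputs
  expect_error(partial_correlation_matrix(x, cbind(z, z)), "rank")
  expect_error(partial_correlation_matrix(x[1:4, ], cbind(z[1:4], rnorm(4))),
               "too few")
})

test_that("the HC reference network has the atlas dimension", {
  cohort <- generate_cohort(cohort_spec(seed = 62))
  hc <- subset_cohort(cohort, group = "HC")
  ref <- build_reference(hc)
  expect_equal(dim(ref$pcc), c(166L, 166L))
  expect_equal(ref$n_hc, 57L)
  expect_equal(ref$covariates, c("age", "sex", "tiv"))
  expect_error(build_reference(cohort), "HC subjects only")
})

test_that("reference recovers a planted block-correlation structure", {
  set.seed(63)
  n <- 120L; r <- 12L
  block <- rep(1:3, each = 4)
  shared <- matrix(rnorm(n * 3), n, 3)
  feats <- 0.8 * shared[, block] + 0.6 * matrix(rnorm(n * r), n)
  colnames(feats) <- sprintf("R%02d", 1:r)
  pcc <- partial_correlation_matrix(feats)
  same <- outer(block, block, `==`) & !diag(r)
  expect_gt(mean(pcc[same]), 0.3)
  expect_lt(abs(mean(pcc[!same & !diag(r)])), 0.1)
})

test_that("correlation is invariant to duplicating every subject", {
  cohort <- generate_cohort(small_spec(seed = 64))
  hc <- subset_cohort(cohort, group = "HC")
  ref1 <- build_reference(hc, covariates = NULL)
  dup <- hc
  dup$features <- rbind(hc$features, hc$features)
  dup$pheno <- rbind(hc$pheno, hc$pheno)
  ref2 <- build_reference(dup, covariates = NULL)
  expect_equal(ref1$pcc, ref2$pcc, tolerance = 1e-12)
})

test_that("leave-one-in Z-scores match a direct recomputation oracle", {
  spec <- cohort_spec(n_id = 5L, n_hc = 20L, n_roi = 10L, n_skeleton = 5L,
                      n_blocks = 2L, subtype_fractions = c(0.6, 0.4),
                      seed = 65)
  cohort <- generate_cohort(spec, skeleton = FALSE)
  hc <- subset_cohort(cohort, group = "HC")
  ref <- build_reference(hc)
  covs <- pgsubtype:::covariate_matrix(cohort$pheno)
  for (i in which(cohort$pheno$group == "ID")) {
    res <- idscn_for_subject(ref, cohort$features[i, ], covs[i, ])
    # oracle: residualize the augmented table explicitly and correlate
    feats_aug <- rbind(hc$features, cohort$features[i, ])
    cov_aug <- rbind(pgsubtype:::covariate_matrix(hc$pheno), covs[i, ])
    d <- cbind(1, cov_aug)
    resid <- feats_aug - d %*% solve(crossprod(d), crossprod(d, feats_aug))
    pcc_aug <- cor(resid)
    delta <- pcc_aug - ref$pcc
    z_oracle <- delta / ((1 - ref$pcc^2) / (ref$n_hc - 1))
    diag(z_oracle) <- 0
    expect_lt(max(abs(res$z - z_oracle)), 1e-10)
    # sign(z) = sign(delta) everywhere off-diagonal
    off <- !diag(10L)
    expect_true(all(sign(res$z[off]) == sign(res$delta_pcc[off])))
    # zero perturbation -> z = 0, p = 1
    expect_true(all((res$delta_pcc == 0 & off) <= (res$p == 1 & off),
                    na.rm = TRUE))
    # symmetry
    expect_equal(res$z, t(res$z), tolerance = 1e-12)
  }
})

test_that("p-values are the two-sided normal tail of z", {
  set.seed(70)
  feats <- matrix(rnorm(15 * 4), 15, 4)
  ref <- structure(list(pcc = partial_correlation_matrix(feats),
                        n_hc = 15L, covariates = NULL,
                        roi_labels = sprintf("R%d", 1:4),
                        hc_features = feats, hc_covariates = NULL),
                   class = "reference_network")
  res <- idscn_for_subject(ref, rnorm(4))
  off <- upper.tri(res$z)
  expect_equal(res$p[off], 2 * pnorm(-abs(res$z[off])), tolerance = 1e-15)
  # the z transform maps a zero perturbation to z = 0, p = 1
  expect_equal(2 * pnorm(-abs(0 / ((1 - 0.3^2) / 14))), 1)
})

test_that("null calibration: no-effect subjects yield centered Z and
           controlled flagging", {
  set.seed(66)
  n_hc <- 57L; r <- 10L; n_new <- 200L
  sigma <- diag(r)
  sigma[1:5, 1:5] <- 0.4
  diag(sigma) <- 1
  ev <- eigen(sigma)
  sqrt_sigma <- ev$vectors %*% diag(sqrt(ev$values)) %*% t(ev$vectors)
  draw <- function(n) matrix(rnorm(n * r), n) %*% sqrt_sigma
  hc_feats <- draw(n_hc)
  colnames(hc_feats) <- sprintf("R%02d", 1:r)
  ref <- structure(list(pcc = partial_correlation_matrix(hc_feats),
                        n_hc = n_hc, covariates = NULL,
                        roi_labels = colnames(hc_feats),
                        hc_features = hc_feats, hc_covariates = NULL),
                   class = "reference_network")
  new_subjects <- draw(n_new)
  zs <- numeric(0)
  flag_rates <- numeric(n_new)
  ut <- upper.tri(ref$pcc)
  for (i in seq_len(n_new)) {
    res <- idscn_for_subject(ref, new_subjects[i, ])
    zs <- c(zs, mean(res$z[ut]))
    sig <- edge_significance(res, alpha = 0.05, method = "bonferroni")
    flag_rates[i] <- mean(sig[ut])
  }
  expect_gt(mean(zs), -0.1)
  expect_lt(mean(zs), 0.1)
  expect_lte(mean(flag_rates), 0.05)
})

test_that("edge significance applies the chosen correction exactly", {
  vals <- c(0.001, 0.004, 0.2, 0.02, 0.03, 0.5, 0.0004, 0.9, 0.06, 0.01)
  p <- matrix(1, 5, 5)
  p[upper.tri(p)] <- vals
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  diag(p) <- NA
  sig_b <- edge_significance(p, alpha = 0.05, method = "bonferroni")
  oracle_b <- (vals <= 0.05 / 10) * 1
  expect_equal(sig_b[upper.tri(sig_b)], oracle_b)
  sig_f <- edge_significance(p, alpha = 0.05, method = "fdr")
  oracle_f <- (p.adjust(vals, "BH") <= 0.05) * 1
  expect_equal(sig_f[upper.tri(sig_f)], oracle_f)
  expect_identical(sig_b, t(sig_b))
  expect_error(edge_significance(p, method = "holm"), "arg")
  # all-zero Z: nothing flagged
  z0 <- structure(list(p = matrix(1, 4, 4)), class = "subject_idscn")
  expect_true(all(edge_significance(z0) == 0))
})

test_that("common-edge counting matches a loop oracle and caps at top_k", {
  set.seed(67)
  r <- 6L
  mk <- function(zvals) {
    z <- matrix(0, r, r)
    z[upper.tri(z)] <- zvals
    z <- z + t(z)
    p <- 2 * pnorm(-abs(z))
    diag(p) <- NA
    structure(list(delta_pcc = z, z = z, p = p), class = "subject_idscn")
  }
  subs <- lapply(1:8, function(s) {
    zv <- rnorm(15, sd = 0.5)
    if (s <= 6) zv[1] <- 8      # edge 1 strongly altered in 6 subjects
    if (s <= 5) zv[2] <- -7     # edge 2 in 5 subjects
    mk(zv)
  })
  names(subs) <- sprintf("S%d", 1:8)
  summ <- top_altered_edges(subs, min_subjects = 5L, top_k = 20L)
  # loop-based counting oracle
  counts_oracle <- matrix(0, r, r)
  for (s in subs) {
    counts_oracle <- counts_oracle + edge_significance(s)
  }
  expect_equal(summ$counts, counts_oracle)
  expect_equal(nrow(summ$edges), 2L)
  expect_equal(summ$edges$count, c(6, 5))
  expect_equal(dim(summ$z_matrix), c(8L, 2L))
  # cap: min_subjects = 1 retains at most top_k edges
  capped <- top_altered_edges(subs, min_subjects = 1L, top_k = 3L)
  expect_lte(nrow(capped$edges), 3L)
  # no qualifying edge -> empty summary
  none <- top_altered_edges(subs, min_subjects = 7L)
  expect_equal(nrow(none$edges), 0L)
  # fractional alternative
  frac <- top_altered_edges(subs, min_fraction = 0.75)
  expect_equal(frac$min_subjects, 6)
})

test_that("clustering on planted edge Z-scores mirrors reference labels", {
  set.seed(68)
  n <- 30L
  truth <- setNames(rep(1:2, each = 15L), sprintf("S%02d", 1:n))
  z_matrix <- matrix(rnorm(n * 4, sd = 0.2), n,
                     dimnames = list(names(truth), NULL))
  z_matrix[truth == 1, 1:2] <- z_matrix[truth == 1, 1:2] + 6
  summ <- structure(list(
    edges = data.frame(i = 1:4, j = 5:8, roi_a = "a", roi_b = "b",
                       count = 10, mean_abs_z = 1),
    z_matrix = z_matrix), class = "edge_summary")
  res <- idscn_based_clustering(summ, c = 2L, seed = 3,
                                reference_labels = truth)
  expect_equal(res$ari, 1)
  expect_equal(dim(res$crosstab), c(2L, 2L))
  empty <- structure(list(edges = data.frame(), z_matrix = z_matrix),
                     class = "edge_summary")
  expect_error(idscn_based_clustering(empty), "empty")
})

test_that("a decoupled region pair is the subject's strongest alteration", {
  set.seed(69)
  n_hc <- 40L; r <- 10L
  # strongly coupled pair (1, 2) in the reference population
  base <- matrix(rnorm(n_hc * r), n_hc)
  base[, 2] <- 0.995 * base[, 1] + sqrt(1 - 0.995^2) * base[, 2]
  colnames(base) <- sprintf("R%02d", 1:r)
  ref <- structure(list(pcc = partial_correlation_matrix(base),
                        n_hc = n_hc, covariates = NULL,
                        roi_labels = colnames(base),
                        hc_features = base, hc_covariates = NULL),
                   class = "reference_network")
  hits <- vapply(1:50, function(s) {
    set.seed(200 + s)
    subj <- rnorm(r)
    subj[2] <- rnorm(1)  # replace by independent noise: decoupled from region 1
    res <- idscn_for_subject(ref, subj)
    az <- abs(res$z); az[lower.tri(az, diag = TRUE)] <- -Inf
    idx <- arrayInd(which.max(az), dim(az))
    all(sort(idx) == c(1L, 2L))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
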