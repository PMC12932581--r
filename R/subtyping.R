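#' Grid for silhouette-based model selection
#'
#' @param lambda_values Structure-loss weights to scan (default 0, 0.1, ..., 1).
#' @param c_values Candidate cluster counts (default 2:5).
#' @param kmeans_restarts Random restarts per K-means fit (default 50).
#' @param seed Seed for the clustering restarts.
#' @return A `selection_grid` list.
#' @export
selection_grid <- function(lambda_values = seq(0, 1, by = 0.1),
                           c_values = 2:5, kmeans_restarts = 50L,
                           seed = 0L) {
  if (!length(lambda_values) || !length(c_values)) {
    stop("selection grid must be non-empty")
  }
  if (any(c_values < 2L)) stop("cluster counts must be >= 2")
  structure(list(lambda_values = lambda_values,
                 c_values = as.integer(c_values),
                 kmeans_restarts = as.integer(kmeans_restarts),
                 seed = as.integer(seed)),
            class = "selection_grid")
}

#' K-means clustering of latent embeddings
#'
#' Best-inertia solution over random restarts; deterministic given `seed`.
#'
#' @param z N x d matrix. @param c Number of clusters (`>= 2`).
#' @param restarts Random restarts (default 50). @param seed Integer seed.
#' @return Integer labels in `1..c`, named by rownames of `z`.
#' @export
cluster_latent <- function(z, c, restarts = 50L, seed = 0L) {
  z <- as.matrix(z)
  if (c < 2L) stop("c must be >= 2 (silhouette undefined for one cluster)")
  if (nrow(z) <= c) stop("need more subjects than clusters")
  set.seed(seed)
  km <- stats::kmeans(z, centers = c, nstart = restarts, iter.max = 100L)
  stats::setNames(km$cluster, rownames(z))
}

#' Mean silhouette coefficient
#'
#' Euclidean-distance silhouette of a labeling of the latent embedding,
#' averaged over samples.
#'
#' @param z N x d matrix. @param labels Cluster labels (>= 2 distinct).
#' @return Scalar in `[-1, 1]`.
#' @export
compute_silhouette <- function(z, labels) {
  labels <- as.integer(as.factor(labels))
  if (length(unique(labels)) < 2L) {
    stop("silhouette requires at least 2 clusters")
  }
  sil <- cluster::silhouette(labels, stats::dist(as.matrix(z)))
  mean(sil[, "sil_width"])
}

#' Silhouette-driven selection of the structure weight and cluster count
#'
#' Trains one autoencoder per candidate `lambda` (the embedding depends on
#' `lambda` only), K-means-clusters each embedding for every candidate `C`,
#' scores every cell by the mean silhouette of the embedding under that
#' labeling, and returns the argmax cell; ties are broken toward smaller `C`,
#' then smaller `lambda`. Failed training runs are recorded as missing cells.
#'
#' @param graph A `population_graph`.
#' @param grid A [selection_grid()].
#' @param enc,dec,train_cfg Model configurations; `train_cfg$lambda_struct`
#'   is overridden by the grid.
#' @return A `subtype_solution`: `labels`, `chosen_lambda`, `chosen_c`,
#'   `silhouette`, `grid_table` (lambda, c, silhouette), and `fit` (the
#'   trained model at the chosen lambda).
#' @export
select_model <- function(graph, grid = selection_grid(),
                         enc = encoder_config(), dec = decoder_config(),
                         train_cfg = train_config()) {
  stopifnot(inherits(grid, "selection_grid"))
  cells <- expand.grid(lambda = grid$lambda_values, c = grid$c_values,
                       KEEP.OUT.ATTRS = FALSE)
  cells$silhouette <- NA_real_
  best <- NULL
  for (lam in grid$lambda_values) {
    cfg <- train_cfg
    cfg$lambda_struct <- lam
    fit <- tryCatch(train_gaae(graph, enc, dec, cfg),
                    error = function(e) {
                      warning("training failed at lambda = ", lam, ": ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (is.null(fit)) next
    for (cc in grid$c_values) {
      labels <- cluster_latent(fit$z, cc, restarts = grid$kmeans_restarts,
                               seed = grid$seed)
      sil <- compute_silhouette(fit$z, labels)
      row <- which(cells$lambda == lam & cells$c == cc)
      cells$silhouette[row] <- sil
      better <- is.null(best) || sil > best$silhouette + 1e-12 ||
        (abs(sil - best$silhouette) <= 1e-12 &&
           (cc < best$chosen_c ||
              (cc == best$chosen_c && lam < best$chosen_lambda)))
      if (better) {
        best <- list(labels = labels, chosen_lambda = lam, chosen_c = cc,
                     silhouette = sil, fit = fit)
      }
    }
  }
  if (is.null(best)) stop("every grid cell failed to train")
  structure(c(best, list(grid_table = cells)), class = "subtype_solution")
}

#' @export
print.subtype_solution <- function(x, ...) {
  cat(sprintf(
    "subtype_solution: C = %d at lambda = %.2f (silhouette %.3f)\n",
    x$chosen_c, x$chosen_lambda, x$silhouette))
  cat("  sizes:", paste(table(x$labels), collapse = "/"), "\n")
  invisible(x)
}

#' Permutation test of inter- versus intra-subtype attention
#'
#' Tests whether attention coefficients on edges connecting different
#' subtypes exceed those within subtypes. The statistic is
#' `mean(inter-subtype alpha) - mean(intra-subtype alpha)`; the null is built
#' by permuting the node-to-subtype assignment, and the one-sided p-value is
#' `(1 + #{perm >= observed}) / (1 + n_perm)`.
#'
#' @param attention data.frame with columns `i`, `j`, `alpha` (e.g. from
#'   [attention_edges()]).
#' @param labels Subtype label per node index.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return List with `statistic`, `p_value`, `n_perm`.
#' @export
attention_subtype_test <- function(attention, labels, n_perm = 10000L,
                                   seed = 0L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  labels <- as.vector(labels)
  inter <- labels[attention$i] != labels[attention$j]
  if (all(inter) || all(!inter)) {
    stop("all edges fall in one class; statistic undefined")
  }
  stat <- function(flag) mean(attention$alpha[flag]) -
    mean(attention$alpha[!flag])
  observed <- stat(inter)
  set.seed(seed)
  null <- replicate(n_perm, {
    perm <- sample(labels)
    flag <- perm[attention$i] != perm[attention$j]
    if (all(flag) || all(!flag)) return(NA_real_)
    stat(flag)
  })
  null <- null[!is.na(null)]
  p <- (1 + sum(null >= observed)) / (1 + length(null))
  list(statistic = observed, p_value = p, n_perm = length(null))
}

#' Two-group comparison of a single variable
#'
#' Continuous variables are compared with Welch's unequal-variance t-test;
#' categorical variables with a chi-square test on the contingency table
#' (no continuity correction).
#'
#' @param values Per-subject values.
#' @param groups Two-level group indicator.
#' @param kind `"continuous"` or `"categorical"`.
#' @param variable Optional variable name carried into the output.
#' @return One-row data.frame: variable, per-group summaries, statistic,
#'   p_value, test.
#' @export
compare_groups <- function(values, groups,
                           kind = c("continuous", "categorical"),
                           variable = NA_character_) {
  kind <- match.arg(kind)
  groups <- as.factor(as.vector(groups))
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 subjects")
  g1 <- values[groups == levels(groups)[1L]]
  g2 <- values[groups == levels(groups)[2L]]
  if (kind == "continuous") {
    tt <- stats::t.test(g1, g2)
    data.frame(variable = variable,
               group1 = levels(groups)[1L], group2 = levels(groups)[2L],
               mean1 = mean(g1), sd1 = stats::sd(g1),
               mean2 = mean(g2), sd2 = stats::sd(g2),
               statistic = unname(tt$statistic),
               p_value = tt$p.value, test = "welch_t",
               stringsAsFactors = FALSE)
  } else {
    tab <- table(groups, values)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(variable = variable,
               group1 = levels(groups)[1L], group2 = levels(groups)[2L],
               mean1 = NA_real_, sd1 = NA_real_,
               mean2 = NA_real_, sd2 = NA_real_,
               statistic = unname(ct$statistic),
               p_value = ct$p.value, test = "chi_square",
               stringsAsFactors = FALSE)
  }
}

#' Group comparison table with FDR correction
#'
#' Runs [compare_groups()] for every variable of a declared family and
#' appends Benjamini-Hochberg adjusted p-values across that family.
#'
#' @param data data.frame of per-subject variables.
#' @param groups Two-level group indicator.
#' @param variables Column names to test.
#' @param kinds Per-variable kind, `"continuous"` (default) or
#'   `"categorical"`; recycled.
#' @return data.frame with one row per variable and a `p_adjusted` column.
#' @export
group_stats_table <- function(data, groups, variables,
                              kinds = "continuous") {
  kinds <- rep(kinds, length.out = length(variables))
  rows <- Map(function(v, k) {
    compare_groups(data[[v]], groups, kind = k, variable = v)
  }, variables, kinds)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Feature-clinical Pearson correlations with FDR correction
#'
#' Pearson correlation (two-sided) between every feature column and every
#' clinical score, with Benjamini-Hochberg adjustment across the whole
#' family of pairs.
#'
#' @param features Subjects x variables matrix or data.frame.
#' @param clinical Subjects x scores matrix or data.frame.
#' @return data.frame: feature, score, r, p_value, p_adjusted.
#' @export
correlate_features_clinical <- function(features, clinical) {
  features <- as.data.frame(features)
  clinical <- as.data.frame(clinical)
  if (nrow(features) != nrow(clinical)) stop("row counts differ")
  if (nrow(features) < 3L) stop("need at least 3 paired observations")
  for (nm in names(features)) {
    if (stats::sd(features[[nm]]) == 0) stop("zero variance in feature ", nm)
  }
  for (nm in names(clinical)) {
    if (stats::sd(clinical[[nm]]) == 0) stop("zero variance in score ", nm)
  }
  out <- expand.grid(feature = names(features), score = names(clinical),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- Map(function(f, s) {
    ct <- stats::cor.test(features[[f]], clinical[[s]], method = "pearson")
    c(unname(ct$estimate), ct$p.value)
  }, out$feature, out$score)
  res <- do.call(rbind, res)
  out$r <- res[, 1L]
  out$p_value <- res[, 2L]
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
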