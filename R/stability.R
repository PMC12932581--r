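#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same subjects:
#' 1 for identical partitions (up to relabeling), approximately 0 for
#' independent ones. When both inputs are named, subjects are aligned by
#' name and the sets must match.
#'
#' @param labels_a,labels_b Cluster labels.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    if (!setequal(names(labels_a), names(labels_b))) {
      stop("mismatched subject sets")
    }
    labels_b <- labels_b[names(labels_a)]
  }
  if (length(labels_a) != length(labels_b)) {
    stop("labelings have different lengths")
  }
  mclust::adjustedRandIndex(labels_a, labels_b)
}

# Restrict a population graph to a subject subset: edges of the full-cohort
# adjacency filtered to retained nodes (no similarity rebuild).
induced_subgraph <- function(graph, idx) {
  adj <- graph$adjacency[idx, idx, drop = FALSE]
  aw <- graph$a_weighted[idx, idx, drop = FALSE]
  ut <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  sub <- structure(list(
    node_features = graph$node_features[idx, , drop = FALSE],
    adjacency = adj,
    a_weighted = aw,
    edge_list = data.frame(i = ut[, 1L], j = ut[, 2L], weight = aw[ut]),
    provenance = c(graph$provenance,
                   list(subsample_of = nrow(graph$adjacency)))
  ), class = "population_graph")
  if (!is.null(graph$pheno)) sub$pheno <- graph$pheno[idx, , drop = FALSE]
  sub
}

#' Subsampling-based clustering stability
#'
#' Repeatedly draws a random subject subset (default 80%, without
#' replacement), retrains the autoencoder on the induced subgraph of the
#' full-cohort adjacency with all hyperparameters fixed, K-means-clusters the
#' resulting embedding at a fixed `c`, and scores every pair of runs by the
#' adjusted Rand index computed on the subjects present in both runs.
#'
#' @param graph A `population_graph` (full cohort).
#' @param enc,dec,train_cfg Model configurations (fixed across runs; the
#'   per-run training seed is `train_cfg$seed + run`).
#' @param fraction Subsample proportion in (0, 1] (default 0.8).
#' @param runs Number of subsampling runs (default 30).
#' @param c Number of clusters (default 2).
#' @param restarts K-means restarts per run.
#' @param seed Base seed for the subject draws.
#' @return A `stability_report`: `runs`, `fraction`, `labels` (per-run named
#'   label vectors), `pairs` (run_a, run_b, overlap_size, ari), `mean_ari`,
#'   `sd_ari`, `failed_runs`.
#' @export
subsample_stability <- function(graph, enc = encoder_config(),
                                dec = decoder_config(),
                                train_cfg = train_config(),
                                fraction = 0.8, runs = 30L, c = 2L,
                                restarts = 50L, seed = 0L) {
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]")
  }
  if (runs < 2L) stop("need at least 2 runs")
  n <- nrow(graph$adjacency)
  m <- round(fraction * n)
  subjects <- rownames(graph$node_features)
  if (is.null(subjects)) subjects <- as.character(seq_len(n))
  labels <- vector("list", runs)
  failed <- integer(0)
  for (r in seq_len(runs)) {
    set.seed(seed + r)
    idx <- sort(sample.int(n, m))
    sub <- induced_subgraph(graph, idx)
    if (nrow(sub$edge_list) == 0L) {
      warning("run ", r, " produced an empty subgraph; excluded",
              call. = FALSE)
      failed <- c(failed, r)
      next
    }
    cfg <- train_cfg
    cfg$seed <- train_cfg$seed + r
    fit <- train_gaae(sub, enc, dec, cfg)
    lab <- cluster_latent(fit$z, c, restarts = restarts, seed = seed + r)
    names(lab) <- subjects[idx]
    labels[[r]] <- lab
  }
  ok <- setdiff(seq_len(runs), failed)
  pairs <- t(utils::combn(ok, 2L))
  res <- data.frame(run_a = pairs[, 1L], run_b = pairs[, 2L],
                    overlap_size = NA_integer_, ari = NA_real_)
  for (row in seq_len(nrow(res))) {
    a <- labels[[res$run_a[row]]]
    b <- labels[[res$run_b[row]]]
    common <- intersect(names(a), names(b))
    res$overlap_size[row] <- length(common)
    res$ari[row] <- if (length(common) >= 2L) {
      adjusted_rand_index(a[common], b[common])
    } else NA_real_
  }
  structure(list(runs = runs, fraction = fraction, labels = labels,
                 pairs = res,
                 mean_ari = mean(res$ari, na.rm = TRUE),
                 sd_ari = stats::sd(res$ari, na.rm = TRUE),
                 failed_runs = failed),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "stability_report: %d runs at %.0f%%, %d pairwise ARIs: %.3f +/- %.3f\n",
    x$runs, 100 * x$fraction, nrow(x$pairs), x$mean_ari, x$sd_ari))
  invisible(x)
}

#' Trend of pairwise ARI against overlap size
#'
#' Ordinary least-squares line of the pairwise ARI on the number of subjects
#' shared by the two runs, used to check that stability does not depend on
#' the overlap.
#'
#' @param report A `stability_report` (or its `pairs` data.frame).
#' @return List with `slope`, `intercept`, `r` (Pearson correlation; NA when
#'   the ARI is constant).
#' @export
ari_overlap_trend <- function(report) {
  pairs <- if (inherits(report, "stability_report")) report$pairs else report
  pairs <- pairs[is.finite(pairs$ari), , drop = FALSE]
  if (nrow(pairs) < 3L) stop("need at least 3 pairwise comparisons")
  if (stats::sd(pairs$overlap_size) == 0) {
    stop("overlap size is constant; slope undefined")
  }
  fit <- stats::lm(ari ~ overlap_size, data = pairs)
  r <- suppressWarnings(stats::cor(pairs$overlap_size, pairs$ari))
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r = r)
}
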