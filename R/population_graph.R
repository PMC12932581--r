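#' Imaging similarity between subjects
#'
#' Computes the cross-subject Pearson correlation matrix for the ROI
#' gray-matter channel and for the skeleton channel, and their sum `S_I`.
#' Correlating subjects across regions (rather than regions across subjects)
#' measures how similar two subjects' regional volume profiles are; summing
#' the two channels preserves complementary regional and cortical-core
#' information without fusing the feature sets themselves.
#'
#' @param roi_features N x F matrix (subjects in rows).
#' @param skeleton_features N x K matrix, same subject order.
#' @return A `similarity_matrices` list with `s_roi`, `s_skel`, `s_i`
#'   (all N x N, symmetric; `s_i` in `[-2, 2]`).
#' @export
imaging_similarity <- function(roi_features, skeleton_features) {
  roi_features <- as.matrix(roi_features)
  skeleton_features <- as.matrix(skeleton_features)
  n <- nrow(roi_features)
  if (n < 3L) stop("need at least 3 subjects")
  if (nrow(skeleton_features) != n) {
    stop("channels disagree on the number of subjects")
  }
  check_nonconstant <- function(x, channel) {
    sds <- apply(x, 1L, stats::sd)
    bad <- which(sds == 0 | !is.finite(sds))
    if (length(bad)) {
      stop("constant or non-finite ", channel, " vector for subject(s): ",
           paste(if (is.null(rownames(x))) bad else rownames(x)[bad],
                 collapse = ", "))
    }
  }
  check_nonconstant(roi_features, "ROI")
  check_nonconstant(skeleton_features, "skeleton")
  s_roi <- stats::cor(t(roi_features))
  s_skel <- stats::cor(t(skeleton_features))
  structure(list(s_roi = s_roi, s_skel = s_skel, s_i = s_roi + s_skel,
                 c_d = NULL, a_weighted = NULL, thresholds = NULL),
            class = "similarity_matrices")
}

#' Binary clinical similarity between subjects
#'
#' For each clinical measure, two subjects are similar when the absolute score
#' difference does not exceed an adaptive threshold: the given percentile
#' (default 25th) of all pairwise absolute differences for that measure.
#' Per-measure binary matrices are combined across measures into the clinical
#' similarity matrix `C_d` with zero diagonal. The default combination is
#' element-wise OR (a pair is clinically comparable when it matches on any
#' measure), which keeps the gate permissive so that the top-percentile
#' sparsification of the fused weights is the operative sparsity mechanism;
#' a strict AND rule is available.
#'
#' @param pheno Data frame containing the measure columns.
#' @param measures Character vector of column names (default PSQI, SAS, SDS).
#' @param percentile Similarity-threshold percentile in (0, 100).
#' @param combine `"or"` (default) or `"and"` across measures.
#' @param sim Optional `similarity_matrices` to fill in place.
#' @return A `similarity_matrices` list with `c_d` (binary N x N) and
#'   `thresholds` (named per-measure, in score units) filled.
#' @export
clinical_similarity <- function(pheno, measures = c("psqi", "sas", "sds"),
                                percentile = 25, combine = c("or", "and"),
                                sim = NULL) {
  combine <- match.arg(combine)
  if (percentile <= 0 || percentile >= 100) {
    stop("percentile must lie strictly between 0 and 100")
  }
  missing_cols <- setdiff(measures, names(pheno))
  if (length(missing_cols)) {
    stop("measures absent from pheno: ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(pheno)
  for (m in measures) {
    bad <- which(!is.finite(pheno[[m]]))
    if (length(bad)) {
      stop("missing/non-finite ", m, " for subject(s): ",
           paste(if ("subject_id" %in% names(pheno))
             pheno$subject_id[bad] else bad, collapse = ", "))
    }
  }
  thresholds <- numeric(0)
  c_d <- NULL
  for (m in measures) {
    diffs <- abs(outer(pheno[[m]], pheno[[m]], `-`))
    t_m <- stats::quantile(diffs[upper.tri(diffs)], percentile / 100,
                           names = FALSE)
    thresholds[m] <- t_m
    sim_m <- (diffs <= t_m) * 1
    c_d <- if (is.null(c_d)) sim_m
           else if (combine == "and") c_d * sim_m
           else pmin(c_d + sim_m, 1)
  }
  diag(c_d) <- 0
  if (!is.null(pheno$subject_id)) {
    dimnames(c_d) <- list(pheno$subject_id, pheno$subject_id)
  }
  if (is.null(sim)) {
    sim <- structure(list(s_roi = NULL, s_skel = NULL, s_i = NULL,
                          c_d = NULL, a_weighted = NULL, thresholds = NULL),
                     class = "similarity_matrices")
  }
  sim$c_d <- c_d
  sim$thresholds <- thresholds
  sim
}

#' Build the sparsified binary population graph
#'
#' Fuses imaging and clinical similarity by the Hadamard product
#' `A = S_I * C_d`, retains the top `sparsity` fraction of the strongest
#' upper-triangle weights (ranked by signed weight, ties broken toward the
#' lexicographically smallest index pair), discards any retained entry with
#' non-positive weight, and symmetrizes into the binary adjacency `A0` with
#' zero diagonal.
#'
#' @param sim A `similarity_matrices` with `s_i` and `c_d` filled on the same
#'   subject ordering.
#' @param node_features N x F matrix of node features (ROI volumes) attached
#'   to the graph.
#' @param sparsity Fraction of upper-triangle entries retained (default 0.20).
#' @param rank_nonzero_only If TRUE, the retention quota is computed over the
#'   clinically gated nonzero weights only rather than all pairs.
#' @param min_degree Connectivity floor (default 1): any node left without an
#'   edge by the global ranking trades the globally weakest retained edge for
#'   its own strongest positive-weight edge, keeping the total edge count at
#'   the sparsity quota. Message passing degenerates on isolated nodes (a
#'   node without neighbors receives no population information), so the
#'   default keeps every node minimally connected; set to 0 for the pure
#'   global threshold. Nodes with no positive-weight edge at all stay
#'   isolated.
#' @return A `population_graph` list: `node_features`, `adjacency` (binary,
#'   symmetric, zero diagonal), `a_weighted`, `edge_list` (data.frame i, j,
#'   weight over retained upper-triangle pairs), `provenance`.
#' @export
build_adjacency <- function(sim, node_features, sparsity = 0.20,
                            rank_nonzero_only = FALSE, min_degree = 1L) {
  stopifnot(inherits(sim, "similarity_matrices"),
            !is.null(sim$s_i), !is.null(sim$c_d))
  n <- nrow(sim$s_i)
  if (!all(dim(sim$c_d) == c(n, n))) stop("s_i and c_d dimensions differ")
  node_features <- as.matrix(node_features)
  if (nrow(node_features) != n) stop("node_features row count != N")
  a_w <- sim$s_i * sim$c_d
  diag(a_w) <- 0
  ut <- which(upper.tri(a_w), arr.ind = TRUE)
  w <- a_w[ut]
  m <- nrow(ut)
  pool <- if (rank_nonzero_only) which(w != 0) else seq_len(m)
  quota <- floor(sparsity * length(pool))
  adj <- matrix(0, n, n)
  edge_list <- data.frame(i = integer(0), j = integer(0), weight = numeric(0))
  if (quota > 0L && length(pool) > 0L) {
    ord <- pool[order(-w[pool], ut[pool, 1L], ut[pool, 2L])]
    keep <- ord[seq_len(min(quota, length(ord)))]
    if (min_degree > 0L) {
      # swap the weakest retained edges for the strongest edge of any node
      # the global ranking left isolated, keeping the edge count fixed
      repeat {
        deg <- tabulate(c(ut[keep, 1L], ut[keep, 2L]), nbins = n)
        lonely <- which(deg == 0L)
        cand <- setdiff(ord, keep)
        cand <- cand[w[cand] > 0]
        if (!length(lonely) || !length(cand)) break
        swapped <- FALSE
        for (node in lonely) {
          mine <- cand[ut[cand, 1L] == node | ut[cand, 2L] == node]
          if (!length(mine)) next
          # drop the weakest retained edge whose endpoints both keep degree
          droppable <- keep[deg[ut[keep, 1L]] > 1L & deg[ut[keep, 2L]] > 1L]
          if (!length(droppable)) break
          keep <- c(setdiff(keep, droppable[length(droppable)]), mine[1L])
          swapped <- TRUE
          break
        }
        if (!swapped) break
      }
      keep <- keep[order(-w[keep], ut[keep, 1L], ut[keep, 2L])]
    }
    keep <- keep[w[keep] > 0]
    if (length(keep)) {
      edge_list <- data.frame(i = ut[keep, 1L], j = ut[keep, 2L],
                              weight = w[keep])
      adj[cbind(edge_list$i, edge_list$j)] <- 1
      adj[cbind(edge_list$j, edge_list$i)] <- 1
    }
  }
  if (nrow(edge_list) == 0L) {
    warning("population graph is empty: no positive clinically gated weights",
            call. = FALSE)
  }
  dimnames(adj) <- dimnames(a_w)
  structure(list(
    node_features = node_features,
    adjacency = adj,
    a_weighted = a_w,
    edge_list = edge_list,
    provenance = list(
      sparsity = sparsity,
      rank_nonzero_only = rank_nonzero_only,
      thresholds = sim$thresholds,
      n_subjects = n,
      n_edges = nrow(edge_list),
      empty = nrow(edge_list) == 0L
    )
  ), class = "population_graph")
}

#' Construct the full population graph from a cohort
#'
#' Convenience wrapper running [imaging_similarity()], [clinical_similarity()]
#' and [build_adjacency()] on the patient (ID) subjects of a cohort. Only the
#' patient group enters the graph: the heterogeneity of interest lies within
#' the disorder, while controls serve downstream as the covariance reference.
#'
#' @param cohort A `subject_cohort`.
#' @param group Which group to include (default `"ID"`).
#' @param measures,percentile,combine Passed to [clinical_similarity()].
#' @param sparsity,rank_nonzero_only,min_degree Passed to
#'   [build_adjacency()].
#' @return A `population_graph`; the retained pheno rows are attached as
#'   `$pheno`.
#' @export
build_population_graph <- function(cohort, group = "ID",
                                   measures = c("psqi", "sas", "sds"),
                                   percentile = 25, combine = "or",
                                   sparsity = 0.20,
                                   rank_nonzero_only = FALSE,
                                   min_degree = 1L) {
  stopifnot(inherits(cohort, "subject_cohort"))
  rows <- which(cohort$pheno$group %in% group)
  if (length(rows) < 3L) stop("fewer than 3 subjects in group ", group)
  sim <- imaging_similarity(cohort$features[rows, , drop = FALSE],
                            cohort$skeleton[rows, , drop = FALSE])
  sim <- clinical_similarity(cohort$pheno[rows, , drop = FALSE],
                             measures = measures, percentile = percentile,
                             combine = combine, sim = sim)
  graph <- build_adjacency(sim, cohort$features[rows, , drop = FALSE],
                           sparsity = sparsity,
                           rank_nonzero_only = rank_nonzero_only,
                           min_degree = min_degree)
  graph$pheno <- cohort$pheno[rows, , drop = FALSE]
  graph$provenance$percentile <- percentile
  graph$provenance$measures <- measures
  graph$provenance$combine <- combine
  graph
}

#' @export
print.population_graph <- function(x, ...) {
  n <- nrow(x$adjacency)
  cat("population_graph:", n, "nodes,", nrow(x$edge_list), "edges",
      sprintf("(density %.3f)\n",
              nrow(x$edge_list) / (n * (n - 1) / 2)))
  invisible(x)
}
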