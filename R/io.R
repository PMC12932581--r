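# Numeric cells are written with 17 significant digits so that doubles
# survive a write/read round trip bit for bit.
fmt_num <- function(x) {
  if (is.double(x)) formatC(x, digits = 17, format = "g") else x
}

write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (nm in names(df)) df[[nm]] <- fmt_num(df[[nm]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

matrix_to_df <- function(x, id_col = "subject_id") {
  df <- data.frame(rownames(x), as.data.frame(x, check.names = FALSE),
                   check.names = FALSE)
  names(df)[1L] <- id_col
  df
}

#' Write a cohort as delimited tables
#'
#' Writes `features.tsv` (subjects x ROI columns named by the atlas labels),
#' `pheno.tsv`, and `skeleton.tsv` when present, all tab-delimited with
#' header rows and a `subject_id` key column.
#'
#' @param cohort A `subject_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "subject_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(matrix_to_df(cohort$features), file.path(dir, "features.tsv"))
  write_tsv(cohort$pheno, file.path(dir, "pheno.tsv"))
  if (!is.null(cohort$skeleton)) {
    write_tsv(matrix_to_df(cohort$skeleton), file.path(dir, "skeleton.tsv"))
  }
  invisible(dir)
}

read_feature_table <- function(path, what) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "subject_id") {
    stop(what, " table must start with a subject_id column: ", path)
  }
  ids <- as.character(df$subject_id)
  if (anyDuplicated(ids)) {
    stop("duplicate subject ids in ", what, " table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- df[, -1L, drop = FALSE]
  for (j in seq_along(m)) {
    v <- m[[j]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop("non-numeric cell in ", what, " table at row ", bad[1L],
             ", column '", names(m)[j], "'")
      }
      m[[j]] <- num
    }
  }
  m <- as.matrix(m)
  rownames(m) <- ids
  m
}

#' Load a cohort from delimited tables
#'
#' Reads the feature, optional skeleton, and pheno tables, inner-joins them
#' on `subject_id` (reporting dropped rows), and preserves the ROI column
#' order as the atlas order.
#'
#' @param feature_path Path to the subjects x ROI table.
#' @param pheno_path Path to the phenotype table (subject_id, group, psqi,
#'   sas, sds, age, sex, tiv, optional true_subtype).
#' @param skeleton_path Optional path to the skeleton channel table.
#' @return A `subject_cohort` (with `spec = NULL`).
#' @export
load_cohort_tables <- function(feature_path, pheno_path,
                               skeleton_path = NULL) {
  features <- read_feature_table(feature_path, "feature")
  pheno <- utils::read.delim(pheno_path, check.names = FALSE,
                             stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(pheno)) {
    stop("pheno table lacks a subject_id column")
  }
  pheno$subject_id <- as.character(pheno$subject_id)
  if (anyDuplicated(pheno$subject_id)) {
    stop("duplicate subject ids in pheno table")
  }
  skeleton <- if (!is.null(skeleton_path)) {
    read_feature_table(skeleton_path, "skeleton")
  }
  ids <- intersect(rownames(features), pheno$subject_id)
  if (!is.null(skeleton)) ids <- intersect(ids, rownames(skeleton))
  all_ids <- union(union(rownames(features), pheno$subject_id),
                   if (is.null(skeleton)) character(0) else
                     rownames(skeleton))
  dropped <- setdiff(all_ids, ids)
  if (length(dropped)) {
    warning(length(dropped), " subject(s) dropped by the inner join: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            call. = FALSE)
  }
  # keep the feature-table row order for the retained subjects
  ids <- rownames(features)[rownames(features) %in% ids]
  pheno <- pheno[match(ids, pheno$subject_id), , drop = FALSE]
  rownames(pheno) <- NULL
  if (!"true_subtype" %in% names(pheno)) {
    pheno$true_subtype <- NA_integer_
  }
  structure(list(features = features[ids, , drop = FALSE],
                 skeleton = if (is.null(skeleton)) NULL else
                   skeleton[ids, , drop = FALSE],
                 pheno = pheno, spec = NULL),
            class = "subject_cohort")
}

#' Write a population graph to disk
#'
#' Writes the binary adjacency in Matrix Market format (`adjacency.mtx`),
#' the retained edges with fused weights (`edges.tsv`), the node features
#' and pheno rows, and a JSON provenance block.
#'
#' @param graph A `population_graph`. @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_graph <- function(graph, dir) {
  stopifnot(inherits(graph, "population_graph"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(graph$adjacency, sparse = TRUE),
                  file.path(dir, "adjacency.mtx"))
  write_tsv(graph$edge_list, file.path(dir, "edges.tsv"))
  write_tsv(matrix_to_df(graph$node_features),
            file.path(dir, "node_features.tsv"))
  if (!is.null(graph$pheno)) {
    write_tsv(graph$pheno, file.path(dir, "pheno.tsv"))
  }
  jsonlite::write_json(graph$provenance,
                       file.path(dir, "graph_provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration of the full analysis pipeline.
#' Every stochastic stage derives its seed from the single global `seed`.
#'
#' @param cohort A [cohort_spec()] for simulation, or NULL when `paths` are
#'   given.
#' @param paths Named list with `features`, `pheno`, optional `skeleton`.
#' @param graph List of graph parameters (`percentile`, `sparsity`,
#'   `measures`, `combine`).
#' @param encoder,decoder,train Model configurations.
#' @param selection NULL for a fixed (`lambda`, `c`), or a
#'   [selection_grid()].
#' @param lambda,c Fixed values used when `selection` is NULL.
#' @param stability NULL to skip, or list(`runs`, `fraction`).
#' @param idscn NULL to skip, or list(`alpha`, `method`, `min_subjects`,
#'   `top_k`).
#' @param seed Global seed.
#' @param out_dir Output directory.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = NULL, paths = NULL,
                            graph = list(percentile = 25, sparsity = 0.20,
                                         measures = c("psqi", "sas", "sds"),
                                         combine = "and"),
                            encoder = encoder_config(),
                            decoder = decoder_config(),
                            train = train_config(),
                            selection = NULL, lambda = 0.3, c = 2L,
                            stability = list(runs = 30L, fraction = 0.8),
                            idscn = list(alpha = 0.05,
                                         method = "bonferroni",
                                         min_subjects = 33L, top_k = 20L),
                            seed = 0L, out_dir = tempfile("pgsubtype_")) {
  cfg <- list(cohort = cohort, paths = paths, graph = graph,
              encoder = encoder, decoder = decoder, train = train,
              selection = selection, lambda = lambda, c = as.integer(c),
              stability = stability, idscn = idscn,
              seed = as.integer(seed), out_dir = out_dir)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$cohort) && is.null(cfg$paths)) {
    stop("config needs either a cohort simulation spec or table paths")
  }
  if (!is.null(cfg$cohort)) validate_cohort_spec(cfg$cohort)
  if (!is.null(cfg$paths)) {
    for (p in c("features", "pheno")) {
      if (is.null(cfg$paths[[p]])) stop("paths$", p, " is required")
      if (!file.exists(cfg$paths[[p]])) {
        stop("missing input table: ", cfg$paths[[p]])
      }
    }
  }
  if (cfg$graph$sparsity <= 0 || cfg$graph$sparsity > 1) {
    stop("graph sparsity must lie in (0, 1]")
  }
  if (cfg$graph$percentile <= 0 || cfg$graph$percentile >= 100) {
    stop("similarity percentile must lie in (0, 100)")
  }
  if (is.null(cfg$selection)) {
    if (cfg$lambda < 0) stop("lambda must be >= 0")
    if (cfg$c < 2L) stop("c must be >= 2")
  }
  if (!is.null(cfg$stability)) {
    if (cfg$stability$fraction <= 0 || cfg$stability$fraction > 1) {
      stop("stability fraction must lie in (0, 1]")
    }
    if (cfg$stability$runs < 2L) stop("stability runs must be >= 2")
  }
  invisible(cfg)
}

#' Run the full subtyping pipeline
#'
#' Executes simulate/load, graph construction, model training (or
#' silhouette-driven selection), subtype characterization, optional
#' stability analysis and optional individualized differential-network
#' analysis, writing every stage's outputs plus a manifest with content
#' hashes under `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage messages.
#' @return A result list (cohort, graph, solution, stats, stability, idscn,
#'   manifest), invisibly writing all outputs.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  validate_pipeline_config(config)
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message("[pgsubtype] ", ...)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- "cohort"
  result <- tryCatch({
    say("stage cohort")
    cohort <- if (!is.null(config$cohort)) {
      spec <- config$cohort
      spec$seed <- config$seed
      generate_cohort(spec)
    } else {
      load_cohort_tables(config$paths$features, config$paths$pheno,
                         config$paths$skeleton)
    }
    write_cohort(cohort, file.path(out, "cohort"))

    stage <- "graph"
    say("stage graph")
    graph <- build_population_graph(
      cohort, percentile = config$graph$percentile,
      measures = config$graph$measures, combine = config$graph$combine,
      sparsity = config$graph$sparsity)
    write_graph(graph, file.path(out, "graph"))

    stage <- "model"
    say("stage model")
    tcfg <- config$train
    tcfg$seed <- config$seed + 1L
    if (!is.null(config$selection)) {
      grid <- config$selection
      grid$seed <- config$seed + 2L
      solution <- select_model(graph, grid, config$encoder, config$decoder,
                               tcfg)
    } else {
      tcfg$lambda_struct <- config$lambda
      fit <- train_gaae(graph, config$encoder, config$decoder, tcfg)
      labels <- cluster_latent(fit$z, config$c, seed = config$seed + 2L)
      solution <- structure(
        list(labels = labels, chosen_lambda = config$lambda,
             chosen_c = config$c,
             silhouette = compute_silhouette(fit$z, labels),
             fit = fit, grid_table = NULL),
        class = "subtype_solution")
    }
    fit <- solution$fit
    write_tsv(matrix_to_df(fit$z), file.path(out, "embeddings.tsv"))
    write_tsv(cbind(epoch = seq_len(nrow(fit$loss_history)),
                    fit$loss_history),
              file.path(out, "loss_history.tsv"))
    write_tsv(attention_edges(fit, layers = seq_along(fit$attention),
                              average_heads = FALSE),
              file.path(out, "attention_edges.tsv"))
    write_tsv(data.frame(subject_id = names(solution$labels),
                         label = unname(solution$labels)),
              file.path(out, "subtypes.tsv"))
    if (!is.null(solution$grid_table)) {
      write_tsv(solution$grid_table, file.path(out, "grid.tsv"))
    }

    stage <- "characterization"
    say("stage characterization")
    pheno <- graph$pheno
    labels <- solution$labels[pheno$subject_id]
    stats_tab <- group_stats_table(
      pheno, labels,
      variables = c("psqi", "sas", "sds", "age", "sex"),
      kinds = c(rep("continuous", 4L), "categorical"))
    write_tsv(stats_tab, file.path(out, "group_stats.tsv"))
    roi_tab <- group_stats_table(
      as.data.frame(graph$node_features, check.names = FALSE), labels,
      variables = colnames(graph$node_features))
    top_rois <- utils::head(roi_tab$variable[order(roi_tab$p_value)], 6L)
    cors <- correlate_features_clinical(
      graph$node_features[, top_rois, drop = FALSE],
      pheno[, intersect(c("psqi", "sas", "sds"), names(pheno))])
    write_tsv(cors, file.path(out, "correlations.tsv"))

    stability_rep <- NULL
    if (!is.null(config$stability)) {
      stage <- "stability"
      say("stage stability")
      scfg <- config$train
      scfg$seed <- config$seed + 3L
      scfg$lambda_struct <- solution$chosen_lambda
      stability_rep <- subsample_stability(
        graph, config$encoder, config$decoder, scfg,
        fraction = config$stability$fraction,
        runs = config$stability$runs, c = solution$chosen_c,
        seed = config$seed + 3L)
      write_tsv(stability_rep$pairs, file.path(out, "stability_pairs.tsv"))
      jsonlite::write_json(
        list(runs = stability_rep$runs,
             n_pairs = nrow(stability_rep$pairs),
             mean_ari = stability_rep$mean_ari,
             sd_ari = stability_rep$sd_ari),
        file.path(out, "stability_summary.json"),
        auto_unbox = TRUE, digits = NA)
    }

    idscn_res <- NULL
    if (!is.null(config$idscn) &&
        any(cohort$pheno$group == "HC")) {
      stage <- "idscn"
      say("stage idscn")
      nets <- idscn_all(cohort)
      summary <- top_altered_edges(
        nets, min_subjects = config$idscn$min_subjects,
        top_k = config$idscn$top_k, alpha = config$idscn$alpha,
        method = config$idscn$method)
      ut <- which(upper.tri(summary$counts) & summary$counts > 0,
                  arr.ind = TRUE)
      write_tsv(data.frame(i = ut[, 1L], j = ut[, 2L],
                           count = summary$counts[ut]),
                file.path(out, "edge_counts.tsv"))
      write_tsv(summary$edges, file.path(out, "top_edges.tsv"))
      idscn_res <- list(summary = summary)
      if (nrow(summary$edges) > 0L) {
        cl <- idscn_based_clustering(summary, c = solution$chosen_c,
                                     seed = config$seed + 4L,
                                     reference_labels = solution$labels)
        write_tsv(data.frame(subject_id = names(cl$labels),
                             label = unname(cl$labels)),
                  file.path(out, "idscn_labels.tsv"))
        jsonlite::write_json(
          list(ari = cl$ari,
               crosstab = as.data.frame(cl$crosstab)),
          file.path(out, "idscn_crosstab.json"),
          auto_unbox = TRUE, digits = NA)
        idscn_res$clustering <- cl
      }
    }

    list(cohort = cohort, graph = graph, solution = solution,
         group_stats = stats_tab, correlations = cors,
         stability = stability_rep, idscn = idscn_res)
  }, error = function(e) {
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  out_norm <- normalizePath(out)
  files <- list.files(out_norm, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("pgsubtype")),
    seed = config$seed,
    parameters = list(
      graph = config$graph, lambda = result$solution$chosen_lambda,
      c = result$solution$chosen_c,
      stability = config$stability, idscn = config$idscn),
    n_subjects = nrow(result$cohort$features),
    n_edges = nrow(result$graph$edge_list),
    n_stability_pairs = if (is.null(result$stability)) NULL else
      nrow(result$stability$pairs),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = lapply(stats::setNames(
      files, substring(files, nchar(out_norm) + 2L)),
      function(f) unname(tools::md5sum(f)))
  )
  manifest$elapsed_sec <- NULL  # keep manifests reproducible across reruns
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  result$manifest <- manifest
  invisible(result)
}
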