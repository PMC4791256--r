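#' Configure the end-to-end candidate-biomarker pipeline
#'
#' @param counts Either a `spectral_counts` object, or NULL when reading from
#'   files.
#' @param counts_path,annotation_path TSV inputs for [read_counts()] (used
#'   when `counts` is NULL).
#' @param out_dir Output directory for the report bundle.
#' @param filter_threshold,filter_aggregator Low-count filter settings (see
#'   [filter_low_counts()]).
#' @param alpha Selection threshold for the beta-binomial and ANOVA tests.
#' @param methods Character vector of selection methods to run; any of
#'   `"betabinom"`, `"nsc"`, `"svm_rfe"`, `"anova"`.
#' @param dcv_nsc,dcv_svm [dcv_config()] objects for the two classifier
#'   methods (seeds are overridden by `seed`).
#' @param seed Master seed recorded in every artifact.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts = NULL, counts_path = NULL,
                            annotation_path = NULL, out_dir = tempfile("protsel_run_"),
                            filter_threshold = 2,
                            filter_aggregator = "total", alpha = 0.05,
                            methods = c("betabinom", "nsc", "svm_rfe", "anova"),
                            dcv_nsc = dcv_config("nsc"),
                            dcv_svm = dcv_config("svm_rfe"), seed = 1) {
  known <- c("betabinom", "nsc", "svm_rfe", "anova")
  bad <- setdiff(methods, known)
  if (length(bad) > 0) stop("unknown method(s): ", paste(bad, collapse = ", "))
  if (is.null(counts) && (is.null(counts_path) || is.null(annotation_path))) {
    stop("provide either `counts` or both `counts_path` and `annotation_path`")
  }
  dcv_nsc$seed <- as.integer(seed)
  dcv_svm$seed <- as.integer(seed)
  structure(list(counts = counts, counts_path = counts_path,
                 annotation_path = annotation_path, out_dir = out_dir,
                 filter_threshold = filter_threshold,
                 filter_aggregator = filter_aggregator, alpha = alpha,
                 methods = methods, dcv_nsc = dcv_nsc, dcv_svm = dcv_svm,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror [pipeline_config()] arguments (flat keys, with
#'   `dcv_nsc:` / `dcv_svm:` sub-maps passed to [dcv_config()]).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("counts_path", "annotation_path", "out_dir",
                                  "filter_threshold", "filter_aggregator",
                                  "alpha", "methods", "seed"))]
  if (!is.null(y$dcv_nsc)) {
    args$dcv_nsc <- do.call(dcv_config, c(list(method = "nsc"), y$dcv_nsc))
  }
  if (!is.null(y$dcv_svm)) {
    args$dcv_svm <- do.call(dcv_config, c(list(method = "svm_rfe"), y$dcv_svm))
  }
  do.call(pipeline_config, args)
}

.write_tsv <- function(df, path) {
  write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

.write_dcv_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("method: %s", report$method),
    sprintf("seed: %d", report$seed),
    sprintf("outer_error: %.6f", report$outer_error),
    sprintf("accuracy: %.6f", report$accuracy),
    sprintf("optimal_N: %d", report$optimal_N),
    sprintf("final_param: %s = %g", names(report$final_param)[1],
            report$final_param[1]),
    "", "confusion (rows = truth):"), con)
  write.table(report$confusion, con, sep = "\t", quote = FALSE)
  writeLines("", con)
  writeLines("per-class metrics:", con)
  write.table(as.data.frame(report$per_class), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines("", con)
  writeLines("per-fold tuning:", con)
  write.table(as.data.frame(report$fold_tuning), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
}

#' Run the full candidate-biomarker pipeline
#'
#' Executes, in order: low-count filtering; the beta-binomial test and the
#' ANOVA baseline with selection at `alpha`; NSC and SVM-RFE under double
#' cross-validation; per-protein class association; Jaccard/Venn concordance
#' of the selected subsets; and clustering diagnostics (hierarchical order,
#' NJ tree, silhouettes from data and tree) before filtering-selection and
#' after restriction to the union of selected candidates. All artifacts are
#' written under `config$out_dir` with stable filenames.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage's in-memory result plus
#'   `summary` (tibble) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "read"
  res <- list(out_dir = config$out_dir)
  tryCatch({
    x <- config$counts %||% read_counts(config$counts_path,
                                        config$annotation_path)
    stage <- "filter"
    n_before <- nrow(x$counts)
    xf <- filter_low_counts(x, config$filter_threshold,
                            config$filter_aggregator)
    res$filtered <- xf
    write_counts(xf, file.path(config$out_dir, "counts_filtered.tsv"),
                 file.path(config$out_dir, "annotation.tsv"))

    lists <- list()
    if ("betabinom" %in% config$methods) {
      stage <- "betabinom"
      bb <- betabinom_test(xf)
      res$betabinom <- betabinom_rank(bb, alpha = config$alpha)
      lists$betabinom <- res$betabinom
      .write_tsv(dplyr::left_join(tibble::as_tibble(res$betabinom),
                                  bb, by = "protein_id"),
                 file.path(config$out_dir, "bb_results.tsv"))
    }
    if ("anova" %in% config$methods) {
      stage <- "anova"
      res$anova <- anova_per_protein(xf, alpha = config$alpha)
      .write_tsv(tibble::as_tibble(res$anova),
                 file.path(config$out_dir, "anova_results.tsv"))
    }
    if ("nsc" %in% config$methods) {
      stage <- "nsc"
      res$nsc <- run_dcv(xf, config$dcv_nsc)
      lists$nsc <- res$nsc$selected_features
      .write_dcv_report(res$nsc, file.path(config$out_dir, "nsc_report.txt"))
    }
    if ("svm_rfe" %in% config$methods) {
      stage <- "svm_rfe"
      res$svm_rfe <- run_dcv(xf, config$dcv_svm)
      lists$svm_rfe <- res$svm_rfe$selected_features
      .write_dcv_report(res$svm_rfe,
                        file.path(config$out_dir, "svmrfe_report.txt"))
    }

    if (length(lists) >= 2) {
      stage <- "compare"
      res$jaccard_curve <- jaccard_curve(lists)
      .write_tsv(res$jaccard_curve,
                 file.path(config$out_dir, "jaccard_curve.tsv"))
    }
    venn_rows <- NULL
    if (length(lists) == 3) {
      res$venn <- venn_partition(lists)
      .write_tsv(res$venn$membership, file.path(config$out_dir, "venn.tsv"))
      rg <- res$venn$regions
      nm <- setdiff(names(rg), "size")
      venn_rows <- tibble::tibble(
        stat = paste0("venn_only_", apply(rg[nm], 1, function(z)
          paste(nm[unlist(z)], collapse = "_and_"))),
        value = as.numeric(rg$size))
    }

    stage <- "cluster"
    labels <- setNames(xf$annotation$class, xf$annotation$run_id)
    diag_pre <- cluster_diagnostics(xf, labels)
    res$cluster_pre <- diag_pre
    ape::write.tree(diag_pre$nj, file.path(config$out_dir, "nj_pre.nwk"))
    union_sel <- sort(Reduce(union, lapply(lists, selected_ids)))
    res$selected_union <- union_sel
    if (length(union_sel) >= 2) {
      xsel <- subset_proteins(xf, union_sel)
      diag_post <- cluster_diagnostics(xsel, labels)
      res$cluster_post <- diag_post
      ape::write.tree(diag_post$nj, file.path(config$out_dir, "nj_post.nwk"))
    }

    stage <- "summary"
    summary <- tibble::tibble(
      stat = c("n_proteins_input", "n_proteins_filtered",
               paste0("N_", names(lists)),
               if (!is.null(res$anova)) "N_anova",
               if (!is.null(res$nsc)) c("dcv_error_nsc", "accuracy_nsc"),
               if (!is.null(res$svm_rfe)) c("dcv_error_svm_rfe",
                                            "accuracy_svm_rfe"),
               if (!is.null(venn_rows)) venn_rows$stat,
               "n_selected_union", "sc_data_pre", "sc_tree_pre",
               if (length(union_sel) >= 2) c("sc_data_post", "sc_tree_post"),
               "seed"),
      value = c(n_before, nrow(xf$counts),
                vapply(lists, function(l) attr(l, "n_selected"), integer(1)),
                if (!is.null(res$anova)) attr(res$anova, "n_selected"),
                if (!is.null(res$nsc)) c(res$nsc$outer_error,
                                         res$nsc$accuracy),
                if (!is.null(res$svm_rfe)) c(res$svm_rfe$outer_error,
                                             res$svm_rfe$accuracy),
                if (!is.null(venn_rows)) venn_rows$value,
                length(union_sel), diag_pre$sc_data$overall,
                diag_pre$sc_tree$overall,
                if (length(union_sel) >= 2) c(res$cluster_post$sc_data$overall,
                                              res$cluster_post$sc_tree$overall),
                config$seed))
    res$summary <- summary
    .write_tsv(summary, file.path(config$out_dir, "summary.tsv"))
    yaml::write_yaml(list(seed = config$seed, methods = config$methods,
                          filter_threshold = config$filter_threshold,
                          alpha = config$alpha,
                          r_version = as.character(getRversion())),
                     file.path(config$out_dir, "manifest.yaml"))
    invisible(res)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Clustering diagnostics for one count matrix
#'
#' Z-scores protein rows, clusters samples hierarchically on the Pearson
#' distance, builds a neighbor-joining tree from the Euclidean distance
#' between samples, and computes silhouette coefficients from the data and
#' from the tree.
#'
#' @param x A `spectral_counts` object (>= 2 proteins).
#' @param labels Named class vector (names = run ids) or vector aligned with
#'   the runs.
#' @return List: `hclust`, `nj` (phylo), `sc_data`, `sc_tree` (see
#'   [silhouette_from_data()]), `dist_euclidean`.
#' @export
cluster_diagnostics <- function(x, labels = NULL) {
  stopifnot(inherits(x, "spectral_counts"))
  labels <- labels %||% setNames(x$annotation$class, x$annotation$run_id)
  if (!is.null(names(labels))) labels <- labels[colnames(x$counts)]
  z <- zscore_rows(x)
  dp <- pearson_distance(z, axis = "samples")
  hc <- hierarchical_cluster(dp, "average")
  de <- as.matrix(dist(t(z)))
  nj <- nj_tree(de)
  sc_data <- silhouette_from_data(de, labels)
  sc_tree <- silhouette_from_tree(nj, setNames(labels, colnames(x$counts)))
  list(hclust = hc, nj = nj, sc_data = sc_data, sc_tree = sc_tree,
       dist_euclidean = de)
}
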