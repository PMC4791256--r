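#' Construct a spectral-count matrix object
#'
#' Bundles a non-negative integer protein-by-run count matrix with its sample
#' annotation (class label and replicate index per run). Spectral counts — the
#' number of MS/MS spectra assigned to a protein in one LC-MS/MS run — are a
#' semi-quantitative proxy for protein abundance in label-free shotgun
#' proteomics; per-run column totals are carried along as the sampling depth.
#'
#' @param counts Integer matrix, proteins in rows (rownames = protein ids),
#'   runs in columns (colnames = run ids). No missing values; absence must be
#'   encoded as 0.
#' @param annotation Data frame with columns `run_id`, `class`, `replicate`,
#'   one row per run. Every class must contain at least two runs.
#' @return An object of class `spectral_counts`: a list with elements
#'   `counts` (integer matrix), `annotation` (tibble, ordered as the matrix
#'   columns) and `run_totals` (named per-run column sums).
#' @export
spectral_counts <- function(counts, annotation) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have protein ids as rownames and run ids as colnames")
  }
  if (anyNA(counts)) stop("`counts` contains missing values; encode absence as 0")
  if (!is.numeric(counts)) stop("`counts` must be numeric")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-integer or negative count at protein '%s', run '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  storage.mode(counts) <- "integer"
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup) > 0) stop("duplicated protein id: ", dup[1])
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup) > 0) stop("duplicated run id: ", dup[1])

  annotation <- tibble::as_tibble(annotation)
  req <- c("run_id", "class")
  if (!all(req %in% names(annotation))) {
    stop("annotation must have columns 'run_id' and 'class'")
  }
  if (!"replicate" %in% names(annotation)) annotation$replicate <- 1L
  missing_runs <- setdiff(colnames(counts), annotation$run_id)
  if (length(missing_runs) > 0) {
    stop("annotation missing run(s): ", paste(missing_runs, collapse = ", "))
  }
  extra <- setdiff(annotation$run_id, colnames(counts))
  if (length(extra) > 0) {
    stop("annotation has run(s) absent from the count matrix: ",
         paste(extra, collapse = ", "))
  }
  annotation <- annotation[match(colnames(counts), annotation$run_id), ]
  annotation$class <- as.character(annotation$class)
  tab <- table(annotation$class)
  if (length(tab) < 2) stop("at least two classes are required")
  if (any(tab < 2)) {
    stop("every class needs >= 2 runs; offending class: ",
         names(tab)[which(tab < 2)[1]])
  }
  structure(
    list(counts = counts, annotation = annotation,
         run_totals = colSums(counts)),
    class = "spectral_counts"
  )
}

#' @export
print.spectral_counts <- function(x, ...) {
  cat(sprintf("<spectral_counts> %d proteins x %d runs\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$annotation$class)
  cat("classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("per-run total spectra: %d-%d (sum %d)\n",
              min(x$run_totals), max(x$run_totals), sum(x$run_totals)))
  invisible(x)
}

#' @export
dim.spectral_counts <- function(x) dim(x$counts)

#' Tidy a spectral-count matrix into long format
#'
#' @param x A `spectral_counts` object.
#' @param ... Unused.
#' @return A tibble with columns `protein_id`, `run_id`, `class`, `replicate`,
#'   `count`, `run_total` (one row per protein-run cell).
#' @method tidy spectral_counts
#' @export
tidy.spectral_counts <- function(x, ...) {
  long <- tibble::tibble(
    protein_id = rep(rownames(x$counts), times = ncol(x$counts)),
    run_id = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.integer(x$counts)
  )
  dplyr::left_join(long, x$annotation, by = "run_id") |>
    dplyr::mutate(run_total = x$run_totals[.data$run_id]) |>
    dplyr::select("protein_id", "run_id", "class", "replicate",
                  "count", "run_total")
}

#' Read a spectral-count matrix and sample annotation from TSV files
#'
#' The counts file is tab-separated UTF-8 with run ids in the header row and
#' protein ids in the first column; the annotation file has columns
#' `run_id`, `class`, `replicate`. Row and column order is preserved.
#'
#' @param path Path to the counts TSV.
#' @param annotation_path Path to the annotation TSV.
#' @return A validated `spectral_counts` object.
#' @export
read_counts <- function(path, annotation_path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  protein_ids <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(mat, 2, as.numeric))), arr.ind = TRUE)
    if (length(bad) > 0) {
      stop(sprintf("non-numeric count at protein '%s', run '%s'",
                   protein_ids[bad[1, 1]], colnames(mat)[bad[1, 2]]))
    }
    storage.mode(mat) <- "numeric"
  }
  rownames(mat) <- protein_ids
  ann <- read.delim(annotation_path, stringsAsFactors = FALSE)
  spectral_counts(mat, ann)
}

#' Write a spectral-count matrix (and annotation) back to TSV
#'
#' @param x A `spectral_counts` object.
#' @param path Output path for the counts TSV (same layout `read_counts` reads).
#' @param annotation_path Optional output path for the annotation TSV.
#' @return `x`, invisibly.
#' @export
write_counts <- function(x, path, annotation_path = NULL) {
  df <- data.frame(protein_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path)) {
    write.table(as.data.frame(x$annotation), annotation_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(x)
}

#' Discard proteins with too few spectra
#'
#' Removes proteins whose aggregated spectral count is less than or equal to
#' `threshold` — the classical "total spectra <= 2" pre-filter that strips
#' proteins quantified too sparsely to carry class information. The run set is
#' unchanged and run totals are recomputed from the surviving proteins.
#'
#' @param x A `spectral_counts` object.
#' @param threshold Non-negative integer; proteins with aggregate <= threshold
#'   are discarded. Default 2.
#' @param aggregator `"total"` (sum across runs, default) or `"max"`
#'   (maximum single-run count).
#' @return A filtered `spectral_counts` object.
#' @export
filter_low_counts <- function(x, threshold = 2, aggregator = c("total", "max")) {
  stopifnot(inherits(x, "spectral_counts"), threshold >= 0)
  aggregator <- match.arg(aggregator)
  agg <- switch(aggregator,
                total = rowSums(x$counts),
                max = apply(x$counts, 1, max))
  keep <- agg > threshold
  if (!any(keep)) warning("all proteins removed by the low-count filter")
  out <- x
  out$counts <- x$counts[keep, , drop = FALSE]
  out$run_totals <- colSums(out$counts)
  out
}

#' Row-wise z-score transform
#'
#' Centers and scales each protein's profile across runs: rows with nonzero
#' spread end with mean 0 and sample standard deviation 1; constant rows map
#' to all zeros (neutral in downstream Pearson or Euclidean distances).
#'
#' @param x A `spectral_counts` object or a numeric matrix.
#' @return A numeric matrix of the same shape.
#' @export
zscore_rows <- function(x) {
  m <- if (inherits(x, "spectral_counts")) x$counts else as.matrix(x)
  if (ncol(m) < 2) stop("z-scoring needs >= 2 runs")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

#' Per-run relative abundance
#'
#' Divides each count by its run's total so each column sums to one. This is
#' the default feature scale fed to the classifiers: it removes differences in
#' sampling depth between MS runs.
#'
#' @param x A `spectral_counts` object.
#' @return A numeric matrix (proteins x runs) with unit column sums.
#' @export
relative_abundance <- function(x) {
  stopifnot(inherits(x, "spectral_counts"))
  zero <- names(x$run_totals)[x$run_totals == 0]
  if (length(zero) > 0) stop("run with zero total spectra: ", zero[1])
  sweep(x$counts, 2, x$run_totals, "/")
}

#' Signed fold change between two classes
#'
#' For each protein, class mean counts a (target) and b (reference) are
#' compared; a zero mean is replaced by one so the ratio is defined. The
#' signed convention returns a/b when a >= b and -b/a otherwise, so |FC| >= 1
#' always and negative means lower abundance in the target class. The flag
#' marks the conventional two-sided |FC| >= 1.3 relevance threshold.
#'
#' @param x A `spectral_counts` object.
#' @param target_class,reference_class Class labels present in the annotation.
#' @param threshold Absolute fold-change flag threshold (default 1.3).
#' @return A tibble: `protein_id`, `mean_target`, `mean_reference`,
#'   `fold_change`, `above_threshold`.
#' @export
fold_change <- function(x, target_class, reference_class, threshold = 1.3) {
  stopifnot(inherits(x, "spectral_counts"))
  cls <- x$annotation$class
  if (!target_class %in% cls) stop("class not present: ", target_class)
  if (!reference_class %in% cls) stop("class not present: ", reference_class)
  a <- rowMeans(x$counts[, cls == target_class, drop = FALSE])
  b <- rowMeans(x$counts[, cls == reference_class, drop = FALSE])
  a1 <- ifelse(a == 0, 1, a)
  b1 <- ifelse(b == 0, 1, b)
  fc <- ifelse(a1 >= b1, a1 / b1, -b1 / a1)
  tibble::tibble(
    protein_id = rownames(x$counts),
    mean_target = unname(a), mean_reference = unname(b),
    fold_change = unname(fc),
    above_threshold = unname(abs(fc) >= threshold)
  )
}

#' Subset a spectral-count matrix to a set of proteins
#'
#' @param x A `spectral_counts` object.
#' @param protein_ids Character vector of protein ids to keep (order kept as
#'   given). Run totals are recomputed on the subset.
#' @return A `spectral_counts` object restricted to `protein_ids`.
#' @export
subset_proteins <- function(x, protein_ids) {
  stopifnot(inherits(x, "spectral_counts"))
  missing <- setdiff(protein_ids, rownames(x$counts))
  if (length(missing) > 0) stop("unknown protein id(s): ",
                                paste(head(missing, 3), collapse = ", "))
  out <- x
  out$counts <- x$counts[protein_ids, , drop = FALSE]
  out$run_totals <- colSums(out$counts)
  out
}
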