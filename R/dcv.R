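#' Configure a double cross-validation run
#'
#' @param method `"nsc"` or `"svm_rfe"`.
#' @param outer_folds Number of stratified outer folds (default 6, matching a
#'   3-class x 6-replicate design with one sample per class held out per
#'   fold) or `"loo"` for leave-one-out.
#' @param inner_folds Number of stratified inner folds (default 5).
#' @param seed Integer seed; all fold assignments flow from it.
#' @param feature_scale `"relative"` (per-run relative abundance, default),
#'   `"counts"` (raw counts), or `"zscore"` (standardized per training fold).
#' @param delta_grid_size NSC: number of shrinkage grid points (default 30).
#' @param C_grid SVM-RFE: soft-margin costs tried in the inner loop (default
#'   `c(0.01, 0.1, 1, 10, 100)`).
#' @param candidate_N SVM-RFE: subset sizes evaluated in the inner loop
#'   (default 1:20 then 30, 40, ... up to the feature count).
#' @param rfe_step RFE elimination step (see [rfe_rank()]).
#' @return A `dcv_config` list.
#' @export
dcv_config <- function(method = c("nsc", "svm_rfe"),
                       outer_folds = 6, inner_folds = 5, seed = 1,
                       feature_scale = c("relative", "counts", "zscore"),
                       delta_grid_size = 30,
                       C_grid = c(0.01, 0.1, 1, 10, 100),
                       candidate_N = NULL, rfe_step = "auto") {
  method <- match.arg(method)
  feature_scale <- match.arg(feature_scale)
  C_grid <- as.numeric(unlist(C_grid))
  if (!is.null(candidate_N)) candidate_N <- as.integer(unlist(candidate_N))
  if (!identical(outer_folds, "loo")) stopifnot(outer_folds >= 3)
  stopifnot(inner_folds >= 2)
  structure(list(method = method, outer_folds = outer_folds,
                 inner_folds = inner_folds, seed = as.integer(seed),
                 feature_scale = feature_scale,
                 delta_grid_size = delta_grid_size, C_grid = C_grid,
                 candidate_N = candidate_N, rfe_step = rfe_step),
            class = "dcv_config")
}

# stratified fold assignment; every fold sees every class in training
.make_folds <- function(labels, k) {
  n <- length(labels)
  if (identical(k, "loo")) return(seq_len(n))
  fold <- integer(n)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.default_candidate_N <- function(p) {
  unique(pmin(c(1:20, seq(30, max(30, p), by = 10)), p))
}

.feature_matrix <- function(x, feature_scale) {
  switch(feature_scale,
         relative = t(relative_abundance(x)),
         counts = t(x$counts),
         zscore = t(x$counts))  # standardized per training fold downstream
}

# inner tuning for NSC on one training set: returns per-delta records
.nsc_inner <- function(Xtr, ytr, inner_folds, delta_grid_size) {
  full <- fit_nsc(Xtr, ytr, delta = 0)
  grid <- nsc_delta_grid(full, delta_grid_size)
  fold <- .make_folds(ytr, inner_folds)
  recs <- vector("list", max(fold))
  for (f in seq_len(max(fold))) {
    tr <- fold != f
    fit0 <- fit_nsc(Xtr[tr, , drop = FALSE], ytr[tr], delta = 0)
    val <- Xtr[!tr, , drop = FALSE]
    truth <- ytr[!tr]
    recs[[f]] <- purrr::map_dfr(grid, function(dl) {
      fit <- .nsc_set_delta(fit0, dl)
      pr <- predict_nsc(fit, val)
      pcols <- paste0("prob_", truth)
      tprob <- vapply(seq_along(truth),
                      function(i) pr[[pcols[i]]][i], numeric(1))
      tibble::tibble(delta = dl,
                     n_err = sum(pr$predicted != truth),
                     n_val = length(truth),
                     prob_sum = sum(tprob))
    })
  }
  per_delta <- dplyr::bind_rows(recs) |>
    dplyr::group_by(.data$delta) |>
    dplyr::summarise(error = sum(.data$n_err) / sum(.data$n_val),
                     prob_sum = sum(.data$prob_sum), .groups = "drop")
  # subset size induced by each delta on the full training fit
  per_delta$N <- vapply(per_delta$delta, function(dl)
    sum(apply(abs(full$d), 2, max) > dl), integer(1))
  list(records = per_delta, full_fit = full)
}

# survivor counts visited by the elimination path on p features
.rfe_sizes <- function(p, step, step_cutoff) {
  sizes <- integer(0)
  m <- p
  while (m > 1) {
    sizes <- c(sizes, m)
    n_drop <- if (identical(step, "auto")) {
      if (m > step_cutoff) max(1L, floor(0.10 * m)) else 1L
    } else if (identical(step, 1) || identical(step, 1L)) 1L
    else max(1L, floor(step * m))
    m <- m - min(n_drop, m - 1L)
  }
  c(sizes, 1L)
}

# inner tuning for SVM-RFE on one training set; candidate subset sizes are
# evaluated from the models the elimination path itself trains
.svm_inner <- function(Xtr, ytr, inner_folds, C_grid, candidate_N, rfe_step,
                       step_cutoff = 200) {
  candidate_N <- intersect(candidate_N,
                           .rfe_sizes(ncol(Xtr), rfe_step, step_cutoff))
  fold <- .make_folds(ytr, inner_folds)
  recs <- list()
  for (f in seq_len(max(fold))) {
    tr <- fold != f
    std <- standardize_features(Xtr[tr, , drop = FALSE],
                                Xtr[!tr, , drop = FALSE])
    truth <- ytr[!tr]
    for (C in C_grid) {
      path <- .rfe_path(std$train, ytr[tr], C, rfe_step, step_cutoff,
                        Xval = std$test, eval_N = candidate_N)
      for (N in candidate_N) {
        pred <- path$val_pred[[as.character(N)]]
        recs[[length(recs) + 1]] <- tibble::tibble(
          C = C, N = N, n_err = sum(pred != truth), n_val = length(truth))
      }
    }
  }
  dplyr::bind_rows(recs) |>
    dplyr::group_by(.data$C, .data$N) |>
    dplyr::summarise(error = sum(.data$n_err) / sum(.data$n_val),
                     .groups = "drop")
}

#' Choose the optimal feature-subset size from inner-loop records
#'
#' SVM-RFE keeps the smallest subset attaining the minimal mean inner error.
#' NSC first minimizes the inner error, then among ties maximizes the summed
#' probability assigned to the true class, then takes the smallest subset.
#'
#' @param inner_records Tibble with columns `N`, `error` and, for NSC,
#'   `prob_sum` (and optionally `delta`).
#' @param method `"nsc"` or `"svm_rfe"`.
#' @return The selected row of `inner_records` (one-row tibble).
#' @export
select_optimal_subset <- function(inner_records, method = c("nsc", "svm_rfe")) {
  method <- match.arg(method)
  r <- tibble::as_tibble(inner_records)
  stopifnot(all(c("N", "error") %in% names(r)))
  r <- r[r$error == min(r$error), , drop = FALSE]
  if (method == "nsc" && "prob_sum" %in% names(r)) {
    r <- r[r$prob_sum == max(r$prob_sum), , drop = FALSE]
  }
  r[order(r$N), ][1, ]
}

#' Run double (nested) cross-validation
#'
#' The outer loop estimates prediction error on held-out samples; within each
#' outer training set an inner cross-validation tunes the method's parameter
#' (NSC shrinkage delta, or SVM cost C and subset size N along the RFE path)
#' so that no information from the outer test samples reaches any tuning
#' decision. Finally, the same inner tuning is applied to the full data set
#' and the model is refit to produce the reported feature subset.
#'
#' @param x A `spectral_counts` object (already low-count filtered).
#' @param config A [dcv_config()].
#' @return A `dcv_report` object: outer predictions, per-fold tuning records,
#'   confusion matrix, accuracy / error / per-class sensitivity-specificity,
#'   optimal N, the final [ranked_features()] list, and per-protein class
#'   association from [assign_protein_class()].
#' @export
run_dcv <- function(x, config = dcv_config()) {
  stopifnot(inherits(x, "spectral_counts"), inherits(config, "dcv_config"))
  set.seed(config$seed)
  labels <- x$annotation$class
  classes <- sort(unique(labels))
  X <- .feature_matrix(x, config$feature_scale)
  candidate_N <- config$candidate_N %||% .default_candidate_N(ncol(X))
  candidate_N <- candidate_N[candidate_N <= ncol(X)]

  fold <- .make_folds(labels, config$outer_folds)
  n_folds <- max(fold)
  outer_rows <- list()
  fold_rows <- list()

  for (f in seq_len(n_folds)) {
    tr <- fold != f
    if (!all(classes %in% labels[tr])) {
      stop("outer training fold ", f, " is missing a class; use fewer folds")
    }
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[!tr, , drop = FALSE]
    if (config$feature_scale == "zscore") {
      std <- standardize_features(Xtr, Xte)
      Xtr <- std$train; Xte <- std$test
    }
    ytr <- labels[tr]
    if (config$method == "nsc") {
      inner <- .nsc_inner(Xtr, ytr, config$inner_folds,
                          config$delta_grid_size)
      pick <- select_optimal_subset(inner$records, "nsc")
      fit <- .nsc_set_delta(inner$full_fit, pick$delta)
      pred <- predict_nsc(fit, Xte)$predicted
      fold_rows[[f]] <- tibble::tibble(
        fold = f, param_name = "delta", param = pick$delta,
        N = pick$N, inner_error = pick$error)
    } else {
      inner <- .svm_inner(Xtr, ytr, config$inner_folds, config$C_grid,
                          candidate_N, config$rfe_step)
      pick <- select_optimal_subset(inner, "svm_rfe")
      std <- standardize_features(Xtr, Xte)
      path <- .rfe_path(std$train, ytr, pick$C, config$rfe_step, 200,
                        Xval = std$test, eval_N = pick$N)
      pred <- path$val_pred[[as.character(pick$N)]]
      fold_rows[[f]] <- tibble::tibble(
        fold = f, param_name = "C", param = pick$C,
        N = pick$N, inner_error = pick$error)
    }
    outer_rows[[f]] <- tibble::tibble(
      fold = f, run_id = rownames(X)[!tr],
      truth = labels[!tr], predicted = pred)
  }

  outer <- dplyr::bind_rows(outer_rows)
  confusion <- table(factor(outer$truth, classes),
                     factor(outer$predicted, classes))
  confusion <- unclass(confusion)
  metrics <- performance_metrics(confusion)

  # final tuning and refit on all samples
  Xall <- if (config$feature_scale == "zscore") {
    standardize_features(X)$train
  } else X
  if (config$method == "nsc") {
    inner <- .nsc_inner(Xall, labels, config$inner_folds,
                        config$delta_grid_size)
    pick <- select_optimal_subset(inner$records, "nsc")
    fit <- .nsc_set_delta(inner$full_fit, pick$delta)
    ranked <- rank_features_nsc(fit)
    final_param <- c(delta = pick$delta)
  } else {
    inner <- .svm_inner(Xall, labels, config$inner_folds, config$C_grid,
                        candidate_N, config$rfe_step)
    pick <- select_optimal_subset(inner, "svm_rfe")
    std <- standardize_features(Xall)
    rk <- rfe_rank(std$train, labels, C = pick$C, step = config$rfe_step)
    ranked <- rfe_as_ranked(rk, n_selected = pick$N)
    final_param <- c(C = pick$C)
  }
  assoc <- assign_protein_class(x, selected_ids(ranked))

  structure(list(
    config = config, method = config$method,
    outer = outer, fold_tuning = dplyr::bind_rows(fold_rows),
    confusion = confusion,
    accuracy = metrics$accuracy, outer_error = 1 - metrics$accuracy,
    per_class = metrics$per_class,
    optimal_N = as.integer(pick$N), final_param = final_param,
    selected_features = ranked, class_assignment = assoc,
    seed = config$seed
  ), class = "dcv_report")
}

#' @export
print.dcv_report <- function(x, ...) {
  cat(sprintf("<dcv_report> method = %s, outer error = %.3f (accuracy %.1f%%), optimal N = %d\n",
              x$method, x$outer_error, 100 * x$accuracy, x$optimal_N))
  cat("confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' @method tidy dcv_report
#' @export
tidy.dcv_report <- function(x, ...) x$outer

#' @method glance dcv_report
#' @export
glance.dcv_report <- function(x, ...) {
  tibble::tibble(method = x$method, accuracy = x$accuracy,
                 outer_error = x$outer_error, optimal_N = x$optimal_N,
                 outer_folds = max(x$outer$fold), seed = x$seed)
}

#' One-vs-rest performance metrics from a confusion matrix
#'
#' @param confusion Square non-negative matrix, rows = truth, columns =
#'   prediction, identically ordered class names.
#' @return List with `per_class` (tibble: class, sensitivity, specificity)
#'   and `accuracy`. A class never observed in truth has undefined (NA)
#'   sensitivity.
#' @export
performance_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion), all(confusion >= 0))
  classes <- rownames(confusion) %||% as.character(seq_len(nrow(confusion)))
  total <- sum(confusion)
  per_class <- purrr::map_dfr(seq_along(classes), function(k) {
    tp <- confusion[k, k]
    fn <- sum(confusion[k, ]) - tp
    fp <- sum(confusion[, k]) - tp
    tn <- total - tp - fn - fp
    tibble::tibble(
      class = classes[k],
      sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
      specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp))
  })
  list(per_class = per_class, accuracy = sum(diag(confusion)) / total)
}

#' Associate selected proteins with the class they characterize
#'
#' The decision-boundary step after selection: each protein is assigned to
#' the class whose mean relative abundance deviates most from the overall
#' mean in NSC-standardized units, (xbar_ik - xbar_i) / (s_i + s0); the
#' direction is up if that deviation is positive. Proteins with identical
#' class means are flagged ambiguous.
#'
#' @param x A `spectral_counts` object.
#' @param protein_ids Selected protein ids (subset of the matrix rows).
#' @return A tibble: `protein_id`, `class`, `direction` (`"up"`, `"down"` or
#'   `"ambiguous"`), `deviation` (the signed standardized deviation).
#' @export
assign_protein_class <- function(x, protein_ids) {
  stopifnot(inherits(x, "spectral_counts"))
  if (length(protein_ids) == 0) {
    return(tibble::tibble(protein_id = character(0), class = character(0),
                          direction = character(0), deviation = numeric(0)))
  }
  X <- t(relative_abundance(x))
  fit <- fit_nsc(X[, protein_ids, drop = FALSE], x$annotation$class, delta = 0)
  dev <- fit$d * outer(fit$class_size_factor, rep(1, length(protein_ids)))
  # undo m_k so classes with unequal sizes are comparable: (xbar_ik-xbar_i)/(s_i+s0)
  purrr::map_dfr(protein_ids, function(p) {
    dv <- dev[, p]
    k <- which.max(abs(dv))
    amb <- max(abs(dv)) == 0
    tibble::tibble(
      protein_id = p,
      class = if (amb) NA_character_ else fit$classes[k],
      direction = if (amb) "ambiguous" else if (dv[k] > 0) "up" else "down",
      deviation = dv[k])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
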