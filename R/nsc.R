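#' Fit a nearest shrunken centroids model
#'
#' Computes, per feature i and class k, the standardized centroid deviation
#' d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0)), where s_i is the pooled
#' within-class standard deviation, s0 the median of the s_i (a guard against
#' near-zero denominators), and m_k = sqrt(1/n_k - 1/n). Each d_ik is then
#' soft-thresholded by delta, d'_ik = sign(d_ik) max(|d_ik| - delta, 0), and
#' the class centroids are reconstructed from the shrunken deviations. A
#' feature whose d'_ik vanish for every class no longer contributes to
#' classification, so delta simultaneously controls shrinkage and feature
#' selection.
#'
#' @param X Numeric matrix, samples in rows, features in columns (named).
#' @param labels Class label per sample (>= 2 classes, each with >= 2
#'   samples).
#' @param delta Shrinkage threshold >= 0.
#' @param priors `"empirical"` (class frequencies, default) or `"uniform"`,
#'   or a named numeric vector summing to 1.
#' @param mk_convention `"minus"` for m_k = sqrt(1/n_k - 1/n) (default) or
#'   `"plus"` for sqrt(1/n_k + 1/n); published descriptions differ.
#' @return An object of class `nsc_fit`.
#' @export
fit_nsc <- function(X, labels, delta = 0, priors = "empirical",
                    mk_convention = c("minus", "plus")) {
  mk_convention <- match.arg(mk_convention)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels), delta >= 0)
  classes <- sort(unique(labels))
  G <- length(classes)
  n <- nrow(X)
  n_k <- vapply(classes, function(k) sum(labels == k), integer(1))
  if (G < 2) stop("need >= 2 classes")
  if (any(n_k < 2)) stop("every class needs >= 2 samples")

  overall <- colMeans(X)
  centroids <- matrix(
    vapply(classes, function(k)
      colMeans(X[labels == k, , drop = FALSE]), numeric(ncol(X))),
    nrow = G, ncol = ncol(X), byrow = TRUE,
    dimnames = list(classes, colnames(X)))

  # pooled within-class sd, n - G denominator
  ss <- Reduce(`+`, lapply(classes, function(k) {
    Xi <- X[labels == k, , drop = FALSE]
    colSums(sweep(Xi, 2, colMeans(Xi))^2)
  }))
  s_i <- sqrt(ss / (n - G))
  s0 <- median(s_i)

  m_k <- switch(mk_convention,
                minus = sqrt(1 / n_k - 1 / n),
                plus = sqrt(1 / n_k + 1 / n))
  denom <- outer(m_k, s_i + s0)          # G x p
  dev <- sweep(centroids, 2, overall)    # xbar_ik - xbar_i
  d <- ifelse(denom > 0, dev / denom, 0)
  d_shrunk <- sign(d) * pmax(abs(d) - delta, 0)
  shrunken_centroids <- sweep(d_shrunk * denom, 2, overall, "+")

  if (identical(priors, "empirical")) {
    pri <- n_k / n
  } else if (identical(priors, "uniform")) {
    pri <- setNames(rep(1 / G, G), classes)
  } else {
    stopifnot(is.numeric(priors), abs(sum(priors) - 1) < 1e-8)
    pri <- priors[classes]
  }

  structure(list(
    classes = classes, features = colnames(X), n = n, n_k = n_k,
    overall_centroid = overall, class_centroids = centroids,
    pooled_sd = s_i, sd_offset = s0, class_size_factor = m_k,
    priors = pri, delta = delta, d = d, shrunken_d = d_shrunk,
    shrunken_centroids = shrunken_centroids,
    mk_convention = mk_convention
  ), class = "nsc_fit")
}

#' @export
print.nsc_fit <- function(x, ...) {
  cat(sprintf("<nsc_fit> %d features, %d classes, delta = %.4g (%d features surviving)\n",
              length(x$features), length(x$classes), x$delta,
              sum(apply(abs(x$shrunken_d), 2, max) > 0)))
  invisible(x)
}

#' Predict classes and class probabilities from an NSC model
#'
#' Uses the discriminant score delta_k(x) = sum_i (x_i - xbar'_ik)^2 /
#' (s_i + s0)^2 - 2 log pi_k; the predicted class minimizes the score and
#' class probabilities are proportional to exp(-delta_k / 2).
#'
#' @param model An `nsc_fit`.
#' @param X Numeric matrix (samples x features) or a single feature vector.
#' @return A tibble with `predicted` plus one probability column per class
#'   (named `prob_<class>`), one row per sample.
#' @export
predict_nsc <- function(model, X) {
  stopifnot(inherits(model, "nsc_fit"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, model$features))
  X <- as.matrix(X)[, model$features, drop = FALSE]
  s2 <- (model$pooled_sd + model$sd_offset)^2
  s2[s2 == 0] <- 1   # zero-spread features carry no information
  disc <- vapply(model$classes, function(k) {
    diffs <- sweep(X, 2, model$shrunken_centroids[k, ])
    rowSums(sweep(diffs^2, 2, s2, "/")) - 2 * log(model$priors[[k]])
  }, numeric(nrow(X)))
  disc <- matrix(disc, nrow = nrow(X),
                 dimnames = list(NULL, model$classes))
  # probabilities ~ exp(-disc/2), stabilized
  w <- exp(-(disc - apply(disc, 1, min)) / 2)
  prob <- w / rowSums(w)
  pred <- model$classes[apply(disc, 1, which.min)]
  out <- tibble::tibble(predicted = unname(pred))
  for (k in model$classes) out[[paste0("prob_", k)]] <- unname(prob[, k])
  out
}

#' Rank features by unshrunken centroid deviation
#'
#' Orders features by descending max_k |d_ik| — the unshrunken score, so the
#' ranking does not depend on delta — and marks as selected those features
#' whose shrunken deviation is nonzero for at least one class at the model's
#' delta.
#'
#' @param model An `nsc_fit`.
#' @return A [ranked_features()] list with `score` = max_k |d_ik|.
#' @export
rank_features_nsc <- function(model) {
  stopifnot(inherits(model, "nsc_fit"))
  score <- apply(abs(model$d), 2, max)
  surv <- apply(abs(model$shrunken_d), 2, max) > 0
  ord <- order(-score, model$features)
  df <- tibble::tibble(protein_id = model$features[ord], score = score[ord])
  # survivors always occupy the top of the ranking (|d| > delta), so top-N works
  ranked_features(df, method = "nsc", n_selected = sum(surv))
}

#' Shrinkage grid for NSC tuning
#'
#' @param model An `nsc_fit` (delta may be 0).
#' @param length_out Number of grid points (default 30), evenly spaced from 0
#'   to max |d_ik|.
#' @return Numeric vector of delta values.
#' @export
nsc_delta_grid <- function(model, length_out = 30) {
  stopifnot(inherits(model, "nsc_fit"))
  seq(0, max(abs(model$d)), length.out = length_out)
}

#' Refit an NSC model at a new shrinkage level without recomputing statistics
#' @noRd
.nsc_set_delta <- function(model, delta) {
  denom <- outer(model$class_size_factor, model$pooled_sd + model$sd_offset)
  model$delta <- delta
  model$shrunken_d <- sign(model$d) * pmax(abs(model$d) - delta, 0)
  model$shrunken_centroids <-
    sweep(model$shrunken_d * denom, 2, model$overall_centroid, "+")
  model
}

#' @method tidy nsc_fit
#' @export
tidy.nsc_fit <- function(x, ...) {
  tibble::tibble(
    feature = rep(x$features, each = length(x$classes)),
    class = rep(x$classes, times = length(x$features)),
    d = as.vector(x$d),
    d_shrunk = as.vector(x$shrunken_d),
    centroid = as.vector(x$class_centroids),
    shrunken_centroid = as.vector(x$shrunken_centroids)
  )
}

#' @method glance nsc_fit
#' @export
glance.nsc_fit <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$features),
    n_classes = length(x$classes),
    delta = x$delta,
    sd_offset = x$sd_offset,
    n_surviving = sum(apply(abs(x$shrunken_d), 2, max) > 0)
  )
}
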