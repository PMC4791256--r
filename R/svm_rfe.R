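#' Train one-vs-one linear maximum-margin classifiers
#'
#' Fits a linear soft-margin SVM for every pair of classes (a single
#' multiclass call; pairwise weight vectors w and intercepts b are extracted
#' from the underlying one-vs-one solution). Multiclass prediction is by
#' pairwise voting, with ties broken by the summed signed decision values.
#'
#' @param X Numeric matrix, samples x features (named columns).
#' @param labels Class per sample (>= 2 classes, all present).
#' @param C Soft-margin cost parameter (> 0).
#' @return An object of class `maxmargin_fit`: list with `pairs` (per pair:
#'   the two classes, `w`, `b`; decision x.w + b > 0 votes for the first
#'   class), `classes`, `features`, `C`.
#' @export
train_linear_maxmargin <- function(X, labels, C = 1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels), C > 0)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need >= 2 classes in the training data")
  pairs <- .ovo_linear(X, labels, C)
  structure(list(pairs = pairs, classes = classes,
                 features = colnames(X), C = C),
            class = "maxmargin_fit")
}

# one e1071::svm call; per-pair (w, b) recovered from the one-vs-one layout:
# support vectors are grouped by libsvm's internal class order and the
# coefficient matrix holds, for the (i, j) subproblem, the class-i rows in
# column j-1 and the class-j rows in column i
.ovo_linear <- function(X, labels, C) {
  m <- e1071::svm(X, factor(labels), kernel = "linear", cost = C,
                  scale = FALSE)
  cls <- m$levels[m$labels]            # internal (appearance) order
  k <- length(cls)
  start <- c(1, cumsum(m$nSV) + 1)
  out <- list()
  idx <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      idx <- idx + 1
      ri <- start[i]:(start[i] + m$nSV[i] - 1)
      rj <- start[j]:(start[j] + m$nSV[j] - 1)
      w <- drop(t(m$coefs[ri, j - 1]) %*% m$SV[ri, , drop = FALSE] +
                  t(m$coefs[rj, i]) %*% m$SV[rj, , drop = FALSE])
      names(w) <- colnames(X)
      out[[idx]] <- list(classes = c(cls[i], cls[j]), w = w, b = -m$rho[idx])
    }
  }
  out
}

# voting prediction from a list of pairwise (classes, w, b)
.ovo_predict <- function(pairs, classes, X) {
  votes <- matrix(0, nrow(X), length(classes),
                  dimnames = list(NULL, classes))
  score <- votes
  for (p in pairs) {
    dec <- drop(X[, names(p$w), drop = FALSE] %*% p$w) + p$b
    win <- ifelse(dec > 0, p$classes[1], p$classes[2])
    for (i in seq_along(win)) votes[i, win[i]] <- votes[i, win[i]] + 1
    score[, p$classes[1]] <- score[, p$classes[1]] + dec
    score[, p$classes[2]] <- score[, p$classes[2]] - dec
  }
  vapply(seq_len(nrow(X)), function(i) {
    v <- votes[i, ]
    top <- names(v)[v == max(v)]
    if (length(top) == 1) return(top)
    s <- score[i, top]
    top[order(-s, top)][1]
  }, character(1))
}

#' Predict classes by pairwise voting
#'
#' @param object A `maxmargin_fit`.
#' @param newdata Samples x features matrix.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.maxmargin_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$features, drop = FALSE]
  .ovo_predict(object$pairs, object$classes, X)
}

# RFE core. Trains on the surviving features each round, removes the
# lowest-criterion block, and (optionally) predicts `Xval` whenever the
# survivor count hits a requested eval size — the survivors at size N are
# exactly the final top-N, so these are the top-N models for free.
.rfe_path <- function(X, labels, C, step, step_cutoff, Xval = NULL,
                      eval_N = NULL) {
  classes <- sort(unique(labels))
  surviving <- colnames(X)
  eliminated <- character(0)
  crit_out <- numeric(0)
  round_out <- integer(0)
  round_i <- 0L
  val_pred <- list()
  while (length(surviving) > 1) {
    round_i <- round_i + 1L
    pairs <- .ovo_linear(X[, surviving, drop = FALSE], labels, C)
    if (!is.null(Xval) && length(surviving) %in% eval_N) {
      val_pred[[as.character(length(surviving))]] <-
        .ovo_predict(pairs, classes, Xval)
    }
    crit <- setNames(numeric(length(surviving)), surviving)
    for (p in pairs) crit <- crit + p$w^2
    n_drop <- if (identical(step, "auto")) {
      if (length(surviving) > step_cutoff)
        max(1L, floor(0.10 * length(surviving))) else 1L
    } else if (identical(step, 1) || identical(step, 1L)) {
      1L
    } else {
      max(1L, floor(step * length(surviving)))
    }
    n_drop <- min(n_drop, length(surviving) - 1L)
    # worst first; criterion ties eliminate the lexicographically larger id
    ord <- order(crit, -xtfrm(surviving))
    drop_ids <- surviving[ord][seq_len(n_drop)]
    eliminated <- c(eliminated, drop_ids)
    crit_out <- c(crit_out, crit[drop_ids])
    round_out <- c(round_out, rep(round_i, n_drop))
    surviving <- setdiff(surviving, drop_ids)
  }
  if (!is.null(Xval) && 1 %in% eval_N) {
    pairs <- .ovo_linear(X[, surviving, drop = FALSE], labels, C)
    val_pred[["1"]] <- .ovo_predict(pairs, classes, Xval)
  }
  eliminated <- c(eliminated, surviving)
  crit_out <- c(crit_out, NA_real_)
  round_out <- c(round_out, round_i + 1L)
  list(elimination_order = eliminated, criterion = unname(crit_out),
       round = round_out, n_rounds = round_i, val_pred = val_pred)
}

#' Recursive feature elimination ranking with a linear SVM
#'
#' Iteratively trains one-vs-one linear SVMs on the surviving features,
#' scores each feature by the summed squared weight c_i = sum over binary
#' problems of w_i^2, and removes the lowest-scoring feature(s). The final
#' ranking is the reverse elimination order: the last survivor ranks first.
#' Features should be standardized beforehand so squared weights are
#' comparable across features.
#'
#' @param X Numeric matrix, samples x features (named columns, >= 2).
#' @param labels Class per sample.
#' @param C Soft-margin cost (default 1).
#' @param step Either `"auto"` (remove 10\% of survivors per round while more
#'   than `step_cutoff` remain, then one per round; bounds runtime on
#'   thousand-feature matrices) or a fixed fraction in (0, 0.5], or 1 for
#'   one-at-a-time.
#' @param step_cutoff Survivor count below which elimination is one-at-a-time
#'   under `step = "auto"` (default 200).
#' @return An object of class `rfe_ranking`: `elimination_order` (first
#'   eliminated ... last survivor), per-feature criterion at removal and
#'   round index.
#' @export
rfe_rank <- function(X, labels, C = 1, step = "auto", step_cutoff = 200) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  stopifnot(ncol(X) >= 2)
  if (is.numeric(step)) stopifnot(step == 1 || (step > 0 && step <= 0.5))
  path <- .rfe_path(X, as.character(labels), C, step, step_cutoff)
  structure(c(path[c("elimination_order", "criterion", "round", "n_rounds")],
              list(C = C, step = step)),
            class = "rfe_ranking")
}

#' @export
print.rfe_ranking <- function(x, ...) {
  cat(sprintf("<rfe_ranking> %d features eliminated over %d rounds (C = %g)\n",
              length(x$elimination_order) - 1, x$n_rounds, x$C))
  invisible(x)
}

#' Convert an RFE elimination record to a ranked feature list
#'
#' @param ranking An `rfe_ranking`.
#' @param n_selected Subset size N to mark as selected (default 0; the DCV
#'   engine fills this in).
#' @return A [ranked_features()] list; `score` is the elimination round
#'   (later = better), best-ranked first.
#' @export
rfe_as_ranked <- function(ranking, n_selected = 0) {
  stopifnot(inherits(ranking, "rfe_ranking"))
  ord <- rev(seq_along(ranking$elimination_order))
  df <- tibble::tibble(
    protein_id = ranking$elimination_order[ord],
    score = ranking$round[ord],
    criterion = ranking$criterion[ord]
  )
  ranked_features(df, method = "svm_rfe", n_selected = n_selected)
}

#' Standardize features using training-set statistics
#'
#' Centers and scales columns of both matrices by the training columns' mean
#' and standard deviation (constant training columns are left centered only).
#'
#' @param train,test Samples x features matrices (test may be NULL).
#' @return List with `train`, `test`, `center`, `scale`.
#' @export
standardize_features <- function(train, test = NULL) {
  train <- as.matrix(train)
  ctr <- colMeans(train)
  scl <- apply(train, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  tr <- sweep(sweep(train, 2, ctr), 2, scl, "/")
  te <- if (!is.null(test)) {
    sweep(sweep(as.matrix(test)[, colnames(train), drop = FALSE], 2, ctr),
          2, scl, "/")
  }
  list(train = tr, test = te, center = ctr, scale = scl)
}
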