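#' Beta-binomial log-likelihood for one protein
#'
#' Spectral counts for a protein are modeled as successes out of the per-run
#' total spectra T_j. The beta-binomial extends the binomial with an
#' overdispersion parameter theta: the per-run success probability is drawn
#' from a Beta(alpha, beta) with alpha = pi/theta, beta = (1 - pi)/theta, so
#' the mean stays pi while the variance inflates. As theta -> 0 the model
#' collapses to Binomial(T_j, pi).
#'
#' @param y Integer vector of per-run counts for one protein.
#' @param size Integer vector of per-run total spectra T_j (same length).
#' @param pi Success proportion in (0,1) (0 or 1 allowed only for degenerate
#'   all-zero / all-full data).
#' @param theta Overdispersion >= 0; `theta = 0` gives the exact binomial
#'   log-likelihood.
#' @return Sum over runs of the log probability mass.
#' @export
betabinom_loglik <- function(y, size, pi, theta) {
  if (length(size) == 1) size <- rep(size, length(y))
  stopifnot(length(y) == length(size), theta >= 0, pi >= 0, pi <= 1)
  if (any(y > size)) stop("count exceeds run total (y > size)")
  if (theta == 0) return(sum(dbinom(y, size, pi, log = TRUE)))
  if (pi == 0) return(if (all(y == 0)) 0 else -Inf)
  if (pi == 1) return(if (all(y == size)) 0 else -Inf)
  a <- pi / theta
  b <- (1 - pi) / theta
  # large shape parameters (theta -> 0) trip lgamma's underflow warning for a
  # correction term that is vanishingly small; the value itself is fine
  suppressWarnings(
    sum(lchoose(size, y) + lbeta(y + a, size - y + b) - lbeta(a, b)))
}

# negative log-likelihood on transformed scale; grp maps runs to classes
.bb_negll <- function(par, y, size, grp, ngroup) {
  pis <- plogis(par[seq_len(ngroup)])
  theta <- exp(par[ngroup + 1])
  ll <- 0
  for (g in seq_len(ngroup)) {
    idx <- grp == g
    ll <- ll + betabinom_loglik(y[idx], size[idx], pis[g], theta)
  }
  if (!is.finite(ll)) return(1e10)
  -ll
}

.bb_fit <- function(y, size, grp, ngroup, starts) {
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, .bb_negll, y = y, size = size, grp = grp, ngroup = ngroup,
            method = "BFGS", control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(
        optim(s, .bb_negll, y = y, size = size, grp = grp, ngroup = ngroup,
              method = "Nelder-Mead", control = list(maxit = 500)),
        error = function(e) NULL)
    }
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  best
}

# logit with a continuity guard for empty/full proportions
.safe_logit <- function(p, lo = 1e-8) qlogis(pmin(pmax(p, lo), 1 - lo))

#' Beta-binomial likelihood-ratio test for one protein
#'
#' Fits by maximum likelihood a null model (one shared proportion pi and one
#' overdispersion theta across all runs) and an alternative with a
#' class-specific proportion pi_g (shared theta), then compares them with the
#' likelihood-ratio statistic Lambda = 2(l_alt - l_null), referred to a
#' chi-square with G - 1 degrees of freedom. Trials are the per-run total
#' spectra, so the test asks whether a protein's spectral fraction differs
#' between classes beyond overdispersed sampling noise.
#'
#' @param x A `spectral_counts` object (use the filtered matrix).
#' @param protein_id Protein to test.
#' @return A one-row tibble: `protein_id`, one `pi_<class>` column per class,
#'   `theta`, `lrt_stat`, `df`, `p_value`, `converged`.
#' @export
betabinom_lrt <- function(x, protein_id) {
  stopifnot(inherits(x, "spectral_counts"))
  if (!protein_id %in% rownames(x$counts)) stop("unknown protein: ", protein_id)
  y <- x$counts[protein_id, ]
  size <- x$run_totals
  res <- .bb_lrt_one(y, size, x$annotation$class)
  tibble::as_tibble(c(list(protein_id = protein_id), res))
}

.bb_lrt_one <- function(y, size, class_labels) {
  classes <- sort(unique(class_labels))
  G <- length(classes)
  grp <- match(class_labels, classes)
  pooled <- sum(y) / sum(size)
  per_class <- vapply(seq_len(G), function(g)
    sum(y[grp == g]) / sum(size[grp == g]), numeric(1))
  theta_starts <- log(c(1e-4, 0.05))

  null_starts <- lapply(theta_starts, function(lt) c(.safe_logit(pooled), lt))
  null_fit <- .bb_fit(y, size, rep(1L, length(y)), 1L, null_starts)

  alt_starts <- c(
    lapply(theta_starts, function(lt) c(.safe_logit(per_class), lt)),
    list(c(rep(.safe_logit(pooled), G),
           if (is.null(null_fit)) log(0.05) else null_fit$par[2]))
  )
  alt_fit <- .bb_fit(y, size, grp, G, alt_starts)

  converged <- !is.null(null_fit) && !is.null(alt_fit) &&
    null_fit$convergence == 0 && alt_fit$convergence == 0
  if (is.null(null_fit) || is.null(alt_fit)) {
    out <- as.list(setNames(rep(NA_real_, G), paste0("pi_", classes)))
    return(c(out, list(theta = NA_real_, lrt_stat = NA_real_, df = G - 1,
                       p_value = NA_real_, converged = FALSE)))
  }
  # the null is nested in the alternative: never report l_alt < l_null
  ll_null <- -null_fit$value
  ll_alt <- max(-alt_fit$value, ll_null)
  lambda <- max(0, 2 * (ll_alt - ll_null))
  pis <- plogis(alt_fit$par[seq_len(G)])
  out <- as.list(setNames(pis, paste0("pi_", classes)))
  c(out, list(theta = exp(alt_fit$par[G + 1]), lrt_stat = lambda,
              df = G - 1L,
              p_value = pchisq(lambda, df = G - 1, lower.tail = FALSE),
              converged = converged))
}

#' Beta-binomial test across all proteins
#'
#' Applies [betabinom_lrt()] to every protein in the matrix.
#'
#' @param x A `spectral_counts` object.
#' @return A tibble with one row per protein (columns as in
#'   [betabinom_lrt()]), in matrix row order.
#' @export
betabinom_test <- function(x) {
  stopifnot(inherits(x, "spectral_counts"))
  size <- x$run_totals
  cls <- x$annotation$class
  rows <- lapply(rownames(x$counts), function(p) {
    res <- .bb_lrt_one(x$counts[p, ], size, cls)
    tibble::as_tibble(c(list(protein_id = p), res))
  })
  dplyr::bind_rows(rows)
}

#' Rank proteins by the beta-binomial test
#'
#' Orders proteins by ascending p-value (ties broken by descending LRT
#' statistic, then protein id) and selects all with p below `alpha`.
#'
#' @param results Output of [betabinom_test()].
#' @param alpha Selection threshold on the raw p-value (default 0.05). Set
#'   `adjust = "BH"` to select on Benjamini-Hochberg adjusted p-values
#'   instead.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A [ranked_features()] list with `score` = p-value.
#' @export
betabinom_rank <- function(results, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  p_sel <- if (adjust == "BH") p.adjust(results$p_value, "BH") else results$p_value
  ord <- order(results$p_value, -results$lrt_stat, results$protein_id)
  df <- tibble::tibble(protein_id = results$protein_id[ord],
                       score = results$p_value[ord],
                       lrt_stat = results$lrt_stat[ord])
  ranked_features(df, method = "betabinom",
                  n_selected = sum(p_sel < alpha, na.rm = TRUE))
}

#' One-way ANOVA per protein
#'
#' The classical univariate baseline: a fixed-effects one-way ANOVA of the
#' (raw) spectral counts on the class factor, one F test per protein,
#' selected at p below `alpha` and ranked by ascending p-value. Degenerate
#' proteins with no variance at all are assigned p = 1 by convention.
#'
#' @param x A `spectral_counts` object.
#' @param alpha Selection threshold (default 0.05).
#' @return A [ranked_features()] list with `score` = p-value and an
#'   `f_stat` column.
#' @export
anova_per_protein <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "spectral_counts"))
  g <- factor(x$annotation$class)
  if (any(table(g) < 2)) stop("every class needs >= 2 runs for ANOVA")
  res <- apply(x$counts, 1, function(y) {
    if (var(y) == 0) return(c(f = 0, p = 1))
    fit <- summary(aov(y ~ g))[[1]]
    f <- fit[["F value"]][1]
    p <- fit[["Pr(>F)"]][1]
    if (!is.finite(f)) { # zero within-class variance, unequal means
      f <- Inf; p <- 0
    }
    c(f = f, p = p)
  })
  ord <- order(res["p", ], -res["f", ], rownames(x$counts))
  df <- tibble::tibble(protein_id = rownames(x$counts)[ord],
                       score = unname(res["p", ord]),
                       f_stat = unname(res["f", ord]))
  ranked_features(df, method = "anova",
                  n_selected = sum(res["p", ] < alpha))
}
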