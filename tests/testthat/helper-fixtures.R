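# small deterministic count matrices used across tests

toy_counts <- function() {
  m <- matrix(c(1, 0,
                2, 2,
                5, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("P1", "P2", "P3"), c("r1", "r2")))
  m
}

# 2 classes x 3 runs, 6 proteins with assorted profiles
small_counts <- function() {
  m <- matrix(c(10, 12,  9,  1,  0,  2,
                 0,  1,  0,  8,  9, 11,
                 5,  5,  5,  5,  5,  5,
                 0,  0,  0,  0,  0,  0,
                20, 18, 22, 21, 19, 20,
                 3,  0,  1,  0,  2,  1), nrow = 6, byrow = TRUE,
              dimnames = list(paste0("P", 1:6),
                              c("a1", "a2", "a3", "b1", "b2", "b3")))
  spectral_counts(m, data.frame(run_id = colnames(m),
                                class = rep(c("A", "B"), each = 3),
                                replicate = rep(1:3, 2)))
}

# 3-class x n_per design with planted effects in two classes so that all
# three classes are mutually separable
planted_counts <- function(n_proteins = 150, n_planted = 20, fold = 10,
                           seed = 11, theta_sim = 0.001, n_per = 6,
                           total_range = c(7500, 9500)) {
  classes <- setNames(rep(n_per, 3), c("carcinoma", "melanoma", "non_cancerous"))
  # pick detectable proteins: regenerate with planting on the upper half of
  # the baseline abundance drawn under the same seed
  base_spec <- synthetic_spec(n_proteins, classes = classes,
                              total_range = total_range,
                              theta_sim = theta_sim, seed = seed)
  baseline <- generate_counts(base_spec)$baseline
  # plant on moderately abundant proteins: skip the top 10% (which dominate
  # the per-run composition, so renormalization would compress their fold
  # effect) and stay above the median (so the low-count filter keeps them)
  rks <- order(-baseline)
  eligible <- rks[seq(ceiling(0.1 * n_proteins),
                      floor(0.5 * n_proteins))]
  idx <- sort(eligible[seq_len(n_planted)])
  half <- n_planted %/% 2
  planted <- data.frame(
    protein = idx,
    class = rep(c("carcinoma", "melanoma"), c(half, n_planted - half)),
    fold = fold)
  spec <- synthetic_spec(n_proteins, classes = classes,
                         total_range = total_range,
                         planted = planted, theta_sim = theta_sim,
                         seed = seed)
  generate_counts(spec)
}

# independent beta-binomial log-mass via explicit log-gamma terms
bb_logmass_oracle <- function(y, size, pi, theta) {
  a <- pi / theta
  b <- (1 - pi) / theta
  sum(lgamma(size + 1) - lgamma(y + 1) - lgamma(size - y + 1) +
        lgamma(y + a) + lgamma(size - y + b) - lgamma(size + a + b) +
        lgamma(a + b) - lgamma(a) - lgamma(b))
}

# grid + 1-D-search maximum-likelihood oracle for the beta-binomial LRT:
# profile the likelihood over theta (coarse log grid, then golden search
# around the best grid point), optimizing each class proportion by golden
# search given theta — independent of the package's joint BFGS fit
bb_lrt_oracle <- function(y, size, labels,
                          theta_grid = c(0, exp(seq(log(1e-6), log(2),
                                                    length.out = 60)))) {
  classes <- sort(unique(labels))
  ll_class <- function(idx, theta) {
    f <- function(p) betabinom_loglik(y[idx], size[idx], p, theta)
    optimize(f, c(1e-9, 1 - 1e-9), maximum = TRUE, tol = 1e-12)$objective
  }
  profile_ll <- function(theta, groups) {
    sum(vapply(groups, function(idx) ll_class(idx, theta), numeric(1)))
  }
  best_theta <- function(groups) {
    vals <- vapply(theta_grid, profile_ll, numeric(1), groups = groups)
    i <- which.max(vals)
    best <- vals[i]
    # refine on the log scale around the best positive grid point
    lo <- theta_grid[max(2, i - 1)]
    hi <- theta_grid[min(length(theta_grid), i + 1)]
    if (hi > lo) {
      opt <- optimize(function(lt) profile_ll(exp(lt), groups),
                      c(log(lo), log(hi)), maximum = TRUE, tol = 1e-10)
      best <- max(best, opt$objective)
    }
    best
  }
  groups_null <- list(seq_along(y))
  groups_alt <- lapply(classes, function(cl) which(labels == cl))
  lambda <- max(0, 2 * (best_theta(groups_alt) - best_theta(groups_null)))
  pchisq(lambda, df = length(classes) - 1, lower.tail = FALSE)
}
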