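test_that("optimal-subset rules follow each method's selection criterion", {
  rec <- tibble::tibble(N = c(5, 10, 20, 40),
                        error = c(0.5, 0.1, 0.1, 0.2))
  expect_equal(select_optimal_subset(rec, "svm_rfe")$N, 10)

  rec2 <- tibble::tibble(N = c(10, 20), error = c(0.2, 0.2),
                         prob_sum = c(9.1, 9.7))
  expect_equal(select_optimal_subset(rec2, "nsc")$N, 20)

  expect_equal(select_optimal_subset(tibble::tibble(N = 7, error = 0.3),
                                     "svm_rfe")$N, 7)
})

test_that("confusion-matrix metrics match one-vs-rest definitions", {
  # perfect prediction
  perfect <- diag(c(6, 6, 6))
  rownames(perfect) <- colnames(perfect) <- c("ca", "me", "nc")
  pm <- performance_metrics(perfect)
  expect_equal(pm$accuracy, 1)
  expect_true(all(pm$per_class$sensitivity == 1))
  expect_true(all(pm$per_class$specificity == 1))

  # 18 samples, one carcinoma run misassigned to non-cancerous
  conf <- matrix(c(5, 0, 1,
                   0, 6, 0,
                   0, 0, 6), nrow = 3, byrow = TRUE,
                 dimnames = list(c("carcinoma", "melanoma", "non_cancerous"),
                                 c("carcinoma", "melanoma", "non_cancerous")))
  pm <- performance_metrics(conf)
  expect_equal(pm$per_class$sensitivity[1], 5 / 6)      # 83.3%
  expect_equal(pm$per_class$specificity[3], 11 / 12)    # 91.7%
  expect_equal(pm$accuracy, 17 / 18)

  # single off-diagonal cell
  one_off <- diag(c(4, 4, 4)); one_off[1, 2] <- 1; one_off[1, 1] <- 3
  expect_equal(performance_metrics(one_off)$accuracy, 11 / 12)
})

test_that("metrics agree with a brute-force enumeration oracle", {
  set.seed(41)
  for (i in 1:100) {
    conf <- matrix(rpois(9, 3), 3, 3,
                   dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
    if (sum(conf) == 0) next
    pm <- performance_metrics(conf)
    # expand to individual (truth, prediction) records and count cases
    truth <- rep(rep(rownames(conf), each = 3), as.vector(t(conf)))
    pred <- rep(rep(colnames(conf), times = 3), as.vector(t(conf)))
    for (k in seq_len(3)) {
      cl <- rownames(conf)[k]
      tp <- sum(truth == cl & pred == cl)
      fn <- sum(truth == cl & pred != cl)
      tn <- sum(truth != cl & pred != cl)
      fp <- sum(truth != cl & pred == cl)
      sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
      spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
      expect_equal(pm$per_class$sensitivity[k], sens)
      expect_equal(pm$per_class$specificity[k], spec)
    }
    expect_equal(pm$accuracy, mean(truth == pred))
  }
})

make_planted_sc <- function() {
  # one protein with widely separated class means, 17 noise proteins
  set.seed(51)
  base <- matrix(rpois(17 * 18, 50), 17, 18)
  sig <- c(rep(20L, 6), rep(300L, 6), rep(1200L, 6))
  m <- rbind(matrix(as.integer(base), 17, 18), sig)
  rownames(m) <- c(sprintf("N%02d", 1:17), "SIG")
  colnames(m) <- paste0(rep(c("ca", "me", "nc"), each = 6), 1:6)
  spectral_counts(m, data.frame(run_id = colnames(m),
                                class = rep(c("ca", "me", "nc"), each = 6),
                                replicate = rep(1:6, 3)))
}

test_that("DCV finds a planted perfect separator with zero outer error", {
  x <- make_planted_sc()
  rep_nsc <- run_dcv(x, dcv_config("nsc", seed = 5))
  expect_equal(rep_nsc$outer_error, 0)
  expect_lte(rep_nsc$optimal_N, 3)
  expect_true("SIG" %in% selected_ids(rep_nsc$selected_features))
  expect_equal(rep_nsc$accuracy + rep_nsc$outer_error, 1)

  g <- glance(rep_nsc)
  expect_equal(g$accuracy, 1)
  expect_equal(nrow(tidy(rep_nsc)), 18)
})

test_that("DCV under permuted labels has chance-level error", {
  x <- make_planted_sc()
  cfg <- dcv_config("nsc", seed = 1, delta_grid_size = 8, inner_folds = 3)
  set.seed(61)
  errs <- vapply(1:20, function(i) {
    xp <- x
    xp$annotation$class <- sample(xp$annotation$class)
    run_dcv(xp, cfg)$outer_error
  }, numeric(1))
  expect_gt(mean(errs), 2 / 3 - 0.12)
})

test_that("reports are deterministic and inner tuning ignores outer-test data", {
  x <- make_planted_sc()
  cfg <- dcv_config("nsc", seed = 17, delta_grid_size = 10)
  r1 <- run_dcv(x, cfg)
  r2 <- run_dcv(x, cfg)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))

  # replace the counts of fold 1's held-out runs with arbitrary values:
  # fold 1's tuning decision must not move
  fold1_runs <- r1$outer$run_id[r1$outer$fold == 1]
  xmod <- x
  xmod$counts[, fold1_runs] <- xmod$counts[nrow(xmod$counts):1, fold1_runs]
  xmod$run_totals <- colSums(xmod$counts)
  r3 <- run_dcv(xmod, cfg)
  expect_identical(r1$fold_tuning[r1$fold_tuning$fold == 1, ],
                   r3$fold_tuning[r3$fold_tuning$fold == 1, ])
  expect_identical(r3$outer$run_id[r3$outer$fold == 1], fold1_runs)
})

test_that("SVM-RFE DCV recovers a planted separator", {
  x <- make_planted_sc()
  cfg <- dcv_config("svm_rfe", seed = 5, inner_folds = 3,
                    C_grid = c(0.1, 1, 10), candidate_N = c(1, 2, 3, 5, 10))
  rep_svm <- run_dcv(x, cfg)
  expect_lte(rep_svm$outer_error, 1 / 18 + 1e-9)
  expect_true("SIG" %in% selected_ids(rep_svm$selected_features))
})

test_that("protein class association points to the enriched class", {
  m <- matrix(c(0L, 0L, 0L, 0L, 30L, 40L, 35L, 28L, 0L, 1L, 0L, 0L,
                5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("MEL", "FLAT"),
                              paste0(rep(c("ca", "me", "nc"), each = 4), 1:4)))
  x <- spectral_counts(m, data.frame(run_id = colnames(m),
                                     class = rep(c("ca", "me", "nc"), each = 4),
                                     replicate = rep(1:4, 3)))
  assoc <- assign_protein_class(x, c("MEL", "FLAT"))
  expect_equal(assoc$class[assoc$protein_id == "MEL"], "me")
  expect_equal(assoc$direction[assoc$protein_id == "MEL"], "up")
  # FLAT has no spread in counts but relative abundances differ slightly
  # across runs only through totals; a protein with exactly equal class
  # means is flagged ambiguous
  m2 <- rbind(m, EQ = rep(c(2L, 4L, 2L, 4L), 3))
  x2 <- spectral_counts(m2, x$annotation)
  x2$run_totals[] <- 100L
  assoc2 <- assign_protein_class(x2, "EQ")
  expect_equal(assoc2$direction, "ambiguous")

  # planted carcinoma-enriched proteins are assigned to carcinoma
  g <- planted_counts(n_proteins = 120, n_planted = 20, fold = 10, seed = 77)
  ca_ids <- g$truth$protein_id[g$truth$class == "carcinoma"]
  assoc3 <- assign_protein_class(filter_low_counts(g$counts), ca_ids)
  expect_gte(mean(assoc3$class == "carcinoma", na.rm = TRUE), 0.9)
})

test_that("selected-set overlap with the planted truth grows with effect size", {
  overlaps <- vapply(c(1.5, 3, 10), function(fold) {
    g <- planted_counts(n_proteins = 80, n_planted = 16, fold = fold,
                        seed = 99)
    xf <- filter_low_counts(g$counts)
    rep1 <- run_dcv(xf, dcv_config("nsc", seed = 3, delta_grid_size = 10,
                                   inner_folds = 3))
    sel <- selected_ids(rep1$selected_features)
    length(intersect(sel, g$truth$protein_id)) / nrow(g$truth)
  }, numeric(1))
  expect_true(all(diff(overlaps) >= -1e-9))
})
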