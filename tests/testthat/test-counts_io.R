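test_that("reading a TSV pair validates counts and computes run totals", {
  d <- withr::local_tempdir()
  m <- toy_counts()
  write.table(data.frame(protein_id = rownames(m), m, check.names = FALSE),
              file.path(d, "counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(run_id = c("r1", "r2"), class = c("A", "B")),
              file.path(d, "ann_bad.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  # a class with a single run violates the design invariant
  expect_error(read_counts(file.path(d, "counts.tsv"),
                           file.path(d, "ann_bad.tsv")),
               ">= 2 runs")

  m2 <- rbind(m, m[1, , drop = FALSE])  # duplicate protein id
  expect_error(spectral_counts(m2, data.frame(run_id = c("r1", "r2"),
                                              class = c("A", "A"))),
               "P1")

  m4 <- cbind(m, r3 = c(0L, 1L, 1L), r4 = c(2L, 0L, 1L))
  write.table(data.frame(protein_id = rownames(m4), m4, check.names = FALSE),
              file.path(d, "counts4.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(run_id = c("r1", "r2", "r3", "r4"),
                         class = c("A", "A", "B", "B"),
                         replicate = c(1, 2, 1, 2)),
              file.path(d, "ann.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  x <- read_counts(file.path(d, "counts4.tsv"), file.path(d, "ann.tsv"))
  expect_equal(unname(x$run_totals), c(8, 5, 2, 3))
  expect_equal(rownames(x$counts), c("P1", "P2", "P3"))

  # negative / non-integer cells are format errors naming the cell
  mneg <- m; mneg[2, 1] <- -1
  expect_error(spectral_counts(mneg, data.frame(run_id = c("r1", "r2"),
                                                class = c("A", "A"))),
               "P2.*r1")

  # round trip preserves layout
  write_counts(x, file.path(d, "out.tsv"), file.path(d, "out_ann.tsv"))
  x2 <- read_counts(file.path(d, "out.tsv"), file.path(d, "out_ann.tsv"))
  expect_identical(x2$counts, x$counts)

  # tidy long form has one row per cell
  long <- tidy(x)
  expect_equal(nrow(long), 12)
  expect_equal(sum(long$count), sum(m4))
})

test_that("low-count filter discards proteins at or below the threshold", {
  m <- matrix(c(0, 0, 0,  1, 1, 0,  2, 1, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("P1", "P2", "P3"), c("r1", "r2", "r3")))
  # row totals 0, 2, 3: the <=2 rule keeps only the total-3 protein
  ann <- data.frame(run_id = colnames(m), class = c("A", "A", "A"))
  ann2 <- rbind(ann, data.frame(run_id = "r4", class = "B"))
  m2 <- cbind(m, r4 = c(0, 0, 0))
  ann2$class <- c("A", "A", "B", "B")
  x <- spectral_counts(m2, ann2)
  xf <- filter_low_counts(x, threshold = 2)
  expect_equal(rownames(xf$counts), "P3")
  expect_equal(unname(xf$run_totals), c(2, 1, 0, 0))

  # all-zero matrix: everything removed, with a warning not an error
  xz <- spectral_counts(matrix(0L, 2, 4,
                               dimnames = list(c("Q1", "Q2"),
                                               colnames(m2))), ann2)
  expect_warning(xf0 <- filter_low_counts(xz), "all proteins")
  expect_equal(nrow(xf0$counts), 0)

  # idempotence
  expect_identical(filter_low_counts(xf)$counts, xf$counts)

  # max aggregator keeps anything with a single run above threshold
  xm <- filter_low_counts(x, threshold = 1, aggregator = "max")
  expect_equal(rownames(xm$counts), "P3")
})

test_that("z-scoring normalizes rows and respects column permutations", {
  z <- zscore_rows(matrix(c(1, 2, 3), 1, dimnames = list("P1", NULL)))
  expect_equal(unname(z[1, ]), c(-1, 0, 1))
  zc <- zscore_rows(matrix(c(4, 4, 4), 1, dimnames = list("P1", NULL)))
  expect_equal(unname(zc[1, ]), c(0, 0, 0))

  set.seed(5)
  m <- matrix(rpois(60, 8), 6, 10,
              dimnames = list(paste0("P", 1:6), paste0("r", 1:10)))
  z <- zscore_rows(m)
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-12 | apply(z, 1, sd) == 0))
  perm <- sample(10)
  expect_equal(zscore_rows(m[, perm]), zscore_rows(m)[, perm])
})

test_that("relative abundance gives unit column sums and flags empty runs", {
  x <- small_counts()
  ra <- relative_abundance(x)
  expect_true(all(abs(colSums(ra) - 1) < 1e-12))
  one <- subset_proteins(x, "P5")
  expect_true(all(relative_abundance(one) == 1))

  m <- x$counts; m[, "a1"] <- 0L
  xz <- spectral_counts(m, x$annotation)
  expect_error(relative_abundance(xz), "a1")
})

test_that("signed fold change follows the zero-replacement convention", {
  m <- matrix(c(3, 3, 0, 0,    # target mean 3, reference 0 -> FC 3
                2, 2, 2, 2,    # equal means -> FC 1
                1, 1, 2, 2),   # target 1, reference 2 -> FC -2
              nrow = 3, byrow = TRUE,
              dimnames = list(c("P1", "P2", "P3"),
                              c("t1", "t2", "c1", "c2")))
  x <- spectral_counts(m, data.frame(run_id = colnames(m),
                                     class = rep(c("T", "C"), each = 2)))
  fc <- fold_change(x, "T", "C")
  expect_equal(fc$fold_change, c(3, 1, -2))
  expect_equal(fc$above_threshold, c(TRUE, FALSE, TRUE))

  # antisymmetry when both means are nonzero and unequal
  fc_rev <- fold_change(x, "C", "T")
  expect_equal(fc_rev$fold_change[3], 2)
  expect_equal(fc$fold_change[3], -fc_rev$fold_change[3])
})
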