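test_that("Pearson distance behaves at its extremes", {
  X <- cbind(v = c(1, 2, 3), same = c(1, 2, 3), neg = c(-1, -2, -3),
             scaled = c(2, 4, 6), flat = c(5, 5, 5))
  d <- pearson_distance(X, axis = "samples")
  expect_equal(d["v", "v"], 0)
  expect_equal(d["v", "same"], 0)
  expect_equal(d["v", "neg"], 2)
  expect_equal(d["v", "scaled"], 0)
  expect_equal(d["v", "flat"], 1)   # constant vector: treated as uncorrelated
  expect_true(isSymmetric(d))
})

test_that("hierarchical clustering merges by hand-computable heights", {
  d <- matrix(c(0, 1, 10,
                1, 0, 10,
                10, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- hierarchical_cluster(d, "average")
  expect_equal(hc$height, c(1, 10))

  # two tight groups far apart separate at the first cut
  set.seed(15)
  X <- cbind(matrix(rnorm(20, 0, 0.1), 5), matrix(rnorm(20, 8, 0.1), 5))
  colnames(X) <- paste0("s", 1:8)
  hc2 <- hierarchical_cluster(as.matrix(dist(t(X))))
  grp <- cutree(hc2, 2)
  expect_equal(length(unique(grp[1:4])), 1)
  expect_equal(length(unique(grp[5:8])), 1)
  expect_true(grp[1] != grp[8])

  # permuting the input leaves merge heights unchanged
  perm <- c(3, 1, 2)
  hc3 <- hierarchical_cluster(d[perm, perm], "average")
  expect_equal(hc3$height, hc$height)
})

test_that("neighbor joining recovers additive trees exactly", {
  # quartet with internal edge 1 and pendants A=1, B=2, C=3, D=1
  d <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  path <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(path, d, tolerance = 1e-12)
  expect_equal(sum(tr$edge.length), 8)   # 1+2+3+1 pendant + 1 internal

  # three equidistant points: a star with unit pendants
  d3 <- matrix(2, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  diag(d3) <- 0
  t3 <- nj_tree(d3)
  expect_equal(sort(unname(t3$edge.length)), c(1, 1, 1))

  # two samples: a single split of the distance
  d2 <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("u", "v"), c("u", "v")))
  t2 <- nj_tree(d2)
  expect_equal(unname(ape::cophenetic.phylo(t2)["u", "v"]), 4)
})

test_that("reconstruction round-trips random additive trees and ignores taxon order", {
  set.seed(33)
  for (i in 1:10) {
    ref <- ape::rtree(6, br = function(n) runif(n, 0.5, 3))
    d <- ape::cophenetic.phylo(ref)
    tr <- nj_tree(d)
    back <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
    expect_equal(back, d, tolerance = 1e-9)
    perm <- sample(6)
    tr2 <- nj_tree(d[perm, perm])
    back2 <- ape::cophenetic.phylo(tr2)[rownames(d), colnames(d)]
    expect_equal(back2, d, tolerance = 1e-9)
  }
})

test_that("silhouettes match the direct formula and a library cross-check", {
  # 4 points, 2 classes, hand-specified distances
  d <- matrix(c(0, 1, 4, 5,
                1, 0, 3, 6,
                4, 3, 0, 2,
                5, 6, 2, 0), 4, 4,
              dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  lab <- c("g1", "g1", "g2", "g2")
  sil <- silhouette_from_data(d, lab)
  # direct formula, written out
  a <- c(1, 1, 2, 2)
  b <- c(mean(c(4, 5)), mean(c(3, 6)), mean(c(4, 3)), mean(c(5, 6)))
  expect_equal(sil$samples$a, a)
  expect_equal(sil$samples$b, b)
  expect_equal(sil$samples$silhouette, (b - a) / pmax(a, b))
  expect_equal(sil$overall, mean((b - a) / pmax(a, b)))
  expect_true(all(abs(sil$samples$silhouette) <= 1))

  # independent implementation (cluster::silhouette)
  ref <- cluster::silhouette(as.integer(factor(lab)), dmatrix = d)
  expect_equal(sil$samples$silhouette, unname(ref[, "sil_width"]))

  # tight, well-separated clusters approach SC = 1; swapped labels go negative
  eps <- 0.01
  dd <- matrix(1 / eps, 6, 6,
               dimnames = list(paste0("t", 1:6), paste0("t", 1:6)))
  dd[1:3, 1:3] <- eps; dd[4:6, 4:6] <- eps
  diag(dd) <- 0
  good <- rep(c("p", "q"), each = 3)
  expect_gt(silhouette_from_data(dd, good)$overall, 0.99)
  swapped <- c("p", "q", "q", "q", "p", "p")
  expect_lt(silhouette_from_data(dd, swapped)$overall, 0)

  # singleton class scores zero
  s1 <- silhouette_from_data(d, c("g1", "g1", "g1", "solo"))
  expect_equal(s1$samples$silhouette[4], 0)
})

test_that("tree silhouettes equal data silhouettes for additive distances", {
  set.seed(44)
  ref <- ape::rtree(8, br = function(n) runif(n, 0.5, 2))
  d <- ape::cophenetic.phylo(ref)
  lab <- setNames(rep(c("u", "v"), 4), rownames(d))
  tr <- nj_tree(d)
  expect_equal(silhouette_from_tree(tr, lab)$overall,
               silhouette_from_data(d, lab[rownames(d)])$overall,
               tolerance = 1e-9)

  # composition: tree silhouette is the data silhouette of path distances
  lab2 <- setNames(sample(c("u", "v", "w"), 8, replace = TRUE),
                   ref$tip.label)
  while (length(unique(lab2)) < 2) {
    lab2 <- setNames(sample(c("u", "v", "w"), 8, replace = TRUE),
                     ref$tip.label)
  }
  dp <- ape::cophenetic.phylo(ref)
  expect_equal(silhouette_from_tree(ref, lab2)$overall,
               silhouette_from_data(dp, lab2[rownames(dp)])$overall)

  # two class-pure clades joined by a long edge score near 1
  clean <- ape::read.tree(text = "((a1:0.1,a2:0.1):5,(b1:0.1,b2:0.1):5);")
  lab3 <- setNames(c("A", "A", "B", "B"), c("a1", "a2", "b1", "b2"))
  expect_gt(silhouette_from_tree(clean, lab3)$overall, 0.9)
})

test_that("feature selection improves the silhouette on planted data", {
  g <- planted_counts(n_proteins = 200, n_planted = 30, fold = 10, seed = 21)
  xf <- filter_low_counts(g$counts)
  labels <- setNames(xf$annotation$class, xf$annotation$run_id)
  pre <- cluster_diagnostics(xf, labels)
  planted_present <- intersect(g$truth$protein_id, rownames(xf$counts))
  post <- cluster_diagnostics(subset_proteins(xf, planted_present), labels)
  expect_gte(post$sc_data$overall, pre$sc_data$overall)
})
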