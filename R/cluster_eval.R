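#' Pearson correlation distance
#'
#' d = 1 - r between row vectors (samples or features), so d ranges over
#' [0, 2]: 0 for perfectly correlated profiles, 2 for perfectly
#' anti-correlated ones. A constant vector has undefined correlation; its
#' distance to every other vector is set to 1 (the uncorrelated value).
#'
#' @param X Numeric matrix.
#' @param axis `"samples"` (distance between columns, default) or
#'   `"features"` (between rows).
#' @return Symmetric distance matrix with zero diagonal, labeled by the
#'   corresponding dimnames.
#' @export
pearson_distance <- function(X, axis = c("samples", "features")) {
  axis <- match.arg(axis)
  M <- if (axis == "samples") as.matrix(X) else t(as.matrix(X))
  r <- suppressWarnings(cor(M))
  r[is.na(r)] <- 0          # constant vectors: treat as uncorrelated
  d <- 1 - r
  diag(d) <- 0
  d
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @param linkage `"average"` (default), `"complete"` or `"ward"` (Ward.D2).
#' @return An `hclust` object (merge heights, deterministic leaf order).
#' @export
hierarchical_cluster <- function(d, linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  meth <- if (linkage == "ward") "ward.D2" else linkage
  hclust(as.dist(d), method = meth)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining: repeatedly joins the pair minimizing
#' Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k), with the usual
#' branch-length estimates. For an additive distance matrix the leaf-to-leaf
#' path lengths of the reconstructed tree reproduce the input exactly.
#' Negative branch-length estimates (possible on non-additive, noisy data)
#' are clamped to zero with the deficit moved to the adjacent branch so
#' nearby leaf-to-leaf distances are preserved.
#'
#' @param d Symmetric distance matrix with sample ids as dimnames (>= 2).
#' @return An `ape::phylo` tree (unrooted, branch lengths >= 0).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n >= 2, isSymmetric(unname(d)))
  ids <- rownames(d) %||% paste0("t", seq_len(n))
  rownames(d) <- colnames(d) <- ids
  if (n == 2) {
    return(ape::read.tree(text = sprintf("(%s:%f,%s:%f);",
                                         ids[1], d[1, 2] / 2,
                                         ids[2], d[1, 2] / 2)))
  }
  tr <- ape::nj(as.dist(d))
  .clamp_negative_edges(tr)
}

# set negative edge lengths to 0 and shift the deficit onto the sibling
# edge(s) at the same node, preserving paths through the parent
.clamp_negative_edges <- function(tr) {
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    sib <- which(tr$edge[, 1] == parent & seq_len(nrow(tr$edge)) != e)
    if (length(sib) > 0) {
      tr$edge.length[sib] <- tr$edge.length[sib] + deficit
      tr$edge.length[sib] <- pmax(tr$edge.length[sib], 0)
    }
  }
  tr
}

#' Silhouette coefficients from a distance matrix and class labels
#'
#' For sample i with intra-class mean distance a(i) (self excluded) and
#' b(i) the smallest mean distance to any other class, the silhouette is
#' s(i) = (b(i) - a(i)) / max(a(i), b(i)), in [-1, 1]; members of singleton
#' classes score 0 by convention. The overall coefficient SC is the mean over
#' samples: values near 1 indicate compact, well-separated classes.
#'
#' @param d Symmetric distance matrix with sample ids.
#' @param labels Class per sample, aligned with the rows of `d`.
#' @return A list with `samples` (tibble: `sample_id`, `class`, `a`, `b`,
#'   `silhouette`) and `overall` (SC).
#' @export
silhouette_from_data <- function(d, labels) {
  d <- as.matrix(d)
  labels <- as.character(labels)
  n <- nrow(d)
  stopifnot(length(labels) == n, length(unique(labels)) >= 2)
  ids <- rownames(d) %||% paste0("s", seq_len(n))
  s <- a <- b <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    own <- own[own != i]
    if (length(own) == 0) { a[i] <- NA; b[i] <- NA; s[i] <- 0; next }
    a[i] <- mean(d[i, own])
    b[i] <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(d[i, labels == cl]), numeric(1)))
    s[i] <- if (max(a[i], b[i]) == 0) 0 else (b[i] - a[i]) / max(a[i], b[i])
  }
  list(samples = tibble::tibble(sample_id = ids, class = labels,
                                a = a, b = b, silhouette = s),
       overall = mean(s))
}

#' Silhouette coefficient from a tree
#'
#' Computes the leaf-to-leaf path-length distances (sum of branch lengths
#' along the connecting path, or edge counts with
#' `distance = "topological"`) and evaluates [silhouette_from_data()] on
#' them, so cluster quality can be read off the tree itself.
#'
#' @param tree An `ape::phylo` with labeled tips.
#' @param labels Class per tip; either named by tip label or aligned with
#'   `tree$tip.label`.
#' @param distance `"branch"` (default) or `"topological"`.
#' @return As [silhouette_from_data()].
#' @export
silhouette_from_tree <- function(tree, labels, distance = c("branch", "topological")) {
  distance <- match.arg(distance)
  t2 <- tree
  if (distance == "topological") t2$edge.length <- rep(1, nrow(t2$edge))
  d <- ape::cophenetic.phylo(t2)
  if (!is.null(names(labels))) labels <- labels[rownames(d)]
  else labels <- labels[match(rownames(d), tree$tip.label)]
  silhouette_from_data(d, labels)
}
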