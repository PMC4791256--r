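#' Jaccard similarity of two id sets
#'
#' @param a,b Character vectors (treated as sets).
#' @return |a intersect b| / |a union b|, defined as 1 when both are empty.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Jaccard similarity curve over top-k prefixes
#'
#' For each k, restricts every ranked list to its top-k proteins and averages
#' the pairwise Jaccard similarity over all list pairs; the curve shows how
#' concordant the methods' rankings are as deeper prefixes are compared. A
#' three-way coefficient (|intersection of all| / |union of all|) is also
#' reported.
#'
#' @param lists A (named) list of two or more [ranked_features()] objects.
#' @param k_max Largest prefix (default: shortest list length).
#' @return A tibble: `k`, `mean_jaccard`, `jaccard_all`, plus one
#'   `jaccard_<i>_<j>` column per list pair.
#' @export
jaccard_curve <- function(lists, k_max = NULL) {
  stopifnot(length(lists) >= 2)
  ids <- lapply(lists, function(l) l$protein_id)
  nm <- names(lists) %||% paste0("list", seq_along(lists))
  k_max <- k_max %||% min(lengths(ids))
  stopifnot(k_max <= min(lengths(ids)))
  prs <- combn(seq_along(ids), 2, simplify = FALSE)
  purrr::map_dfr(seq_len(k_max), function(k) {
    tops <- lapply(ids, utils::head, k)
    pj <- vapply(prs, function(pr) jaccard(tops[[pr[1]]], tops[[pr[2]]]),
                 numeric(1))
    row <- tibble::tibble(k = k, mean_jaccard = mean(pj),
                          jaccard_all = length(Reduce(intersect, tops)) /
                            length(Reduce(union, tops)))
    for (i in seq_along(prs)) {
      row[[paste0("jaccard_", nm[prs[[i]][1]], "_", nm[prs[[i]][2]])]] <- pj[i]
    }
    row
  })
}

#' Three-set Venn partition of selected feature subsets
#'
#' Partitions the union of three methods' selected subsets into the seven
#' exclusive Venn regions.
#'
#' @param lists A named list of exactly three [ranked_features()] objects (or
#'   plain character vectors when `use_selected = FALSE` semantics do not
#'   apply).
#' @param use_selected If TRUE (default) use each list's selected top-N
#'   subset; if FALSE use the full ranking.
#' @return A list with `regions` (tibble: membership flags per region and
#'   `size`) and `membership` (tibble: `protein_id` plus one logical column
#'   per input list).
#' @export
venn_partition <- function(lists, use_selected = TRUE) {
  stopifnot(length(lists) == 3)
  nm <- names(lists) %||% paste0("set", 1:3)
  sets <- lapply(lists, function(l) {
    if (inherits(l, "ranked_features")) {
      if (use_selected) selected_ids(l) else l$protein_id
    } else as.character(l)
  })
  all_ids <- sort(Reduce(union, sets))
  membership <- tibble::tibble(protein_id = all_ids)
  for (i in 1:3) membership[[nm[i]]] <- all_ids %in% sets[[i]]
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), 3))[-8, ]
  names(combos) <- nm
  regions <- purrr::map_dfr(seq_len(nrow(combos)), function(r) {
    inset <- rep(TRUE, length(all_ids))
    for (i in 1:3) {
      inset <- inset & (membership[[nm[i]]] == combos[r, nm[i]])
    }
    out <- tibble::as_tibble(combos[r, , drop = FALSE])
    out$size <- sum(inset)
    out
  })
  list(regions = regions, membership = membership)
}
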