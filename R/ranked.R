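#' Construct a ranked feature list
#'
#' A thin tibble subclass shared by all three selection methods: proteins in
#' rank order (best first) with the method's score and a selected-subset size
#' N (the top-N proteins form the method's candidate set).
#'
#' @param data Tibble with at least `protein_id` and `score`, ordered best
#'   first. A `rank` column is (re)written 1..nrow.
#' @param method Method name, e.g. `"betabinom"`, `"anova"`, `"nsc"`,
#'   `"svm_rfe"`.
#' @param n_selected Selected-subset size N, 0 <= N <= nrow(data).
#' @return A `ranked_features` tibble with columns `rank`, `protein_id`,
#'   `score`, `selected`, and attributes `method` and `n_selected`.
#' @export
ranked_features <- function(data, method, n_selected) {
  data <- tibble::as_tibble(data)
  stopifnot("protein_id" %in% names(data))
  if (anyDuplicated(data$protein_id)) stop("duplicate protein ids in ranking")
  n_selected <- as.integer(n_selected)
  stopifnot(n_selected >= 0, n_selected <= nrow(data))
  data$rank <- seq_len(nrow(data))
  data$selected <- data$rank <= n_selected
  data <- dplyr::relocate(data, "rank", "protein_id")
  structure(data,
            class = c("ranked_features", class(tibble::tibble())),
            method = method, n_selected = n_selected)
}

#' Selected subset of a ranked feature list
#'
#' @param x A `ranked_features` object.
#' @return Character vector of the top-N selected protein ids.
#' @export
selected_ids <- function(x) {
  stopifnot(inherits(x, "ranked_features"))
  x$protein_id[x$selected]
}

#' @export
print.ranked_features <- function(x, ...) {
  cat(sprintf("<ranked_features> method = %s, N = %d of %d\n",
              attr(x, "method"), attr(x, "n_selected"), nrow(x)))
  NextMethod()
}
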