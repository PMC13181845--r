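#' Continuous Tanimoto similarity and distance
#'
#' Generalisation of the Tanimoto (Jaccard) coefficient to real-valued
#' descriptor vectors:
#' \deqn{T(a,b) = \frac{\langle a,b\rangle}{\|a\|^2 + \|b\|^2 -
#'   \langle a,b\rangle}}
#' with distance \eqn{1 - T}. Intended for z-scored descriptor vectors; for
#' vectors with negative components the value can leave \[0, 1\] and is
#' reported as computed, never clipped.
#'
#' @param a,b Numeric vectors of equal length.
#' @return The similarity (or distance) as a single numeric value. Errors
#'   when both vectors are all-zero (0/0 undefined).
#' @export
tanimoto_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  ab <- sum(a * b)
  denom <- sum(a * a) + sum(b * b) - ab
  if (denom == 0 && ab == 0) {
    stop_glio("Tanimoto undefined for two all-zero vectors", "input_error")
  }
  ab / denom
}

#' @rdname tanimoto_similarity
#' @export
tanimoto_distance <- function(a, b) 1 - tanimoto_similarity(a, b)

# All pairwise continuous-Tanimoto distances between rows of x and rows of y
# (or within x when y is NULL), vectorised through the Gram matrix.
tanimoto_distance_matrix <- function(x, y = NULL) {
  x <- as.matrix(x)
  y <- if (is.null(y)) x else as.matrix(y)
  g <- x %*% t(y)
  nx <- rowSums(x^2)
  ny <- rowSums(y^2)
  denom <- outer(nx, ny, "+") - g
  1 - g / denom
}

#' Summarise pairwise Tanimoto distances within a compound set
#'
#' Diversity diagnostic over a feature matrix (typically z-scored
#' descriptors): mean, standard deviation and a histogram of all pairwise
#' continuous-Tanimoto distances. The pair count follows the declared
#' convention — `n(n-1)` ordered distinct pairs (each unordered pair counted
#' in both directions) or `n(n-1)/2` unordered; the mean and sd are identical
#' under both.
#'
#' @param m Feature matrix.
#' @param rows Optional row subset (indices or rownames).
#' @param pairing `"ordered_distinct"` (default) or `"unordered_distinct"`.
#' @param breaks Histogram break specification passed to [graphics::hist()].
#' @return A list of class `similarity_summary`: `pair_count`, `mean`, `sd`,
#'   `histogram` (a `histogram` object), `pairing`, `n_compounds`.
#' @export
pairwise_distance_summary <- function(m, rows = NULL,
                                      pairing = c("ordered_distinct",
                                                  "unordered_distinct"),
                                      breaks = 30) {
  pairing <- match.arg(pairing)
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  n <- nrow(m)
  if (n < 2) stop_glio("need at least 2 rows for pairwise distances",
                       "input_error")
  if (sum(rowSums(m^2) == 0) >= 2) {
    stop_glio("more than one all-zero row: pairwise Tanimoto undefined",
              "input_error")
  }
  d <- tanimoto_distance_matrix(m)
  vals <- d[lower.tri(d)]
  structure(list(
    pair_count = if (pairing == "ordered_distinct") n * (n - 1L)
                 else (n * (n - 1L)) %/% 2L,
    mean = mean(vals), sd = stats::sd(vals),
    histogram = graphics::hist(vals, breaks = breaks, plot = FALSE),
    pairing = pairing, n_compounds = n),
    class = "similarity_summary")
}

#' @export
print.similarity_summary <- function(x, ...) {
  cat(sprintf(
    "Pairwise Tanimoto distances: %d compounds, %d %s pairs, %.2f +/- %.2f\n",
    x$n_compounds, x$pair_count, x$pairing, x$mean, x$sd))
  invisible(x)
}
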