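#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected pair-counting agreement between two partitions of the
#' same items, computed from the contingency table:
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - E}{\tfrac12\left[\sum_i\binom{a_i}{2}+\sum_j\binom{b_j}{2}\right] - E},
#'   \quad E = \sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}\Big/\binom{n}{2}}
#' It is symmetric, equals 1 exactly when the partitions are identical
#' (up to label renaming), and is approximately 0 in expectation for
#' independent random partitions.
#'
#' @param a,b Cluster labels over the same items (any atomic type),
#'   `length(a) == length(b) >= 2`.
#' @return The ARI, a number in \[-1, 1\].  When both partitions are
#'   degenerate in the same way (both all-singletons or both one block) the
#'   correction denominator vanishes and 1 is returned, since the
#'   partitions are identical.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))  # 1
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 1, 1))          # 0
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    stop("partitions must label the same items (lengths differ)",
         call. = FALSE)
  }
  n <- length(a)
  if (n < 2) stop("ARI requires at least 2 items", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("partition labels must not be NA",
                                 call. = FALSE)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
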