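#' @useDynLib mcicps, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats rbinom runif rnorm pchisq pnorm dnorm sd cor kmeans
#'   median dist quantile
NULL

## Evaluate `expr` under a temporary RNG state so package functions are
## deterministic given `seed` without clobbering the caller's stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

## Derive a child seed from a parent seed and a stage tag, kept < 2^31 so it
## is always a valid R integer.  Stages can thus be regenerated independently.
child_seed <- function(seed, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.double(seed) * 7919 + h * 131 + as.double(index)) %% 2147483629
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two cluster labelings; 1 means the
#' partitions are identical up to relabeling, 0 is the expected value under
#' independent random partitions.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return A single numeric value in \[-1, 1\].
#' @export
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

## Gauss-Hermite nodes/weights by Golub-Welsch, re-expressed so that
## E_{mu ~ N(0,1)}[g(mu)] ~= sum_l w[l] * g(x[l]).
gauss_hermite_normal <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  b <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- e$vectors[1, ]^2  # already sum to 1 after the sqrt(pi) cancels
  ord <- order(nodes)
  list(x = sqrt(2) * nodes[ord], w = weights[ord])
}

## Median of pairwise Euclidean distances; bandwidth fallback when the data
## collapse to (near-)duplicates.
median_heuristic <- function(x) {
  d <- stats::dist(x)
  m <- stats::median(d)
  if (!is.finite(m) || m <= 0) m <- 1
  m
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}
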