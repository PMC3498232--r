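# Upper-tail hypergeometric statistics for motif and category enrichment.

#' Upper-tail hypergeometric probability
#'
#' P(X >= m) for X ~ hypergeometric with population size `N`, `n` success
#' items and `M` draws:
#' \deqn{p = \sum_{i=m}^{\min(n,M)} \binom{n}{i}\binom{N-n}{M-i} / \binom{N}{M}}
#' Terms are accumulated on the log-gamma scale (via [lchoose()]) so large
#' counts stay numerically stable; the result is clamped to (0, 1].
#'
#' @param m observed successes among the draws (>= 0).
#' @param M number of draws (e.g. cluster size).
#' @param n success items in the population (e.g. genes containing the
#'   motif in the database).
#' @param N population size (e.g. genes in the database).
#' @return P(X >= m), a scalar in (0, 1].
#' @export
#' @examples
#' hypergeom_tail(4, 4, 5, 10)  # 5 / 210
hypergeom_tail <- function(m, M, n, N) {
  if (any(c(m, M, n, N) < 0) || n > N || M > N)
    stop("inconsistent counts: need 0 <= n, M <= N", call. = FALSE)
  if (m > n || m > M)
    stop("inconsistent counts: m cannot exceed min(n, M)", call. = FALSE)
  if (m == 0) return(1)
  i <- seq.int(m, min(n, M))
  p <- sum(exp(lchoose(n, i) + lchoose(N - n, M - i) - lchoose(N, M)))
  min(max(p, .Machine$double.xmin), 1)
}

#' Motif enrichment ratio
#'
#' Relative frequency of motif-containing genes in a cluster over the
#' background database: `(m/M) / (n/N)`.
#'
#' @inheritParams hypergeom_tail
#' @return Ratio >= 0; `NA` when `n = 0` (motif absent from the database,
#'   enrichment undefined).
#' @export
enrichment_ratio <- function(m, M, n, N) {
  if (M <= 0 || N <= 0) stop("`M` and `N` must be positive", call. = FALSE)
  if (m > M || n > N) stop("need m <= M and n <= N", call. = FALSE)
  if (n == 0) return(NA_real_)
  (m / M) / (n / N)
}

#' Enrichment p-value of a motif in a cluster
#'
#' Upper-tail hypergeometric probability of seeing at least `m` motif-
#' containing genes in a cluster of `M` genes, when `n` of the `N`
#' database genes contain the motif.
#'
#' @inheritParams hypergeom_tail
#' @return p-value in (0, 1].
#' @export
enrichment_pvalue <- function(m, M, n, N) hypergeom_tail(m, M, n, N)

#' Co-occurrence p-value of a motif pair in a cluster
#'
#' Upper-tail hypergeometric probability of seeing at least `t` cluster
#' genes carrying the windowed motif pair, given `k` such genes among the
#' `K` database genes and a cluster of size `T`. Symmetric in the pair
#' order by construction.
#'
#' @param t cluster genes containing the co-occurring pair.
#' @param T cluster size.
#' @param k database genes containing the co-occurring pair.
#' @param K database size.
#' @return p-value in (0, 1].
#' @export
cooccurrence_pvalue <- function(t, T, k, K) {
  if (k == 0 && t > 0)
    stop("inconsistent background: pair seen in cluster but k = 0",
         call. = FALSE)
  hypergeom_tail(t, T, k, K)
}

# significance classes used for Cytoscape-style rendering; boundaries fall
# in the less significant class (strict upper bounds)
classify_node <- function(p) {
  ifelse(p < 0.001, "diamond", ifelse(p < 0.05, "triangle", "circle"))
}

classify_edge <- function(p) {
  ifelse(p < 0.01, "solid", ifelse(p < 0.05, "dash", "none"))
}
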