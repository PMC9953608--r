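# Gene-set burden test: is a curated disease-gene list over-represented
# among the nominal hits of the collapsing analysis? Modelled as sampling
# without replacement from the universe of testable genes.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` of which `K` are "special", the probability of seeing at
#' least `k` special genes. The tail is accumulated in log-space
#' (log-sum-exp) for numerical safety, and includes the observed overlap.
#'
#' @param N Universe size.
#' @param K Special genes in the universe.
#' @param n Number drawn.
#' @param k Observed overlap.
#' @return The upper-tail probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  vals <- c(N, K, n, k)
  if (any(is.na(vals)) || any(vals < 0) || any(vals != floor(vals))) {
    abort("N, K, n, k must be non-negative integers")
  }
  if (K > N || n > N) abort("K and n must not exceed N")
  if (k > min(K, n)) abort("k must not exceed min(K, n)")
  if (k <= 0) return(1)
  support <- k:min(K, n)
  logp <- dhyper(support, K, N - K, n, log = TRUE)
  m <- max(logp)
  min(exp(m + log(sum(exp(logp - m)))), 1)
}

#' Gene-set burden test of a curated list against collapsing-analysis hits
#'
#' Intersects the curated disease-gene list with the collapsing-analysis
#' universe (curated genes that were untestable reduce `K`), takes the
#' nominal-hit set (case-enriched genes with `p < alpha` by default, or an
#' explicit `hits` override for replication of a published hit list), and
#' computes the upper-tail hypergeometric probability of the observed
#' overlap.
#'
#' @param gca A `gca_result` from [run_gca()] or [gca_from_counts()].
#' @param curated Character vector of curated gene symbols (e.g.
#'   [read_gene_list()]).
#' @param hits Optional explicit hit-gene override; default uses
#'   `gca$hits`.
#' @return An object of class `overlap_test`: list with `universe_N`,
#'   `list_K`, `hits_n`, `overlap_k`, `overlap_genes`, `p_value`.
#' @export
run_burden_test <- function(gca, curated, hits = NULL) {
  stopifnot(inherits(gca, "gca_result"))
  universe <- gca$universe
  if (length(universe) == 0) abort("empty universe")
  curated <- unique(toupper(curated))
  curated_in <- intersect(curated, universe)
  dropped <- setdiff(curated, universe)
  if (length(dropped)) {
    inform(sprintf(
      "%d curated gene(s) absent from the universe and dropped: %s",
      length(dropped), toString(head(dropped, 10))
    ))
  }
  if (length(curated_in) == 0) {
    abort("curated list is disjoint from the collapsing-analysis universe")
  }
  hits <- if (is.null(hits)) gca$hits else intersect(unique(toupper(hits)), universe)
  overlap <- intersect(curated_in, hits)
  p <- hypergeom_upper_tail(
    N = length(universe), K = length(curated_in),
    n = length(hits), k = length(overlap)
  )
  structure(
    list(
      universe_N = length(universe), list_K = length(curated_in),
      hits_n = length(hits), overlap_k = length(overlap),
      overlap_genes = sort(overlap), p_value = p
    ),
    class = "overlap_test"
  )
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "<overlap_test> overlap %d of list %d among %d hits (universe %d): P(X >= %d) = %.3g\n",
    x$overlap_k, x$list_K, x$hits_n, x$universe_N, x$overlap_k, x$p_value
  ))
  if (length(x$overlap_genes)) cat("  overlap:", toString(x$overlap_genes), "\n")
  invisible(x)
}
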