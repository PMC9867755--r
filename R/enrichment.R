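#' Upper-tail hypergeometric probability
#'
#' P(X >= k) where X counts members of a size-`K` set among `n` draws
#' without replacement from a universe of size `N`: the probability of
#' seeing at least the observed overlap by chance.
#'
#' @param k observed overlap.
#' @param n query list size.
#' @param K gene set size (within the universe).
#' @param N universe size.
#' @return Exact upper-tail p-value in (0, 1].
#' @export
hypergeom_upper <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || n > N || K > N) {
    abort_validation("inconsistent hypergeometric counts: k=", k, " n=", n,
                     " K=", K, " N=", N)
  }
  if (k == 0) return(1)
  # stats::phyper is exact; lower.tail=FALSE gives P(X > k-1) = P(X >= k)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set enrichment with found-entity tracking
#'
#' For each set, the overlap with the query defines the enrichment: the
#' overlapping genes ("found entities") are recorded and an exact upper-tail
#' hypergeometric p-value is computed against the universe. Query genes
#' absent from the universe are dropped with a logged count. BH q-values are
#' computed across the collection; results with p <= `keep_p` are retained.
#'
#' @param query a [gene_list()].
#' @param sets a `gene_set_collection` from [read_gmt()] (or named list).
#' @param universe a [gene_list()] of all detected genes.
#' @param keep_p retention cutoff on the raw p-value (default 0.01; use 1 to
#'   keep everything).
#' @return data.frame: set, query, universe_size, set_size, query_size,
#'   overlap, p_value, q_value, found_entities (semicolon-joined).
#' @export
enrich_collection <- function(query, sets, universe, keep_p = 0.01) {
  stopifnot(inherits(query, "gene_list"), inherits(universe, "gene_list"))
  if (!length(universe$genes)) abort_validation("empty universe")
  qg <- intersect(query$genes, universe$genes)
  dropped <- length(query$genes) - length(qg)
  if (dropped > 0) {
    log_msg(dropped, " query gene(s) absent from the universe; dropped")
  }
  N <- length(universe$genes)
  n <- length(qg)
  rows <- lapply(names(sets), function(nm) {
    sg <- intersect(sets[[nm]], universe$genes)
    if (!length(sg)) return(NULL)
    found <- intersect(qg, sg)
    data.frame(set = nm, query = query$name, universe_size = N,
               set_size = length(sg), query_size = n,
               overlap = length(found),
               p_value = hypergeom_upper(length(found), n, length(sg), N),
               found_entities = paste(sort(found), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    abort_validation("no set intersects the universe")
  }
  out$q_value <- adjust_fdr(out$p_value)
  out <- out[out$p_value <= keep_p, , drop = FALSE]
  rownames(out) <- NULL
  out[, c("set", "query", "universe_size", "set_size", "query_size",
          "overlap", "p_value", "q_value", "found_entities")]
}

#' Significance of the overlap between two gene lists
#'
#' Hypergeometric upper tail with k = |A intersect B|, treating A as the
#' draw and B as the marked set in a universe of size N (symmetric in A/B).
#'
#' @param listA,listB [gene_list()] objects, or integers giving the list
#'   sizes (then `overlap` must be supplied).
#' @param universe_size N, the number of genes either list could have drawn
#'   from (no default: it determines the test).
#' @param overlap observed overlap when sizes are given directly.
#' @return Upper-tail p-value.
#' @export
overlap_test <- function(listA, listB, universe_size, overlap = NULL) {
  if (inherits(listA, "gene_list") && inherits(listB, "gene_list")) {
    k <- length(intersect(listA$genes, listB$genes))
    nA <- length(listA$genes); nB <- length(listB$genes)
  } else {
    if (is.null(overlap)) abort_validation("overlap required with size inputs")
    nA <- listA; nB <- listB; k <- overlap
  }
  hypergeom_upper(k, nA, nB, universe_size)
}

#' Proportion with one-sided binomial enrichment test
#'
#' Percent = 100 k / n (rounded to one decimal, or to the nearest integer
#' when `round_integer`); p-value is the upper-tail binomial probability of
#' >= k hits in n trials at background rate `p0`.
#'
#' @param k hits.
#' @param n trials.
#' @param p0 background success rate in (0, 1).
#' @param round_integer round the percent to an integer instead of one
#'   decimal.
#' @return List with `percent` and `p_value`.
#' @export
proportion_enrichment <- function(k, n, p0, round_integer = FALSE) {
  if (k < 0 || n < 0 || k > n) abort_validation("need 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1) abort_validation("p0 must be in (0, 1)")
  percent <- round_half_up(100 * k / n, if (round_integer) 0 else 1)
  p <- if (k == 0) 1 else pbinom(k - 1, n, p0, lower.tail = FALSE)
  list(percent = percent, p_value = p)
}
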