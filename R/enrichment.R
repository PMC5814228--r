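# Over-representation of a miRNA's target set against gene-set collections:
# upper-tail hypergeometric probability computed in log space, BH across
# tested sets.

#' Upper-tail hypergeometric probability
#'
#' Probability of drawing at least `x` members of a size-`K` category when
#' sampling `n` items without replacement from a universe of size `N`:
#' p = sum over k = x..min(K, n) of C(K, k) C(N - K, n - k) / C(N, n).
#' Terms are accumulated in log space (log binomials + log-sum-exp) so that
#' large universes do not underflow.
#'
#' @param x Overlap count, `0 <= x <= min(K, n)`.
#' @param K Category (gene-set) size within the universe.
#' @param n Query (target-set) size within the universe.
#' @param N Universe size.
#' @return p in (0, 1]; `x = 0` gives exactly 1.
#' @export
hypergeom_tail <- function(x, K, n, N) {
  if (any(c(x, K, n, N) < 0) || K > N || n > N || x > min(K, n))
    stop(sprintf("inconsistent hypergeometric arguments: x=%d K=%d n=%d N=%d",
                 x, K, n, N))
  if (x == 0) return(1)
  k <- x:min(K, n)
  logterms <- lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)
  mx <- max(logterms)
  min(1, exp(mx + log(sum(exp(logterms - mx)))))
}

#' Target-set over-representation analysis
#'
#' Tests each gene set of a collection for over-representation of a target
#' list within a gene universe. Sets are first reduced to their universe
#' members; sets with fewer than `min_set_size` members in the universe are
#' skipped (count reported). Targets outside the universe are dropped with a
#' warning. BH adjustment runs across the tested sets only.
#'
#' @param targets Character vector of target gene ids.
#' @param collection A [gene_set_collection()].
#' @param universe Non-empty character vector of gene ids defining N.
#' @param fdr_threshold Reported threshold (records are returned for all
#'   tested sets; `significant` flags `fdr < fdr_threshold`).
#' @param min_set_size Minimum in-universe set size to test (default 2).
#' @return data.frame of class `EnrichmentTable`, sorted by `p`: `set_id`,
#'   `description`, `x` (overlap), `n` (targets in universe), `K` (set size
#'   in universe), `N`, `p`, `fdr`, `significant`.
#' @export
enrich_target_set <- function(targets, collection, universe,
                              fdr_threshold = 0.05, min_set_size = 2L) {
  stopifnot(inherits(collection, "GeneSetCollection2"))
  universe <- unique(canonicalize_gene_id(universe))
  if (length(universe) == 0L) stop("empty gene universe")
  targets <- unique(canonicalize_gene_id(targets))
  drop <- setdiff(targets, universe)
  if (length(drop)) {
    warning(sprintf("%d target(s) outside the universe dropped", length(drop)))
    targets <- intersect(targets, universe)
  }
  sets_u <- lapply(collection$sets, intersect, universe)
  testable <- lengths(sets_u) >= min_set_size
  n_skip <- sum(!testable)
  if (n_skip)
    message(sprintf("skipped %d set(s) with < %d members in the universe",
                    n_skip, min_set_size))
  sets_u <- sets_u[testable]
  N <- length(universe)
  n <- length(targets)
  recs <- lapply(names(sets_u), function(id) {
    K <- length(sets_u[[id]])
    x <- length(intersect(targets, sets_u[[id]]))
    data.frame(set_id = id, description = collection$descriptions[[id]],
               x = x, n = n, K = K, N = N,
               p = hypergeom_tail(x, K, n, N), stringsAsFactors = FALSE)
  })
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(set_id = character(0), description = character(0),
               x = integer(0), n = integer(0), K = integer(0), N = integer(0),
               p = numeric(0))
  out$fdr <- bh_fdr(out$p)
  out$significant <- out$fdr < fdr_threshold
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentTable", "data.frame")
  out
}
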