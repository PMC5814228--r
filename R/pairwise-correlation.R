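# Exhaustive correlation of every DE-miRNA x DE-mRNA pair across the paired
# samples. P-values come from the t transform of the correlation
# coefficient; BH adjustment is applied once over the full pair universe,
# and negative significant pairs are counted afterwards.

#' Pearson correlation of two sample vectors
#'
#' Thin validated wrapper around the product-moment coefficient. A constant
#' vector has no defined correlation: the result is `NA` (the pair is later
#' excluded and counted, not silently dropped).
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return Correlation in \[-1, 1\], or `NA_real_` for a constant input.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ")
  if (length(x) < 3L) stop("need at least 3 paired samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' P-value for a correlation coefficient
#'
#' t = r * sqrt((n - 2) / (1 - r^2)) referred to a Student t distribution
#' with n - 2 degrees of freedom. `|r| = 1` gives p = 0. One-sided mode
#' tests for negative correlation (lower tail).
#'
#' @param r Correlation coefficient(s), `|r| <= 1`.
#' @param n Number of paired samples, >= 3.
#' @param sided `"two"` (default) or `"neg"` for a one-sided negative test.
#' @return P-value(s).
#' @export
corr_pvalue <- function(r, n, sided = c("two", "neg")) {
  sided <- match.arg(sided)
  if (n < 3L) stop("need at least 3 paired samples")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must be <= 1")
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))  # +/-Inf at |r| = 1
  if (sided == "two") 2 * stats::pt(-abs(tstat), df = n - 2)
  else stats::pt(tstat, df = n - 2)
}

#' Correlation table over every miRNA x mRNA pair
#'
#' Computes one record per (miRNA feature, mRNA feature) combination:
#' correlation across the shared samples, p-value, and BH FDR over the full
#' pair universe. The two matrices must carry the samples in identical
#' order; a mismatch is an error, never silently realigned. Constant
#' features have no defined correlation: their pairs are excluded from the
#' table and from the BH universe, and the excluded pair count is reported.
#'
#' Work proceeds in blocks of mRNA features so that full-scale universes
#' (hundreds of miRNAs times thousands of mRNAs) stay within desktop
#' memory; results are independent of the block size.
#'
#' @param mirna_expr,mrna_expr Log2 [expression_matrix()] objects restricted
#'   to the features of interest (typically the DE sets).
#' @param method `"pearson"` or `"spearman"`.
#' @param sided `"two"` or `"neg"` (see [corr_pvalue()]).
#' @param de_mirna,de_mrna Optional `DEResult` tables; when given, signed
#'   fold changes are attached as `fc_mirna`/`fc_mrna`.
#' @param block_size Number of mRNA features per block.
#' @return data.frame of class `PairTable` with columns `mirna_id`,
#'   `mrna_id`, `cor`, `p`, `fdr` (+ `fc_mirna`, `fc_mrna` when DE tables
#'   are supplied); attributes `n_samples`, `n_excluded_pairs`,
#'   `excluded_mirnas`, `excluded_mrnas`, `method`, `sided`.
#' @export
all_pairs <- function(mirna_expr, mrna_expr, method = c("pearson", "spearman"),
                      sided = c("two", "neg"), de_mirna = NULL, de_mrna = NULL,
                      block_size = 1024L) {
  method <- match.arg(method)
  sided <- match.arg(sided)
  stopifnot(inherits(mirna_expr, "ExpressionMatrix"),
            inherits(mrna_expr, "ExpressionMatrix"))
  if (!identical(sample_ids(mirna_expr), sample_ids(mrna_expr)))
    stop("miRNA and mRNA matrices must carry identical samples in identical order")
  n <- ncol(mirna_expr$values)
  if (n < 3L) stop("need at least 3 paired samples")

  mir <- mirna_expr$values
  mrn <- mrna_expr$values
  const_mir <- apply(mir, 1L, function(r) stats::sd(r) == 0)
  const_mrn <- apply(mrn, 1L, function(r) stats::sd(r) == 0)
  n_excluded <- sum(const_mir) * nrow(mrn) +
    sum(const_mrn) * nrow(mir) - sum(const_mir) * sum(const_mrn)
  if (n_excluded > 0L)
    message(sprintf("excluded %d pair(s) involving constant features", n_excluded))
  mir <- mir[!const_mir, , drop = FALSE]
  mrn <- mrn[!const_mrn, , drop = FALSE]

  tm <- t(mir)
  blocks <- split(seq_len(nrow(mrn)),
                  ceiling(seq_len(nrow(mrn)) / max(1L, block_size)))
  cors <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    rb <- stats::cor(tm, t(mrn[blocks[[b]], , drop = FALSE]), method = method)
    cors[[b]] <- as.vector(rb)  # column-major: miRNAs fastest
  }
  corv <- unlist(cors, use.names = FALSE)
  out <- data.frame(
    mirna_id = rep.int(rownames(mir), nrow(mrn)),
    mrna_id = rep(rownames(mrn), each = nrow(mir)),
    cor = corv,
    p = corr_pvalue(corv, n, sided),
    stringsAsFactors = FALSE)
  out$fdr <- bh_fdr(out$p)
  if (!is.null(de_mirna))
    out$fc_mirna <- de_mirna$signed_fc[match(out$mirna_id, de_mirna$feature_id)]
  if (!is.null(de_mrna))
    out$fc_mrna <- de_mrna$signed_fc[match(out$mrna_id, de_mrna$feature_id)]
  attr(out, "n_samples") <- n
  attr(out, "n_excluded_pairs") <- n_excluded
  attr(out, "excluded_mirnas") <- rownames(mirna_expr$values)[const_mir]
  attr(out, "excluded_mrnas") <- rownames(mrna_expr$values)[const_mrn]
  attr(out, "method") <- method
  attr(out, "sided") <- sided
  class(out) <- c("PairTable", "data.frame")
  out
}

#' Pair-count funnel summary
#'
#' Counts the full pair universe, the negatively correlated pairs, and the
#' negative pairs significant at `fdr < fdr_threshold`, together with the
#' significant fraction of the universe as a one-decimal percentage (the
#' form in which such funnels are usually printed).
#'
#' @param pairs A `PairTable` (or any data.frame with `cor` and `fdr`).
#' @param fdr_threshold Strict cutoff.
#' @return List of class `PairCounts`: `total`, `negative`,
#'   `negative_significant`, `pct_negative_significant`.
#' @export
summarize_counts <- function(pairs, fdr_threshold = 0.05) {
  neg <- sum(pairs$cor < 0)
  sig <- sum(pairs$cor < 0 & pairs$fdr < fdr_threshold)
  structure(list(total = nrow(pairs), negative = neg,
                 negative_significant = sig,
                 pct_negative_significant = percent1(sig, nrow(pairs))),
            class = "PairCounts")
}

#' @export
print.PairCounts <- function(x, ...) {
  cat(sprintf("pairs: %d total; %d negative; %d negative at FDR < threshold (%.1f%%)\n",
              x$total, x$negative, x$negative_significant,
              x$pct_negative_significant))
  invisible(x)
}

#' @rdname all_pairs
#' @param pairs A `PairTable`.
#' @param path Output path; rows are written sorted by `fdr`.
#' @param sep Field separator.
#' @export
write_pair_table <- function(pairs, path, sep = "\t") {
  ord <- order(pairs$fdr, pairs$cor, pairs$mirna_id, pairs$mrna_id)
  utils::write.table(as.data.frame(pairs)[ord, , drop = FALSE], path,
                     sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
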