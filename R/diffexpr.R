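# Two-group differential expression with empirical-Bayes variance
# moderation. Counts are normalized by median-of-ratios size factors and
# log2-transformed; log2-scale data are tested directly. The moderated
# statistic shrinks per-feature variances toward a pooled (optionally
# mean-trended) prior estimated by moment matching on log variances.

#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over features g (with a
#' positive geometric mean across samples) of count_gj / geomean_g. Features
#' containing a zero in any sample drop out of the reference set.
#'
#' @param counts An [expression_matrix()] of kind `"counts"`.
#' @return Named numeric vector of positive per-sample factors.
#' @export
estimate_size_factors <- function(counts) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$value_kind != "counts") stop("size factors need a counts matrix")
  v <- counts$values
  loggeo <- rowMeans(log(v))
  use <- is.finite(loggeo)
  if (!any(use))
    stop("no feature has positive counts in every sample; ",
         "filter low-count features before normalization")
  sf <- apply(v[use, , drop = FALSE], 2L,
              function(cnt) exp(stats::median(log(cnt) - loggeo[use])))
  if (any(!is.finite(sf) | sf <= 0)) stop("non-positive size factor estimated")
  sf
}

#' Size-factor normalization and log2 transform
#'
#' value = log2(count / factor + offset). The pseudo-count offset keeps the
#' transform finite at zero counts; offset = 1 maps a zero count to 0.
#'
#' @param counts An [expression_matrix()] of kind `"counts"`.
#' @param factors Per-sample size factors from [estimate_size_factors()].
#' @param offset Pseudo-count added after scaling (default 1).
#' @return An [expression_matrix()] of kind `"log2"`.
#' @export
log2_normalize <- function(counts, factors = estimate_size_factors(counts),
                           offset = 1) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$value_kind != "counts") stop("expected a counts matrix")
  if (length(factors) != ncol(counts$values))
    stop("one size factor per sample required")
  if (any(!is.finite(factors) | factors <= 0)) stop("non-positive size factor")
  if (offset <= 0) stop("'offset' must be positive")
  v <- log2(sweep(counts$values, 2L, factors, "/") + offset)
  expression_matrix(v, "log2")
}

#' Per-feature two-group linear fit
#'
#' For each feature: effect = mean(case) - mean(control); residual variance
#' is the pooled within-group variance on n - 2 degrees of freedom;
#' `mean_expr` is the grand mean over all samples. Constant features must be
#' removed beforehand (see [de_table()], which does so and reports the count).
#'
#' @param expr An [expression_matrix()] of kind `"log2"`.
#' @param sheet A [sample_sheet()] covering the matrix samples.
#' @return data.frame with columns `feature_id`, `mean_expr`, `logfc`, `s2`,
#'   `df`, plus attributes `n_case`/`n_ctrl`.
#' @export
fit_two_group <- function(expr, sheet) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$value_kind != "log2") stop("two-group fit expects log2 values")
  check_samples(sheet, expr)
  grp <- sheet$group[match(sample_ids(expr), sheet$sample_id)]
  n1 <- sum(grp == "case"); n2 <- sum(grp == "control")
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  v <- expr$values
  case <- v[, grp == "case", drop = FALSE]
  ctrl <- v[, grp == "control", drop = FALSE]
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  ss1 <- rowSums((case - m1)^2)
  ss2 <- rowSums((ctrl - m2)^2)
  out <- data.frame(feature_id = rownames(v),
                    mean_expr = rowMeans(v),
                    logfc = m1 - m2,
                    s2 = (ss1 + ss2) / (n1 + n2 - 2L),
                    df = n1 + n2 - 2L,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_case") <- n1
  attr(out, "n_ctrl") <- n2
  out
}

# Inverse of the trigamma function by Newton iteration on the transformed
# equation 1/trigamma(y) = 1/x, which is nearly linear; monotone and stable
# for any positive x.
trigamma_inverse <- function(x) {
  stopifnot(is.finite(x), x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderation of residual variances
#'
#' Models the per-feature variances as scaled-F draws around a prior
#' variance s0^2 with d0 prior degrees of freedom and returns the posterior
#' (shrunken) variances s2_post = (d0 s0^2 + df s2) / (d0 + df). Estimation
#' is by moment matching on z = log s2: with
#' e = z - digamma(df/2) + log(df/2), the excess of var(e) over
#' trigamma(df/2) estimates trigamma(d0/2), solved by monotone root-finding,
#' and mean(e) locates s0^2. With `trend = TRUE` the prior variance follows
#' a locally weighted regression of e on mean expression, so features of
#' different abundance shrink toward different priors; d0 is then estimated
#' from the residuals of that fit.
#'
#' Non-positive excess variance means the observed spread of variances is no
#' wider than sampling noise: d0 is set infinite (complete shrinkage,
#' s2_post = s0^2) and a message is emitted; this is not an error.
#'
#' @param s2 Per-feature residual variances.
#' @param df Residual degrees of freedom (scalar or per-feature).
#' @param mean_expr Per-feature mean log2 expression; required when
#'   `trend = TRUE`.
#' @param trend Fit a mean-variance trend for the prior variance.
#' @param span Smoother span for the trend fit.
#' @return List of class `ModerationState`: `d0`, `s0_2` (scalar, or
#'   per-feature when trended), `s2_post`, `trend`, `span`.
#' @export
moderate_variances <- function(s2, df, mean_expr = NULL, trend = FALSE,
                               span = 0.5) {
  n <- length(s2)
  if (n < 10L) stop("need >= 10 features for stable moment estimation")
  df <- rep_len(df, n)
  if (trend && is.null(mean_expr))
    stop("'mean_expr' is required when trend = TRUE")
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 10L) stop("need >= 10 positive variances")
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)

  if (trend) {
    o <- order(mean_expr[ok])
    fit <- stats::lowess(mean_expr[ok][o], e[o], f = span)
    efit_ok <- stats::approx(fit$x, fit$y, xout = mean_expr[ok], rule = 2,
                             ties = mean)$y
    resid <- e - efit_ok
    # prior location for every feature, including any s2 = 0 ones
    efit_all <- stats::approx(fit$x, fit$y, xout = mean_expr, rule = 2,
                              ties = mean)$y
  } else {
    efit_ok <- rep(mean(e), sum(ok))
    resid <- e - mean(e)
    efit_all <- rep(mean(e), n)
  }

  excess <- sum(resid^2) / (length(resid) - 1L) - mean(trigamma(df[ok] / 2))
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_2 <- exp(efit_all + digamma(d0 / 2) - log(d0 / 2))
  } else {
    message("variance spread no wider than sampling noise; ",
            "prior degrees of freedom set infinite")
    d0 <- Inf
    s0_2 <- exp(efit_all)
  }
  s2_post <- if (is.infinite(d0)) s0_2 else (d0 * s0_2 + df * s2) / (d0 + df)
  if (!trend) s0_2 <- s0_2[1L]
  structure(list(d0 = d0, s0_2 = s0_2, s2_post = s2_post, trend = trend,
                 span = span),
            class = "ModerationState")
}

#' Moderated t-statistic and p-value
#'
#' t = logfc / sqrt(s2_post * (1/n_case + 1/n_ctrl)), referred to a Student
#' t distribution with d0 + df degrees of freedom (the normal limit when d0
#' is infinite). With d0 = 0 the statistic reduces to the classical
#' equal-variance two-sample t-test.
#'
#' @param logfc Per-feature effect estimates.
#' @param s2_post Posterior variances from [moderate_variances()] (raw s2
#'   when d0 = 0).
#' @param d0 Prior degrees of freedom (may be `Inf` or 0).
#' @param df Residual degrees of freedom.
#' @param n_case,n_ctrl Group sizes.
#' @return data.frame with columns `t_mod` and `p` (two-sided).
#' @export
moderated_t <- function(logfc, s2_post, d0, df, n_case, n_ctrl) {
  if (any(s2_post <= 0))
    stop("zero posterior variance; remove constant features before testing")
  tstat <- logfc / sqrt(s2_post * (1 / n_case + 1 / n_ctrl))
  dft <- if (is.infinite(d0)) Inf else d0 + df
  data.frame(t_mod = tstat, p = 2 * stats::pt(-abs(tstat), df = dft))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q_(i) = min over j >= i of m * p_(j) / j, capped at 1 and returned in the
#' input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(m / seq.int(m, 1L) * p[o]))
  q[order(o)]
}

#' Signed linear-scale fold change
#'
#' 2^logfc for logfc >= 0 and -2^(-logfc) otherwise, the usual convention
#' for printing fold changes: values are never inside (-1, 1), and a
#' two-fold decrease prints as -2 rather than 0.5.
#'
#' @param logfc Finite log2 fold changes.
#' @return Signed fold changes.
#' @examples
#' signed_fc(c(0, 1, -1, log2(9.91)))
#' @export
signed_fc <- function(logfc) {
  if (any(!is.finite(logfc))) stop("'logfc' must be finite")
  ifelse(logfc >= 0, 2^logfc, -2^(-logfc))
}

#' Differential-expression table for one data type
#'
#' Runs the full per-feature pipeline: (counts only) size-factor
#' normalization and log2 transform; removal of constant features (count
#' reported with a message); two-group fit; variance moderation; moderated
#' t and BH adjustment; signed fold change and an up/down/ns call at
#' `fdr < fdr_threshold` (strict).
#'
#' @param expr An [expression_matrix()] (`"counts"` or `"log2"`).
#' @param sheet A [sample_sheet()].
#' @param trend Use the mean-variance trend when moderating.
#' @param fdr_threshold Strict FDR cutoff for the direction call.
#' @param log2_offset Pseudo-count for the counts transform.
#' @param span Trend smoother span.
#' @return data.frame of class `DEResult` with columns `feature_id`,
#'   `mean_expr`, `logfc`, `signed_fc`, `s2`, `t_mod`, `p`, `fdr`,
#'   `direction`; attributes `moderation` (the `ModerationState`),
#'   `n_constant_removed`, `n_case`, `n_ctrl`.
#' @export
de_table <- function(expr, sheet, trend = TRUE, fdr_threshold = 0.05,
                     log2_offset = 1, span = 0.5) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$value_kind == "counts")
    expr <- log2_normalize(expr, estimate_size_factors(expr), log2_offset)
  v <- expr$values
  const <- apply(v, 1L, function(r) max(r) == min(r))
  if (any(const)) {
    message(sprintf("removed %d constant feature(s) before testing", sum(const)))
    expr <- expression_matrix(v[!const, , drop = FALSE], "log2")
  }
  fit <- fit_two_group(expr, sheet)
  mod <- moderate_variances(fit$s2, fit$df, mean_expr = fit$mean_expr,
                            trend = trend, span = span)
  tt <- moderated_t(fit$logfc, mod$s2_post, mod$d0, fit$df,
                    attr(fit, "n_case"), attr(fit, "n_ctrl"))
  out <- data.frame(feature_id = fit$feature_id,
                    mean_expr = fit$mean_expr,
                    logfc = fit$logfc,
                    signed_fc = signed_fc(fit$logfc),
                    s2 = fit$s2,
                    t_mod = tt$t_mod,
                    p = tt$p,
                    fdr = bh_fdr(tt$p),
                    stringsAsFactors = FALSE)
  out$direction <- ifelse(out$fdr < fdr_threshold,
                          ifelse(out$logfc > 0, "up", "down"), "ns")
  attr(out, "moderation") <- mod
  attr(out, "n_constant_removed") <- sum(const)
  attr(out, "n_case") <- attr(fit, "n_case")
  attr(out, "n_ctrl") <- attr(fit, "n_ctrl")
  class(out) <- c("DEResult", "data.frame")
  out
}

#' Select differentially expressed features
#'
#' Partitions a [de_table()] result at `fdr < fdr_threshold` (strict: a
#' feature sitting exactly on the threshold is excluded) by the sign of the
#' log fold change.
#'
#' @param results A `DEResult` data.frame.
#' @param fdr_threshold Strict cutoff.
#' @return List with character vectors `up` and `down` plus `n_up`,
#'   `n_down`, `n_total` counts.
#' @export
select_de <- function(results, fdr_threshold = 0.05) {
  if (nrow(results) == 0L)
    return(list(up = character(0), down = character(0),
                n_up = 0L, n_down = 0L, n_total = 0L))
  sig <- results$fdr < fdr_threshold
  up <- results$feature_id[sig & results$logfc > 0]
  down <- results$feature_id[sig & results$logfc < 0]
  list(up = up, down = down, n_up = length(up), n_down = length(down),
       n_total = length(up) + length(down))
}

#' @rdname de_table
#' @param de A `DEResult`.
#' @param path Output path for the delimited DE table.
#' @param sep Field separator.
#' @export
write_de_table <- function(de, path, sep = "\t") {
  utils::write.table(as.data.frame(de), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
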