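# Normalization, the two-group fit, variance moderation and selection.

make_counts <- function(m, ids = sprintf("f%02d", seq_len(nrow(m))),
                        samples = sprintf("s%02d", seq_len(ncol(m)))) {
  dimnames(m) <- list(ids, samples)
  expression_matrix(m, "counts")
}

test_that("size factors are 1 for identical columns and scale with depth", {
  m <- make_counts(matrix(rep(c(10, 20, 30), 4), 3, 4))
  expect_equal(estimate_size_factors(m), setNames(rep(1, 4), sprintf("s%02d", 1:4)))

  set.seed(21)
  base <- matrix(rnbinom(250, mu = 50, size = 5) + 1, 50, 5)
  doubled <- base; doubled[, 2] <- 2L * doubled[, 2]
  f0 <- estimate_size_factors(make_counts(base))
  f2 <- estimate_size_factors(make_counts(doubled))
  # doubling a zero-free column doubles its factor relative to the others
  expect_equal((f2[2] / f2[1]) / (f0[2] / f0[1]), 2, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("size factors equal an independent median-of-ratios pass", {
  set.seed(33)
  # odd zero-free reference set: the median of ratios is then a single
  # order statistic, identical in linear and log space
  m <- matrix(rnbinom(255, mu = 80, size = 3) + 1, 51, 5)
  em <- make_counts(m)
  sf <- estimate_size_factors(em)
  # independently coded oracle: explicit loops over the definition
  geo <- exp(rowMeans(log(m)))
  oracle <- sapply(seq_len(ncol(m)), function(j)
    median(m[, j] / geo))
  expect_equal(unname(sf), oracle, tolerance = 1e-12)
  expect_equal(unname(sf),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("size factor estimation demands a zero-free feature", {
  m <- make_counts(rbind(c(0, 1, 2), c(3, 0, 4)))
  expect_error(estimate_size_factors(m), "filter")
})

test_that("log2 transform hits its anchors and is monotone", {
  m <- make_counts(matrix(c(0, 7, 1, 3), 2, 2))
  lg <- log2_normalize(m, factors = c(1, 1), offset = 1)
  expect_equal(lg$values[1, 1], 0)
  expect_equal(lg$values[2, 1], 3)  # log2(7 + 1)
  expect_error(log2_normalize(m, factors = c(1, -1)), "size factor")

  set.seed(8)
  for (i in 1:20) {
    cnt <- matrix(rpois(20, 30), 4, 5)
    cnt2 <- cnt
    pos <- sample(20, 1)
    cnt2[pos] <- cnt2[pos] + sample(1:10, 1)
    f <- runif(5, 0.5, 2)
    a <- log2_normalize(make_counts(cnt), f)$values
    b <- log2_normalize(make_counts(cnt2), f)$values
    expect_true(all(b >= a))
  }
})

test_that("two-group fit matches the pooled-variance textbook formulas", {
  sh <- sample_sheet(sprintf("s%02d", 1:4), c("case", "case", "control", "control"))
  em <- expression_matrix(
    matrix(c(2, 2, 1, 1), 1, 4, dimnames = list("f1", sprintf("s%02d", 1:4))),
    "log2")
  fit <- fit_two_group(em, sh)
  expect_equal(fit$logfc, 1)
  expect_equal(fit$s2, 0)

  set.seed(14)
  v <- matrix(rnorm(30), 5, 6, dimnames = list(sprintf("f%d", 1:5),
                                               sprintf("s%02d", 1:6)))
  sh6 <- sample_sheet(sprintf("s%02d", 1:6),
                      c("case", "case", "case", "control", "control", "control"))
  fit6 <- fit_two_group(expression_matrix(v, "log2"), sh6)
  for (g in 1:5) {
    ca <- v[g, 1:3]; co <- v[g, 4:6]
    expect_equal(fit6$logfc[g], mean(ca) - mean(co), tolerance = 1e-12)
    expect_equal(fit6$s2[g],
                 (2 * var(ca) + 2 * var(co)) / 4, tolerance = 1e-12)
    expect_equal(fit6$mean_expr[g], mean(v[g, ]), tolerance = 1e-12)
  }
  expect_error(fit_two_group(expression_matrix(v[, 1:3], "log2"),
                             sample_sheet(sprintf("s%02d", 1:3),
                                          c("case", "case", "control"))),
               "at least 2")
})

test_that("equal variances trip the infinite-prior branch", {
  expect_message(
    st <- moderate_variances(rep(2, 20), df = 4),
    "infinite")
  expect_true(is.infinite(st$d0))
  expect_equal(unname(st$s2_post), rep(st$s0_2, 20))
})

test_that("moment matching recovers the variance prior", {
  set.seed(101)
  d0 <- 10; s0 <- 2; df <- 10; n <- 5000
  s2 <- s0 * (rchisq(n, df) / df) / (rchisq(n, d0) / d0)
  st <- moderate_variances(s2, df = df)
  expect_lt(abs(st$d0 - d0) / d0, 0.20)
  expect_lt(abs(st$s0_2 - s0) / s0, 0.10)
  # shrinkage formula
  expect_equal(st$s2_post,
               (st$d0 * st$s0_2 + df * s2) / (st$d0 + df), tolerance = 1e-12)
})

test_that("moderated t is zero-centred, sign-symmetric, classical at d0 = 0", {
  r0 <- moderated_t(0, s2_post = 1, d0 = 5, df = 4, n_case = 3, n_ctrl = 3)
  expect_equal(r0$t_mod, 0)
  expect_equal(r0$p, 1)
  rp <- moderated_t(1.3, 0.8, 5, 4, 3, 3)
  rn <- moderated_t(-1.3, 0.8, 5, 4, 3, 3)
  expect_equal(rp$p, rn$p)
  expect_error(moderated_t(1, 0, 5, 4, 3, 3), "variance")

  set.seed(17)
  v <- matrix(rnorm(60), 10, 6, dimnames = list(sprintf("f%d", 1:10),
                                                sprintf("s%d", 1:6)))
  sh <- sample_sheet(sprintf("s%d", 1:6),
                     c("case", "case", "case", "control", "control", "control"))
  fit <- fit_two_group(expression_matrix(v, "log2"), sh)
  res <- moderated_t(fit$logfc, fit$s2, d0 = 0, df = fit$df, 3, 3)
  for (g in 1:10) {
    tt <- t.test(v[g, 1:3], v[g, 4:6], var.equal = TRUE)
    expect_equal(res$t_mod[g], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p[g], tt$p.value, tolerance = 1e-12)
  }
})

test_that("d0 -> 0 and d0 -> Inf bracket the classical statistic", {
  set.seed(27)
  v <- matrix(rnorm(48), 8, 6, dimnames = list(sprintf("f%d", 1:8),
                                               sprintf("s%d", 1:6)))
  sh <- sample_sheet(sprintf("s%d", 1:6),
                     c("case", "case", "case", "control", "control", "control"))
  fit <- fit_two_group(expression_matrix(v, "log2"), sh)
  s0 <- mean(fit$s2)
  classical <- abs(moderated_t(fit$logfc, fit$s2, 0, fit$df, 3, 3)$t_mod)
  shrunk <- abs(moderated_t(fit$logfc, rep(s0, 8), Inf, fit$df, 3, 3)$t_mod)
  lo <- pmin(classical, shrunk); hi <- pmax(classical, shrunk)
  for (d0 in c(0.5, 2, 10, 100)) {
    st <- (d0 * s0 + fit$df * fit$s2) / (d0 + fit$df)
    mid <- abs(moderated_t(fit$logfc, st, d0, fit$df, 3, 3)$t_mod)
    expect_true(all(mid >= lo - 1e-12 & mid <= hi + 1e-12))
  }
})

test_that("the full moderated pipeline agrees with an independent EB fit", {
  ds <- tiny_dataset(19)
  mirl <- log2_normalize(ds$mirna)
  de <- de_table(expression_matrix(mirl$values, "log2"), ds$samples,
                 trend = FALSE)
  design <- cbind(1, ds$samples$group == "case")
  lf <- limma::eBayes(limma::lmFit(mirl$values, design), trend = FALSE)
  expect_equal(de$logfc, unname(lf$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(de$t_mod, unname(lf$t[, 2]), tolerance = 1e-6)
  expect_equal(de$p, unname(lf$p.value[, 2]), tolerance = 1e-6)
})

test_that("BH matches its closed forms and stays monotone", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")

  set.seed(55)
  for (i in 1:10) {
    p <- runif(sample(5:100, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, bh_brute_force(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    # monotone in p-rank; permutation-invariant
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), q[perm], tolerance = 1e-15)
  }
})

test_that("signed fold change obeys the printing convention", {
  expect_equal(signed_fc(c(0, 1, -1)), c(1, 2, -2))
  expect_equal(signed_fc(log2(9.91)), 9.91)
  lf <- runif(20, 0.01, 6)
  expect_equal(signed_fc(-lf), -signed_fc(lf))
  expect_true(all(abs(signed_fc(rnorm(50))) >= 1))
})

test_that("DE selection is strict at the threshold", {
  de <- data.frame(feature_id = c("a", "b", "c"),
                   logfc = c(2, -2, 1),
                   fdr = c(0.01, 0.05, 0.2))
  sel <- select_de(de, 0.05)
  expect_identical(sel$up, "a")
  expect_identical(sel$down, character(0))  # fdr == threshold excluded
  empty <- select_de(de[0, ], 0.05)
  expect_identical(empty$n_total, 0L)
})

test_that("de_table removes constant features and keeps fdr coherent", {
  ds <- tiny_dataset(23, n_mirna = 60L)
  v <- ds$mrna$values[1:60, ]
  v[1, ] <- 5  # constant
  expect_message(
    de <- de_table(expression_matrix(v, "log2"), ds$samples),
    "removed 1 constant")
  expect_identical(nrow(de), 59L)
  expect_true(all(de$fdr >= de$p - 1e-15))
  expect_true(all(abs(de$signed_fc) >= 1))
  expect_identical(unique(de$direction[de$fdr >= 0.05]), "ns")
})
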