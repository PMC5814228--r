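# Shared fixtures: all synthetic, generated in code at test time.

# Small generator configuration for module tests (fast; the recovery suite
# uses the package defaults instead).
tiny_params <- function(seed, ...) {
  args <- list(seed = seed, n_mirna = 80L, n_mrna = 400L,
               n_planted_edges = 40L,
               db_specs = list(dbA = list(coverage = 0.5, n_false = 300L),
                               dbB = list(coverage = 0.6, n_false = 500L),
                               dbC = list(coverage = 0.4, n_false = 400L)))
  utils::modifyList(args, list(...))
}

tiny_dataset <- function(seed, ...) {
  generate_dataset(do.call(synthetic_params, tiny_params(seed, ...)))
}

# Random log2 expression matrix.
rand_log2 <- function(n_feat, n_samp, seed, prefix = "f") {
  set.seed(seed)
  m <- matrix(rnorm(n_feat * n_samp), n_feat, n_samp,
              dimnames = list(sprintf("%s%04d", prefix, seq_len(n_feat)),
                              sprintf("s%02d", seq_len(n_samp))))
  expression_matrix(m, "log2")
}

# Pair keys for truth comparisons.
key_of <- function(mirna, gene) paste(mirna, gene, sep = "\t")

# Independent step-up BH oracle: quadratic-time evaluation of
# q_(i) = min_{j >= i} m p_(j) / j on the sorted values.
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Exact hypergeometric upper tail by direct combinatorial summation.
hyper_enum <- function(x, K, n, N) {
  if (x == 0) return(1)
  k <- x:min(K, n)
  sum(choose(K, k) * choose(N - K, n - k)) / choose(N, n)
}

# Run DE -> correlate -> integrate on a synthetic dataset and return the
# pieces needed for recovery scoring.
run_recovery <- function(ds, fdr = 0.05, min_dbs = 1L) {
  de_mir <- de_table(ds$mirna, ds$samples)
  de_mrn <- de_table(ds$mrna, ds$samples)
  sel_mir <- select_de(de_mir, fdr)
  sel_mrn <- select_de(de_mrn, fdr)
  ids_mir <- c(sel_mir$up, sel_mir$down)
  ids_mrn <- c(sel_mrn$up, sel_mrn$down)
  if (length(ids_mir) == 0L || length(ids_mrn) == 0L)
    return(NULL)
  mirl <- log2_normalize(ds$mirna)
  pairs <- all_pairs(
    expression_matrix(mirl$values[ids_mir, , drop = FALSE], "log2"),
    expression_matrix(ds$mrna$values[ids_mrn, , drop = FALSE], "log2"),
    de_mirna = de_mir, de_mrna = de_mrn)
  interactions <- filter_interactions(
    annotate_predictions(pairs, ds$dbs), fdr, min_dbs)
  list(de_mirna = de_mir, de_mrna = de_mrn, sel_mirna = sel_mir,
       sel_mrna = sel_mrn, pairs = pairs, interactions = interactions)
}
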