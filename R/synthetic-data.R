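# Synthetic paired case/control miRNA/mRNA datasets with planted negative
# regulator->target structure, plus synthetic prediction databases with
# controlled true-edge coverage and false predictions. The generator
# returns full ground truth so every downstream stage can be scored for
# calibration, precision and recovery.
#
# The emulated design is a small unbalanced tissue study: 9 cases vs 3
# controls, miRNA abundance as negative-binomial sequencing counts with
# per-sample library factors, mRNA abundance as Gaussian log2 intensities.

#' Parameters for the synthetic generator
#'
#' Defaults describe the test-scale configuration: 9 cases + 3 controls,
#' 300 miRNAs x 2000 mRNAs, 31% / 20% DE fractions, mean absolute log2
#' effect 1.5, 200 planted negative edges with coupling 0.8 on the log2
#' scale, and three prediction databases of differing size with low mutual
#' overlap. [study_scale_params()] gives the genome-wide variant
#' (1733 miRNAs x 18570 mRNAs).
#'
#' @param seed Integer seed; mandatory, drives all randomness.
#' @param n_case,n_ctrl Group sizes.
#' @param n_mirna,n_mrna Feature counts.
#' @param frac_de_mirna,frac_de_mrna Fractions of features with a planted
#'   group effect.
#' @param lfc_magnitude Mean absolute log2 group effect (gamma-distributed
#'   magnitudes, shape 2).
#' @param n_planted_edges Number of planted regulator->target edges.
#' @param coupling Strength (log2 units per SD of regulator signal) of the
#'   negative coupling from a planted regulator onto its target.
#' @param noise_sd Gaussian noise SD for mRNA log2 values.
#' @param nb_dispersion Negative-binomial dispersion of miRNA counts.
#' @param library_size_range Range of per-sample library factors.
#' @param db_specs Named list; each element a list with `coverage` (fraction
#'   of planted edges included as true predictions) and `n_false` (false
#'   pairs sampled from non-edges).
#' @param pairwise_db_overlap_target Fraction of planted edges shared by all
#'   databases before independent sampling; overlap targeting is
#'   best-effort and the achieved mean pairwise Jaccard is reported.
#' @return List of class `SyntheticParams`.
#' @export
synthetic_params <- function(seed,
                             n_case = 9L, n_ctrl = 3L,
                             n_mirna = 300L, n_mrna = 2000L,
                             frac_de_mirna = 0.31, frac_de_mrna = 0.20,
                             lfc_magnitude = 1.5,
                             n_planted_edges = 200L,
                             coupling = 0.8, noise_sd = 0.5,
                             nb_dispersion = 0.15,
                             library_size_range = c(0.7, 1.4),
                             db_specs = list(
                               dbA = list(coverage = 0.40, n_false = 1000L),
                               dbB = list(coverage = 0.70, n_false = 3000L),
                               dbC = list(coverage = 0.55, n_false = 2000L)),
                             pairwise_db_overlap_target = 0.15) {
  if (missing(seed)) stop("'seed' is mandatory")
  stopifnot(length(seed) == 1L, is.finite(seed))
  fr <- c(frac_de_mirna, frac_de_mrna, pairwise_db_overlap_target)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  cnts <- c(n_case, n_ctrl, n_mirna, n_mrna)
  if (any(cnts <= 0)) stop("counts must be positive")
  if (n_case < 2L || n_ctrl < 2L) stop("each group needs at least 2 samples")
  if (n_planted_edges < 0) stop("'n_planted_edges' must be >= 0")
  if (is.null(names(db_specs)) || any(!nzchar(names(db_specs))))
    stop("'db_specs' must be a named list")
  library_size_range <- as.numeric(unlist(library_size_range))
  structure(list(seed = as.integer(seed),
                 n_case = as.integer(n_case), n_ctrl = as.integer(n_ctrl),
                 n_mirna = as.integer(n_mirna), n_mrna = as.integer(n_mrna),
                 frac_de_mirna = frac_de_mirna, frac_de_mrna = frac_de_mrna,
                 lfc_magnitude = lfc_magnitude,
                 n_planted_edges = as.integer(n_planted_edges),
                 coupling = coupling, noise_sd = noise_sd,
                 nb_dispersion = nb_dispersion,
                 library_size_range = library_size_range,
                 db_specs = db_specs,
                 pairwise_db_overlap_target = pairwise_db_overlap_target),
            class = "SyntheticParams")
}

#' @rdname synthetic_params
#' @param ... Overrides passed on to [synthetic_params()].
#' @export
study_scale_params <- function(seed, ...) {
  synthetic_params(seed,
                   n_mirna = 1733L, n_mrna = 18570L,
                   n_planted_edges = 1500L,
                   db_specs = list(
                     dbA = list(coverage = 0.40, n_false = 8000L),
                     dbB = list(coverage = 0.70, n_false = 30000L),
                     dbC = list(coverage = 0.55, n_false = 15000L)),
                   ...)
}

#' Generate a synthetic paired dataset with ground truth
#'
#' MiRNA counts are negative-binomial with per-sample library factors and a
#' multiplicative group effect for DE features. Each mRNA log2 value is
#' baseline + group effect (if DE) - coupling * z(regulator) + Gaussian
#' noise, where z is the per-feature standardized log2 library-normalized
#' abundance of each planted regulator, so the sign of the planted
#' correlation is controlled independently of the count noise level.
#' Planted edges connect only opposite-direction DE pairs (up-miRNA with
#' down-mRNA, down-miRNA with up-mRNA). Databases share a common core of
#' planted edges (tuning their overlap toward
#' `pairwise_db_overlap_target`), draw the rest of their true predictions
#' independently, and add `n_false` false pairs sampled uniformly from
#' non-edges.
#'
#' @param params A [synthetic_params()] object.
#' @return List of class `SyntheticDataset`: `mirna` (counts
#'   [expression_matrix()]), `mrna` (log2 [expression_matrix()]), `samples`
#'   ([sample_sheet()]), `dbs` (list of [target_db()]), `truth` (list of
#'   class `SyntheticTruth`: `de_mirna`, `de_mrna` data.frames with
#'   `feature_id`, `direction`, `lfc`; `edges` data.frame; `params`;
#'   `achieved_db_jaccard`).
#' @export
generate_dataset <- function(params) {
  stopifnot(inherits(params, "SyntheticParams"))
  p <- params
  set.seed(p$seed)
  n_samp <- p$n_case + p$n_ctrl
  sample_id <- c(sprintf("case%02d", seq_len(p$n_case)),
                 sprintf("ctrl%02d", seq_len(p$n_ctrl)))
  is_case <- rep(c(1, 0), c(p$n_case, p$n_ctrl))
  sheet <- sample_sheet(sample_id, rep(c("case", "control"),
                                       c(p$n_case, p$n_ctrl)))
  mir_ids <- sprintf("miR-sim%04d", seq_len(p$n_mirna))
  gene_ids <- sprintf("GENE%05d", seq_len(p$n_mrna))

  draw_de <- function(ids, frac) {
    n_de <- round(frac * length(ids))
    idx <- sort(sample.int(length(ids), n_de))
    dir <- sample(c(1, -1), n_de, replace = TRUE)
    lfc <- dir * stats::rgamma(n_de, shape = 2, scale = p$lfc_magnitude / 2)
    data.frame(feature_id = ids[idx], direction = dir, lfc = lfc,
               stringsAsFactors = FALSE)
  }
  de_mir <- draw_de(mir_ids, p$frac_de_mirna)
  de_mrn <- draw_de(gene_ids, p$frac_de_mrna)

  # miRNA counts: NB with library factors and group effect
  libf <- stats::runif(n_samp, p$library_size_range[1], p$library_size_range[2])
  base_mir <- stats::runif(p$n_mirna, 3, 9)           # baseline log2 mean
  lfc_mir <- stats::setNames(rep(0, p$n_mirna), mir_ids)
  lfc_mir[de_mir$feature_id] <- de_mir$lfc
  mu <- outer(2^base_mir, libf) * 2^(outer(lfc_mir, is_case))
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / p$nb_dispersion),
                   nrow = p$n_mirna,
                   dimnames = list(mir_ids, sample_id))
  mirna <- expression_matrix(counts, "counts")

  # standardized latent regulator signal from normalized log2 abundance
  norm_log2 <- log2(sweep(counts, 2L, libf, "/") + 1)
  zsig <- t(apply(norm_log2, 1L, function(r) {
    s <- stats::sd(r)
    if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))

  # planted edges: opposite-direction DE pairs only
  up_mir <- de_mir$feature_id[de_mir$direction > 0]
  dn_mir <- de_mir$feature_id[de_mir$direction < 0]
  up_mrn <- de_mrn$feature_id[de_mrn$direction > 0]
  dn_mrn <- de_mrn$feature_id[de_mrn$direction < 0]
  cand <- rbind(
    expand.grid(mirna_id = up_mir, mrna_id = dn_mrn,
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE),
    expand.grid(mirna_id = dn_mir, mrna_id = up_mrn,
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE))
  if (p$n_planted_edges > nrow(cand))
    stop(sprintf("n_planted_edges = %d exceeds the %d available opposite-direction DE pairs",
                 p$n_planted_edges, nrow(cand)))
  edges <- if (p$n_planted_edges > 0L)
    cand[sort(sample.int(nrow(cand), p$n_planted_edges)), , drop = FALSE]
  else cand[0, , drop = FALSE]
  rownames(edges) <- NULL
  edges$sign <- rep(-1L, nrow(edges))

  # mRNA log2 intensities
  base_mrn <- stats::runif(p$n_mrna, 5, 12)
  lfc_mrn <- stats::setNames(rep(0, p$n_mrna), gene_ids)
  lfc_mrn[de_mrn$feature_id] <- de_mrn$lfc
  expr <- outer(base_mrn, rep(1, n_samp)) + outer(lfc_mrn, is_case) +
    matrix(stats::rnorm(p$n_mrna * n_samp, sd = p$noise_sd), nrow = p$n_mrna)
  dimnames(expr) <- list(gene_ids, sample_id)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges)))
      expr[edges$mrna_id[i], ] <- expr[edges$mrna_id[i], ] -
        p$coupling * zsig[edges$mirna_id[i], ]
  }
  mrna <- expression_matrix(expr, "log2")

  # prediction databases: shared core + independent true draws + false pairs
  edge_key <- pair_key(edges$mirna_id, edges$mrna_id)
  n_core <- round(p$pairwise_db_overlap_target * nrow(edges))
  core <- if (nrow(edges)) sample.int(nrow(edges), min(n_core, nrow(edges)))
  else integer(0)
  dbs <- vector("list", length(p$db_specs))
  names(dbs) <- names(p$db_specs)
  for (nm in names(p$db_specs)) {
    spec <- p$db_specs[[nm]]
    n_true <- round(spec$coverage * nrow(edges))
    extra <- setdiff(seq_len(nrow(edges)), core)
    take <- c(core, if (n_true > length(core))
      sample(extra, min(n_true - length(core), length(extra))))
    false_idx <- integer(0)
    if (spec$n_false > 0L) {
      # oversample flat indices, discard planted edges, keep the quota
      pool <- unique(sample.int(p$n_mirna * p$n_mrna,
                                min(p$n_mirna * p$n_mrna,
                                    spec$n_false * 2L + 100L)))
      fm <- ((pool - 1L) %% p$n_mirna) + 1L
      fg <- ((pool - 1L) %/% p$n_mirna) + 1L
      keyp <- pair_key(mir_ids[fm], gene_ids[fg])
      okf <- !(keyp %in% edge_key)
      false_idx <- which(okf)[seq_len(min(spec$n_false, sum(okf)))]
      false_idx <- pool[false_idx]
    }
    fm <- ((false_idx - 1L) %% p$n_mirna) + 1L
    fg <- ((false_idx - 1L) %/% p$n_mirna) + 1L
    dbs[[nm]] <- target_db(nm,
                           c(edges$mirna_id[take], mir_ids[fm]),
                           c(edges$mrna_id[take], gene_ids[fg]))
  }
  jac <- NA_real_
  if (length(dbs) >= 2L) {
    pr <- utils::combn(length(dbs), 2L)
    jac <- mean(apply(pr, 2L, function(ij) {
      a <- dbs[[ij[1]]]$key; b <- dbs[[ij[2]]]$key
      length(intersect(a, b)) / length(union(a, b))
    }))
  }

  truth <- structure(list(de_mirna = de_mir, de_mrna = de_mrn, edges = edges,
                          params = p, achieved_db_jaccard = jac),
                     class = "SyntheticTruth")
  structure(list(mirna = mirna, mrna = mrna, samples = sheet, dbs = dbs,
                 truth = truth),
            class = "SyntheticDataset")
}

#' Write or re-read a synthetic dataset
#'
#' Emits every pipeline input in its on-disk format (expression matrices,
#' sample sheet, one file per database) plus plain-text truth tables
#' (`truth_edges.tsv`, `truth_de_mirna.tsv`, `truth_de_mrna.tsv`) and a
#' `params.yaml` echo. `read_dataset()` reverses the operation; matrices
#' round-trip bitwise.
#'
#' @param dataset A `SyntheticDataset`.
#' @param out_dir Writable directory (created if absent).
#' @return Named character vector of the files written.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "SyntheticDataset"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  f <- function(x) file.path(out_dir, x)
  paths <- c(mirna = f("mirna_counts.tsv"), mrna = f("mrna_log2.tsv"),
             samples = f("samples.tsv"))
  write_expression_matrix(dataset$mirna, paths["mirna"])
  write_expression_matrix(dataset$mrna, paths["mrna"])
  write_sample_sheet(dataset$samples, paths["samples"])
  for (d in dataset$dbs) {
    pth <- f(sprintf("db_%s.tsv", d$name))
    write_target_db(d, pth)
    paths[paste0("db_", d$name)] <- pth
  }
  tr <- dataset$truth
  num17 <- function(df) {
    df[] <- lapply(df, function(col)
      if (is.double(col)) sprintf("%.17g", col) else col)
    df
  }
  utils::write.table(num17(tr$edges), f("truth_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(num17(tr$de_mirna), f("truth_de_mirna.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(num17(tr$de_mrna), f("truth_de_mrna.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pl <- tr$params
  class(pl) <- NULL
  yaml::write_yaml(pl, f("params.yaml"), precision = 17L)
  paths <- c(paths, truth_edges = f("truth_edges.tsv"),
             truth_de_mirna = f("truth_de_mirna.tsv"),
             truth_de_mrna = f("truth_de_mrna.tsv"),
             params = f("params.yaml"))
  paths
}

#' @rdname write_dataset
#' @param dir Directory previously populated by [write_dataset()].
#' @export
read_dataset <- function(dir) {
  f <- function(x) file.path(dir, x)
  pl <- yaml::read_yaml(f("params.yaml"))
  params <- do.call(synthetic_params, pl)
  read_truth_df <- function(path, numeric_cols) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                             colClasses = "character")
    for (cc in intersect(numeric_cols, colnames(tab)))
      tab[[cc]] <- as.numeric(tab[[cc]])
    tab
  }
  dbs <- lapply(names(params$db_specs), function(nm)
    read_target_db(f(sprintf("db_%s.tsv", nm)), nm))
  names(dbs) <- names(params$db_specs)
  edges <- read_truth_df(f("truth_edges.tsv"), "sign")
  if ("sign" %in% colnames(edges)) edges$sign <- as.integer(edges$sign)
  truth <- structure(list(
    de_mirna = read_truth_df(f("truth_de_mirna.tsv"), c("direction", "lfc")),
    de_mrna = read_truth_df(f("truth_de_mrna.tsv"), c("direction", "lfc")),
    edges = edges, params = params, achieved_db_jaccard = NA_real_),
    class = "SyntheticTruth")
  structure(list(mirna = read_expression_matrix(f("mirna_counts.tsv"), "counts"),
                 mrna = read_expression_matrix(f("mrna_log2.tsv"), "log2"),
                 samples = read_sample_sheet(f("samples.tsv")),
                 dbs = dbs, truth = truth),
            class = "SyntheticDataset")
}

#' Random gene-set collection
#'
#' Draws gene sets of uniformly random size from a gene universe; useful as
#' a synthetic stand-in for pathway collections when testing enrichment.
#'
#' @param genes Character vector of gene ids to draw from.
#' @param n_sets Number of sets.
#' @param set_size_range Inclusive size range.
#' @param seed Integer seed.
#' @return A [gene_set_collection()] with sets `SET001`, `SET002`, ...
#' @export
simulate_gene_sets <- function(genes, n_sets = 50L, set_size_range = c(10L, 60L),
                               seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  set.seed(as.integer(seed))
  sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets,
                  replace = TRUE)
  sets <- lapply(sizes, function(s) sample(genes, min(s, length(genes))))
  names(sets) <- sprintf("SET%03d", seq_len(n_sets))
  gene_set_collection(sets, rep("synthetic gene set", n_sets))
}
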