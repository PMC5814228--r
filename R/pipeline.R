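# End-to-end orchestration: a validated config drives the stages
# simulate (optional) -> de -> correlate -> integrate -> summarize ->
# enrich, each runnable standalone on the previous stage's files. Every
# filtering step logs row counts in and out, and a JSON manifest records
# parameters, seed and the pair-count funnel.

#' Pipeline configuration
#'
#' All knobs of the pipeline in one validated object. Either `simulate`
#' holds generator overrides (see [synthetic_params()]) and the simulate
#' stage creates the inputs under `<out_dir>/data`, or `inputs` names
#' existing files: `mirna_counts`, `mrna_log2`, `samples`, `dbs` (named
#' list of target-db paths) and optionally `gmt`.
#'
#' @param out_dir Run directory (created on demand); all stage outputs and
#'   the manifest land here.
#' @param seed Integer seed; the only source of randomness.
#' @param simulate `NULL`, or a (possibly empty) list of overrides for
#'   [synthetic_params()].
#' @param inputs `NULL`, or a named list of input paths (see above).
#' @param fdr_de,fdr_cor,fdr_enrich Strict FDR thresholds, all in (0, 1).
#' @param cor_method,cor_sided Passed to [all_pairs()].
#' @param min_dbs Database-support threshold for the interaction table.
#' @param log2_offset,trend,span Passed to [de_table()].
#' @param enrich_universe `"expressed"` (all mRNAs on the array) or `"de"`
#'   (DE mRNAs only) as the enrichment universe.
#' @return List of class `PipelineConfig`.
#' @export
pipeline_config <- function(out_dir, seed, simulate = NULL, inputs = NULL,
                            fdr_de = 0.05, fdr_cor = 0.05, fdr_enrich = 0.05,
                            cor_method = "pearson", cor_sided = "two",
                            min_dbs = 1L, log2_offset = 1, trend = TRUE,
                            span = 0.5, enrich_universe = "expressed") {
  th <- c(fdr_de, fdr_cor, fdr_enrich)
  if (any(th <= 0 | th >= 1)) stop("FDR thresholds must lie in (0, 1)")
  if (is.null(simulate) && is.null(inputs))
    stop("provide either 'simulate' parameters or 'inputs' paths")
  if (!is.null(inputs)) {
    need <- c("mirna_counts", "mrna_log2", "samples", "dbs")
    miss <- setdiff(need, names(inputs))
    if (length(miss))
      stop("'inputs' is missing: ", paste(miss, collapse = ", "))
    flat <- c(inputs$mirna_counts, inputs$mrna_log2, inputs$samples,
              unlist(inputs$dbs), inputs$gmt)
    gone <- flat[!file.exists(flat)]
    if (length(gone))
      stop("input file(s) not found: ", paste(gone, collapse = ", "))
  }
  if (min_dbs < 1L) stop("'min_dbs' must be >= 1")
  if (!is.null(inputs) && min_dbs > length(inputs$dbs))
    stop(sprintf("'min_dbs' = %d exceeds the %d configured database(s)",
                 min_dbs, length(inputs$dbs)))
  if (!is.null(simulate) && !is.null(simulate$db_specs) &&
      min_dbs > length(simulate$db_specs))
    stop(sprintf("'min_dbs' = %d exceeds the %d configured database(s)",
                 min_dbs, length(simulate$db_specs)))
  enrich_universe <- match.arg(enrich_universe, c("expressed", "de"))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, inputs = inputs,
                 fdr_de = fdr_de, fdr_cor = fdr_cor, fdr_enrich = fdr_enrich,
                 cor_method = cor_method, cor_sided = cor_sided,
                 min_dbs = as.integer(min_dbs), log2_offset = log2_offset,
                 trend = trend, span = span,
                 enrich_universe = enrich_universe),
            class = "PipelineConfig")
}

#' @rdname pipeline_config
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

log_stage <- function(...) message("[mircor] ", sprintf(...))

# Resolve the pipeline input paths: explicit config$inputs, or the files
# the simulate stage wrote under <out_dir>/data.
resolve_inputs <- function(config) {
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    if (is.null(names(inp$dbs)))
      names(inp$dbs) <- sprintf("db%d", seq_along(inp$dbs))
    return(inp)
  }
  dd <- file.path(config$out_dir, "data")
  if (!file.exists(file.path(dd, "samples.tsv")))
    stop("expected simulated inputs under ", dd,
         "; run stage_simulate() first")
  params <- yaml::read_yaml(file.path(dd, "params.yaml"))
  db_names <- names(params$db_specs)
  dbs <- stats::setNames(file.path(dd, sprintf("db_%s.tsv", db_names)),
                         db_names)
  list(mirna_counts = file.path(dd, "mirna_counts.tsv"),
       mrna_log2 = file.path(dd, "mrna_log2.tsv"),
       samples = file.path(dd, "samples.tsv"),
       dbs = as.list(dbs),
       gmt = {
         g <- file.path(dd, "gene_sets.gmt")
         if (file.exists(g)) g else NULL
       })
}

read_inputs <- function(config) {
  inp <- resolve_inputs(config)
  dbs <- lapply(names(inp$dbs), function(nm) read_target_db(inp$dbs[[nm]], nm))
  names(dbs) <- names(inp$dbs)
  list(mirna = read_expression_matrix(inp$mirna_counts, "counts"),
       mrna = read_expression_matrix(inp$mrna_log2, "log2"),
       samples = read_sample_sheet(inp$samples),
       dbs = dbs, gmt = inp$gmt)
}

#' Pipeline stages
#'
#' Each stage reads the previous stage's files from the run directory (or
#' the configured inputs), writes its own outputs there, and returns a
#' small list of row counts for the manifest. [run_pipeline()] chains them;
#' running them one by one produces byte-identical files.
#'
#' @param config A [pipeline_config()].
#' @return A list of per-stage counts (invisible from [run_pipeline()]).
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(config$simulate)) stop("config has no 'simulate' block")
  args <- config$simulate
  args$seed <- config$seed
  params <- do.call(synthetic_params, args)
  ds <- generate_dataset(params)
  paths <- write_dataset(ds, file.path(config$out_dir, "data"))
  # convenience: a config snippet pointing at the files just written
  snippet <- list(inputs = list(
    mirna_counts = unname(paths[["mirna"]]),
    mrna_log2 = unname(paths[["mrna"]]),
    samples = unname(paths[["samples"]]),
    dbs = as.list(paths[grepl("^db_", names(paths))])))
  names(snippet$inputs$dbs) <- sub("^db_", "", names(snippet$inputs$dbs))
  yaml::write_yaml(snippet, file.path(config$out_dir, "data",
                                      "inputs_snippet.yaml"))
  log_stage("simulate: %d miRNAs x %d samples; %d mRNAs; %d planted edges",
            nrow(ds$mirna$values), ncol(ds$mirna$values),
            nrow(ds$mrna$values), nrow(ds$truth$edges))
  invisible(list(n_mirna = nrow(ds$mirna$values),
                 n_mrna = nrow(ds$mrna$values),
                 n_planted_edges = nrow(ds$truth$edges)))
}

#' @rdname pipeline_stages
#' @export
stage_de <- function(config) {
  inp <- read_inputs(config)
  de_mir <- de_table(inp$mirna, inp$samples, trend = config$trend,
                     fdr_threshold = config$fdr_de,
                     log2_offset = config$log2_offset, span = config$span)
  de_mrn <- de_table(inp$mrna, inp$samples, trend = config$trend,
                     fdr_threshold = config$fdr_de, span = config$span)
  write_de_table(de_mir, file.path(config$out_dir, "de_mirna.tsv"))
  write_de_table(de_mrn, file.path(config$out_dir, "de_mrna.tsv"))
  sel_mir <- select_de(de_mir, config$fdr_de)
  sel_mrn <- select_de(de_mrn, config$fdr_de)
  log_stage("de: %d/%d miRNAs (%d up, %d down), %d/%d mRNAs (%d up, %d down) at FDR < %g",
            sel_mir$n_total, nrow(de_mir), sel_mir$n_up, sel_mir$n_down,
            sel_mrn$n_total, nrow(de_mrn), sel_mrn$n_up, sel_mrn$n_down,
            config$fdr_de)
  invisible(list(n_de_mirna = sel_mir$n_total, n_de_mrna = sel_mrn$n_total))
}

read_stage_file <- function(config, file, stage) {
  path <- file.path(config$out_dir, file)
  if (!file.exists(path))
    stop(sprintf("missing '%s'; run %s first", path, stage))
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname pipeline_stages
#' @export
stage_correlate <- function(config) {
  inp <- read_inputs(config)
  de_mir <- read_stage_file(config, "de_mirna.tsv", "stage_de()")
  de_mrn <- read_stage_file(config, "de_mrna.tsv", "stage_de()")
  sel_mir <- select_de(de_mir, config$fdr_de)
  sel_mrn <- select_de(de_mrn, config$fdr_de)
  ids_mir <- c(sel_mir$up, sel_mir$down)
  ids_mrn <- c(sel_mrn$up, sel_mrn$down)
  if (length(ids_mir) == 0L || length(ids_mrn) == 0L)
    stop("no differentially expressed features; nothing to correlate")
  mir_log2 <- log2_normalize(inp$mirna, estimate_size_factors(inp$mirna),
                             config$log2_offset)
  mir_sub <- expression_matrix(
    mir_log2$values[feature_ids(mir_log2) %in% ids_mir, , drop = FALSE], "log2")
  mrn_sub <- expression_matrix(
    inp$mrna$values[feature_ids(inp$mrna) %in% ids_mrn, , drop = FALSE], "log2")
  pairs <- all_pairs(mir_sub, mrn_sub, method = config$cor_method,
                     sided = config$cor_sided, de_mirna = de_mir,
                     de_mrna = de_mrn)
  counts <- summarize_counts(pairs, config$fdr_cor)
  negsig <- pairs[pairs$cor < 0 & pairs$fdr < config$fdr_cor, , drop = FALSE]
  write_pair_table(negsig, file.path(config$out_dir, "pairs_negsig.tsv"))
  utils::write.table(
    data.frame(total = counts$total, negative = counts$negative,
               negative_significant = counts$negative_significant,
               pct_negative_significant = counts$pct_negative_significant),
    file.path(config$out_dir, "pair_counts.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("correlate: %d pairs -> %d negative -> %d significant (%.1f%%)",
            counts$total, counts$negative, counts$negative_significant,
            counts$pct_negative_significant)
  invisible(list(pairs_total = counts$total, pairs_negative = counts$negative,
                 pairs_negative_significant = counts$negative_significant))
}

#' @rdname pipeline_stages
#' @export
stage_integrate <- function(config) {
  inp <- read_inputs(config)
  negsig <- read_stage_file(config, "pairs_negsig.tsv", "stage_correlate()")
  annotated <- annotate_predictions(negsig, inp$dbs)
  interactions <- filter_interactions(annotated, config$fdr_cor, min_dbs = 1L)
  final <- filter_interactions(annotated, config$fdr_cor, config$min_dbs)
  high_conf <- filter_interactions(annotated, config$fdr_cor,
                                   length(inp$dbs))
  write_interactions(interactions, file.path(config$out_dir,
                                             "interactions.tsv"))
  write_interactions(final, file.path(config$out_dir,
                                      "interactions_selected.tsv"))
  write_interactions(high_conf, file.path(config$out_dir,
                                          "interactions_highconf.tsv"))
  vr <- venn_regions(inp$dbs, universe = interactions)
  utils::write.table(data.frame(region = names(vr), count = as.integer(vr)),
                     file.path(config$out_dir, "venn_regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(vr), file.path(config$out_dir,
                                              "venn_regions.json"),
                       auto_unbox = TRUE)
  log_stage("integrate: %d significant negative pairs -> %d predicted (>=1 db) -> %d selected (>=%d dbs); %d high-confidence",
            nrow(negsig), nrow(interactions), nrow(final), config$min_dbs,
            nrow(high_conf))
  invisible(list(pairs_predicted = nrow(interactions),
                 interactions_final = nrow(final),
                 interactions_highconf = nrow(high_conf)))
}

#' @rdname pipeline_stages
#' @export
stage_summarize <- function(config) {
  interactions <- read_stage_file(config, "interactions_selected.tsv",
                                  "stage_integrate()")
  de_mir <- read_stage_file(config, "de_mirna.tsv", "stage_de()")
  de_mrn <- read_stage_file(config, "de_mrna.tsv", "stage_de()")
  inp <- read_inputs(config)
  sel_mir <- select_de(de_mir, config$fdr_de)
  sel_mrn <- select_de(de_mrn, config$fdr_de)
  universe <- c(sel_mrn$up, sel_mrn$down)
  tpm <- targets_per_mirna(interactions)
  utils::write.table(tpm, file.path(config$out_dir, "targets_per_mirna.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  red <- reduction_report(interactions, inp$dbs,
                          c(sel_mir$up, sel_mir$down), universe)
  utils::write.table(red, file.path(config$out_dir, "reduction_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(universe)) {
    cov <- cumulative_coverage(interactions, universe)
    utils::write.table(as.data.frame(cov),
                       file.path(config$out_dir, "coverage_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    hist <- mirnas_per_mrna_histogram(interactions, universe)
    utils::write.table(data.frame(bin = names(hist),
                                  count = as.integer(hist)),
                       file.path(config$out_dir, "mirnas_per_mrna.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  g <- build_network(interactions, de_mir, de_mrn)
  export_network(g, file.path(config$out_dir, "network.graphml"),
                 file.path(config$out_dir, "network_edges.tsv"))
  log_stage("summarize: %d interactions, %d miRNA nodes, %d mRNA nodes",
            nrow(interactions), sum(igraph::V(g)$kind == "miRNA"),
            sum(igraph::V(g)$kind == "mRNA"))
  invisible(list(n_mirna_nodes = sum(igraph::V(g)$kind == "miRNA"),
                 n_mrna_nodes = sum(igraph::V(g)$kind == "mRNA")))
}

#' @rdname pipeline_stages
#' @export
stage_enrich <- function(config) {
  inp <- read_inputs(config)
  if (is.null(inp$gmt)) {
    log_stage("enrich: no gene-set collection configured; skipping")
    return(invisible(list(enriched_sets = NA_integer_)))
  }
  interactions <- read_stage_file(config, "interactions_selected.tsv",
                                  "stage_integrate()")
  de_mrn <- read_stage_file(config, "de_mrna.tsv", "stage_de()")
  collection <- read_gmt(inp$gmt)
  tpm <- targets_per_mirna(interactions)
  if (nrow(tpm) == 0L) stop("no interactions to enrich; empty interaction table")
  top <- tpm$mirna_id[1L]
  targets <- unique(interactions$mrna_id[interactions$mirna_id == top])
  universe <- if (config$enrich_universe == "expressed")
    de_mrn$feature_id else {
      sel <- select_de(de_mrn, config$fdr_de)
      c(sel$up, sel$down)
    }
  log_stage("enrich: top miRNA '%s' with %d targets; universe '%s' (%d genes)",
            top, length(targets), config$enrich_universe, length(unique(universe)))
  enr <- enrich_target_set(targets, collection, universe,
                           fdr_threshold = config$fdr_enrich)
  utils::write.table(as.data.frame(enr),
                     file.path(config$out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(enriched_sets = sum(enr$significant),
                 top_mirna = top))
}

#' Run the whole pipeline
#'
#' Executes simulate (when configured) -> de -> correlate -> integrate ->
#' summarize -> enrich and writes `manifest.json` recording the package
#' version, seed, configuration and the pair-count funnel
#' (total >= negative >= significant >= predicted >= final). A stage
#' failure aborts with the stage name; the manifest is only written on
#' success, so a partial run directory is recognizable by its absence.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  stages <- list(simulate = stage_simulate, de = stage_de,
                 correlate = stage_correlate, integrate = stage_integrate,
                 summarize = stage_summarize, enrich = stage_enrich)
  if (is.null(config$simulate)) stages$simulate <- NULL
  info <- list()
  for (nm in names(stages)) {
    info[[nm]] <- tryCatch(stages[[nm]](config), error = function(e)
      stop(sprintf("stage '%s' failed: %s", nm, conditionMessage(e)),
           call. = FALSE))
  }
  cfg <- unclass(config)
  manifest <- list(
    package = "mircor",
    version = as.character(utils::packageVersion("mircor")),
    seed = config$seed,
    config = cfg[setdiff(names(cfg), c("simulate", "inputs", "out_dir"))],
    stages = info,
    funnel = list(total = info$correlate$pairs_total,
                  negative = info$correlate$pairs_negative,
                  significant = info$correlate$pairs_negative_significant,
                  predicted = info$integrate$pairs_predicted,
                  final = info$integrate$interactions_final))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
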