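# Intersection of correlation evidence with target-prediction databases:
# per-pair database support flags and their sum, the filtered interaction
# table, the database-overlap (Venn) decomposition, and the per-miRNA
# reduction report comparing retained interactions with raw predictions.

db_list_names <- function(dbs) {
  vapply(dbs, function(d) d$name, "")
}

pair_key <- function(mirna, gene) paste(mirna, gene, sep = "\t")

#' Flag pairs with database support
#'
#' Adds one 0/1 indicator column per database (named after the database)
#' plus `dat_sum`, the number of supporting databases. No records are added
#' or removed; both sides are canonicalized before lookup.
#'
#' @param pairs A `PairTable` from [all_pairs()].
#' @param dbs Non-empty list of [target_db()] objects with distinct names.
#' @return The input table with the flag columns appended; attribute
#'   `db_names` records the flag column names.
#' @export
annotate_predictions <- function(pairs, dbs) {
  if (length(dbs) == 0L) stop("at least one target-prediction database required")
  nms <- db_list_names(dbs)
  if (anyDuplicated(nms)) stop("database names must be distinct")
  key <- pair_key(suppressMessages(canonicalize_mirna_id(pairs$mirna_id)),
                  canonicalize_gene_id(pairs$mrna_id))
  for (d in dbs) pairs[[d$name]] <- as.integer(key %in% d$key)
  pairs$dat_sum <- as.integer(rowSums(as.matrix(pairs[, nms, drop = FALSE])))
  attr(pairs, "db_names") <- nms
  pairs
}

#' Filter to the supported negative interactions
#'
#' Keeps records with `cor < 0`, `fdr < fdr_threshold` (strict) and
#' `dat_sum >= min_dbs`. With `min_dbs` equal to the number of loaded
#' databases this is the high-confidence subset (every database agrees).
#'
#' @param annotated Output of [annotate_predictions()].
#' @param fdr_threshold Strict FDR cutoff.
#' @param min_dbs Minimum number of supporting databases (>= 1).
#' @return The retained records, class `InteractionTable`; `db_names`
#'   attribute preserved.
#' @export
filter_interactions <- function(annotated, fdr_threshold = 0.05, min_dbs = 1L) {
  nms <- attr(annotated, "db_names")
  if (is.null(nms)) stop("run annotate_predictions() first")
  if (min_dbs < 1L) stop("'min_dbs' must be >= 1")
  if (min_dbs > length(nms))
    stop(sprintf("'min_dbs' = %d exceeds the %d loaded database(s)",
                 min_dbs, length(nms)))
  keep <- annotated$cor < 0 & annotated$fdr < fdr_threshold &
    annotated$dat_sum >= min_dbs
  out <- annotated[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "db_names") <- nms
  class(out) <- unique(c("InteractionTable", class(out)))
  out
}

#' Exclusive-region (Venn) decomposition of database membership
#'
#' Counts, for every non-empty membership pattern of the databases, the
#' pairs of `universe` carrying exactly that pattern. Region counts sum to
#' the size of the union within the universe, so inclusion-exclusion
#' identities hold exactly.
#'
#' @param dbs List of >= 2 [target_db()] objects.
#' @param universe Optional pair universe: a data.frame with
#'   `mirna_id`/`mrna_id` columns (e.g. an interaction table), or a
#'   character vector of `"mirna\tgene"` keys. Defaults to the union of the
#'   databases.
#' @return Named integer vector over the 2^k - 1 non-empty patterns; names
#'   join member databases with `"&"`. Attribute `universe_size`.
#' @export
venn_regions <- function(dbs, universe = NULL) {
  if (length(dbs) < 2L) stop("need at least 2 databases")
  nms <- db_list_names(dbs)
  keys <- if (is.null(universe)) {
    unique(unlist(lapply(dbs, `[[`, "key"), use.names = FALSE))
  } else if (is.data.frame(universe)) {
    unique(pair_key(suppressMessages(canonicalize_mirna_id(universe$mirna_id)),
                    canonicalize_gene_id(universe$mrna_id)))
  } else {
    unique(as.character(universe))
  }
  k <- length(dbs)
  region_names <- vapply(seq_len(2^k - 1L), function(code) {
    paste(nms[bitwAnd(code, 2^(seq_len(k) - 1L)) > 0], collapse = "&")
  }, "")
  if (length(keys) == 0L) {
    out <- stats::setNames(integer(2^k - 1L), region_names)
    attr(out, "universe_size") <- 0L
    return(out)
  }
  member <- vapply(dbs, function(d) keys %in% d$key, logical(length(keys)))
  member <- matrix(member, nrow = length(keys))
  code <- as.integer(member %*% 2^(seq_len(k) - 1L))
  counts <- tabulate(code, nbins = 2^k - 1L)
  out <- stats::setNames(counts, region_names)
  attr(out, "universe_size") <- length(keys)
  out
}

#' Per-miRNA reduction of raw predictions
#'
#' For each differentially expressed miRNA: `kept` is its number of distinct
#' retained targets in the interaction table; `orig` is the number of
#' distinct targets predicted for it by the union of the databases,
#' restricted (by default) to the DE mRNA universe; `reduction_pct` is
#' (orig - kept) / orig * 100 rounded to the nearest integer. miRNAs with no
#' raw predictions are flagged (`reduction_pct = NA`) and excluded from the
#' global average.
#'
#' @param interactions An `InteractionTable`.
#' @param dbs The database list used for annotation.
#' @param de_mirnas Character vector of DE miRNA ids to report on.
#' @param de_mrnas Character vector restricting the prediction universe;
#'   `NULL` disables the restriction.
#' @return data.frame with columns `mirna_id`, `kept`, `orig`,
#'   `reduction_pct`, sorted by `kept` descending; attribute
#'   `mean_reduction_pct` is the global average over unflagged miRNAs.
#' @export
reduction_report <- function(interactions, dbs, de_mirnas, de_mrnas = NULL) {
  de_mirnas <- unique(suppressMessages(canonicalize_mirna_id(de_mirnas)))
  union_pairs <- unique(do.call(rbind, lapply(dbs, function(d)
    d$pairs[, c("mirna_id", "gene_id")])))
  if (!is.null(de_mrnas))
    union_pairs <- union_pairs[union_pairs$gene_id %in%
                                 canonicalize_gene_id(de_mrnas), , drop = FALSE]
  orig <- vapply(de_mirnas, function(m)
    length(unique(union_pairs$gene_id[union_pairs$mirna_id == m])), 0L)
  kept <- vapply(de_mirnas, function(m)
    length(unique(interactions$mrna_id[interactions$mirna_id == m])), 0L)
  red <- ifelse(orig > 0L, round((orig - kept) / orig * 100), NA_real_)
  out <- data.frame(mirna_id = de_mirnas, kept = kept, orig = orig,
                    reduction_pct = red, stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- out[order(-out$kept, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mean_reduction_pct") <- mean(red[orig > 0L])
  out
}

#' @rdname filter_interactions
#' @param interactions An `InteractionTable`.
#' @param path Output path; written ranked (see [rank_interactions()]).
#' @param sep Field separator.
#' @export
write_interactions <- function(interactions, path, sep = "\t") {
  utils::write.table(as.data.frame(rank_interactions(interactions)), path,
                     sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
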