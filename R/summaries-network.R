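# Ranking, per-feature target statistics, cumulative coverage of the DE
# mRNA universe, and bipartite network export (GraphML + edge list).

#' Rank an interaction table
#'
#' Deterministic three-key sort: FDR ascending, correlation ascending (more
#' negative first), then (mirna_id, mrna_id) lexicographic to break exact
#' ties.
#'
#' @param table An interaction (or pair) table.
#' @return The table reordered; attributes preserved.
#' @export
rank_interactions <- function(table) {
  ord <- order(table$fdr, table$cor, table$mirna_id, table$mrna_id)
  out <- table[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "db_names") <- attr(table, "db_names")
  out
}

#' Distinct-target counts per miRNA
#'
#' @param table An interaction table.
#' @return data.frame with `mirna_id` and `n_targets`, sorted by count
#'   descending then id.
#' @export
targets_per_mirna <- function(table) {
  if (nrow(table) == 0L)
    return(data.frame(mirna_id = character(0), n_targets = integer(0)))
  uniq <- unique(table[, c("mirna_id", "mrna_id")])
  cnt <- base::table(uniq$mirna_id)
  out <- data.frame(mirna_id = names(cnt), n_targets = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_targets, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cumulative coverage of the DE mRNA universe
#'
#' Walks the miRNAs in descending target-count order and records, at each
#' step, the cumulative number and fraction of universe mRNAs targeted by
#' at least one miRNA so far. The terminal fraction equals the fraction of
#' universe mRNAs with any targeting miRNA.
#'
#' @param table An interaction table whose `mrna_id`s all lie in `universe`.
#' @param universe Non-empty character vector of DE mRNA ids.
#' @return data.frame of class `CoverageCurve`: `mirna_id`, `n_targets`,
#'   `cum_mrnas`, `cum_fraction`.
#' @export
cumulative_coverage <- function(table, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty mRNA universe")
  outside <- setdiff(unique(table$mrna_id), universe)
  if (length(outside))
    stop("interaction mRNA(s) outside the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  ranked <- targets_per_mirna(table)
  seen <- character(0)
  cum <- integer(nrow(ranked))
  for (i in seq_len(nrow(ranked))) {
    seen <- union(seen, table$mrna_id[table$mirna_id == ranked$mirna_id[i]])
    cum[i] <- length(seen)
  }
  out <- data.frame(ranked, cum_mrnas = cum,
                    cum_fraction = cum / length(universe))
  class(out) <- c("CoverageCurve", "data.frame")
  out
}

#' Regulator-count histogram over the mRNA universe
#'
#' Bins every universe mRNA by its number of distinct targeting miRNAs into
#' the categories 0, 1, ..., `max_bin`, and `> max_bin`. Bin totals sum to
#' the universe size.
#'
#' @param table An interaction table.
#' @param universe Non-empty character vector of DE mRNA ids.
#' @param max_bin Upper exact bin (default 5, i.e. bins 0-5 and ">5").
#' @return Named integer vector of bin counts.
#' @export
mirnas_per_mrna_histogram <- function(table, universe, max_bin = 5L) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty mRNA universe")
  uniq <- unique(table[, c("mirna_id", "mrna_id")])
  deg <- base::table(factor(uniq$mrna_id, levels = universe))
  bins <- c(as.character(0:max_bin), paste0(">", max_bin))
  cut_deg <- ifelse(deg > max_bin, paste0(">", max_bin), as.character(deg))
  counts <- base::table(factor(cut_deg, levels = bins))
  stats::setNames(as.integer(counts), bins)
}

#' Build and export the bipartite interaction network
#'
#' Nodes are the distinct miRNA and mRNA endpoints of the interaction table
#' with attributes `kind` ("miRNA"/"mRNA"), `signed_fc` and `direction`
#' taken from the DE tables; edges carry `cor`, `fdr` and `dat_sum`.
#' `export_network()` writes standard GraphML (re-parseable with any GraphML
#' reader) and a delimited edge list.
#'
#' @param table An interaction table (typically the high-confidence subset).
#' @param de_mirna,de_mrna `DEResult` tables supplying node attributes.
#' @return An `igraph` bipartite graph.
#' @export
build_network <- function(table, de_mirna, de_mrna) {
  mir <- unique(table$mirna_id)
  mrn <- unique(table$mrna_id)
  grab <- function(ids, de, col)
    de[[col]][match(ids, de$feature_id)]
  nodes <- data.frame(
    name = c(mir, mrn),
    kind = rep(c("miRNA", "mRNA"), c(length(mir), length(mrn))),
    signed_fc = c(grab(mir, de_mirna, "signed_fc"),
                  grab(mrn, de_mrna, "signed_fc")),
    direction = c(grab(mir, de_mirna, "direction"),
                  grab(mrn, de_mrna, "direction")),
    stringsAsFactors = FALSE)
  edges <- data.frame(from = table$mirna_id, to = table$mrna_id,
                      cor = table$cor, fdr = table$fdr,
                      dat_sum = if ("dat_sum" %in% colnames(table))
                        table$dat_sum else NA_integer_,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
  igraph::V(g)$type <- igraph::V(g)$kind == "mRNA"
  g
}

#' @rdname build_network
#' @param g Graph from [build_network()].
#' @param graphml_path,edgelist_path Output paths (`NULL` to skip one).
#' @param sep Field separator for the edge list.
#' @export
export_network <- function(g, graphml_path = NULL, edgelist_path = NULL,
                           sep = "\t") {
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(edgelist_path)) {
    el <- igraph::as_data_frame(g, what = "edges")
    colnames(el)[1:2] <- c("mirna_id", "mrna_id")
    utils::write.table(el, edgelist_path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(graphml = graphml_path, edgelist = edgelist_path))
}
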