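# Domain containers and readers/writers for every external format the
# pipeline touches: expression matrices, sample sheets, target-prediction
# tables and GMT gene-set collections. All identifiers are canonicalized on
# entry; all tables are plain delimited text (tab by default, comma via
# `sep`), decimal separator always ".".

#' Construct an expression matrix
#'
#' An `ExpressionMatrix` is a features x samples numeric matrix tagged with
#' the kind of values it holds: raw sequencing counts (`"counts"`) or
#' continuous log2-scale intensities (`"log2"`). Feature and sample
#' identifiers must be unique; count matrices must be non-negative integers
#' and log2 matrices finite.
#'
#' @param values Numeric matrix with rownames (feature ids) and colnames
#'   (sample ids).
#' @param value_kind Either `"counts"` or `"log2"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `value_kind`.
#' @examples
#' m <- matrix(1:4, 2, 2, dimnames = list(c("miR-1", "miR-2"), c("s1", "s2")))
#' expression_matrix(m, "counts")
#' @export
expression_matrix <- function(values, value_kind = c("counts", "log2")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry feature ids as rownames and sample ids as colnames")
  dup_f <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_f))
    stop("duplicate feature id(s): ", paste(unique(dup_f), collapse = ", "))
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  if (value_kind == "counts") {
    if (anyNA(values) || any(values < 0))
      stop("count matrix must be non-negative with no missing values")
    frac <- which(values != round(values), arr.ind = TRUE)
    if (nrow(frac))
      stop(sprintf("count matrix contains a fractional value at row '%s', column '%s'",
                   rownames(values)[frac[1, 1]], colnames(values)[frac[1, 2]]))
  } else {
    if (anyNA(values) || any(!is.finite(values)))
      stop("log2 matrix must be finite with no missing values")
  }
  structure(list(values = values, value_kind = value_kind),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d features x %d samples\n",
              x$value_kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x An `ExpressionMatrix`.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read or write an expression matrix
#'
#' The on-disk layout is delimited text with the feature id in the first
#' column and one header column per sample. Values are written with full
#' double precision so that a write/read round trip is bitwise exact.
#'
#' @param path Path to a delimited text file.
#' @param value_kind `"counts"` or `"log2"`; the declared kind is validated
#'   against the values.
#' @param sep Field separator, tab by default.
#' @return `read_expression_matrix()` returns an [expression_matrix()];
#'   `write_expression_matrix()` returns `path` invisibly.
#' @export
read_expression_matrix <- function(path, value_kind = c("counts", "log2"),
                                   sep = "\t") {
  value_kind <- match.arg(value_kind)
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  if (ncol(tab) < 2L) stop("expression matrix needs a feature id column plus >= 1 sample")
  ids <- tab[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate feature id(s) in ", path, ": ", paste(unique(dup), collapse = ", "))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s'",
                 vals[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(vals)[bad[1, 2]]))
  dimnames(num) <- list(ids, colnames(vals))
  expression_matrix(num, value_kind)
}

#' @rdname read_expression_matrix
#' @param em An `ExpressionMatrix`.
#' @export
write_expression_matrix <- function(em, path, sep = "\t") {
  stopifnot(inherits(em, "ExpressionMatrix"))
  v <- em$values
  out <- cbind(feature_id = rownames(v),
               array(sprintf("%.17g", v), dim = dim(v), dimnames = dimnames(v)))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct or read a case/control sample sheet
#'
#' Assigns every expression sample to exactly one of the two groups. Both
#' groups must contain at least two samples for the two-group model to have
#' residual degrees of freedom.
#'
#' @param sample_id Character vector of unique sample ids.
#' @param group Character vector, each element `"case"` or `"control"`.
#' @return A `data.frame` of class `SampleSheet` with columns `sample_id`
#'   and `group`.
#' @export
sample_sheet <- function(sample_id, group) {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (length(sample_id) != length(group))
    stop("'sample_id' and 'group' lengths differ")
  if (anyDuplicated(sample_id))
    stop("duplicate sample id(s): ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (!all(group %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'")
  if (sum(group == "case") < 2L || sum(group == "control") < 2L)
    stop("each group needs at least 2 samples")
  structure(data.frame(sample_id = sample_id, group = group,
                       stringsAsFactors = FALSE),
            class = c("SampleSheet", "data.frame"))
}

#' @rdname sample_sheet
#' @param path Two-column delimited text file with header `sample_id`, `group`.
#' @param sep Field separator.
#' @export
read_sample_sheet <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           check.names = FALSE, colClasses = "character")
  need <- c("sample_id", "group")
  if (!all(need %in% colnames(tab)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  sample_sheet(tab$sample_id, tab$group)
}

#' @rdname sample_sheet
#' @param sheet A `SampleSheet`.
#' @export
write_sample_sheet <- function(sheet, path, sep = "\t") {
  utils::write.table(sheet, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Checks that a sample sheet covers exactly the samples of one or more
# expression matrices, in any order.
check_samples <- function(sheet, ...) {
  for (em in list(...)) {
    if (!setequal(sample_ids(em), sheet$sample_id) ||
        length(sample_ids(em)) != nrow(sheet))
      stop("sample sheet does not match expression matrix sample ids")
  }
  invisible(TRUE)
}

#' Canonicalize miRNA identifiers
#'
#' Strips a leading three-letter species prefix (e.g. `"hsa-"`) when it is
#' followed by a `miR`/`mir`/`let` stem, case-folds the `mir` stem to `miR`,
#' and trims surrounding whitespace. Arm suffixes (`-5p`/`-3p`) and the
#' star/passenger-strand marker (`*`) are preserved: `miR-148a` and
#' `miR-148a*` are distinct mature species and are never merged. The
#' transformation is idempotent.
#'
#' @param x Character vector of miRNA ids; empty strings are an error.
#' @return Character vector of canonical ids.
#' @examples
#' canonicalize_mirna_id(c("hsa-miR-21", "MIR-148a*", "hsa-let-7a"))
#' @export
canonicalize_mirna_id <- function(x) {
  x <- trimws(as.character(x))
  if (length(x) == 0L) return(character(0))
  if (anyNA(x) || any(!nzchar(x))) stop("empty miRNA id")
  stripped <- sub("^[A-Za-z]{3}-(?=(miR|mir|MIR|let|Let|LET)\\b|(miR|mir|MIR|let|Let|LET)-)",
                  "", x, perl = TRUE)
  n_strip <- sum(stripped != x)
  if (n_strip > 0L)
    message(sprintf("stripped species prefix from %d miRNA id(s)", n_strip))
  out <- sub("^(mir|MIR|MiR|mIR|miR)", "miR", stripped)
  sub("^(let|Let|LET)", "let", out)
}

# Gene symbols are matched by exact string equality after uppercasing; no
# alias or synonym resolution is attempted.
canonicalize_gene_id <- function(x) {
  x <- trimws(as.character(x))
  if (anyNA(x) || any(!nzchar(x))) stop("empty gene id")
  toupper(x)
}

#' Construct a target-prediction database
#'
#' A `TargetPredictionDB` is a named set of predicted (miRNA, gene) pairs,
#' optionally scored, standing in for exports of prediction resources such
#' as TargetScan, miRDB or miRSVR. Ids are canonicalized and duplicate pairs
#' collapsed (keeping the first score); the number of duplicates removed is
#' reported with a message.
#'
#' @param name Database name (used as the flag column name downstream).
#' @param mirna,gene Character vectors of equal length.
#' @param score Optional numeric vector of prediction scores.
#' @return An object of class `TargetPredictionDB` with elements `name`,
#'   `pairs` (data.frame `mirna_id`, `gene_id`, optional `score`) and `key`
#'   (canonical `"mirna\tgene"` strings).
#' @export
target_db <- function(name, mirna, gene, score = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(mirna) != length(gene)) stop("'mirna' and 'gene' lengths differ")
  mirna <- canonicalize_mirna_id(mirna)
  gene <- canonicalize_gene_id(gene)
  key <- paste(mirna, gene, sep = "\t")
  dup <- duplicated(key)
  if (any(dup))
    message(sprintf("db '%s': removed %d duplicate pair(s) after canonicalization",
                    name, sum(dup)))
  pairs <- data.frame(mirna_id = mirna[!dup], gene_id = gene[!dup],
                      stringsAsFactors = FALSE)
  if (!is.null(score)) {
    stopifnot(length(score) == length(mirna))
    pairs$score <- as.numeric(score)[!dup]
  }
  structure(list(name = name, pairs = pairs, key = key[!dup]),
            class = "TargetPredictionDB")
}

#' @export
print.TargetPredictionDB <- function(x, ...) {
  cat(sprintf("TargetPredictionDB '%s': %d pairs (%d miRNAs, %d genes)\n",
              x$name, nrow(x$pairs), length(unique(x$pairs$mirna_id)),
              length(unique(x$pairs$gene_id))))
  invisible(x)
}

#' Read or write a target-prediction table
#'
#' @param path Delimited text file with at least a miRNA and a gene column.
#' @param name Database name.
#' @param mirna_col,gene_col,score_col Column names to use; `score_col = NULL`
#'   means no scores.
#' @param sep Field separator.
#' @return A [target_db()] object.
#' @export
read_target_db <- function(path, name, mirna_col = "mirna", gene_col = "gene",
                           score_col = NULL, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           check.names = FALSE, colClasses = "character")
  need <- c(mirna_col, gene_col, score_col)
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("target db ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), " (expected: ",
         paste(need, collapse = ", "), ")")
  score <- if (!is.null(score_col)) as.numeric(tab[[score_col]]) else NULL
  target_db(name, tab[[mirna_col]], tab[[gene_col]], score)
}

#' @rdname read_target_db
#' @param db A `TargetPredictionDB`.
#' @export
write_target_db <- function(db, path, sep = "\t") {
  out <- db$pairs
  colnames(out)[1:2] <- c("mirna", "gene")
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene-set collections in GMT format
#'
#' `gene_set_collection()` builds a collection from a named list of member
#' vectors; `read_gmt()`/`write_gmt()` handle the standard tab-delimited GMT
#' layout (set id, description, then one member per field). Members are
#' canonicalized (uppercased) and de-duplicated; empty sets and duplicate
#' set ids are rejected.
#'
#' @param sets Named list of character vectors (gene ids).
#' @param descriptions Optional character vector parallel to `sets`.
#' @return An object of class `GeneSetCollection2`: list with `sets` and
#'   `descriptions`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set needs a set id")
  if (anyDuplicated(names(sets)))
    stop("duplicate set id(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(m) unique(canonicalize_gene_id(m)))
  if (any(lengths(sets) == 0L)) stop("empty gene set(s) rejected")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  stopifnot(length(descriptions) == length(sets))
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions),
            class = "GeneSetCollection2")
}

#' @rdname gene_set_collection
#' @param path Path to a GMT file.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d has %d field(s); need set id, description and >= 1 member",
                 short[1], lengths(fields)[short[1]]))
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate set id(s) in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- ids
  gene_set_collection(sets, vapply(fields, `[[`, "", 2L))
}

#' @rdname gene_set_collection
#' @param collection A `GeneSetCollection2`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection2"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# One-decimal percentage as printed in result tables (e.g. 22.4 for
# 443100/1978149).
percent1 <- function(x, total) {
  if (total == 0) return(0)
  round(100 * x / total, 1)
}
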