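# Sequence-based target-prediction tables: loading, union over databases,
# and restriction to differentially expressed features.

#' Construct a prediction set
#'
#' A deduplicated set of (miR, gene) couples, each tagged with the
#' prediction databases that report it. Matching between tables is
#' case-insensitive with the `hsa-` prefix stripped (see
#' [normalize_mir_id()]); the first spelling seen is kept for display.
#'
#' @param mir,gene character vectors of equal length.
#' @param database database name per row (recycled if length one).
#' @return object of class `prediction_set`: a data.frame with columns
#'   `mir`, `gene`, `n_databases`, `databases` (semicolon-joined), plus
#'   internal matching keys.
#' @export
prediction_set <- function(mir, gene, database) {
  mir <- as.character(mir)
  gene <- as.character(gene)
  if (length(mir) != length(gene))
    stop("'mir' and 'gene' must have the same length")
  database <- rep_len(as.character(database), length(mir))
  key <- couple_key(mir, gene)
  first <- !duplicated(key)
  dbs <- vapply(split(database, key), function(d)
    paste(sort(unique(d)), collapse = ";"), character(1))
  ndb <- vapply(split(database, key), function(d)
    length(unique(d)), integer(1))
  out <- data.frame(mir = mir[first], gene = gene[first],
                    key = key[first], stringsAsFactors = FALSE)
  out$databases <- unname(dbs[out$key])
  out$n_databases <- unname(ndb[out$key])
  out <- out[order(out$mir, out$gene), c("mir", "gene", "n_databases",
                                         "databases", "key")]
  rownames(out) <- NULL
  class(out) <- c("prediction_set", "data.frame")
  out
}

#' Load one target-prediction database from TSV
#'
#' @param path TSV with columns `mir` and `gene` (extra columns ignored).
#' @param database_name label recorded as the source of every couple.
#' @return a [prediction_set()]. An empty file yields an empty set with a
#'   warning; rows with blank identifiers raise an error naming the line.
#' @export
load_prediction_table <- function(path, database_name) {
  if (!file.exists(path)) stop("prediction table not found: ", path)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(tab) == 0) {
    warning("prediction table ", path, " is empty")
    return(prediction_set(character(0), character(0), database_name))
  }
  if (!all(c("mir", "gene") %in% names(tab)))
    stop("prediction table ", path, " must have columns 'mir' and 'gene'")
  bad <- which(is.na(tab$mir) | is.na(tab$gene) |
                 tab$mir == "" | tab$gene == "")
  if (length(bad))
    stop("malformed prediction rows in ", path, " at line(s) ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  prediction_set(tab$mir, tab$gene, database_name)
}

#' Union of prediction databases
#'
#' Merges several prediction sets and keeps couples supported by at least
#' `min_databases` distinct sources ("reported in at least 1 database" is
#' the permissive default; no score threshold is applied anywhere).
#'
#' @param sets list of [prediction_set()] objects.
#' @param min_databases minimum number of supporting databases (default 1).
#' @return a [prediction_set()] with merged `databases` annotations.
#' @export
union_predictions <- function(sets, min_databases = 1) {
  if (!is.list(sets) || length(sets) == 0)
    stop("'sets' must be a non-empty list of prediction sets")
  if (inherits(sets, "prediction_set")) sets <- list(sets)
  if (min_databases < 1 || min_databases > length(sets))
    stop("'min_databases' must lie between 1 and the number of sets")
  mir <- unlist(lapply(sets, function(s) rep(s$mir, s$n_databases)),
                use.names = FALSE)
  gene <- unlist(lapply(sets, function(s) rep(s$gene, s$n_databases)),
                 use.names = FALSE)
  db <- unlist(lapply(sets, function(s)
    unlist(strsplit(s$databases, ";", fixed = TRUE))), use.names = FALSE)
  merged <- prediction_set(mir, gene, if (length(db)) db else character(0))
  out <- merged[merged$n_databases >= min_databases, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("prediction_set", "data.frame")
  out
}

#' Restrict predictions to differentially expressed features, per day
#'
#' Only couples whose miRNA and gene are both differentially expressed at
#' a given day are retained for that day. miRNAs that are differentially
#' expressed but absent from every database simply contribute no couples;
#' they are listed in the `no_coverage` attribute so the report can flag
#' missing prediction coverage.
#'
#' @param preds a [prediction_set()] (typically the database union).
#' @param de_genes named list: day -> character vector of DE gene symbols.
#' @param de_mirs named list: day -> character vector of DE miRNA IDs.
#' @return named list (by day) of prediction sets; each carries attribute
#'   `no_coverage` with the DE miRNAs lacking any predicted couple.
#' @export
restrict_to_de <- function(preds, de_genes, de_mirs) {
  stopifnot(inherits(preds, "prediction_set"))
  days <- intersect(names(de_mirs), names(de_genes))
  setNames(lapply(days, function(d) {
    mir_keys <- normalize_mir_id(de_mirs[[d]])
    gene_keys <- normalize_gene_id(de_genes[[d]])
    keep <- normalize_mir_id(preds$mir) %in% mir_keys &
      normalize_gene_id(preds$gene) %in% gene_keys
    out <- preds[keep, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("prediction_set", "data.frame")
    covered <- unique(normalize_mir_id(out$mir))
    attr(out, "no_coverage") <-
      de_mirs[[d]][!mir_keys %in% intersect(mir_keys,
                                            normalize_mir_id(preds$mir))]
    out
  }), days)
}

#' Write a prediction set to TSV
#' @param preds a [prediction_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(preds, path) {
  write.table(preds[, c("mir", "gene", "n_databases", "databases")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
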