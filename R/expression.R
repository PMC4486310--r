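# Expression containers, TSV input, and the two probe-level filters.

#' Construct an expression matrix object
#'
#' Container for a features-by-samples table of log2 intensities, as
#' produced by rma-style summarisation. Values are stored as a plain
#' numeric matrix; gene platforms may carry a probe-to-gene map so that
#' probe-level results can later be collapsed to gene symbols.
#'
#' @param values numeric matrix, features in rows (rownames = feature IDs),
#'   samples in columns (colnames = sample IDs), log2 scale.
#' @param platform `"gene"` or `"mir"`.
#' @param probe_to_gene optional named character vector mapping probe IDs to
#'   gene symbols (names = probes). Only meaningful for gene platforms.
#' @return an object of class `expr_matrix` with elements `values`,
#'   `platform` and `probe_to_gene`.
#' @examples
#' v <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
#' expression_matrix(v, "gene")
#' @export
expression_matrix <- function(values, platform = c("gene", "mir"),
                              probe_to_gene = NULL) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix of log2 intensities")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (!all(is.finite(values)))
    stop("non-finite expression values present")
  if (!is.null(probe_to_gene)) {
    if (is.null(names(probe_to_gene)))
      stop("'probe_to_gene' must be a named character vector (names = probes)")
    probe_to_gene <- setNames(as.character(probe_to_gene),
                              names(probe_to_gene))
  }
  structure(list(values = values, platform = platform,
                 probe_to_gene = probe_to_gene),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %s platform: %d features x %d samples\n",
              x$platform, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Feature identifiers of an expression matrix
#' @param m an `expr_matrix`.
#' @return character vector of feature IDs.
#' @export
features <- function(m) rownames(m$values)

# internal: subset features, preserving order and metadata
subset_features <- function(m, keep) {
  m$values <- m$values[keep, , drop = FALSE]
  if (!is.null(m$probe_to_gene))
    m$probe_to_gene <- m$probe_to_gene[names(m$probe_to_gene) %in%
                                         rownames(m$values)]
  m
}

#' Validate a sample design table
#'
#' The design describes a two-condition (transfected vs parental),
#' three-day time course with replicate arrays: every sample column of an
#' expression matrix must appear here exactly once.
#'
#' @param design data.frame with columns `sample`, `condition`
#'   (`"transfected"` or `"parental"`), `day` (integer, e.g. 0, 7, 14) and
#'   `replicate`.
#' @return the validated design with normalised column types, class
#'   `sample_design`.
#' @export
sample_design <- function(design) {
  if (inherits(design, "sample_design")) return(design)
  req <- c("sample", "condition", "day", "replicate")
  miss <- setdiff(req, names(design))
  if (length(miss))
    stop("design is missing columns: ", paste(miss, collapse = ", "))
  design <- as.data.frame(design)[, req]
  design$sample <- as.character(design$sample)
  design$condition <- as.character(design$condition)
  design$day <- as.integer(design$day)
  design$replicate <- as.integer(design$replicate)
  if (anyDuplicated(design$sample))
    stop("duplicate sample IDs in design")
  bad <- setdiff(unique(design$condition), c("transfected", "parental"))
  if (length(bad))
    stop("unknown condition labels: ", paste(bad, collapse = ", "))
  if (length(unique(design$day)) < 2)
    stop("design must contain at least two days")
  class(design) <- c("sample_design", "data.frame")
  design
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds feature IDs and
#' whose remaining header names are sample IDs; every sample must be
#' declared in the design (and vice versa).
#'
#' @param path path to the TSV file.
#' @param design a [sample_design()] table.
#' @inheritParams expression_matrix
#' @return an `expr_matrix`.
#' @export
read_expression_matrix <- function(path, design, platform = c("gene", "mir"),
                                   probe_to_gene = NULL) {
  platform <- match.arg(platform)
  design <- sample_design(design)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("matrix file needs a feature column plus samples: ",
                          path)
  feats <- as.character(tab[[1]])
  if (anyDuplicated(feats)) {
    dup <- unique(feats[duplicated(feats)])
    stop("duplicated feature rows in ", path, ": ",
         paste(dup, collapse = ", "))
  }
  vals <- tab[, -1, drop = FALSE]
  extra <- setdiff(colnames(vals), design$sample)
  if (length(extra))
    stop("samples in ", path, " absent from design: ",
         paste(extra, collapse = ", "))
  missing_s <- setdiff(design$sample, colnames(vals))
  if (length(missing_s))
    stop("design samples missing from ", path, ": ",
         paste(missing_s, collapse = ", "))
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v)) {
      bad_row <- which(is.na(v))[1]
      stop(sprintf("non-numeric value in %s at row %d (feature %s), column %s",
                   path, bad_row, feats[bad_row], colnames(vals)[j]))
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)[, design$sample, drop = FALSE]
  rownames(m) <- feats
  expression_matrix(m, platform, probe_to_gene)
}

#' Read a sample design table from TSV
#' @param path TSV with columns sample, condition, day, replicate.
#' @return a `sample_design`.
#' @export
read_sample_design <- function(path) {
  sample_design(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Read a probe-to-gene map from TSV
#' @param path TSV with columns probe, gene.
#' @return named character vector (names = probes).
#' @export
read_probe_map <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("probe", "gene") %in% names(tab)))
    stop("probe map must have columns 'probe' and 'gene'")
  setNames(as.character(tab$gene), as.character(tab$probe))
}

#' Write an expression matrix to TSV
#' @param m an `expr_matrix`.
#' @param path output path.
#' @param id_column header for the feature column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, id_column = "feature") {
  df <- data.frame(rownames(m$values), m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove low-intensity features
#'
#' Drops every feature whose raw-scale intensity (`2^log2`) is at or below
#' `raw_threshold` in at least `frac` of the samples. All boundaries are
#' inclusive, so a feature at exactly the threshold in exactly
#' `frac * n` samples is removed.
#'
#' @param m an `expr_matrix` with log2 values.
#' @param raw_threshold raw intensity cut-off (default 100).
#' @param frac minimum fraction of samples at/below the cut-off for removal
#'   (default 0.75); must lie in (0, 1].
#' @return the filtered `expr_matrix` (row order preserved).
#' @export
filter_low_expression <- function(m, raw_threshold = 100, frac = 0.75) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!is.numeric(frac) || length(frac) != 1 || frac <= 0 || frac > 1)
    stop("'frac' must lie in (0, 1]")
  if (!is.numeric(raw_threshold) || raw_threshold <= 0)
    stop("'raw_threshold' must be a positive intensity")
  raw <- 2^m$values
  low_frac <- rowMeans(raw <= raw_threshold)
  subset_features(m, low_frac < frac)
}

#' Remove low-variability features by inter-quartile range
#'
#' Computes each feature's IQR of log2 values (type-7 linear-interpolation
#' quartiles) and removes features whose IQR is at or below the median of
#' all feature IQRs. Note the rule is not idempotent: after removal the
#' median IQR shifts, so re-application removes further features.
#'
#' @param m an `expr_matrix` with at least two features.
#' @return the filtered `expr_matrix`.
#' @export
filter_low_iqr <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (nrow(m$values) < 2)
    stop("IQR filter is undefined for fewer than two features")
  iqr <- apply(m$values, 1, IQR, type = 7)
  subset_features(m, iqr > median(iqr))
}

#' Apply the standard preprocessing filters
#'
#' Intensity filter first, then (optionally) the IQR filter computed on the
#' features that survive the intensity filter — the order in which the two
#' rules are stated for the array analysis.
#'
#' @inheritParams filter_low_expression
#' @param apply_iqr apply the IQR filter after the intensity filter
#'   (default TRUE; typically FALSE for miRNA platforms).
#' @return the filtered `expr_matrix`.
#' @export
preprocess_expression <- function(m, raw_threshold = 100, frac = 0.75,
                                  apply_iqr = TRUE) {
  m <- filter_low_expression(m, raw_threshold = raw_threshold, frac = frac)
  if (apply_iqr) m <- filter_low_iqr(m)
  m
}
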