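# Gene-set over-representation (hypergeometric) and PCA ordination of
# samples.

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(bad, collapse = ", "))
  setNames(lapply(parts, function(p) unique(p[-(1:2)])),
           vapply(parts, `[[`, character(1), 1))
}

#' Bundle gene sets with a background universe
#'
#' @param sets named list of character vectors (no empty set allowed).
#' @param universe background gene list (e.g. all annotated genes on the
#'   array); testing uses each set's intersection with the universe.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe) {
  if (length(sets) == 0 || is.null(names(sets)))
    stop("'sets' must be a non-empty named list")
  if (any(lengths(sets) == 0)) stop("empty gene sets are not allowed")
  universe <- unique(normalize_gene_id(universe))
  if (length(universe) == 0) stop("empty universe")
  sets <- lapply(sets, function(s) unique(normalize_gene_id(s)))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Hypergeometric over-representation analysis
#'
#' For each set, tests whether the query list overlaps the set more than
#' expected by chance against the background universe, using the
#' one-sided hypergeometric upper tail `P(X >= k)`; p-values are
#' BH-adjusted across sets and results sorted by p. Query genes outside
#' the universe are dropped with a warning.
#'
#' @param query_genes character vector of gene symbols.
#' @param collection a [gene_set_collection()].
#' @param alpha adjusted-p significance cut-off (default 0.1).
#' @return data.frame with columns `set`, `k` (overlap), `q` (query size
#'   in universe), `m` (set size in universe), `N` (universe size), `p`,
#'   `p_adj`, `significant`.
#' @export
fisher_enrichment <- function(query_genes, collection, alpha = 0.1) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(normalize_gene_id(query_genes))
  if (length(query) == 0) stop("empty query")
  outside <- setdiff(query, collection$universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- setdiff(query, outside)
  }
  if (length(query) == 0) stop("no query genes left inside the universe")
  N <- length(collection$universe)
  q <- length(query)
  res <- do.call(rbind, lapply(names(collection$sets), function(nm) {
    set_u <- intersect(collection$sets[[nm]], collection$universe)
    m <- length(set_u)
    k <- length(intersect(query, set_u))
    p <- if (k == 0) 1 else phyper(k - 1, m, N - m, q, lower.tail = FALSE)
    data.frame(set = nm, k = k, q = q, m = m, N = N, p = p,
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- bh_adjust(res$p)
  res$significant <- res$p_adj <= alpha
  res <- res[order(res$p, res$set), ]
  rownames(res) <- NULL
  res
}

#' PCA ordination of samples on a feature subset
#'
#' Projects the samples of a log2 expression matrix onto the first two
#' principal components of the feature-centred data (features centred,
#' no scaling) — the standard ordination used to place profiled samples
#' relative to external reference profiles that are supplied as extra
#' columns of the matrix.
#'
#' @param m an [expression_matrix()].
#' @param feature_subset features to use (intersected with the matrix;
#'   typically the differentially expressed probes of one day).
#' @param design optional [sample_design()]; matched annotation columns
#'   are appended to the coordinates (samples without design rows, e.g.
#'   external references, get NA).
#' @return list with `coordinates` (data.frame: sample, PC1, PC2, and
#'   design columns when available) and `variance_explained` (fraction
#'   per component, non-increasing).
#' @export
pca_ordinate <- function(m, feature_subset, design = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m$values) < 2) stop("ordination needs at least two samples")
  feats <- intersect(feature_subset, rownames(m$values))
  if (length(feats) == 0)
    stop("no requested features present in the matrix")
  x <- m$values[feats, , drop = FALSE]
  pc <- prcomp(t(x), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(2, ncol(pc$x))
  coords <- data.frame(sample = colnames(m$values),
                       PC1 = pc$x[, 1],
                       PC2 = if (k >= 2) pc$x[, 2] else 0,
                       stringsAsFactors = FALSE)
  rownames(coords) <- NULL
  if (!is.null(design)) {
    design <- sample_design(design)
    idx <- match(coords$sample, design$sample)
    coords$condition <- design$condition[idx]
    coords$day <- design$day[idx]
  }
  list(coordinates = coords, variance_explained = ve)
}
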