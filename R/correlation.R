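# Per-day Pearson correlation screening between differentially expressed
# miRNAs and gene probes.

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (n >= 3), neither constant.
#' @return the correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have the same length")
  if (length(x) < 3) stop("correlation requires at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation is undefined for a constant vector")
  cor(x, y, method = "pearson")
}

#' Asymptotic p-value for a Pearson correlation
#'
#' Default is the usual t transform, `t = r * sqrt(n - 2) / sqrt(1 - r^2)`
#' on `n - 2` degrees of freedom, two-sided; `|r| = 1` maps to p = 0. The
#' Fisher z alternative (`z = atanh(r) * sqrt(n - 3)`, normal reference)
#' is exposed because with very few paired samples per day the two give
#' visibly different calibrations.
#'
#' @param r correlation coefficient(s) in \[-1, 1\].
#' @param n number of paired observations (>= 3; >= 4 for `"fisher_z"`).
#' @param method `"t"` (default) or `"fisher_z"`.
#' @return two-sided p-value(s).
#' @export
correlation_pvalue <- function(r, n, method = c("t", "fisher_z")) {
  method <- match.arg(method)
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must not exceed 1")
  r <- pmin(1, pmax(-1, r))
  if (n < 3) stop("need at least 3 observations")
  if (method == "t") {
    p <- ifelse(abs(r) >= 1, 0, {
      tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
      2 * pt(-abs(tstat), df = n - 2)
    })
  } else {
    if (n < 4) stop("Fisher z requires at least 4 observations")
    p <- ifelse(abs(r) >= 1, 0,
                2 * pnorm(-abs(atanh(r)) * sqrt(n - 3)))
  }
  pmin(p, 1)
}

#' Correlate every DE miRNA against every DE gene probe for one day
#'
#' Samples are paired by identity between the two platforms. By default
#' only that day's arrays enter the correlation (`sample_scope =
#' "per_day"`); `"all_samples"` pools the whole series instead. One record
#' is produced per (miR, probe) pair; pairs where either vector is
#' constant are skipped with a warning. No multiplicity correction is
#' applied at this stage — type I error is controlled downstream by the
#' high `|r|` cut-off.
#'
#' @param mir_m,gene_m [expression_matrix()] objects sharing sample IDs.
#' @param day the day to screen.
#' @param de_mirs,de_probes feature IDs to correlate (rows of the
#'   respective matrices).
#' @param design a [sample_design()].
#' @param sample_scope `"per_day"` (default) or `"all_samples"`.
#' @param p_method p-value method, see [correlation_pvalue()].
#' @return data.frame with columns `mir`, `probe`, `gene`, `day`, `r`,
#'   `p`, `sign` (`"positive"` for r >= 0, `"negative"` otherwise).
#' @export
correlate_day <- function(mir_m, gene_m, day, de_mirs, de_probes, design,
                          sample_scope = c("per_day", "all_samples"),
                          p_method = "t") {
  stopifnot(inherits(mir_m, "expr_matrix"), inherits(gene_m, "expr_matrix"))
  sample_scope <- match.arg(sample_scope)
  design <- sample_design(design)
  samples <- if (sample_scope == "per_day")
    design$sample[design$day == day] else design$sample
  if (length(samples) < 3)
    stop("need at least 3 paired samples for day ", day)
  for (mm in list(mir_m, gene_m)) {
    missing_s <- setdiff(samples, colnames(mm$values))
    if (length(missing_s))
      stop("samples not present on both platforms (pairing error): ",
           paste(missing_s, collapse = ", "))
  }
  de_mirs <- intersect(de_mirs, rownames(mir_m$values))
  de_probes <- intersect(de_probes, rownames(gene_m$values))
  if (length(de_mirs) == 0 || length(de_probes) == 0)
    return(empty_correlation_records())

  xm <- mir_m$values[de_mirs, samples, drop = FALSE]
  xg <- gene_m$values[de_probes, samples, drop = FALSE]
  const_m <- apply(xm, 1, sd) == 0
  const_g <- apply(xg, 1, sd) == 0
  if (any(const_m) || any(const_g)) {
    warning(sum(const_m), " miRNA(s) and ", sum(const_g),
            " probe(s) with constant expression skipped for day ", day)
    xm <- xm[!const_m, , drop = FALSE]
    xg <- xg[!const_g, , drop = FALSE]
  }
  if (nrow(xm) == 0 || nrow(xg) == 0) return(empty_correlation_records())

  rmat <- cor(t(xm), t(xg), method = "pearson")
  n <- length(samples)
  probes <- rep(colnames(rmat), each = nrow(rmat))
  genes <- if (!is.null(gene_m$probe_to_gene)) {
    g <- unname(gene_m$probe_to_gene[probes])
    ifelse(is.na(g), probes, g)
  } else probes
  out <- data.frame(
    mir = rep(rownames(rmat), times = ncol(rmat)),
    probe = probes,
    gene = genes,
    day = day,
    r = as.vector(rmat),
    stringsAsFactors = FALSE
  )
  out$p <- correlation_pvalue(out$r, n, method = p_method)
  out$sign <- ifelse(out$r < 0, "negative", "positive")
  out
}

empty_correlation_records <- function() {
  data.frame(mir = character(0), probe = character(0), gene = character(0),
             day = integer(0), r = numeric(0), p = numeric(0),
             sign = character(0), stringsAsFactors = FALSE)
}

#' Filter correlation records by the significance rule
#'
#' A record is significant when `|r| >= r_min` and `p <= p_max` (both
#' inclusive). Positive and negative correlations are both retained; an
#' exactly zero correlation is never significant.
#'
#' @param records data.frame from [correlate_day()].
#' @param r_min minimum absolute correlation (default 0.7).
#' @param p_max maximum p-value (default 0.05).
#' @return the significant subset.
#' @export
filter_correlations <- function(records, r_min = 0.7, p_max = 0.05) {
  # r_min above 1 is allowed: it simply selects nothing
  if (r_min < 0) stop("'r_min' must be non-negative")
  if (p_max <= 0 || p_max > 1) stop("'p_max' must lie in (0, 1]")
  keep <- abs(records$r) >= r_min & records$p <= p_max & records$r != 0
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
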