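# Per-day two-group differential expression with an empirical-Bayes
# moderated t-statistic and Benjamini-Hochberg FDR control.

#' Invert the trigamma function
#'
#' Newton iteration on `trigamma(x) = y`, used by the moment estimator of
#' the prior degrees of freedom. Converges monotonically from the starting
#' value `0.5 + 1/y`.
#'
#' @param y positive value(s).
#' @param tol convergence tolerance on the relative step (default 1e-8).
#' @return x with `trigamma(x) = y`.
#' @keywords internal
trigamma_inverse <- function(y, tol = 1e-8) {
  if (any(y <= 0)) stop("trigamma_inverse requires positive input")
  out <- y
  hi <- y > 1e7
  lo <- y < 1e-6
  out[hi] <- 1 / sqrt(y[hi])
  out[lo] <- 1 / y[lo]
  mid <- !(hi | lo)
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2)
      x <- x + dif
      if (max(-dif / x) < tol) break
    }
    out[mid] <- x
  }
  out
}

# Moment estimator of the scaled-F prior for residual variances.
# Matches z = log(s^2) to the log-F distribution: with residual df d_g,
# E log s^2 = log s0^2 + digamma(d_g/2) - log(d_g/2) - digamma(d0/2) +
# log(d0/2) and Var log s^2 = trigamma(d_g/2) + trigamma(d0/2), solved in
# closed form via the trigamma inverse. Zero variances are offset to a
# small positive multiple of the median, as is standard for log-scale
# moment matching.
fit_variance_prior <- function(s2, df1) {
  n <- length(s2)
  if (n < 2) stop("need at least two residual variances to fit the prior")
  s2 <- pmax(s2, 0)
  m <- median(s2)
  if (m == 0) {
    warning("more than half of the residual variances are zero; ",
            "variance moderation is unreliable")
    m <- 1
  }
  s2 <- pmax(s2, 1e-5 * m)
  z <- log(s2)
  e <- z - digamma(df1 / 2) + log(df1 / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (n - 1) - trigamma(df1 / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- mean(s2)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated t-test per day for a two-condition time course
#'
#' Fits a single cell-means linear model over all condition-by-day groups
#' (pooling the residual variance across the whole series), shrinks the
#' per-feature variances towards an empirical-Bayes prior estimated by
#' moment matching of the log variances, and tests, for each day, the
#' transfected-minus-parental group-mean difference:
#'
#' \deqn{\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}, \qquad
#'       t_g = \frac{\mathrm{logFC}_g}{\tilde s_g \sqrt{1/n_1 + 1/n_2}}}
#'
#' with `d0 + d_g` degrees of freedom. Two-sided p-values are adjusted by
#' Benjamini-Hochberg within each day's contrast.
#'
#' @param m an [expression_matrix()] of log2 values.
#' @param design a [sample_design()] covering all columns of `m`; every
#'   condition-by-day cell needs at least two samples.
#' @param d0,s0_sq optional fixed prior degrees of freedom / prior variance
#'   overriding the moment estimate (`d0 = Inf` gives fully pooled
#'   variance, `d0 = 0` the ordinary per-feature pooled t-test).
#' @return data.frame with columns `feature`, `day`, `logFC` (transfected
#'   minus parental), `t`, `p`, `p_adj`, plus attribute
#'   `moderation` = list(d0, s0_sq, d_g) and attribute `zero_variance`
#'   naming features whose residual variance was exactly zero (these are
#'   assigned the shrunken prior variance).
#' @export
fit_moderated_t <- function(m, design, d0 = NULL, s0_sq = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  design <- sample_design(design)
  missing_s <- setdiff(design$sample, colnames(m$values))
  if (length(missing_s))
    stop("design samples missing from matrix: ",
         paste(missing_s, collapse = ", "))
  x <- m$values[, design$sample, drop = FALSE]
  grp <- interaction(design$condition, design$day, drop = TRUE)
  if (any(table(grp) < 2))
    stop("every condition-by-day cell needs at least two samples")
  n <- ncol(x)
  k <- nlevels(grp)
  d_g <- n - k
  if (d_g <= 0) stop("zero residual degrees of freedom")

  ind <- model.matrix(~ 0 + grp)
  colnames(ind) <- levels(grp)
  means <- x %*% ind %*% diag(1 / colSums(ind), k)
  colnames(means) <- levels(grp)
  fitted <- means[, as.integer(grp), drop = FALSE]
  s2 <- rowSums((x - fitted)^2) / d_g
  zero <- s2 < 1e-12

  if (is.null(d0) != is.null(s0_sq))
    stop("supply both 'd0' and 's0_sq', or neither")
  if (is.null(d0)) {
    prior <- fit_variance_prior(s2, d_g)
    d0 <- prior$d0
    s0_sq <- prior$s0_sq
  } else {
    if (d0 < 0 || s0_sq <= 0) stop("invalid moderation parameters")
  }
  if (is.finite(d0)) {
    s2_post <- (d0 * s0_sq + d_g * s2) / (d0 + d_g)
  } else {
    s2_post <- rep(s0_sq, length(s2))
  }
  df_total <- d0 + d_g

  days <- sort(unique(design$day))
  res <- lapply(days, function(d) {
    g1 <- paste("transfected", d, sep = ".")
    g2 <- paste("parental", d, sep = ".")
    if (!all(c(g1, g2) %in% colnames(means)))
      stop("day ", d, " lacks one of the two conditions")
    n1 <- sum(grp == g1)
    n2 <- sum(grp == g2)
    logfc <- means[, g1] - means[, g2]
    se <- sqrt(s2_post * (1 / n1 + 1 / n2))
    tstat <- logfc / se
    p <- 2 * pt(-abs(tstat), df = df_total)
    data.frame(feature = rownames(x), day = d, logFC = unname(logfc),
               t = unname(tstat), p = unname(p),
               p_adj = bh_adjust(unname(p)),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  attr(out, "moderation") <- list(d0 = d0, s0_sq = s0_sq, d_g = d_g)
  attr(out, "zero_variance") <- rownames(x)[zero]
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around [stats::p.adjust()] with `method = "BH"`:
#' adjusted values are monotone in rank and capped at one.
#'
#' @param p numeric vector of raw p-values in \[0, 1\]; NA/NaN are rejected.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p)) stop("missing or NaN p-values are not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call significant features by fold-change and p-value thresholds
#'
#' A feature passes for a day when `|logFC| >= lfc_min` and its p-value
#' (adjusted or raw, both inclusive) is at most `p_max`. Rows whose
#' selected p-value is missing (e.g. fixture tables that only record the
#' significant entries) never pass.
#'
#' Defaults follow the conventional array thresholds: genes at
#' `|logFC| >= 0.585` (fold change 1.5) with BH-adjusted `p <= 0.05`;
#' miRNAs are typically called at `|logFC| >= 0.485` (fold change 1.4)
#' with raw `p <= 0.01`.
#'
#' @param results data.frame with columns `feature`, `day`, `logFC`, `p`
#'   and (if `use_adjusted`) `p_adj`, as from [fit_moderated_t()].
#' @param lfc_min minimum absolute log2 fold change.
#' @param p_max maximum p-value.
#' @param use_adjusted use the BH-adjusted p-value (default TRUE).
#' @return the significant subset of `results`, with an added `direction`
#'   column (`"up"`/`"down"`).
#' @export
call_significant <- function(results, lfc_min = 0.585, p_max = 0.05,
                             use_adjusted = TRUE) {
  if (!all(c("feature", "day", "logFC", "p") %in% names(results)))
    stop("'results' must have columns feature, day, logFC, p")
  if (lfc_min < 0 || p_max <= 0) stop("thresholds must be positive")
  if (nrow(results) == 0) {
    out <- results
    out$direction <- character(0)
    return(out)
  }
  pcol <- if (use_adjusted) {
    if (!"p_adj" %in% names(results))
      stop("use_adjusted = TRUE requires a 'p_adj' column")
    results$p_adj
  } else {
    results$p
  }
  keep <- !is.na(results$logFC) & !is.na(pcol) &
    abs(results$logFC) >= lfc_min & pcol <= p_max
  out <- results[keep, , drop = FALSE]
  out$direction <- ifelse(out$logFC > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Per-day sets of significant features
#'
#' @param significant output of [call_significant()].
#' @return named list (one element per day, names = day values) of
#'   character vectors of feature IDs.
#' @export
de_feature_sets <- function(significant) {
  days <- sort(unique(significant$day))
  setNames(lapply(days, function(d) {
    unique(significant$feature[significant$day == d])
  }), as.character(days))
}

#' Convert a log2 fold change to a linear fold change
#'
#' @param logFC numeric log2 fold change(s).
#' @return `2^logFC`.
#' @examples
#' logfc_to_fc(0.585) # ~1.5
#' logfc_to_fc(0.485) # ~1.4
#' @export
logfc_to_fc <- function(logFC) {
  if (!all(is.finite(logFC))) stop("logFC must be finite")
  2^logFC
}
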