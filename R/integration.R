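# Intersection of the correlation and prediction evidence streams, probe
# collapse, and the pipeline summary tables.

#' Intersect significant correlations with predicted couples
#'
#' Keeps the probe-level significant correlation records whose (miR, gene)
#' couple is also predicted by sequence. Predictions may be supplied as a
#' single [prediction_set()] (applied to every day) or as a named per-day
#' list as returned by [restrict_to_de()].
#'
#' @param records significant correlation records
#'   (from [filter_correlations()]), any mix of days.
#' @param predictions a `prediction_set` or named list of them (names =
#'   days).
#' @return the predicted subset of `records`, with `n_databases` and
#'   `databases` columns appended.
#' @export
intersect_couples <- function(records, predictions) {
  if (nrow(records) == 0) return(annotate_predictions(records, NULL))
  per_day <- is.list(predictions) && !inherits(predictions, "prediction_set")
  parts <- lapply(sort(unique(records$day)), function(d) {
    preds <- if (per_day) predictions[[as.character(d)]] else predictions
    rec <- records[records$day == d, , drop = FALSE]
    if (is.null(preds) || nrow(preds) == 0)
      return(rec[0, , drop = FALSE])
    keep <- couple_key(rec$mir, rec$gene) %in% preds$key
    annotate_predictions(rec[keep, , drop = FALSE], preds)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# internal: append database support columns to correlation records
annotate_predictions <- function(records, preds) {
  if (is.null(preds) || nrow(records) == 0) {
    records$n_databases <- integer(nrow(records))
    records$databases <- character(nrow(records))
    return(records)
  }
  idx <- match(couple_key(records$mir, records$gene), preds$key)
  records$n_databases <- preds$n_databases[idx]
  records$databases <- preds$databases[idx]
  records
}

#' Collapse probe-level couples to gene level
#'
#' For each (miR, gene, day), the probe with the largest `|r|` is
#' retained ("the most correlated is shown"); exact ties are broken by the
#' lexicographically smallest probe ID, and any tie-break applied is
#' reported in a message.
#'
#' @param couples probe-level records from [intersect_couples()].
#' @return one record per (miR, gene, day), same columns.
#' @export
collapse_probes <- function(couples) {
  if (nrow(couples) == 0) return(couples)
  key <- paste(couple_key(couples$mir, couples$gene), couples$day)
  ord <- order(key, -abs(couples$r), couples$probe)
  sorted <- couples[ord, , drop = FALSE]
  skey <- key[ord]
  first <- !duplicated(skey)
  ties <- tapply(abs(sorted$r), skey, function(a)
    sum(a == max(a)) > 1)
  if (any(ties))
    message(sum(ties), " (miR, gene, day) group(s) had tied |r|; ",
            "smallest probe ID retained")
  out <- sorted[first, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wide per-day couple table
#'
#' Reshapes collapsed couples into one row per (miR, gene) with one `r`
#' column per day (NA where the couple is not significant that day).
#'
#' @param collapsed output of [collapse_probes()].
#' @param days days to report columns for (default: those present).
#' @return data.frame with columns `mir`, `gene`, `r_day<d>`...
#' @export
couples_table <- function(collapsed, days = sort(unique(collapsed$day))) {
  key <- couple_key(collapsed$mir, collapsed$gene)
  first <- !duplicated(key)
  out <- data.frame(mir = collapsed$mir[first], gene = collapsed$gene[first],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  for (d in days) {
    col <- rep(NA_real_, nrow(out))
    sel <- collapsed$day == d
    col[match(key[sel], key[first])] <- collapsed$r[sel]
    out[[paste0("r_day", d)]] <- col
  }
  out[order(out$mir, out$gene), , drop = FALSE]
}

#' Summarise a wide couple table
#'
#' Works on any table with `mir`, `gene` and `r_day*` columns (package
#' output or a transcribed reference table). A couple's sign is the sign
#' of its most-correlated day. Counts are over table rows, so a couple
#' printed on two rows (e.g. the same gene re-entered for a second day)
#' contributes twice, mirroring how such tables are published; per-day
#' counts are deduplicated at the (miR, gene) level.
#'
#' @param tab wide couple table, see [couples_table()].
#' @return list with `n_couples`, `n_mirs`, `n_single_target`, `per_mir`
#'   (data.frame: mir, n_couples, n_positive, n_negative) and `per_day`
#'   (data.frame: day, n_couples, n_mirs, n_genes).
#' @export
summarize_couples <- function(tab) {
  rcols <- grep("^r_day", names(tab), value = TRUE)
  if (length(rcols) == 0) stop("no r_day* columns found")
  rmat <- as.matrix(tab[, rcols, drop = FALSE])
  best <- apply(rmat, 1, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else v[which.max(abs(v))]
  })
  sign_lab <- ifelse(best < 0, "negative", "positive")
  mir_key <- normalize_mir_id(tab$mir)
  per_mir <- do.call(rbind, lapply(split(seq_len(nrow(tab)), mir_key),
    function(i) data.frame(
      mir = tab$mir[i[1]],
      n_couples = length(i),
      n_positive = sum(sign_lab[i] == "positive", na.rm = TRUE),
      n_negative = sum(sign_lab[i] == "negative", na.rm = TRUE),
      stringsAsFactors = FALSE)))
  per_mir <- per_mir[order(-per_mir$n_couples, per_mir$mir), ]
  rownames(per_mir) <- NULL
  per_day <- do.call(rbind, lapply(rcols, function(cl) {
    d <- as.integer(sub("^r_day", "", cl))
    sel <- !is.na(tab[[cl]])
    ck <- couple_key(tab$mir[sel], tab$gene[sel])
    data.frame(day = d, n_couples = length(unique(ck)),
               n_mirs = length(unique(mir_key[sel])),
               n_genes = length(unique(normalize_gene_id(tab$gene[sel]))))
  }))
  list(n_couples = nrow(tab),
       n_mirs = length(unique(mir_key)),
       n_single_target = sum(per_mir$n_couples == 1),
       per_mir = per_mir,
       per_day = per_day)
}

#' Per-day and overall correlation-screen summary from counts
#'
#' Derives the percentages of the correlation stage (significant overall
#' and, when supplied, the positive/negative split) from raw per-day
#' counts. Percentages are always derived, never stored.
#'
#' @param n_computed,n_significant integer vectors, one entry per day.
#' @param days day labels (default sequential).
#' @param n_positive,n_negative optional per-day sign split of the
#'   significant records.
#' @param digits rounding for the reported percentages (default 1).
#' @return list with `per_day` (data.frame) and `overall_pct_significant`.
#' @export
correlation_screen_summary <- function(n_computed, n_significant,
                                       days = seq_along(n_computed),
                                       n_positive = NULL, n_negative = NULL,
                                       digits = 1) {
  if (length(n_computed) != length(n_significant))
    stop("count vectors must have the same length")
  if (any(n_significant > n_computed))
    stop("significant counts cannot exceed computed counts")
  per_day <- data.frame(
    day = days, n_computed = n_computed, n_significant = n_significant,
    pct_significant = round(100 * n_significant / pmax(n_computed, 1),
                            digits))
  if (!is.null(n_positive) && !is.null(n_negative)) {
    if (any(n_positive + n_negative != n_significant))
      stop("positive + negative must equal significant per day")
    per_day$n_positive <- n_positive
    per_day$n_negative <- n_negative
    per_day$pct_positive <- round(100 * n_positive / pmax(n_significant, 1),
                                  digits)
    per_day$pct_negative <- round(100 * n_negative / pmax(n_significant, 1),
                                  digits)
  }
  list(per_day = per_day,
       overall_pct_significant =
         round(100 * sum(n_significant) / max(sum(n_computed), 1), digits))
}

#' Summarise every stage of the pipeline
#'
#' Collects the per-day and total counts of the whole analysis: DE probes
#' and genes with direction split, DE miRNAs, correlations computed and
#' significant with sign split, prediction counts at probe and gene
#' level, and the integrated couples. Totals for feature counts are
#' union-style (a feature or couple is counted once across days).
#'
#' @param stages named list with elements `de_genes` (significant gene
#'   rows incl. `direction`), `de_mirs` (same for miRNAs),
#'   `correlations` (all records), `correlations_significant`,
#'   `predictions_by_day` (list of prediction sets), `couples`
#'   (collapsed couple records), and optionally `probe_to_gene`.
#' @return list of per-stage summary data.frames, class
#'   `pipeline_summary`.
#' @export
summarize_pipeline <- function(stages) {
  req <- c("de_genes", "de_mirs", "correlations",
           "correlations_significant", "predictions_by_day", "couples")
  absent <- setdiff(req, names(stages))
  if (length(absent))
    stop("incomplete summary; missing stage(s): ",
         paste(absent, collapse = ", "))
  p2g <- stages$probe_to_gene

  days <- sort(unique(c(stages$de_genes$day, stages$de_mirs$day,
                        stages$correlations$day)))
  count_de <- function(sig, map = NULL) {
    do.call(rbind, lapply(days, function(d) {
      s <- sig[sig$day == d, , drop = FALSE]
      feats <- s$feature
      genes <- if (!is.null(map)) unique(map[feats]) else NULL
      data.frame(day = d, n = length(unique(feats)),
                 n_up = sum(s$direction == "up"),
                 n_down = sum(s$direction == "down"),
                 n_genes = if (is.null(genes)) NA_integer_ else
                   length(genes[!is.na(genes)]))
    }))
  }
  genes_tab <- count_de(stages$de_genes, p2g)
  mirs_tab <- count_de(stages$de_mirs)

  n_comp <- vapply(days, function(d)
    sum(stages$correlations$day == d), integer(1))
  sig <- stages$correlations_significant
  n_sig <- vapply(days, function(d) sum(sig$day == d), integer(1))
  n_pos <- vapply(days, function(d)
    sum(sig$day == d & sig$sign == "positive"), integer(1))
  corr <- correlation_screen_summary(n_comp, n_sig, days = days,
                                     n_positive = n_pos,
                                     n_negative = n_sig - n_pos)

  pred_tab <- do.call(rbind, lapply(days, function(d) {
    ps <- stages$predictions_by_day[[as.character(d)]]
    n_gene_level <- if (is.null(ps)) 0L else nrow(ps)
    n_probe_level <- if (is.null(ps) || is.null(p2g)) NA_integer_ else {
      probes_per_gene <- table(normalize_gene_id(p2g))
      sum(probes_per_gene[normalize_gene_id(ps$gene)], na.rm = TRUE)
    }
    data.frame(day = d, n_gene_level = n_gene_level,
               n_probe_level = n_probe_level)
  }))

  cp <- stages$couples
  couple_tab <- do.call(rbind, lapply(days, function(d) {
    s <- cp[cp$day == d, , drop = FALSE]
    data.frame(day = d,
               n_couples = length(unique(couple_key(s$mir, s$gene))),
               n_mirs = length(unique(normalize_mir_id(s$mir))),
               n_genes = length(unique(normalize_gene_id(s$gene))))
  }))
  totals <- list(
    n_de_probes = length(unique(stages$de_genes$feature)),
    n_de_mirs = length(unique(stages$de_mirs$feature)),
    n_couples = length(unique(couple_key(cp$mir, cp$gene))),
    n_mirs_with_couples = length(unique(normalize_mir_id(cp$mir))),
    overall_pct_significant = corr$overall_pct_significant)

  structure(list(genes = genes_tab, mirs = mirs_tab,
                 correlations = corr$per_day, predictions = pred_tab,
                 couples = couple_tab, totals = totals),
            class = "pipeline_summary")
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat("== Differentially expressed gene probes ==\n")
  print(x$genes, row.names = FALSE)
  cat("== Differentially expressed miRNAs ==\n")
  print(x$mirs, row.names = FALSE)
  cat("== Correlation screen ==\n")
  print(x$correlations, row.names = FALSE)
  cat(sprintf("overall significant: %.1f%%\n",
              x$totals$overall_pct_significant))
  cat("== Predictions (restricted to DE features) ==\n")
  print(x$predictions, row.names = FALSE)
  cat("== Integrated couples ==\n")
  print(x$couples, row.names = FALSE)
  cat(sprintf("total couples (union over days): %d across %d miRNAs\n",
              x$totals$n_couples, x$totals$n_mirs_with_couples))
  invisible(x)
}
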