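# Curated example tables from a published CD99-transfection osteosarcoma
# differentiation time course (Saos-2 vs Sa/CD99, days 0/7/14), shipped
# as small TSV files. They serve as worked examples for the reporting
# layer: the miRNA differential-expression table and the final
# integrated miRNA-gene couple table.

#' Example miRNA differential-expression table
#'
#' Per-miRNA log2 fold changes (transfected minus parental) at days 0, 7
#' and 14 with the published raw p-values; entries reported as not
#' significant carry NA p-values. One day-0 p-value was printed with a
#' missing decimal separator in the original table and is encoded here as
#' 0.00841.
#'
#' @param long return the long (feature, day, logFC, p) layout used by
#'   [call_significant()] (default TRUE); otherwise the wide table as
#'   shipped.
#' @return data.frame; in long form with columns `feature`, `day`,
#'   `logFC`, `p`.
#' @examples
#' sig <- call_significant(example_mir_de(), lfc_min = 0.485,
#'                         p_max = 0.01, use_adjusted = FALSE)
#' table(sig$day)
#' @export
example_mir_de <- function(long = TRUE) {
  path <- system.file("extdata", "cd99_mir_de.tsv", package = "miRcouple",
                      mustWork = TRUE)
  wide <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                     check.names = FALSE)
  if (!long) return(wide)
  days <- c(0L, 7L, 14L)
  out <- do.call(rbind, lapply(days, function(d) {
    data.frame(feature = wide$mir, day = d,
               logFC = wide[[paste0("logFC_day", d)]],
               p = wide[[paste0("p_day", d)]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Example integrated miRNA-gene couple table
#'
#' The final couple table of the same study: each row is a (miRNA, gene)
#' couple that was both significantly correlated and predicted by at
#' least one target database, with the per-day correlation of the
#' most-correlated probe (NA where not significant). The table is kept
#' exactly as printed, including one couple that appears on two rows for
#' different days, so row counts match the published totals.
#'
#' @return wide data.frame with columns `mir`, `gene`, `r_day0`,
#'   `r_day7`, `r_day14`, ready for [summarize_couples()].
#' @examples
#' summarize_couples(example_integrated_couples())$n_couples
#' @export
example_integrated_couples <- function() {
  path <- system.file("extdata", "cd99_integrated_couples.tsv",
                      package = "miRcouple", mustWork = TRUE)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}
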