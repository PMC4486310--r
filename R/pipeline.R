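# End-to-end pipeline: preprocessing -> differential expression ->
# (prediction union || correlation screen) -> intersection -> networks ->
# summary, with every intermediate persisted as TSV.

#' Pipeline configuration
#'
#' Every stage threshold as a named key. The defaults are the
#' conventional array-analysis values: genes at |logFC| >= 0.585 with
#' BH-adjusted p <= 0.05; miRNAs at |logFC| >= 0.485 with raw p <= 0.01
#' (the miRNA rule is stated without multiple-test correction; set
#' `mir_use_adjusted = TRUE` for the stricter reading); correlations at
#' |r| >= 0.7 with asymptotic p <= 0.05 on that day's arrays; prediction
#' union over at least one database.
#'
#' @param raw_threshold,frac intensity filter, see
#'   [filter_low_expression()].
#' @param apply_iqr apply the IQR filter to the gene matrix.
#' @param mir_raw_threshold intensity cut-off for the miRNA matrix (the
#'   miRNA platform is filtered by the same intensity rule, no IQR
#'   filter).
#' @param gene_lfc,gene_p,gene_use_adjusted gene significance thresholds.
#' @param mir_lfc,mir_p,mir_use_adjusted miRNA significance thresholds.
#' @param r_min,p_max correlation significance thresholds.
#' @param sample_scope `"per_day"` or `"all_samples"`, see
#'   [correlate_day()].
#' @param cor_p_method `"t"` or `"fisher_z"`, see [correlation_pvalue()].
#' @param min_databases union rule, see [union_predictions()].
#' @param out_dir optional directory; when set, every stage output is
#'   written there as TSV.
#' @param seed optional seed recorded with the run (the pipeline itself
#'   is deterministic; the seed matters when the caller also generates
#'   data).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(raw_threshold = 100, frac = 0.75,
                            apply_iqr = TRUE, mir_raw_threshold = 100,
                            gene_lfc = 0.585, gene_p = 0.05,
                            gene_use_adjusted = TRUE,
                            mir_lfc = 0.485, mir_p = 0.01,
                            mir_use_adjusted = FALSE,
                            r_min = 0.7, p_max = 0.05,
                            sample_scope = "per_day", cor_p_method = "t",
                            min_databases = 1, out_dir = NULL,
                            seed = NULL) {
  cfg <- as.list(environment())
  if (cfg$gene_lfc < 0 || cfg$mir_lfc < 0 || cfg$gene_p <= 0 ||
      cfg$mir_p <= 0)
    stop("significance thresholds must be positive")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full integration pipeline
#'
#' Stages, in order: probe filters on both platforms; per-day moderated-t
#' differential expression; significance calls; prediction-database union
#' restricted per day to DE features; per-day Pearson screen of every DE
#' miRNA against every DE probe; significance filter; intersection of the
#' two evidence streams; probe collapse; per-day bipartite networks; and
#' the pipeline summary. When `truth` is supplied (synthetic data), the
#' recovery of planted couples is also evaluated.
#'
#' @param gene_m,mir_m [expression_matrix()] objects (log2).
#' @param design a [sample_design()].
#' @param predictions list of [prediction_set()] objects (one per
#'   database).
#' @param config a [pipeline_config()].
#' @param truth optional `truth_ledger` for recovery benchmarking.
#' @return list of class `mircouple_run` with elements `gene_filtered`,
#'   `mir_filtered`, `de_gene`, `de_mir`, `de_gene_sig`, `de_mir_sig`,
#'   `prediction_union`, `predictions_by_day`, `correlations`,
#'   `correlations_significant`, `couples` (probe level),
#'   `couples_collapsed`, `couples_wide`, `networks` (per day),
#'   `summary`, `recovery` (or NULL), `config`.
#' @export
run_pipeline <- function(gene_m, mir_m, design, predictions,
                         config = pipeline_config(), truth = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- sample_design(design)
  if (inherits(predictions, "prediction_set")) predictions <- list(predictions)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  gene_f <- run_stage("preprocess_gene",
    preprocess_expression(gene_m, raw_threshold = config$raw_threshold,
                          frac = config$frac,
                          apply_iqr = config$apply_iqr))
  mir_f <- run_stage("preprocess_mir",
    filter_low_expression(mir_m, raw_threshold = config$mir_raw_threshold,
                          frac = config$frac))

  de_gene <- run_stage("de_gene", fit_moderated_t(gene_f, design))
  de_mir <- run_stage("de_mir", fit_moderated_t(mir_f, design))
  de_gene_sig <- call_significant(de_gene, config$gene_lfc, config$gene_p,
                                  config$gene_use_adjusted)
  de_mir_sig <- call_significant(de_mir, config$mir_lfc, config$mir_p,
                                 config$mir_use_adjusted)

  days <- sort(unique(design$day))
  de_probe_sets <- de_feature_sets(de_gene_sig)
  de_mir_sets <- de_feature_sets(de_mir_sig)
  for (d in as.character(days)) {
    if (is.null(de_probe_sets[[d]])) de_probe_sets[[d]] <- character(0)
    if (is.null(de_mir_sets[[d]])) de_mir_sets[[d]] <- character(0)
  }
  p2g <- gene_m$probe_to_gene
  de_gene_sets <- lapply(de_probe_sets, function(pr) {
    if (is.null(p2g)) unique(pr) else
      unique(unname(p2g[pr]))
  })

  pred_union <- run_stage("prediction_union",
    union_predictions(predictions, min_databases = config$min_databases))
  preds_by_day <- run_stage("restrict_predictions",
    restrict_to_de(pred_union, de_gene_sets, de_mir_sets))

  correlations <- run_stage("correlation", do.call(rbind, lapply(days,
    function(d) correlate_day(mir_f, gene_f, d,
                              de_mir_sets[[as.character(d)]],
                              de_probe_sets[[as.character(d)]], design,
                              sample_scope = config$sample_scope,
                              p_method = config$cor_p_method))))
  cor_sig <- filter_correlations(correlations, config$r_min, config$p_max)

  couples <- run_stage("intersection",
                       intersect_couples(cor_sig, preds_by_day))
  collapsed <- collapse_probes(couples)
  wide <- if (nrow(collapsed)) couples_table(collapsed, days = days) else
    data.frame(mir = character(0), gene = character(0))

  networks <- setNames(lapply(days, function(d)
    build_network(collapsed, day = d)), as.character(days))

  summary <- run_stage("summary", summarize_pipeline(list(
    de_genes = de_gene_sig, de_mirs = de_mir_sig,
    correlations = correlations, correlations_significant = cor_sig,
    predictions_by_day = preds_by_day, couples = collapsed,
    probe_to_gene = p2g)))

  recovery <- if (!is.null(truth) && nrow(collapsed) >= 0)
    evaluate_recovery(collapsed[, c("mir", "gene", "day")], truth)
  else NULL

  out <- structure(list(
    gene_filtered = gene_f, mir_filtered = mir_f,
    de_gene = de_gene, de_mir = de_mir,
    de_gene_sig = de_gene_sig, de_mir_sig = de_mir_sig,
    prediction_union = pred_union, predictions_by_day = preds_by_day,
    correlations = correlations, correlations_significant = cor_sig,
    couples = couples, couples_collapsed = collapsed,
    couples_wide = wide, networks = networks, summary = summary,
    recovery = recovery, config = config), class = "mircouple_run")
  if (!is.null(config$out_dir)) persist_run(out, config$out_dir)
  out
}

# internal: write every stage output of a run as TSV
persist_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  w(run$de_gene, "de_gene.tsv")
  w(run$de_mir, "de_mir.tsv")
  w(run$de_gene_sig, "de_gene_significant.tsv")
  w(run$de_mir_sig, "de_mir_significant.tsv")
  write_predictions(run$prediction_union, file.path(dir,
                                                    "prediction_union.tsv"))
  w(run$correlations, "correlations.tsv")
  w(run$correlations_significant, "correlations_significant.tsv")
  w(run$couples_collapsed, "couples.tsv")
  w(run$couples_wide, "couples_wide.tsv")
  for (d in names(run$networks))
    export_network(run$networks[[d]],
                   file.path(dir, sprintf("network_day%s.sif", d)), "sif")
  if (!is.null(run$recovery)) w(run$recovery, "recovery.tsv")
  capture <- utils::capture.output(print(run$summary))
  writeLines(capture, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' @export
print.mircouple_run <- function(x, ...) {
  cat("<mircouple_run>\n")
  print(x$summary)
  if (!is.null(x$recovery)) {
    cat("== Recovery of planted couples ==\n")
    print(x$recovery, row.names = FALSE)
  }
  invisible(x)
}
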