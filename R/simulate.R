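# Synthetic paired gene/miRNA datasets with planted regulation and a
# ground-truth ledger, for end-to-end benchmarking of the pipeline.

#' Configuration for the synthetic dataset generator
#'
#' The defaults emulate a two-condition (transfected vs parental), three
#' day, two-replicate array study — 12 samples per platform — with a
#' predominantly down-regulated differential gene signature (~80% of
#' regulated genes down), a panel of regulated miRNAs whose planted
#' per-day log2 effects are at least 0.6 (so the usual 0.485/0.585
#' thresholds are exercisable on both sides), multi-probe genes, and four
#' imperfect prediction databases.
#'
#' @param n_probes number of gene probes (default 2000).
#' @param n_genes number of genes; the surplus probes are distributed so
#'   some genes carry 2-3 probes (default 1500).
#' @param n_mirs number of miRNAs (default 150).
#' @param n_de_mirs number of regulated miRNAs (default 12).
#' @param targets_per_mir integer range (length 2) of targets per
#'   regulated miRNA (default c(5, 50)); the upper bound may not exceed
#'   `n_genes`.
#' @param frac_down fraction of regulated target genes that are
#'   down-regulated (default 0.80).
#' @param beta regulation effect size on the log2 scale: a target gene
#'   moves by `beta` times its miRNA's deviation, with the couple's sign
#'   (default 1.0; 0 disables regulation entirely).
#' @param sigma residual noise SD on the log2 scale (default 0.25).
#' @param db_sensitivity probability that a true couple is listed in any
#'   one database (default 0.7).
#' @param db_fpr expected false couples per database, as a fraction of
#'   all non-true (miR, gene) pairs (default 0.001).
#' @param n_databases number of synthetic prediction databases (default 4).
#' @param frac_low_intensity fraction of genes planted at raw intensity
#'   <= 100 to exercise the intensity filter (default 0.10).
#' @param frac_flat fraction of genes planted with near-zero IQR to
#'   exercise the IQR filter (default 0.05).
#' @param prob_mir_up probability that a regulated miRNA is up-regulated
#'   in the transfected condition (default 0.8, the canonical situation
#'   in which repressed targets account for the down-regulated bulk).
#' @param seed RNG seed; identical seeds give bit-identical datasets.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 2000, n_genes = 1500, n_mirs = 150,
                       n_de_mirs = 12, targets_per_mir = c(5, 50),
                       frac_down = 0.80, beta = 1.0, sigma = 0.25,
                       db_sensitivity = 0.7, db_fpr = 0.001,
                       n_databases = 4, frac_low_intensity = 0.10,
                       frac_flat = 0.05, prob_mir_up = 0.8, seed = 1) {
  cfg <- list(n_probes = as.integer(n_probes), n_genes = as.integer(n_genes),
              n_mirs = as.integer(n_mirs), n_de_mirs = as.integer(n_de_mirs),
              targets_per_mir = as.integer(targets_per_mir),
              frac_down = frac_down, beta = beta, sigma = sigma,
              db_sensitivity = db_sensitivity, db_fpr = db_fpr,
              n_databases = as.integer(n_databases),
              frac_low_intensity = frac_low_intensity,
              frac_flat = frac_flat, prob_mir_up = prob_mir_up,
              seed = as.integer(seed))
  counts <- c("n_probes", "n_genes", "n_mirs", "n_de_mirs", "n_databases")
  for (nm in counts)
    if (is.na(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop("invalid config: '", nm, "' must be a positive count")
  if (length(cfg$targets_per_mir) != 2 ||
      any(cfg$targets_per_mir <= 0) ||
      cfg$targets_per_mir[1] > cfg$targets_per_mir[2])
    stop("invalid config: 'targets_per_mir' must be a positive range")
  if (cfg$targets_per_mir[2] > cfg$n_genes)
    stop("invalid config: targets_per_mir upper bound exceeds n_genes")
  if (cfg$n_probes < cfg$n_genes || cfg$n_probes > 3L * cfg$n_genes)
    stop("invalid config: n_probes must lie in [n_genes, 3*n_genes]")
  if (cfg$n_de_mirs > cfg$n_mirs)
    stop("invalid config: n_de_mirs exceeds n_mirs")
  for (nm in c("frac_down", "db_sensitivity", "db_fpr",
               "frac_low_intensity", "frac_flat", "prob_mir_up"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("invalid config: '", nm, "' must lie in [0, 1]")
  if (cfg$beta < 0 || cfg$sigma < 0)
    stop("invalid config: 'beta' and 'sigma' must be non-negative")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic paired miRNA/gene dataset
#'
#' Produces log2 expression matrices for both platforms over the
#' 2-condition x 3-day x 2-replicate design, synthetic prediction
#' databases, and a ground-truth ledger. One global RNG stream seeded by
#' `config$seed` is consumed in a fixed, documented order (probe/gene
#' structure, gene baselines and drift, miRNA plan, couples, miRNA
#' values, gene/probe values, databases), so identical configurations
#' give bit-identical outputs.
#'
#' Generative model (log2 scale): a regulated miRNA carries a per-day
#' condition effect `delta` (|delta| in \[0.6, 1.6\]) on its active days;
#' each of its target genes moves by `sign * beta * (miR deviation)` —
#' negative couples move opposite to the miRNA (canonical repression),
#' positive couples with it. Raw intensities are defined as `2^log2`, so
#' a planted fraction of low-baseline genes falls under the raw-intensity
#' filter and a planted fraction of flat genes under the IQR filter;
#' neither class is ever a regulation target.
#'
#' @param config a [sim_config()].
#' @return list of class `mircouple_dataset`: `gene` and `mir`
#'   [expression_matrix()] objects, `design` ([sample_design()]),
#'   `predictions` (list of [prediction_set()], one per database),
#'   `truth` (ledger: `couples`, `de_mirs_by_day`, `de_genes_by_day`,
#'   feature namespaces) and `config`.
#' @export
generate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  days <- c(0L, 7L, 14L)
  grid <- expand.grid(replicate = 1:2, day = days,
                      condition = c("transfected", "parental"),
                      stringsAsFactors = FALSE)
  grid$sample <- sprintf("%s_d%d_r%d", grid$condition, grid$day,
                         grid$replicate)
  design <- sample_design(grid[, c("sample", "condition", "day",
                                   "replicate")])
  ns <- nrow(design)
  day_of <- design$day
  transfected <- design$condition == "transfected"

  # -- 1. probe/gene structure ------------------------------------------
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  extra <- config$n_probes - config$n_genes
  pool <- rep(seq_len(config$n_genes), 2)
  extra_idx <- if (extra > 0) sample(pool, extra) else integer(0)
  probe_gene_idx <- c(seq_len(config$n_genes), extra_idx)
  probe_num <- stats::ave(probe_gene_idx, probe_gene_idx,
                          FUN = seq_along)
  probes <- sprintf("%s_p%d", genes[probe_gene_idx], probe_num)
  probe_to_gene <- setNames(genes[probe_gene_idx], probes)

  # -- 2. gene classes, baselines, day drift ----------------------------
  n_flat <- round(config$frac_flat * config$n_genes)
  n_low <- round(config$frac_low_intensity * config$n_genes)
  cls <- rep("normal", config$n_genes)
  flat_g <- sample(config$n_genes, n_flat)
  cls[flat_g] <- "flat"
  low_g <- sample(which(cls == "normal"), n_low)
  cls[low_g] <- "low"
  base_g <- numeric(config$n_genes)
  base_g[cls != "low"] <- runif(sum(cls != "low"), 7, 12)
  base_g[cls == "low"] <- runif(sum(cls == "low"), 4, 6.2)
  drift <- matrix(rnorm(config$n_genes * 3, 0, 0.3), config$n_genes, 3,
                  dimnames = list(genes, days))
  drift[cls == "flat", ] <- 0

  # -- 3. miRNA plan ----------------------------------------------------
  mirs <- sprintf("mir-%03d", seq_len(config$n_mirs))
  de_mir_idx <- sort(sample(config$n_mirs, config$n_de_mirs))
  mir_dir <- ifelse(runif(config$n_de_mirs) < config$prob_mir_up, 1, -1)
  active <- matrix(runif(config$n_de_mirs * 3) < 0.6,
                   config$n_de_mirs, 3)
  for (i in which(rowSums(active) == 0)) active[i, sample(3, 1)] <- TRUE
  delta <- matrix(0, config$n_de_mirs, 3)
  delta[active] <- runif(sum(active), 0.6, 1.6)
  delta <- delta * mir_dir
  base_m <- runif(config$n_mirs, 6, 12)
  non_de <- setdiff(seq_len(config$n_mirs), de_mir_idx)
  low_m <- sample(non_de, round(0.1 * length(non_de)))
  base_m[low_m] <- runif(length(low_m), 4, 6.2)

  # -- 4. true couples --------------------------------------------------
  normal_genes <- which(cls == "normal")
  couples <- do.call(rbind, lapply(seq_len(config$n_de_mirs), function(i) {
    k <- sample(seq(config$targets_per_mir[1], config$targets_per_mir[2]), 1)
    k <- min(k, length(normal_genes))
    tg <- sample(normal_genes, k)
    down <- runif(k) < config$frac_down
    s_c <- ifelse(down, -mir_dir[i], mir_dir[i])
    data.frame(mir_idx = de_mir_idx[i], gene_idx = tg, s = s_c,
               stringsAsFactors = FALSE)
  }))
  couples <- couples[!duplicated(couples[, c("mir_idx", "gene_idx")]), ]

  # -- 5. miRNA expression ----------------------------------------------
  eff_m <- matrix(0, config$n_mirs, ns)
  day_col <- match(day_of, days)
  for (i in seq_len(config$n_de_mirs))
    eff_m[de_mir_idx[i], transfected] <-
      delta[i, day_col[transfected]]
  mir_vals <- base_m + eff_m +
    matrix(rnorm(config$n_mirs * ns, 0, config$sigma), config$n_mirs, ns)
  dimnames(mir_vals) <- list(mirs, design$sample)

  # -- 6. gene signal and probe values ----------------------------------
  mir_dev <- mir_vals - base_m  # realized deviation incl. noise
  reg <- matrix(0, config$n_genes, ns)
  if (nrow(couples) && config$beta > 0) {
    contrib <- (couples$s * config$beta) *
      mir_dev[couples$mir_idx, , drop = FALSE]
    agg <- rowsum(contrib, group = couples$gene_idx)
    reg[as.integer(rownames(agg)), ] <- agg
  }
  gene_signal <- base_g + drift[, day_col, drop = FALSE] + reg
  probe_offset <- runif(config$n_probes, -0.3, 0.3)
  noise_sd <- ifelse(cls[probe_gene_idx] == "flat", 1e-3, config$sigma)
  probe_vals <- gene_signal[probe_gene_idx, , drop = FALSE] + probe_offset +
    matrix(rnorm(config$n_probes * ns, 0, 1), config$n_probes, ns) * noise_sd
  # flat genes: constant by construction (no drift, no regulation)
  probe_vals[cls[probe_gene_idx] == "flat", ] <-
    (base_g[probe_gene_idx] + probe_offset)[cls[probe_gene_idx] == "flat"] +
    matrix(rnorm(sum(cls[probe_gene_idx] == "flat") * ns, 0, 1e-3),
           ncol = ns)
  dimnames(probe_vals) <- list(probes, design$sample)

  # -- 7. ground-truth ledger -------------------------------------------
  de_mirs_by_day <- do.call(rbind, lapply(1:3, function(j) {
    act <- which(active[, j])
    if (!length(act)) return(NULL)
    data.frame(day = days[j], mir = mirs[de_mir_idx[act]],
               direction = ifelse(mir_dir[act] > 0, "up", "down"),
               stringsAsFactors = FALSE)
  }))
  de_genes_by_day <- do.call(rbind, lapply(1:3, function(j) {
    act_mirs <- de_mir_idx[active[, j]]
    cc <- couples[couples$mir_idx %in% act_mirs, , drop = FALSE]
    if (!nrow(cc)) return(NULL)
    d_idx <- match(cc$mir_idx, de_mir_idx)
    eff <- cc$s * config$beta * delta[cbind(d_idx, j)]
    agg <- tapply(eff, cc$gene_idx, sum)
    agg <- agg[abs(agg) > 1e-12]
    if (!length(agg)) return(NULL)
    data.frame(day = days[j], gene = genes[as.integer(names(agg))],
               direction = ifelse(agg > 0, "up", "down"),
               effect = unname(agg), stringsAsFactors = FALSE)
  }))
  truth <- structure(list(
    couples = data.frame(mir = mirs[couples$mir_idx],
                         gene = genes[couples$gene_idx],
                         sign = ifelse(couples$s > 0, "positive",
                                       "negative"),
                         stringsAsFactors = FALSE),
    de_mirs_by_day = de_mirs_by_day,
    de_genes_by_day = de_genes_by_day,
    mirs = mirs, genes = genes), class = "truth_ledger")

  # -- 8. prediction databases ------------------------------------------
  n_pairs <- config$n_mirs * config$n_genes
  true_code <- (couples$mir_idx - 1L) * config$n_genes + couples$gene_idx
  predictions <- lapply(seq_len(config$n_databases), function(j) {
    listed <- runif(nrow(couples)) < config$db_sensitivity
    n_false <- rbinom(1, n_pairs - nrow(couples), config$db_fpr)
    false_code <- integer(0)
    while (length(false_code) < n_false) {
      cand <- sample.int(n_pairs, n_false - length(false_code) + 50L)
      cand <- setdiff(cand, c(true_code, false_code))
      false_code <- c(false_code, cand)
    }
    false_code <- false_code[seq_len(n_false)]
    mir_i <- c(couples$mir_idx[listed], (false_code - 1L) %/%
                 config$n_genes + 1L)
    gene_i <- c(couples$gene_idx[listed], (false_code - 1L) %%
                  config$n_genes + 1L)
    prediction_set(mirs[mir_i], genes[gene_i], sprintf("db%d", j))
  })

  structure(list(
    gene = expression_matrix(probe_vals, "gene", probe_to_gene),
    mir = expression_matrix(mir_vals, "mir"),
    design = design, predictions = predictions, truth = truth,
    config = config), class = "mircouple_dataset")
}

#' Write a synthetic dataset to a directory of TSV files
#'
#' The ledger is written alongside but is never read by the analysis
#' pipeline; it exists only for benchmarking.
#'
#' @param ds a `mircouple_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "mircouple_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  write_expression_matrix(ds$gene, file.path(dir, "gene_matrix.tsv"),
                          id_column = "probe")
  write_expression_matrix(ds$mir, file.path(dir, "mir_matrix.tsv"),
                          id_column = "mir")
  w(as.data.frame(unclass(ds$design))[, c("sample", "condition", "day",
                                          "replicate")], "design.tsv")
  w(data.frame(probe = names(ds$gene$probe_to_gene),
               gene = unname(ds$gene$probe_to_gene)), "probe_map.tsv")
  for (i in seq_along(ds$predictions))
    write_predictions(ds$predictions[[i]],
                      file.path(dir, sprintf("predictions_db%d.tsv", i)))
  w(ds$truth$couples, "truth_couples.tsv")
  w(ds$truth$de_mirs_by_day, "truth_de_mirs.tsv")
  w(ds$truth$de_genes_by_day, "truth_de_genes.tsv")
  invisible(dir)
}

#' Precision and recall of reported couples against the ledger
#'
#' Precision counts reported couples that are true planted couples
#' (regardless of day); recall counts, per day, the recovered fraction of
#' planted couples whose miRNA and gene are both truly regulated at that
#' day. An empty reported set gives undefined precision (NA, flagged via
#' the `n_reported` column) and recall 0; a day with no truly regulated
#' couples gives recall NA.
#'
#' @param reported data.frame with columns `mir`, `gene`, `day`.
#' @param truth a `truth_ledger` from [generate_dataset()].
#' @return data.frame with one row per day plus an `"overall"` row:
#'   `day`, `n_reported`, `n_relevant`, `precision`, `recall`.
#' @export
evaluate_recovery <- function(reported, truth) {
  stopifnot(inherits(truth, "truth_ledger"))
  if (!all(c("mir", "gene", "day") %in% names(reported)))
    stop("'reported' must have columns mir, gene, day")
  bad_m <- setdiff(normalize_mir_id(reported$mir),
                   normalize_mir_id(truth$mirs))
  bad_g <- setdiff(normalize_gene_id(reported$gene),
                   normalize_gene_id(truth$genes))
  if (length(bad_m) || length(bad_g))
    stop("unknown identifiers outside the ledger namespaces: ",
         paste(c(bad_m, bad_g), collapse = ", "))
  true_keys <- couple_key(truth$couples$mir, truth$couples$gene)
  days <- sort(unique(c(truth$de_mirs_by_day$day, reported$day)))
  score <- function(rep_keys, relevant) {
    precision <- if (length(rep_keys) == 0) NA_real_ else
      mean(rep_keys %in% true_keys)
    recall <- if (length(relevant) == 0) NA_real_ else
      mean(relevant %in% rep_keys)
    c(precision = precision, recall = recall)
  }
  relevant_for_day <- function(d) {
    dm <- normalize_mir_id(
      truth$de_mirs_by_day$mir[truth$de_mirs_by_day$day == d])
    dg <- normalize_gene_id(
      truth$de_genes_by_day$gene[truth$de_genes_by_day$day == d])
    true_keys[normalize_mir_id(truth$couples$mir) %in% dm &
                normalize_gene_id(truth$couples$gene) %in% dg]
  }
  rows <- lapply(days, function(d) {
    rep_keys <- unique(couple_key(reported$mir[reported$day == d],
                                  reported$gene[reported$day == d]))
    rel <- relevant_for_day(d)
    sc <- score(rep_keys, rel)
    data.frame(day = as.character(d), n_reported = length(rep_keys),
               n_relevant = length(rel), precision = sc["precision"],
               recall = sc["recall"], stringsAsFactors = FALSE)
  })
  all_rep <- unique(couple_key(reported$mir, reported$gene))
  all_rel <- unique(unlist(lapply(days, relevant_for_day)))
  sc <- score(all_rep, all_rel)
  out <- rbind(do.call(rbind, rows),
               data.frame(day = "overall", n_reported = length(all_rep),
                          n_relevant = length(all_rel),
                          precision = sc["precision"],
                          recall = sc["recall"],
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
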