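make_records <- function(mir, gene, day, r, probe = paste0(gene, "_p1")) {
  data.frame(mir = mir, probe = probe, gene = gene, day = day, r = r,
             p = 0.01, sign = ifelse(r < 0, "negative", "positive"),
             stringsAsFactors = FALSE)
}

test_that("intersection keeps exactly the predicted significant couples", {
  rec <- make_records(
    mir = c("miR-1", "miR-1", "miR-2", "miR-2", "miR-3"),
    gene = c("G1", "G2", "G1", "G3", "G4"), day = 0,
    r = c(-0.9, 0.8, -0.85, 0.95, -0.99))
  preds <- prediction_set(c("miR-1", "miR-2", "miR-3"),
                          c("G1", "G3", "G9"), "db")
  out <- intersect_couples(rec, preds)
  # brute-force set intersection as the oracle
  manual <- paste(rec$mir, rec$gene) %in%
    paste(preds$mir, preds$gene)
  expect_equal(paste(out$mir, out$gene),
               paste(rec$mir, rec$gene)[manual])
  expect_equal(out$n_databases, rep(1L, 2))

  # empty predictions -> empty output
  none <- prediction_set(character(0), character(0), character(0))
  expect_equal(nrow(intersect_couples(rec, none)), 0L)

  # correlations fully covered by predictions pass through unchanged
  all_pred <- prediction_set(rec$mir, rec$gene, "db")
  expect_equal(nrow(intersect_couples(rec, all_pred)), nrow(rec))

  # per-day prediction lists apply day by day
  rec2 <- rbind(rec, make_records("miR-1", "G1", 7, -0.8))
  by_day <- list(`0` = preds, `7` = none)
  out2 <- intersect_couples(rec2, by_day)
  expect_true(all(out2$day == 0))
})

test_that("probe collapse retains the most-correlated probe per day", {
  two <- rbind(make_records("miR-34a", "C18orf25", 0, -0.945, "pA"),
               make_records("miR-34a", "C18orf25", 0, -0.917, "pB"))
  out <- collapse_probes(two)
  expect_equal(nrow(out), 1L)
  expect_equal(out$r, -0.945)

  single <- make_records("miR-1", "G1", 0, 0.8)
  expect_equal(collapse_probes(single), single)

  # an exact tie goes to the lexicographically smaller probe ID
  tie <- rbind(make_records("m", "G", 0, 0.9, "pZ"),
               make_records("m", "G", 0, 0.9, "pA"))
  expect_message(out_tie <- collapse_probes(tie), "tie")
  expect_equal(out_tie$probe, "pA")

  # collapse never increases, and keeps per-day duplicates of a couple
  multi <- rbind(two, make_records("miR-34a", "C18orf25", 7, -0.856))
  cl <- collapse_probes(multi)
  expect_lte(nrow(cl), nrow(multi))
  expect_equal(nrow(cl), 2L)  # one per day
})

test_that("wide couple tables pivot days into r columns", {
  cl <- rbind(make_records("miR-1", "G1", 0, -0.9),
              make_records("miR-1", "G1", 7, -0.8),
              make_records("miR-2", "G2", 14, 0.85))
  wide <- couples_table(cl, days = c(0, 7, 14))
  expect_equal(nrow(wide), 2L)
  expect_equal(wide$r_day0[wide$mir == "miR-1"], -0.9)
  expect_equal(wide$r_day7[wide$mir == "miR-1"], -0.8)
  expect_true(is.na(wide$r_day14[wide$mir == "miR-1"]))
  expect_equal(wide$r_day14[wide$mir == "miR-2"], 0.85)
})

test_that("the curated couple table reproduces the published structure", {
  tab <- example_integrated_couples()
  s <- summarize_couples(tab)
  # per-day distinct couples / miRNAs / genes
  expect_equal(s$per_day$n_couples, c(11L, 22L, 36L))
  expect_equal(s$per_day$n_mirs, c(2L, 2L, 6L))
  expect_equal(s$per_day$n_genes, c(11L, 22L, 32L))
  # the sign split of the smaller hubs
  pm <- s$per_mir
  m342 <- pm[normalize_mir_id(pm$mir) == "mir-342-3p", ]
  expect_equal(m342$n_couples, 9L)
  expect_equal(m342$n_positive, 8L)
})

test_that("correlation summaries derive percentages from counts", {
  cs <- correlation_screen_summary(c(100, 200), c(10, 30), days = c(0, 7),
                                   n_positive = c(4, 10),
                                   n_negative = c(6, 20))
  expect_equal(cs$per_day$pct_significant, c(10, 15))
  expect_equal(cs$per_day$pct_positive, c(40, 33.3))
  expect_equal(cs$overall_pct_significant, round(100 * 40 / 300, 1))
  expect_error(correlation_screen_summary(c(10), c(11)), "exceed")
  expect_error(correlation_screen_summary(c(10, 10), c(1, 1), n_positive =
    c(1, 1), n_negative = c(1, 1)), "must equal")
})

test_that("the pipeline summary needs every stage and keeps invariants", {
  expect_error(summarize_pipeline(list(de_genes = NULL)),
               "missing stage")
  ds <- generate_dataset(small_config(seed = 8))
  run <- run_pipeline(ds$gene, ds$mir, ds$design, ds$predictions,
                      pipeline_config(), truth = ds$truth)
  sm <- run$summary
  expect_true(all(sm$correlations$n_significant <=
                    sm$correlations$n_computed))
  expect_true(all(sm$correlations$n_positive + sm$correlations$n_negative ==
                    sm$correlations$n_significant))
  expect_true(all(unlist(sm$totals) >= 0))
  # integrated couples cannot exceed either evidence stream
  n_sig_couples <- length(unique(paste(
    run$correlations_significant$mir, run$correlations_significant$gene)))
  n_pred <- sum(vapply(run$predictions_by_day, nrow, integer(1)))
  expect_lte(sm$totals$n_couples, n_sig_couples)
  expect_lte(nrow(run$couples_collapsed), n_pred + n_sig_couples)
})

test_that("dropping a database never increases the integrated couples", {
  ds <- generate_dataset(small_config(seed = 12))
  full <- run_pipeline(ds$gene, ds$mir, ds$design, ds$predictions,
                       pipeline_config())
  fewer <- run_pipeline(ds$gene, ds$mir, ds$design, ds$predictions[1:2],
                        pipeline_config())
  expect_lte(nrow(fewer$couples_collapsed), nrow(full$couples_collapsed))
  expect_true(all(paste(fewer$couples_collapsed$mir,
                        fewer$couples_collapsed$gene) %in%
                    paste(full$couples_collapsed$mir,
                          full$couples_collapsed$gene)))
})
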