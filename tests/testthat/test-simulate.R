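test_that("identical seeds give bit-identical datasets", {
  a <- generate_dataset(small_config(seed = 5))
  b <- generate_dataset(small_config(seed = 5))
  expect_identical(a, b)
  c <- generate_dataset(small_config(seed = 6))
  expect_false(identical(a$gene$values, c$gene$values))

  # file output is byte-identical too
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(a, d1)
  write_dataset(b, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(targets_per_mir = c(5, 9999)), "n_genes")
  expect_error(sim_config(frac_down = 1.2), "frac_down")
  expect_error(sim_config(n_mirs = 0), "n_mirs")
  expect_error(sim_config(n_de_mirs = 200, n_mirs = 100), "n_de_mirs")
  expect_error(sim_config(db_sensitivity = -0.1), "db_sensitivity")
})

test_that("the design is 2 conditions x 3 days x 2 replicates per platform", {
  ds <- generate_dataset(small_config(seed = 2))
  expect_equal(nrow(ds$design), 12L)
  expect_equal(ncol(ds$gene$values), 12L)
  expect_equal(ncol(ds$mir$values), 12L)
  expect_equal(sort(unique(ds$design$day)), c(0L, 7L, 14L))
  expect_equal(as.integer(table(ds$design$condition)), c(6L, 6L))
  expect_true(all(table(ds$design$condition, ds$design$day) == 2))
  # every probe maps to a generated gene, genes carry 1-3 probes
  p2g <- ds$gene$probe_to_gene
  expect_true(all(p2g %in% ds$truth$genes))
  expect_true(all(table(p2g) <= 3))
})

test_that("planted down-regulated fraction sits near 0.80", {
  for (seed in 1:3) {
    ds <- generate_dataset(sim_config(seed = seed))
    dg <- ds$truth$de_genes_by_day
    expect_gt(nrow(dg), 100)
    expect_lt(abs(mean(dg$direction == "down") - 0.80), 0.05)
  }
})

test_that("planted low-intensity and flat probes exercise both filters", {
  ds <- generate_dataset(sim_config(seed = 4))
  kept_int <- features(filter_low_expression(ds$gene))
  expect_lt(length(kept_int), nrow(ds$gene$values))
  kept_iqr <- features(filter_low_iqr(ds$gene))
  expect_lt(length(kept_iqr), nrow(ds$gene$values))
  # flat probes are always IQR-filtered: their IQR is essentially zero
  iqr <- apply(ds$gene$values, 1, IQR)
  flat <- names(iqr)[iqr < 0.01]
  expect_gt(length(flat), 0)
  expect_false(any(flat %in% kept_iqr))
})

test_that("synthetic databases list true couples at the configured sensitivity", {
  cfg <- sim_config(seed = 9)
  ds <- generate_dataset(cfg)
  truth_keys <- paste(ds$truth$couples$mir, ds$truth$couples$gene)
  hit_rates <- vapply(ds$predictions, function(db) {
    mean(truth_keys %in% paste(db$mir, db$gene))
  }, numeric(1))
  expect_true(all(abs(hit_rates - cfg$db_sensitivity) < 0.08))
  # false couples stay rare relative to the pair space
  for (db in ds$predictions) {
    n_false <- sum(!paste(db$mir, db$gene) %in% truth_keys)
    n_pairs <- cfg$n_mirs * cfg$n_genes
    expect_lt(n_false / n_pairs, 5 * cfg$db_fpr)
  }
})

test_that("recovery scoring has the exact set-arithmetic semantics", {
  ds <- generate_dataset(small_config(seed = 3))
  truth <- ds$truth
  # reporting exactly the truly-regulated couples of each day is perfect
  perfect <- do.call(rbind, lapply(unique(truth$de_mirs_by_day$day),
    function(d) {
      dm <- truth$de_mirs_by_day$mir[truth$de_mirs_by_day$day == d]
      dg <- truth$de_genes_by_day$gene[truth$de_genes_by_day$day == d]
      cc <- truth$couples[truth$couples$mir %in% dm &
                            truth$couples$gene %in% dg, ]
      if (!nrow(cc)) return(NULL)
      data.frame(mir = cc$mir, gene = cc$gene, day = d)
    }))
  res <- evaluate_recovery(perfect, truth)
  expect_true(all(res$precision == 1))
  expect_true(all(res$recall == 1))

  # empty report: precision undefined, recall zero where couples exist
  empty <- perfect[0, ]
  res0 <- evaluate_recovery(empty, truth)
  expect_true(all(is.na(res0$precision)))
  expect_true(all(res0$recall[res0$n_relevant > 0] == 0))

  expect_error(evaluate_recovery(
    data.frame(mir = "mir-999", gene = "nope", day = 0), truth),
    "unknown identifiers")
})

test_that("with no regulation planted couples decorrelate", {
  # Monte-Carlo: under beta = 0 the per-day correlation of planted couples
  # is centred at zero
  rs <- unlist(lapply(1:100, function(seed) {
    ds <- generate_dataset(sim_config(
      n_probes = 60, n_genes = 50, n_mirs = 10, n_de_mirs = 2,
      targets_per_mir = c(2, 4), beta = 0, seed = seed))
    day0 <- ds$design$sample[ds$design$day == 0]
    cc <- ds$truth$couples[1:2, ]
    probe <- names(ds$gene$probe_to_gene)[
      match(cc$gene, ds$gene$probe_to_gene)]
    vapply(seq_len(nrow(cc)), function(i)
      cor(ds$mir$values[cc$mir[i], day0],
          ds$gene$values[probe[i], day0]), numeric(1))
  }))
  expect_lt(abs(mean(rs)), 0.1)
  # recovery of a random "reported" set is no better than chance would give
  expect_gt(sd(rs), 0.3)  # n = 4 null correlations are wide, not peaked
})

test_that("stronger regulation monotonically improves recall", {
  mean_recall <- vapply(c(0.5, 1.0, 1.5), function(beta) {
    mean(vapply(1:20, function(seed) {
      ds <- generate_dataset(small_config(seed = seed, beta = beta,
                                          sigma = 0.25))
      run <- run_pipeline(ds$gene, ds$mir, ds$design, ds$predictions,
                          pipeline_config(), truth = ds$truth)
      rec <- run$recovery$recall[run$recovery$day == "overall"]
      if (is.na(rec)) 0 else rec
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_recall) > 0))
})
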