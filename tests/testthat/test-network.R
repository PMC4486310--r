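star_records <- function(n_leaves = 56, hub = "miR-34a") {
  data.frame(mir = rep(hub, n_leaves),
             gene = sprintf("G%02d", seq_len(n_leaves)),
             sign = rep("negative", n_leaves), day = rep(0, n_leaves),
             stringsAsFactors = FALSE)
}

test_that("network construction builds simple bipartite graphs", {
  expect_equal(nrow(build_network(star_records(0))$edges), 0L)

  net <- build_network(star_records())
  expect_equal(length(net$mirs), 1L)
  expect_equal(length(net$genes), 56L)
  expect_equal(nrow(net$edges), 56L)

  # a gene shared by two miRs has degree 2
  two <- data.frame(mir = c("m1", "m2"), gene = "G1", sign = "negative",
                    day = 0)
  n2 <- build_network(two)
  g <- as_igraph(n2)
  expect_equal(unname(igraph::degree(g)["G1"]), 2)

  # parallel evidence collapses to a simple edge
  dup <- rbind(two, two)
  expect_equal(nrow(build_network(dup)$edges), 2L)

  # miR/gene namespace clash is refused
  clash <- data.frame(mir = "X", gene = "X", sign = "negative", day = 0)
  expect_error(build_network(clash), "disjoint")
})

test_that("connected components match an independent flood fill", {
  star_plus <- rbind(star_records(5),
                     data.frame(mir = "miR-9", gene = "G99",
                                sign = "positive", day = 0))
  comps <- connected_subnetworks(build_network(star_plus))
  expect_length(comps, 2L)
  expect_equal(length(comps[[1]]$genes), 5L)  # largest first

  full <- expand.grid(mir = c("m1", "m2"), gene = c("G1", "G2"),
                      stringsAsFactors = FALSE)
  expect_length(connected_subnetworks(build_network(full)), 1L)

  for (seed in 1:10) {
    set.seed(seed)
    edges <- data.frame(
      mir = sprintf("m%d", sample(8, 20, TRUE)),
      gene = sprintf("G%d", sample(12, 20, TRUE)),
      stringsAsFactors = FALSE)
    edges <- edges[!duplicated(edges), ]
    comps <- connected_subnetworks(build_network(edges))
    mine <- lapply(comps, function(n) sort(c(n$mirs, n$genes)))
    oracle <- lapply(flood_fill_components(edges), sort)
    expect_setequal(vapply(mine, paste, character(1), collapse = ","),
                    vapply(oracle, paste, character(1), collapse = ","))
    # component sizes sum to the node count
    expect_equal(sum(lengths(mine)), length(unique(unlist(edges))))
  }
})

test_that("degree centralization is exact on the canonical topologies", {
  expect_equal(degree_centralization(build_network(star_records(56))), 1)

  # any regular graph scores zero: a bipartite 4-cycle
  cyc <- data.frame(mir = c("m1", "m1", "m2", "m2"),
                    gene = c("G1", "G2", "G1", "G2"))
  expect_equal(degree_centralization(build_network(cyc)), 0)

  # path of 4 nodes: sum(d_max - d_i) = 2 over (n-1)(n-2) = 6
  path4 <- data.frame(mir = c("m1", "m2", "m2"),
                      gene = c("G1", "G1", "G2"))
  expect_equal(degree_centralization(build_network(path4)), 1 / 3)

  expect_error(degree_centralization(build_network(star_records(1))),
               "3 nodes")
})

test_that("centralization stays in [0,1] and characterises stars/regular graphs", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (i in 1:2000) {
    n_m <- sample(1:5, 1)
    n_g <- sample(2:7, 1)
    n_e <- sample(2:(n_m * n_g), 1)
    pairs <- expand.grid(mir = sprintf("m%d", 1:n_m),
                         gene = sprintf("G%d", 1:n_g),
                         stringsAsFactors = FALSE)
    edges <- pairs[sample(nrow(pairs), n_e), ]
    net <- build_network(edges)
    n <- length(net$mirs) + length(net$genes)
    if (n < 3) next
    C <- degree_centralization(net)
    expect_gte(C, 0)
    expect_lte(C, 1)
    deg <- table(factor(c(edges$mir, edges$gene),
                        levels = c(net$mirs, net$genes)))
    is_star <- max(deg) == n - 1 && sum(deg) == 2 * (n - 1)
    expect_equal(C == 1, is_star)
    expect_equal(C == 0, length(unique(as.integer(deg))) == 1)
    # agrees with the graph library's Freeman centralization
    ig <- igraph::centr_degree(as_igraph(net), loops = FALSE,
                               normalized = TRUE)
    expect_equal(C, ig$centralization, tolerance = 1e-12)
  }
})

test_that("SIF and GraphML exports round-trip the network", {
  net <- build_network(star_records(56))
  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  expect_length(readLines(sif), 56L)
  back <- import_network(sif, "sif")
  expect_setequal(paste(back$edges$mir, back$edges$gene),
                  paste(net$edges$mir, net$edges$gene))

  empty <- build_network(star_records(0))
  sif0 <- withr::local_tempfile(fileext = ".sif")
  export_network(empty, sif0, "sif")
  expect_equal(length(readLines(sif0)), 0L)
  gml0 <- withr::local_tempfile(fileext = ".graphml")
  export_network(empty, gml0, "graphml")
  expect_true(any(grepl("graphml", readLines(gml0))))  # valid skeleton

  for (seed in 1:5) {
    set.seed(seed)
    edges <- unique(data.frame(
      mir = sprintf("m%d", sample(5, 12, TRUE)),
      gene = sprintf("G%d", sample(8, 12, TRUE)),
      sign = sample(c("positive", "negative"), 12, TRUE),
      stringsAsFactors = FALSE))
    net <- build_network(edges)
    gml <- withr::local_tempfile(fileext = ".graphml")
    export_network(net, gml, "graphml")
    back <- import_network(gml, "graphml")
    expect_setequal(back$mirs, net$mirs)
    expect_setequal(back$genes, net$genes)
    expect_setequal(paste(back$edges$mir, back$edges$gene,
                          back$edges$sign),
                    paste(net$edges$mir, net$edges$gene, net$edges$sign))
  }
  expect_error(export_network(net, tempfile(), "gexf"), "arg")
})
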