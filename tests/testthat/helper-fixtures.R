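# Shared builders for small in-code fixtures.

# the standard 2-condition x 3-day x 2-replicate design (12 samples)
toy_design <- function() {
  grid <- expand.grid(replicate = 1:2, day = c(0L, 7L, 14L),
                      condition = c("transfected", "parental"),
                      stringsAsFactors = FALSE)
  grid$sample <- sprintf("%s_d%d_r%d", grid$condition, grid$day,
                         grid$replicate)
  sample_design(grid[, c("sample", "condition", "day", "replicate")])
}

# random log2 matrix over the toy design
toy_matrix <- function(n_features = 10, platform = "gene", mean = 8,
                       sd = 1, prefix = if (platform == "gene") "p" else
                         "mir", seed = NULL, probe_to_gene = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- toy_design()
  v <- matrix(rnorm(n_features * nrow(d), mean, sd), n_features, nrow(d),
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n_features)),
                              d$sample))
  expression_matrix(v, platform, probe_to_gene)
}

# a fast, small simulation configuration for replicated tests
small_config <- function(seed = 1, ...) {
  sim_config(n_probes = 220, n_genes = 180, n_mirs = 30, n_de_mirs = 5,
             targets_per_mir = c(3, 10), seed = seed, ...)
}

# independent brute-force BH step-up, straight from the definition
bh_brute_force <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# independent flood-fill connected components over an edge list
flood_fill_components <- function(edges) {
  nodes <- unique(c(edges$mir, edges$gene))
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (start in nodes) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      nb <- c(edges$gene[edges$mir == v], edges$mir[edges$gene == v])
      queue <- c(queue, nb[is.na(comp[nb])])
    }
  }
  split(names(comp), comp)
}
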