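# Independent oracles and small fixture builders. Each oracle is a literal,
# slow re-derivation of the statistic it checks, kept free of the package's
# own code paths.

# Brute-force Benjamini-Hochberg step-up: find, for each i, the smallest
# q such that p_(k) <= q*k/m for some k >= rank(i) -- i.e. min over k >= i of
# m*p_(k)/k, computed by direct enumeration.
bh_oracle <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(k) m * ps[k] / k, numeric(1))
    adj[i] <- min(1, min(cand))
  }
  res <- numeric(m)
  res[o] <- adj
  res
}

# Literal O(N) GSEA running sum: walk the full ranked list, track the running
# sum, return the deviation with maximum absolute value (positive on ties).
es_oracle <- function(ranked, gene_set, exponent = 1) {
  genes <- ranked$gene_id
  N <- length(genes)
  hit <- genes %in% gene_set
  stopifnot(any(hit), !all(hit))
  w <- abs(ranked$rs)^exponent
  wh <- sum(w[hit])
  inc <- if (wh > 0) w * hit / wh else hit / sum(hit)
  dec <- (!hit) / (N - sum(hit))
  running <- cumsum(inc - dec)
  mx <- max(running, 0)  # the sum returns to 0 after the last position
  mn <- min(running, 0)
  es <- if (mx >= -mn) mx else mn
  structure(es, extremes = c(mx, mn))
}

# Compare an ES against the oracle: magnitudes must always agree; the sign is
# checked only when the positive and negative extremes are not a numerical
# tie (on exact ties the two arithmetic routes may legitimately differ).
expect_es_equal <- function(actual, oracle, tol = 1e-12) {
  ext <- attr(oracle, "extremes")
  expect_equal(abs(actual), max(abs(ext)), tolerance = tol)
  if (abs(ext[1] + ext[2]) > 1e-9) {
    expect_equal(actual, as.numeric(oracle), tolerance = tol)
  }
}

# Dense personalized-PageRank oracle: solve (I - d * W) s = (1-d) v with W the
# column-stochastic transition operator including dangling teleportation.
ppr_oracle <- function(graph, seeds, damping = 0.85) {
  n <- igraph::vcount(graph)
  nodes <- igraph::V(graph)$name
  A <- as.matrix(igraph::as_adjacency_matrix(
    graph, attr = if (!is.null(igraph::E(graph)$weight)) "weight" else NULL))
  deg <- rowSums(A)
  P <- matrix(0, n, n)
  v <- numeric(n); v[nodes %in% seeds] <- 1 / sum(nodes %in% seeds)
  for (i in seq_len(n)) {
    if (deg[i] == 0) P[i, ] <- v else P[i, ] <- A[i, ] / deg[i]
  }
  s <- solve(diag(n) - damping * t(P), (1 - damping) * v)
  stats::setNames(s / sum(s), nodes)
}

# Partial correlation by the residual route: correlate the OLS residuals of
# l ~ purity and g ~ purity.
pcor_oracle <- function(l, g, purity) {
  rl <- stats::residuals(stats::lm(l ~ purity))
  rg <- stats::residuals(stats::lm(g ~ purity))
  stats::cor(rl, rg)
}

# Random connected-ish weighted graph with named nodes, for PPR checks.
random_graph <- function(n, p_edge = 0.4, lnc_frac = 0.5) {
  repeat {
    g <- igraph::sample_gnp(n, p_edge)
    if (igraph::ecount(g) > 0) break
  }
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  igraph::V(g)$class <- ifelse(stats::runif(n) < lnc_frac, "lncRNA", "gene")
  igraph::E(g)$weight <- stats::runif(igraph::ecount(g), 0.1, 1)
  g
}

# Tiny deterministic expression fixture: 2 genes, 2 lncRNAs, n samples.
toy_expression <- function(n = 8, seed = 42) {
  withr::with_seed(seed, {
    V <- matrix(rnorm(4 * n), 4, n,
                dimnames = list(c("G1", "G2", "L1", "L2"), paste0("S", 1:n)))
    expression_matrix(V, c(G1 = "gene", G2 = "gene",
                           L1 = "lncRNA", L2 = "lncRNA"))
  })
}

# Write the standard input files for a simulated cohort; returns the paths.
write_sim_inputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  V <- sim$expr$values
  write_table(data.frame(feature_id = rownames(V), V, check.names = FALSE),
              file.path(dir, "expression.tsv"), sort_rows = FALSE)
  write_table(data.frame(feature_id = rownames(V),
                         class = unname(sim$expr$feature_class)),
              file.path(dir, "classes.tsv"), sort_rows = FALSE)
  write_table(data.frame(sample_id = names(sim$purity),
                         purity = unname(sim$purity)),
              file.path(dir, "purity.tsv"), sort_rows = FALSE)
  writeLines(sim$truth$icp_genes, file.path(dir, "icp.txt"))
  write_table(sim$edges, file.path(dir, "interactions.tsv"), sort_rows = FALSE)
  gmt <- vapply(names(sim$gene_sets), function(nm)
    paste(c(nm, "synthetic immune pathway", sim$gene_sets[[nm]]),
          collapse = "\t"), character(1))
  writeLines(gmt, file.path(dir, "pathways.gmt"))
  list(expr = file.path(dir, "expression.tsv"),
       classes = file.path(dir, "classes.tsv"),
       purity = file.path(dir, "purity.tsv"),
       icp = file.path(dir, "icp.txt"),
       interactions = file.path(dir, "interactions.tsv"),
       gmt = file.path(dir, "pathways.gmt"))
}
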