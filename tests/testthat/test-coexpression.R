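test_that("pearson_with_p matches the t-distribution oracle and handles edge cases", {
  withr::local_seed(7)
  for (i in 1:20) {
    x <- rnorm(20); y <- 0.4 * x + rnorm(20)
    got <- pearson_with_p(x, y)
    r <- cor(x, y)
    t <- r * sqrt(18 / (1 - r^2))
    expect_equal(got$r, r, tolerance = 1e-12)
    expect_equal(got$p, 2 * pt(-abs(t), 18), tolerance = 1e-10)
    expect_identical(got$n_obs, 20L)
    # cross-check against the packaged t machinery's independent counterpart
    expect_equal(got$p, cor.test(x, y)$p.value, tolerance = 1e-10)
  }
  x <- rnorm(10)
  ident <- pearson_with_p(x, x)
  expect_equal(ident$r, 1)
  expect_gt(ident$p, 0)          # p floored, never exactly 0
  # orthogonal mean-zero pair -> r = 0, p = 1
  x <- c(-1, 1, -1, 1); y <- c(-1, -1, 1, 1)
  orth <- pearson_with_p(x, y)
  expect_equal(orth$r, 0)
  expect_equal(orth$p, 1)
  # missing entries are removed pairwise and n_obs records the pair count
  xm <- c(rnorm(8), NA, 2); ym <- c(rnorm(9), NA)
  expect_identical(pearson_with_p(xm, ym)$n_obs, 8L)
  expect_error(pearson_with_p(c(1, 2, NA), c(1, 2, 3)),
               class = "icplnc_undefined_correlation")
  expect_error(pearson_with_p(rep(1, 5), rnorm(5)),
               class = "icplnc_undefined_correlation")
})

test_that("bh_adjust matches hand computation and brute-force oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  withr::local_seed(11)
  for (i in 1:50) {
    p <- runif(sample(1:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
  }
  # NAs pass through untouched
  withNA <- bh_adjust(c(0.01, NA, 0.5))
  expect_true(is.na(withNA[2]))
  expect_equal(withNA[c(1, 3)], bh_oracle(c(0.01, 0.5)))
})

test_that("build_network recovers a planted co-expression block", {
  withr::local_seed(3)
  n <- 100
  f <- rnorm(n)
  planted_lnc <- sprintf("PL%02d", 1:5)
  noise_lnc <- sprintf("NL%02d", 1:50)
  icp <- c("ICPA", "ICPB")
  mk <- function(signal) sqrt(0.81) * f * signal + sqrt(1 - 0.81 * signal) * rnorm(n)
  V <- rbind(t(sapply(1:2, function(i) mk(1))),
             t(sapply(1:5, function(i) mk(1))),
             t(sapply(1:50, function(i) mk(0))))
  rownames(V) <- c(icp, planted_lnc, noise_lnc)
  colnames(V) <- sprintf("S%03d", 1:n)
  em <- expression_matrix(V, setNames(c("gene", "gene", rep("lncRNA", 55)),
                                      rownames(V)))
  inter <- expand.grid(node_a = c(planted_lnc, noise_lnc), node_b = icp,
                       stringsAsFactors = FALSE)
  inter$weight <- NA_real_
  g <- build_network(em, icp, inter, alpha = 0.05)
  edges <- igraph::as_data_frame(g, "edges")
  planted_edges <- paste(rep(planted_lnc, each = 2), rep(icp, 5))
  got_edges <- c(paste(edges$from, edges$to), paste(edges$to, edges$from))
  expect_true(all(planted_edges %in% got_edges))
  false_edges <- sum(edges$from %in% noise_lnc | edges$to %in% noise_lnc)
  expect_lte(false_edges, ceiling(0.05 * nrow(inter)))
  expect_true(all(igraph::E(g)$weight > 0))
  expect_true(all(igraph::V(g)$is_icp[igraph::V(g)$class == "lncRNA"] == FALSE))

  # invariance to sample-column permutation
  perm <- sample(n)
  em2 <- expression_matrix(V[, perm], em$feature_class)
  g2 <- build_network(em2, icp, inter, alpha = 0.05)
  e2 <- igraph::as_data_frame(g2, "edges")
  o1 <- order(edges$from, edges$to); o2 <- order(e2$from, e2$to)
  expect_equal(edges$r[o1], e2$r[o2], tolerance = 1e-10)
  expect_equal(edges$p_adj[o1], e2$p_adj[o2], tolerance = 1e-10)

  # degenerate configurations
  expect_error(build_network(em, c("NOPE"), inter),
               class = "icplnc_config_error")
  expect_warning(g0 <- build_network(em, icp, inter[0, ]), "empty")
  expect_equal(igraph::vcount(g0), 0)
  g_alpha0 <- build_network(em, icp, inter, alpha = 0)
  expect_equal(igraph::ecount(g_alpha0), 0)
})

test_that("null co-expression pass rate is alpha-controlled", {
  # pure-noise simulation: 200 pairs per repetition, p_adj < 0.05 rate
  withr::local_seed(19)
  reps <- 200
  hits <- numeric(reps)
  for (b in seq_len(reps)) {
    X <- matrix(rnorm(100 * 20), 20, 100)
    a_idx <- sample(20, 200, replace = TRUE)
    b_idx <- sample(20, 200, replace = TRUE)
    keep <- a_idx != b_idx
    r <- vapply(which(keep), function(i) cor(X[a_idx[i], ], X[b_idx[i], ]),
                numeric(1))
    p <- 2 * pt(-abs(r * sqrt(98 / (1 - r^2))), 98)
    hits[b] <- mean(bh_adjust(p) < 0.05)
  }
  se <- sd(hits) / sqrt(reps)
  expect_lte(mean(hits), 0.05 + 3 * se)
})
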