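test_that("partial_correlation matches the residual-regression oracle", {
  withr::local_seed(41)
  for (i in 1:100) {
    n <- 30L
    pur <- runif(n, 0.2, 0.95)
    l <- 0.5 * pur + rnorm(n)
    g <- -0.3 * pur + 0.4 * l + rnorm(n)
    got <- partial_correlation(l, g, pur)
    expect_equal(got$pcc, pcor_oracle(l, g, pur), tolerance = 1e-10)
    expect_identical(got$n_obs, n)
    # p from t on n-3 df
    t <- got$pcc * sqrt((n - 3) / (1 - got$pcc^2))
    expect_equal(got$p, 2 * pt(-abs(t), n - 3), tolerance = 1e-12)
  }
})

test_that("partial_correlation collapses and errors as specified", {
  withr::local_seed(43)
  n <- 40L
  l <- rnorm(n); g <- 0.6 * l + rnorm(n)
  pur <- runif(n)
  # purity orthogonal to both (population): PCC ~ R_LG; check exact algebra
  r_lg <- cor(l, g); r_lp <- cor(l, pur); r_gp <- cor(g, pur)
  manual <- (r_lg - r_lp * r_gp) / (sqrt(1 - r_lp^2) * sqrt(1 - r_gp^2))
  expect_equal(partial_correlation(l, g, pur)$pcc, manual, tolerance = 1e-12)
  # identical vectors: PCC = 1 regardless of purity
  expect_equal(partial_correlation(l, l, pur)$pcc, 1)
  # degenerate covariate
  expect_error(partial_correlation(l, g, l),
               class = "icplnc_degenerate_covariate")
  expect_error(partial_correlation(rnorm(3), rnorm(3), runif(3)),
               class = "icplnc_insufficient_data")
  # missing triples dropped jointly
  l[1] <- NA; g[2] <- NA; pur[3] <- NA
  expect_identical(partial_correlation(l, g, pur)$n_obs, n - 3L)
})

test_that("rank_score implements -log10(p) * sign(PCC)", {
  expect_equal(rank_score(0.01, 0.8), 2)
  expect_equal(rank_score(1, -0.5), 0)
  expect_equal(rank_score(0.001, -0.2), -3)
  expect_equal(rank_score(0.05, 0), 0)
  expect_error(rank_score(0, 0.5))
  # vectorized, and p underflow is floored rather than infinite
  expect_equal(rank_score(c(0.1, 1e-320), c(1, 1)), c(1, 300))
})

test_that("gsea_es agrees with the brute-force running-sum oracle", {
  # fixed 10-gene list, 3-gene set, exponent 1
  rs <- setNames(c(5, 4, 3, 2, 1, -1, -2, -3, -4, -5), paste0("g", 1:10))
  ranked <- ranked_gene_list(rs)
  set3 <- c("g1", "g2", "g4")
  expect_es_equal(gsea_es(ranked, set3, exponent = 1),
                  es_oracle(ranked, set3, exponent = 1))
  # top-ranked single gene, exponent 0 -> ES = 1
  expect_equal(gsea_es(ranked, "g1", exponent = 0), 1)
  # bottom-ranked single gene: running sum bottoms out at -1 just before the hit
  expect_es_equal(gsea_es(ranked, "g10", exponent = 0),
                  es_oracle(ranked, "g10", exponent = 0))
  expect_equal(gsea_es(ranked, "g10", exponent = 0), -1)

  withr::local_seed(47)
  for (i in 1:500) {
    N <- sample(5:50, 1)
    rs <- setNames(rnorm(N) * sample(c(1, 5), N, replace = TRUE),
                   sprintf("x%03d", sample.int(999, N)))
    ranked <- ranked_gene_list(rs)
    k <- sample(1:(N - 1), 1)
    gene_set <- sample(names(rs), k)
    expo <- sample(c(0, 1, 1.5), 1)
    expect_es_equal(gsea_es(ranked, gene_set, exponent = expo),
                    es_oracle(ranked, gene_set, exponent = expo))
  }

  expect_error(gsea_es(ranked, "absent"), class = "icplnc_no_overlap")
  expect_error(gsea_es(ranked, names(rs)), class = "icplnc_degenerate_set")
})

test_that("ranked_gene_list orders by RS descending with id tie-break", {
  rs <- c(b = 1, a = 1, c = 2, d = -1)
  rl <- ranked_gene_list(rs)
  expect_identical(rl$gene_id, c("c", "a", "b", "d"))
  expect_error(ranked_gene_list(c(1, 2)))
})

test_that("gsea_permutation_p is deterministic, saturates under signal, and is calibrated", {
  withr::local_seed(53)
  N <- 500
  rs <- setNames(sort(rnorm(N), decreasing = TRUE), sprintf("g%03d", 1:N))
  ranked <- ranked_gene_list(rs)

  planted <- ranked$gene_id[1:20]
  a <- gsea_permutation_p(ranked, planted, n_perm = 500, seed = 99)
  b <- gsea_permutation_p(ranked, planted, n_perm = 500, seed = 99)
  expect_identical(a, b)
  expect_gt(a$es, 0)
  # saturation: p at the attainable minimum ~ 1/(n_sign+1)
  expect_lte(a$p, 3 / 500)

  # uniform p under random sets: 200 replicates, KS at 0.01
  pvals <- vapply(1:200, function(i) {
    gsea_permutation_p(ranked, sample(ranked$gene_id, 25), n_perm = 200,
                       seed = NULL)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("lncres_score implements the signed piecewise formula", {
  expect_equal(lncres_score(0.0025, 0.7), 0.995)
  expect_equal(lncres_score(0, 0.3), 1)
  expect_equal(lncres_score(0, -0.3), -1)
  expect_equal(lncres_score(0.5, 0.9), 0)
  expect_equal(lncres_score(0.5, -0.9), 0)
  expect_equal(lncres_score(0.2, 0), 0)
  # antisymmetry and monotonicity over a p grid
  p <- seq(0.001, 1, length.out = 101)
  expect_equal(lncres_score(p, 1), -lncres_score(p, -1))
  expect_true(all(diff(abs(lncres_score(p[p <= 0.5], 1))) <= 0))
  expect_true(all(abs(lncres_score(p, 1)) <= 1))
})

test_that("call_significant applies strict two-part thresholds", {
  rec <- data.frame(
    lncRNA = "L", pathway = c("a", "b", "c", "d"),
    ES = 1, p_value = 0.001,
    FDR = c(0.049, 0.049, 0.05, 0.01),
    lncRES = c(0.995, 0.996, 0.999, -0.9951))
  out <- call_significant(rec)
  expect_identical(out$significant, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("lncres_scan recovers a planted pair and stays quiet on shuffled data", {
  sim <- simulate_cohort(sim_config(n_lncrnas = 40, n_genes = 300,
                                    n_pathways = 3, n_related = 2,
                                    n_confounded = 5),
                         seed = 101)
  lnc <- sim$truth$related_lncrnas
  scan <- lncres_scan(sim$expr, sim$purity, lnc, sim$gene_sets,
                      n_perm = 1000, seed = 7)
  planted <- paste(sim$truth$planted_pairs$lncRNA,
                   sim$truth$planted_pairs$pathway)
  hit <- paste(scan$lncRNA, scan$pathway) %in% planted
  expect_true(all(scan$significant[hit]))
  expect_true(all(abs(scan$lncRES) <= 1))
  expect_true(all(scan$FDR >= scan$p_value))
  # |lncRES| = |1 - 2p| always; sign follows ES whenever p < 0.5
  expect_equal(abs(scan$lncRES), abs(1 - 2 * scan$p_value), tolerance = 1e-12)
  conf <- scan$ES != 0 & scan$p_value < 0.5
  expect_identical(sign(scan$lncRES[conf]), sign(scan$ES[conf]))
  # determinism of the full scan
  scan2 <- lncres_scan(sim$expr, sim$purity, lnc, sim$gene_sets,
                       n_perm = 1000, seed = 7)
  expect_identical(scan, scan2)

  # shuffling each candidate lncRNA's samples destroys the association
  shuf <- sim$expr
  withr::with_seed(5, for (id in lnc)
    shuf$values[id, ] <- sample(shuf$values[id, ]))
  scan0 <- lncres_scan(shuf, sim$purity, lnc, sim$gene_sets,
                       n_perm = 1000, seed = 7)
  expect_lte(sum(scan0$significant), 1)
})
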