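# Synthetic cohort generator with planted, recoverable structure. Expression
# is a Gaussian latent-factor model: every feature is a unit-variance linear
# combination of independent standard-normal factors plus residual noise, so
# population correlations equal dot products of loading vectors and all
# downstream statistics have exact oracles.
#
# Planted structure:
#   * a shared "immune activity" factor F on which the ICP genes and the
#     related lncRNAs load sqrt(rho_signal), giving pairwise correlation
#     rho_signal between every related lncRNA and every ICP gene;
#   * per related lncRNA k one or more private sub-factors (loading
#     sqrt((1-rho_signal)/core_blocks) each) and a pathway whose leading-edge
#     genes load sqrt(rho_pathway) on one of the sub-factors — correlated
#     with lncRNA k (purity-adjusted) but with no other lncRNA;
#   * purity-confounded (lncRNA, gene) pairs whose members both load
#     sqrt(confound_strength) on the standardized purity covariate: raw
#     Pearson r ~ confound_strength but partial correlation ~ 0.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a cohort at the scale the method targets: 120 tumor
#' samples, 500 protein-coding genes, 300 lncRNAs, 10 ICP genes, 5 immune
#' pathways of 40 genes.
#'
#' @param n_samples,n_genes,n_lncrnas,n_icp cohort dimensions.
#' @param n_pathways,pathway_size immune pathway count and size.
#' @param n_related number of planted ICP-related lncRNAs (one planted
#'   pathway each; must be <= n_pathways and <= n_lncrnas).
#' @param rho_signal population correlation between each related lncRNA and
#'   each ICP gene (default 0.7).
#' @param rho_pathway squared loading of planted pathway core genes on their
#'   lncRNA's private factor (default 0.8, giving a population correlation of
#'   about 0.49 between each core gene and its lncRNA).
#' @param pathway_core_size number of member genes per planted pathway that
#'   carry the enrichment signal (the leading edge, default 40\% of the set,
#'   i.e. 16 of the default 40); the
#'   remaining members are mutually independent noise so that unrelated
#'   lncRNAs see an essentially uncorrelated gene set and the permutation
#'   null stays honest.
#' @param core_blocks number of independent co-regulation blocks the leading
#'   edge is split into (default 1, a single co-regulated leading edge). Each
#'   block has its own latent sub-factor shared with the lncRNA.
#' @param confound_strength raw correlation induced between the members of a
#'   purity-confounded pair (default 0.6); both members load
#'   \code{sqrt(confound_strength)} on the purity covariate.
#' @param n_confounded number of purity-confounded (lncRNA, gene) pairs.
#' @param noise_sd multiplier on the residual standard deviation (default 1
#'   keeps features at unit variance; larger values dilute all correlations).
#' @param missing_fraction fraction of expression cells set to NA (default 0).
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 120, n_genes = 500, n_lncrnas = 300,
                       n_icp = 10, n_pathways = 5, pathway_size = 40,
                       n_related = 5, rho_signal = 0.7, rho_pathway = 0.8,
                       pathway_core_size = NULL, core_blocks = 1,
                       confound_strength = 0.6,
                       n_confounded = 20, noise_sd = 1,
                       missing_fraction = 0) {
  cfg <- as.list(environment())
  if (is.null(cfg$pathway_core_size))
    cfg$pathway_core_size <- max(1, ceiling(0.4 * cfg$pathway_size))
  .assert(cfg$pathway_size <= cfg$n_genes,
          "pathway_size exceeds n_genes", class = "icplnc_config_error")
  .assert(cfg$n_related <= cfg$n_pathways && cfg$n_related <= cfg$n_lncrnas,
          "n_related must be <= n_pathways and <= n_lncrnas",
          class = "icplnc_config_error")
  .assert(cfg$n_icp <= cfg$n_genes, "n_icp exceeds n_genes",
          class = "icplnc_config_error")
  .assert(cfg$pathway_core_size >= 1 &&
            cfg$pathway_core_size <= cfg$pathway_size,
          "pathway_core_size must lie in [1, pathway_size]",
          class = "icplnc_config_error")
  .assert(cfg$core_blocks >= 1 && cfg$core_blocks <= cfg$pathway_core_size,
          "core_blocks must lie in [1, pathway_core_size]",
          class = "icplnc_config_error")
  .assert(cfg$n_pathways * cfg$pathway_size + cfg$n_icp <= cfg$n_genes,
          "pathways + ICP genes exceed the gene pool",
          class = "icplnc_config_error")
  .assert(cfg$rho_signal > 0 && cfg$rho_signal < 1 &&
            cfg$rho_pathway > 0 && cfg$rho_pathway < 1 &&
            cfg$confound_strength >= 0 && cfg$confound_strength < 1,
          "correlation parameters must lie in (0,1)",
          class = "icplnc_config_error")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Emits all pipeline inputs in their standard containers: expression matrix,
#' purity vector (Beta(5,2), clipped to \[0,1\]), candidate interaction edge
#' list (all lncRNA x ICP pairs, the ICP-ICP PPI clique, and the confounded
#' lncRNA-gene pairs), immune gene sets, and the planted truth.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the same seed gives byte-identical output.
#' @return list with \code{expr} ([expression_matrix()]), \code{purity}
#'   (named numeric), \code{edges} (data.frame node_a/node_b/weight),
#'   \code{gene_sets} (named list), \code{truth} (list: \code{icp_genes},
#'   \code{related_lncrnas}, \code{planted_pairs} data.frame,
#'   \code{confounded_pairs} data.frame, \code{config}, \code{seed}).
#' @export
simulate_cohort <- function(config = sim_config(), seed) {
  .assert(inherits(config, "sim_config"), "config must come from sim_config()")
  .assert(!missing(seed) && is.numeric(seed), "an integer seed is required",
          class = "icplnc_config_error")
  .with_seed(as.integer(seed), {
    cfg <- config
    m <- cfg$n_samples
    sample_ids <- sprintf("S%03d", seq_len(m))
    gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
    icp_ids <- sprintf("ICP%02d", seq_len(cfg$n_icp))
    # ICP genes replace the first n_icp generic gene ids
    gene_ids[seq_len(cfg$n_icp)] <- icp_ids
    lnc_ids <- sprintf("LNC%04d", seq_len(cfg$n_lncrnas))

    purity <- pmin(1, pmax(0, stats::rbeta(m, 5, 2)))
    z_pur <- as.numeric(scale(purity))

    f_imm <- stats::rnorm(m)
    B <- cfg$core_blocks
    H <- matrix(stats::rnorm(m * B * cfg$n_related), m, B * cfg$n_related)

    related <- lnc_ids[seq_len(cfg$n_related)]
    pathway_ids <- sprintf("PATHWAY%02d", seq_len(cfg$n_pathways))
    # pathway member genes drawn after the ICP block, disjoint across pathways
    pool <- gene_ids[(cfg$n_icp + 1):cfg$n_genes]
    gene_sets <- list()
    for (i in seq_len(cfg$n_pathways)) {
      gene_sets[[pathway_ids[i]]] <-
        pool[((i - 1) * cfg$pathway_size + 1):(i * cfg$pathway_size)]
    }
    attr(gene_sets, "descriptions") <-
      stats::setNames(rep("synthetic immune pathway", cfg$n_pathways),
                      pathway_ids)
    planted <- data.frame(lncRNA = related,
                          pathway = pathway_ids[seq_len(cfg$n_related)],
                          stringsAsFactors = FALSE)

    # confounded pairs drawn from unplanted lncRNAs and free genes
    free_lnc <- setdiff(lnc_ids, related)
    free_gene <- setdiff(pool, unlist(gene_sets))
    n_conf <- min(cfg$n_confounded, length(free_lnc), length(free_gene))
    confounded <- data.frame(
      lncRNA = sample(free_lnc, n_conf),
      gene = sample(free_gene, n_conf),
      stringsAsFactors = FALSE)

    n_feat <- cfg$n_genes + cfg$n_lncrnas
    feat_ids <- c(gene_ids, lnc_ids)
    # loadings: columns = factors (F, H_11..H_1B, ..., H_K1..H_KB, purity)
    n_fac <- 2 + B * cfg$n_related
    L <- matrix(0, n_feat, n_fac, dimnames = list(feat_ids, NULL))
    a <- sqrt(cfg$rho_signal)
    L[icp_ids, 1] <- a
    L[related, 1] <- a
    for (k in seq_len(cfg$n_related)) {
      hcols <- 1 + ((k - 1) * B + 1):(k * B)
      L[related[k], hcols] <- sqrt((1 - cfg$rho_signal) / B)
      core <- gene_sets[[planted$pathway[k]]][seq_len(cfg$pathway_core_size)]
      block <- rep(seq_len(B), length.out = length(core))
      for (b in seq_len(B))
        L[core[block == b], hcols[b]] <- sqrt(cfg$rho_pathway)
    }
    cs <- sqrt(cfg$confound_strength)
    L[confounded$lncRNA, n_fac] <- cs
    L[confounded$gene, n_fac] <- cs

    Fmat <- cbind(f_imm, H, z_pur)             # m x (2 + n_related)
    s2 <- rowSums(L^2)
    .assert(all(s2 <= 1 + 1e-12), "internal: loadings exceed unit variance")
    resid_sd <- cfg$noise_sd * sqrt(pmax(1 - s2, 0))
    X <- L %*% t(Fmat) +
      matrix(stats::rnorm(n_feat * m), n_feat, m) * resid_sd
    colnames(X) <- sample_ids

    if (cfg$missing_fraction > 0) {
      n_na <- round(cfg$missing_fraction * length(X))
      X[sample.int(length(X), n_na)] <- NA_real_
    }

    classes <- stats::setNames(
      c(rep("gene", cfg$n_genes), rep("lncRNA", cfg$n_lncrnas)), feat_ids)
    expr <- expression_matrix(X, classes)

    icp_pairs <- expand.grid(node_a = lnc_ids, node_b = icp_ids,
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ppi <- t(utils::combn(icp_ids, 2))
    edges <- rbind(icp_pairs,
                   data.frame(node_a = ppi[, 1], node_b = ppi[, 2],
                              stringsAsFactors = FALSE),
                   data.frame(node_a = confounded$lncRNA,
                              node_b = confounded$gene,
                              stringsAsFactors = FALSE))
    edges$weight <- NA_real_
    edges <- edges[!duplicated(paste(edges$node_a, edges$node_b)), ]
    rownames(edges) <- NULL

    list(expr = expr,
         purity = stats::setNames(purity, sample_ids),
         edges = edges,
         gene_sets = gene_sets,
         truth = list(icp_genes = icp_ids, related_lncrnas = related,
                      planted_pairs = planted, confounded_pairs = confounded,
                      config = unclass(cfg), seed = as.integer(seed)))
  })
}

#' Score pipeline output against the planted truth
#'
#' @param truth the \code{truth} element of [simulate_cohort()] output.
#' @param top_lncrnas character vector from [top_k_lncrnas()] (may be NULL to
#'   skip that block).
#' @param lncres_records data.frame from [lncres_scan()] (may be NULL).
#' @return data.frame of metrics (one row per metric: \code{metric},
#'   \code{value}); precision is NA (flagged undefined) when nothing was
#'   called.
#' @export
recovery_report <- function(truth, top_lncrnas = NULL, lncres_records = NULL) {
  rows <- list()
  if (!is.null(top_lncrnas)) {
    .assert(is.character(top_lncrnas), "top_lncrnas must be character ids")
    tp <- sum(truth$related_lncrnas %in% top_lncrnas)
    rows$lnc <- data.frame(
      metric = c("top_k_recall", "top_k_precision"),
      value = c(tp / length(truth$related_lncrnas),
                if (length(top_lncrnas) > 0) tp / length(top_lncrnas)
                else NA_real_))
  }
  if (!is.null(lncres_records)) {
    lnc_universe <- sprintf("LNC%04d", seq_len(truth$config$n_lncrnas))
    .assert(all(lncres_records$lncRNA %in% lnc_universe),
            "lncRES records reference lncRNA ids absent from the synthetic cohort",
            class = "icplnc_config_error")
    sig <- lncres_records[lncres_records$significant, , drop = FALSE]
    key <- function(d) paste(d$lncRNA, d$pathway, sep = "\r")
    planted_keys <- paste(truth$planted_pairs$lncRNA,
                          truth$planted_pairs$pathway, sep = "\r")
    tp <- sum(planted_keys %in% key(sig))
    rows$pairs <- data.frame(
      metric = c("pair_recall", "pair_precision", "n_significant"),
      value = c(tp / length(planted_keys),
                if (nrow(sig) > 0) tp / nrow(sig) else NA_real_,
                nrow(sig)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
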