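# Stage 1-2: ICP-anchored Pearson screening and assembly of the weighted
# lncRNA-gene co-expression network.

#' Pearson correlation with a two-sided p-value
#'
#' Pairwise-complete Pearson coefficient; the p-value comes from
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom,
#' floored at 1e-300 so downstream log transforms stay finite.
#'
#' @param x,y numeric vectors of equal length; NAs removed pairwise.
#' @return list with \code{r}, \code{p}, \code{n_obs}.
#' @export
pearson_with_p <- function(x, y) {
  .assert(length(x) == length(y), "x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  .assert(n >= 3, "need >=3 jointly non-missing pairs (have ", n, ")",
          class = "icplnc_undefined_correlation")
  xs <- x[ok]; ys <- y[ok]
  .assert(stats::sd(xs) > 0 && stats::sd(ys) > 0,
          "zero variance: correlation undefined",
          class = "icplnc_undefined_correlation")
  r <- stats::cor(xs, ys)
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) .P_FLOOR else
    .t_pvalue(r * sqrt((n - 2) / (1 - r^2)), n - 2)
  list(r = r, p = p, n_obs = n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric vector of p-values in (0,1]; NAs propagate.
#' @return adjusted p-values, same order as input, capped at 1, monotone in the
#'   order statistics. Empty input gives empty output.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric(0))
  ok <- !is.na(p)
  .assert(all(p[ok] > 0 & p[ok] <= 1), "p-values must lie in (0,1]")
  out <- rep(NA_real_, length(p))
  pp <- p[ok]
  m <- length(pp)
  o <- order(pp, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * pp[o]))[order(o)]
  out[ok] <- adj
  out
}

# Correlations for a list of feature pairs of an ExpressionMatrix. Uses a
# single standardized matrix product when the data are complete; falls back to
# per-pair pairwise-complete computation otherwise.
.pair_correlations <- function(expr, a_ids, b_ids) {
  V <- expr$values
  n_pairs <- length(a_ids)
  r <- p <- rep(NA_real_, n_pairs); n_obs <- rep(NA_integer_, n_pairs)
  complete <- !anyNA(V[unique(c(a_ids, b_ids)), , drop = FALSE])
  if (complete) {
    n <- ncol(V)
    feats <- unique(c(a_ids, b_ids))
    Z <- V[feats, , drop = FALSE]
    mu <- rowMeans(Z)
    Z <- Z - mu
    ss <- sqrt(rowSums(Z^2))
    constant <- ss == 0
    Z <- Z / ifelse(ss == 0, 1, ss)
    ri <- rowSums(Z[a_ids, , drop = FALSE] * Z[b_ids, , drop = FALSE])
    ri[constant[a_ids] | constant[b_ids]] <- NA_real_
    r <- pmax(-1, pmin(1, ri))
    n_obs <- rep(n, n_pairs)
    p <- ifelse(abs(r) >= 1, .P_FLOOR,
                .t_pvalue(r * sqrt((n - 2) / (1 - r^2)), n - 2))
    p[is.na(r)] <- NA_real_
  } else {
    for (i in seq_len(n_pairs)) {
      res <- tryCatch(pearson_with_p(V[a_ids[i], ], V[b_ids[i], ]),
                      icplnc_undefined_correlation = function(e) NULL)
      if (!is.null(res)) {
        r[i] <- res$r; p[i] <- res$p; n_obs[i] <- res$n_obs
      }
    }
  }
  data.frame(feature_a = a_ids, feature_b = b_ids, r = r, p = p,
             n_obs = n_obs, stringsAsFactors = FALSE)
}

#' Build the ICP-anchored co-expression network
#'
#' Tests the candidate pairs named in the interaction list (lncRNA-gene pairs,
#' plus gene-gene pairs touching an ICP gene, e.g. PPI edges among ICP genes),
#' adjusts p-values by Benjamini-Hochberg over all tested pairs jointly, and
#' keeps edges with \code{p_adj < alpha} and \code{|r| >= min_abs_r}. Edge
#' weight is \code{|r|} (propagation needs non-negative weights); the signed
#' coefficient is kept in edge attributes \code{r} and \code{sign}.
#'
#' @param expr an [expression_matrix()].
#' @param icp_genes character vector of ICP gene ids (must intersect the
#'   gene features of \code{expr}).
#' @param interactions edge data.frame as returned by [read_edges()]; restricts
#'   which pairs are tested.
#' @param alpha adjusted-p threshold for keeping an edge (default 0.05).
#' @param min_abs_r optional absolute-correlation floor (default 0).
#' @param keep_icp_icp keep gene-gene edges between two ICP genes
#'   (default TRUE).
#' @return an \code{igraph} with vertex attributes \code{class}
#'   (\code{gene}/\code{lncRNA}) and \code{is_icp}, and edge attributes
#'   \code{weight}, \code{r}, \code{p}, \code{p_adj}, \code{sign}. The full
#'   tested-pair table is attached as graph attribute \code{correlations}.
#' @export
build_network <- function(expr, icp_genes, interactions, alpha = 0.05,
                          min_abs_r = 0, keep_icp_icp = TRUE) {
  genes <- em_genes(expr); lncs <- em_lncrnas(expr)
  icp_present <- intersect(icp_genes, genes)
  .assert(length(icp_present) > 0, "no ICP gene present in the expression matrix",
          class = "icplnc_config_error")
  if (nrow(interactions) == 0) {
    warning("empty interaction list: returning empty graph")
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(g)
  }
  a <- interactions$node_a; b <- interactions$node_b
  present <- a %in% em_features(expr) & b %in% em_features(expr)
  a <- a[present]; b <- b[present]
  cls <- expr$feature_class
  is_lnc_a <- cls[a] == "lncRNA"; is_lnc_b <- cls[b] == "lncRNA"
  lnc_gene <- xor(is_lnc_a, is_lnc_b)
  gene_gene <- !is_lnc_a & !is_lnc_b &
    (a %in% icp_present | b %in% icp_present)
  if (!keep_icp_icp)
    gene_gene <- gene_gene & !(a %in% icp_present & b %in% icp_present)
  keep <- lnc_gene | gene_gene
  a <- a[keep]; b <- b[keep]
  # canonical orientation + dedup so each pair is tested once
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  dup <- duplicated(paste(a, b, sep = "\r"))
  a <- a[!dup]; b <- b[!dup]
  if (length(a) == 0) {
    warning("no candidate pair is measurable in the expression matrix")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  tab <- .pair_correlations(expr, a, b)
  tab$p_adj <- bh_adjust(tab$p)
  keep_edge <- !is.na(tab$p_adj) & tab$p_adj < alpha & abs(tab$r) >= min_abs_r
  edges <- tab[keep_edge, , drop = FALSE]
  nodes <- unique(c(edges$feature_a, edges$feature_b))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$feature_a, to = edges$feature_b,
               weight = abs(edges$r), r = edges$r, p = edges$p,
               p_adj = edges$p_adj, sign = sign(edges$r)),
    directed = FALSE,
    vertices = data.frame(name = nodes,
                          class = unname(cls[nodes]),
                          is_icp = nodes %in% icp_present))
  igraph::graph_attr(g, "correlations") <- tab
  g
}
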