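# Stage 3: personalized PageRank over the weighted co-expression graph,
# seeded at the ICP genes; lncRNAs are then ranked by influence score.

#' Personalized PageRank by power iteration
#'
#' Random walk with restart on the row-normalized weighted transition matrix of
#' an undirected graph (each undirected edge contributes both directions). The
#' personalization vector is uniform over the seed nodes and zero elsewhere;
#' dangling nodes teleport their mass to the personalization vector. Iteration
#' stops when the L1 change drops below \code{tol}; if \code{max_iter} is
#' reached first, the last iterate is returned with \code{converged = FALSE}
#' and a warning.
#'
#' @param graph an undirected \code{igraph} with strictly positive edge
#'   weights (attribute \code{weight}; unweighted graphs get unit weights).
#' @param seeds character vector of seed node names; the intersection with the
#'   graph must be non-empty.
#' @param damping continuation probability (default 0.85).
#' @param max_iter maximum number of power iterations (default 100).
#' @param tol L1 convergence tolerance (default 1e-6).
#' @return list with \code{scores} (named, non-negative, sums to 1),
#'   \code{converged}, \code{iterations}.
#' @export
personalized_pagerank <- function(graph, seeds, damping = 0.85,
                                  max_iter = 100, tol = 1e-6) {
  n <- igraph::vcount(graph)
  .assert(n > 0, "graph is empty", class = "icplnc_config_error")
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  seed_idx <- which(nodes %in% seeds)
  .assert(length(seed_idx) > 0, "no seed node present in graph",
          class = "icplnc_config_error")
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(graph))
  .assert(all(w > 0), "edge weights must be strictly positive",
          class = "icplnc_contract_error")
  # symmetric weighted adjacency; both directions of each undirected edge
  A <- igraph::as_adjacency_matrix(graph, attr =
                                     if (igraph::ecount(graph) > 0 &&
                                         !is.null(igraph::E(graph)$weight))
                                       "weight" else NULL,
                                   sparse = TRUE)
  A <- methods::as(A, "CsparseMatrix")
  deg <- Matrix::rowSums(A)
  dangling <- deg == 0
  inv_deg <- ifelse(dangling, 0, 1 / deg)
  # column-stochastic operator: M = t(D^-1 A); x' = d(Mx + dangling mass * v) + (1-d)v
  M <- Matrix::t(A * inv_deg)
  v <- numeric(n); v[seed_idx] <- 1 / length(seed_idx)
  x <- v
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    x_new <- as.numeric(damping * (M %*% x + sum(x[dangling]) * v) +
                          (1 - damping) * v)
    delta <- sum(abs(x_new - x))
    x <- x_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("personalized PageRank did not converge in %d iterations (L1 change %.3g)",
                    max_iter, delta))
  x <- x / sum(x)  # guard against drift; mass is conserved analytically
  list(scores = stats::setNames(x, nodes), converged = converged,
       iterations = it)
}

#' Select the top-k lncRNAs by influence score
#'
#' Restricts the propagation scores to lncRNA nodes, sorts by score descending
#' with ties broken by lexicographic node id, and returns the first
#' \code{min(k, #lncRNAs)} ids. Nodes with zero influence score are excluded:
#' a node unreachable from every seed (e.g. in a graph component disconnected
#' from the ICP genes) receives no propagation mass and cannot meaningfully be
#' called ICP-related, however short the candidate list is.
#'
#' @param result output of [personalized_pagerank()].
#' @param graph the graph the scores were computed on (provides the
#'   \code{class} vertex attribute).
#' @param k number of lncRNAs to keep (default 200).
#' @return character vector of lncRNA ids, best first.
#' @export
top_k_lncrnas <- function(result, graph, k = 200) {
  .assert(k >= 1, "k must be >= 1", class = "icplnc_config_error")
  cls <- igraph::V(graph)$class
  nodes <- igraph::V(graph)$name
  lnc <- nodes[!is.null(cls) & cls == "lncRNA"]
  if (length(lnc) == 0) {
    warning("graph has no lncRNA nodes")
    return(character(0))
  }
  s <- result$scores[lnc]
  reached <- s > 0
  if (!all(reached)) {
    .msg(sum(!reached), " lncRNA(s) unreachable from the seeds excluded")
    lnc <- lnc[reached]; s <- s[reached]
  }
  if (length(lnc) == 0) {
    warning("no lncRNA received propagation mass")
    return(character(0))
  }
  ord <- order(-s, lnc, method = "radix")
  lnc[ord][seq_len(min(k, length(lnc)))]
}
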