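# Stage 4: tumor-purity-adjusted partial correlation, rank scores, pre-ranked
# GSEA enrichment with a permutation null, and the signed lncRES score.

#' First-order partial correlation with tumor purity as covariate
#'
#' \deqn{PCC = (R_{LG} - R_{LP} R_{GP}) / (\sqrt{1-R_{LP}^2}\sqrt{1-R_{GP}^2})}
#' where \eqn{R_{LG}}, \eqn{R_{LP}}, \eqn{R_{GP}} are the pairwise Pearson
#' coefficients of lncRNA expression, gene expression and purity. The p-value
#' is two-sided from \eqn{t = PCC\sqrt{(n-3)/(1-PCC^2)}} on \eqn{n-3} degrees
#' of freedom.
#'
#' @param l,g,purity numeric vectors of equal length (lncRNA expression, gene
#'   expression, purity); rows with any missing value are dropped.
#' @return list with \code{pcc}, \code{p}, \code{n_obs}.
#' @export
partial_correlation <- function(l, g, purity) {
  .assert(length(l) == length(g) && length(l) == length(purity),
          "l, g, purity must have equal length")
  ok <- is.finite(l) & is.finite(g) & is.finite(purity)
  n <- sum(ok)
  .assert(n >= 4, "need >=4 jointly non-missing triples (have ", n, ")",
          class = "icplnc_insufficient_data")
  l <- l[ok]; g <- g[ok]; p <- purity[ok]
  .assert(stats::sd(l) > 0 && stats::sd(g) > 0 && stats::sd(p) > 0,
          "zero variance: partial correlation undefined",
          class = "icplnc_undefined_correlation")
  r_lg <- stats::cor(l, g); r_lp <- stats::cor(l, p); r_gp <- stats::cor(g, p)
  .assert(abs(r_lp) < 1 - 1e-12 && abs(r_gp) < 1 - 1e-12,
          "purity is collinear with an expression vector (|R| = 1)",
          class = "icplnc_degenerate_covariate")
  pcc <- (r_lg - r_lp * r_gp) / (sqrt(1 - r_lp^2) * sqrt(1 - r_gp^2))
  pcc <- max(-1, min(1, pcc))
  pv <- if (abs(pcc) >= 1) .P_FLOOR else
    .t_pvalue(pcc * sqrt((n - 3) / (1 - pcc^2)), n - 3)
  list(pcc = pcc, p = pv, n_obs = n)
}

#' Rank score for a lncRNA-gene pair
#'
#' \code{RS = -log10(p) * sign(PCC)}; p is floored at 1e-300 before the log
#' and \code{sign(0)} is treated as 0.
#'
#' @param p p-value(s) in (0,1].
#' @param pcc partial correlation coefficient(s).
#' @return numeric rank score(s).
#' @export
rank_score <- function(p, pcc) {
  .assert(all(p > 0 & p <= 1), "p must lie in (0,1]")
  -log10(pmax(p, .P_FLOOR)) * sign(pcc)
}

#' Build a ranked gene list from rank scores
#'
#' @param rs named numeric vector of RS scores (names = gene ids, unique).
#' @return data.frame with columns \code{gene_id}, \code{rs}, sorted RS
#'   descending with ties broken by gene id ascending.
#' @export
ranked_gene_list <- function(rs) {
  .assert(!is.null(names(rs)) && !anyDuplicated(names(rs)),
          "rs must be named with unique gene ids")
  ord <- order(-rs, names(rs), method = "radix")
  data.frame(gene_id = names(rs)[ord], rs = unname(rs)[ord],
             stringsAsFactors = FALSE)
}

# ES from sorted hit positions in a ranked list of length N.
# w: |RS|^exponent over the full list (in rank order). Hits step the running
# sum up by w[pos]/sum(w[pos]); misses step it down by 1/(N - k). ES is the
# extreme deviation of the running sum, signed; positive wins ties.
.es_from_positions <- function(pos, w, N) {
  k <- length(pos)
  pos <- sort(pos)
  wh <- w[pos]
  W <- sum(wh)
  if (W <= 0) wh[] <- 1 / k else wh <- wh / W
  phit <- cumsum(wh)
  pmiss_at <- (pos - seq_len(k)) / (N - k)   # misses seen before each hit
  up <- phit - pmiss_at                      # running sum just after each hit
  dn <- c(0, phit[-k]) - pmiss_at            # just before each hit
  max_up <- max(up); min_dn <- min(dn, 0)
  if (max_up >= -min_dn) max_up else min_dn
}

#' Pre-ranked GSEA enrichment score
#'
#' Classic running-sum statistic: walking down the ranked list, members of the
#' gene set increment the sum by \code{|RS|^exponent} (normalized over the hit
#' weights) and non-members decrement it by \code{1/(N - |hits|)}; ES is the
#' maximum signed deviation from zero, in \[-1, 1\].
#'
#' @param ranked a [ranked_gene_list()] data.frame.
#' @param gene_set character vector of gene ids; must intersect the ranked
#'   universe and must not equal it.
#' @param exponent weighting exponent on \code{|RS|} (default 1; 0 gives the
#'   unweighted Kolmogorov-Smirnov form).
#' @return the enrichment score (scalar).
#' @export
gsea_es <- function(ranked, gene_set, exponent = 1) {
  genes <- ranked$gene_id
  N <- length(genes)
  pos <- which(genes %in% gene_set)
  .assert(length(pos) > 0, "gene set does not overlap the ranked universe",
          class = "icplnc_no_overlap")
  .assert(length(pos) < N, "gene set equals the ranked universe",
          class = "icplnc_degenerate_set")
  w <- abs(ranked$rs)^exponent
  .es_from_positions(pos, w, N)
}

#' Permutation p-value for a GSEA enrichment score
#'
#' The null distribution comes from \code{n_perm} random gene sets of the same
#' effective size drawn without replacement from the ranked universe
#' (gene-label permutation). The p-value is one-tailed on the observed sign
#' with a +1 pseudocount:
#' \code{p = (1 + #\{null: same sign & |ES_null| >= |ES|\}) /
#'           (1 + #\{null: same sign\})},
#' so p is always in (0, 1] and reproducible given \code{seed}.
#'
#' @inheritParams gsea_es
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed, or NULL to draw from the current RNG stream.
#' @return list with \code{es}, \code{p}, \code{n_hits}, \code{n_perm}.
#' @export
gsea_permutation_p <- function(ranked, gene_set, n_perm = 1000, seed = NULL,
                               exponent = 1) {
  .assert(n_perm >= 100, "n_perm must be >= 100", class = "icplnc_config_error")
  es <- gsea_es(ranked, gene_set, exponent)
  N <- nrow(ranked)
  k <- sum(ranked$gene_id %in% gene_set)
  w <- abs(ranked$rs)^exponent
  null_es <- .with_seed(seed, vapply(
    seq_len(n_perm),
    function(i) .es_from_positions(sample.int(N, k), w, N),
    numeric(1)))
  if (es == 0) return(list(es = 0, p = 1, n_hits = k, n_perm = n_perm))
  same_sign <- sign(null_es) == sign(es)
  p <- (1 + sum(same_sign & abs(null_es) >= abs(es))) / (1 + sum(same_sign))
  list(es = es, p = p, n_hits = k, n_perm = n_perm)
}

#' lncRES score
#'
#' Combines the permutation p-value with the sign of the enrichment score:
#' \code{1 - 2p} when \code{ES > 0}, \code{2p - 1} when \code{ES < 0}, and 0
#' for the degenerate \code{ES = 0}. Values range over \[-1, 1\].
#'
#' @param p p-value(s) in \[0,1\].
#' @param es enrichment score(s); only the sign is used.
#' @return lncRES score(s).
#' @export
lncres_score <- function(p, es) {
  .assert(all(p >= 0 & p <= 1), "p must lie in [0,1]")
  ifelse(es > 0, 1 - 2 * p, ifelse(es < 0, 2 * p - 1, 0))
}

#' Apply the two-part significance filter
#'
#' A (lncRNA, pathway) record is significant iff \code{|lncRES| > lncres_thr}
#' AND \code{FDR < fdr_cut}, both strict.
#'
#' @param records data.frame with columns \code{lncRES} and \code{FDR}.
#' @param lncres_thr absolute lncRES threshold (default 0.995).
#' @param fdr_cut FDR threshold (default 0.05).
#' @return \code{records} with the \code{significant} column (re)set.
#' @export
call_significant <- function(records, lncres_thr = 0.995, fdr_cut = 0.05) {
  records$significant <- abs(records$lncRES) > lncres_thr &
    records$FDR < fdr_cut
  records
}

# Purity-adjusted PCC/p/RS of one lncRNA against every feature in `universe`,
# vectorized for the complete-data case.
.rs_profile <- function(expr, purity, lnc_id, universe) {
  V <- expr$values
  l <- V[lnc_id, ]
  pur <- purity[colnames(V)]
  G <- V[universe, , drop = FALSE]
  if (!anyNA(l) && !anyNA(pur) && !anyNA(G)) {
    n <- length(l)
    .assert(n >= 4, "need >=4 samples", class = "icplnc_insufficient_data")
    zl <- as.numeric(scale(l)); zp <- as.numeric(scale(pur))
    Zg <- t(scale(t(G)))
    r_lg <- as.numeric(Zg %*% zl) / (n - 1)
    r_lp <- sum(zl * zp) / (n - 1)
    r_gp <- as.numeric(Zg %*% zp) / (n - 1)
    .assert(abs(r_lp) < 1, "purity collinear with lncRNA expression",
            class = "icplnc_degenerate_covariate")
    pcc <- (r_lg - r_lp * r_gp) / (sqrt(1 - r_lp^2) * sqrt(pmax(1 - r_gp^2, 0)))
    pcc <- pmax(-1, pmin(1, pcc))
    p <- ifelse(abs(pcc) >= 1, .P_FLOOR,
                .t_pvalue(pcc * sqrt((n - 3) / (1 - pcc^2)), n - 3))
  } else {
    res <- lapply(universe, function(gid)
      partial_correlation(l, V[gid, ], pur))
    pcc <- vapply(res, `[[`, numeric(1), "pcc")
    p <- vapply(res, `[[`, numeric(1), "p")
  }
  data.frame(gene_id = universe, pcc = pcc, p = p, stringsAsFactors = FALSE)
}

#' Score candidate lncRNAs against immune pathways (lncRES scan)
#'
#' For each candidate lncRNA: compute the purity-adjusted partial correlation
#' and p-value against every feature of the ranking universe, convert to rank
#' scores, run pre-ranked GSEA with a gene-label permutation null against each
#' pathway, then adjust all permutation p-values jointly (Benjamini-Hochberg
#' over the full lncRNA x pathway grid) and call significance on
#' \code{|lncRES|} and FDR.
#'
#' @param expr an [expression_matrix()].
#' @param purity named numeric purity vector covering the samples of
#'   \code{expr}.
#' @param lnc_ids character vector of candidate lncRNA ids (typically the
#'   top-k from [top_k_lncrnas()]).
#' @param gene_sets named list of character vectors ([read_gmt()]).
#' @param n_perm permutations per (lncRNA, pathway) pair (default 1000).
#' @param seed integer seed driving all permutations.
#' @param rank_universe \code{"genes"} (default) ranks protein-coding genes
#'   only; \code{"all"} also ranks the other lncRNAs.
#' @param lncres_thr,fdr_cut significance thresholds (defaults 0.995, 0.05).
#' @param exponent GSEA weighting exponent (default 1).
#' @return data.frame with one row per (lncRNA, pathway):
#'   \code{lncRNA, pathway, ES, p_value, FDR, lncRES, significant}.
#' @export
lncres_scan <- function(expr, purity, lnc_ids, gene_sets, n_perm = 1000,
                        seed = 17, rank_universe = c("genes", "all"),
                        lncres_thr = 0.995, fdr_cut = 0.05, exponent = 1) {
  rank_universe <- match.arg(rank_universe)
  .assert(length(lnc_ids) > 0, "no candidate lncRNAs supplied",
          class = "icplnc_config_error")
  .assert(all(lnc_ids %in% em_lncrnas(expr)),
          "candidate ids missing from expression matrix: ",
          paste(utils::head(setdiff(lnc_ids, em_lncrnas(expr)), 5),
                collapse = ", "),
          class = "icplnc_config_error")
  .assert(length(gene_sets) > 0, "no gene sets supplied",
          class = "icplnc_config_error")
  missing_pur <- setdiff(em_samples(expr), names(purity))
  .assert(length(missing_pur) == 0, "purity missing for sample(s): ",
          paste(utils::head(missing_pur, 5), collapse = ", "),
          class = "icplnc_config_error")
  .with_seed(seed, {
    rows <- vector("list", length(lnc_ids) * length(gene_sets))
    idx <- 0L
    for (lnc in lnc_ids) {
      universe <- if (rank_universe == "genes") em_genes(expr) else
        setdiff(em_features(expr), lnc)
      prof <- .rs_profile(expr, purity, lnc, universe)
      rs <- stats::setNames(rank_score(prof$p, prof$pcc), prof$gene_id)
      ranked <- ranked_gene_list(rs)
      for (ps in names(gene_sets)) {
        idx <- idx + 1L
        res <- tryCatch(
          gsea_permutation_p(ranked, gene_sets[[ps]], n_perm = n_perm,
                             seed = NULL, exponent = exponent),
          icplnc_no_overlap = function(e) NULL)
        if (is.null(res)) next
        rows[[idx]] <- data.frame(lncRNA = lnc, pathway = ps, ES = res$es,
                                  p_value = res$p, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    .assert(!is.null(out) && nrow(out) > 0,
            "no (lncRNA, pathway) pair could be scored",
            class = "icplnc_config_error")
    out$FDR <- bh_adjust(out$p_value)
    out$lncRES <- lncres_score(out$p_value, out$ES)
    rownames(out) <- NULL
    call_significant(out, lncres_thr = lncres_thr, fdr_cut = fdr_cut)
  })
}
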