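# Consumers of the lncRES output: Spearman association with immune scores,
# linear risk scoring with a median split, RECIST response labeling, and a
# first-principles log-rank test for exercising the split end-to-end.

#' Spearman association of lncRNAs with per-sample immune scores
#'
#' Spearman rho (average ranks for ties) and a two-sided p-value from the
#' t approximation for every (lncRNA, score) pair over their shared samples,
#' with a Benjamini-Hochberg column appended. Undefined pairs (constant
#' vector, too few samples) are recorded with NA statistics, not dropped.
#'
#' @param expr an [expression_matrix()].
#' @param scores data.frame or matrix of per-sample scores: rownames = sample
#'   ids, one column per score (e.g. infiltration fraction per cell type).
#' @param lnc_ids lncRNA ids to test (default: all lncRNAs in \code{expr}).
#' @return data.frame with columns \code{lncRNA}, \code{score}, \code{rho},
#'   \code{p}, \code{p_adj}, \code{n_obs}.
#' @export
spearman_association <- function(expr, scores, lnc_ids = em_lncrnas(expr)) {
  scores <- as.matrix(scores)
  .assert(!is.null(rownames(scores)), "scores must have sample rownames")
  shared <- intersect(em_samples(expr), rownames(scores))
  .assert(length(shared) >= 4, "need >=4 shared samples",
          class = "icplnc_insufficient_data")
  .assert(all(lnc_ids %in% em_features(expr)), "unknown lncRNA id(s)")
  grid <- expand.grid(lncRNA = lnc_ids, score = colnames(scores),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- expr$values[grid$lncRNA[i], shared]
    y <- scores[shared, grid$score[i]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 4) return(c(NA_real_, NA_real_, n))
    rx <- rank(x[ok]); ry <- rank(y[ok])
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
      return(c(NA_real_, NA_real_, n))
    rho <- stats::cor(rx, ry)
    rho <- max(-1, min(1, rho))
    p <- if (abs(rho) >= 1) .P_FLOOR else
      .t_pvalue(rho * sqrt((n - 2) / (1 - rho^2)), n - 2)
    c(rho, p, n)
  })
  res <- do.call(rbind, res)
  out <- data.frame(grid, rho = res[, 1], p = res[, 2],
                    p_adj = bh_adjust(res[, 2]), n_obs = as.integer(res[, 3]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Linear risk score and median split
#'
#' \code{RiskScore = sum_j beta_j * exp_j} per sample, plus the
#' high/low-risk labels from the median split used for Kaplan-Meier grouping.
#'
#' @param expr an [expression_matrix()].
#' @param model data.frame with columns \code{lncRNA} and \code{beta}
#'   (unique ids; e.g. LASSO coefficients supplied by the caller).
#' @return list with \code{score} (named numeric per sample) and \code{group}
#'   (named factor \code{high}/\code{low}; scores above the median are
#'   \code{high}).
#' @export
risk_score <- function(expr, model) {
  .assert(is.data.frame(model) && nrow(model) > 0 &&
            all(c("lncRNA", "beta") %in% names(model)),
          "model must be a non-empty data.frame with columns lncRNA, beta",
          class = "icplnc_config_error")
  .assert(!anyDuplicated(model$lncRNA), "duplicate lncRNA ids in model",
          class = "icplnc_config_error")
  absent <- setdiff(model$lncRNA, em_features(expr))
  .assert(length(absent) == 0, "model lncRNA(s) missing from expression: ",
          paste(absent, collapse = ", "), class = "icplnc_config_error")
  E <- expr$values[model$lncRNA, , drop = FALSE]
  s <- as.numeric(crossprod(E, model$beta))
  names(s) <- em_samples(expr)
  med <- stats::median(s)
  .assert(any(s > med) && any(s <= med) && stats::sd(s) > 0,
          "degenerate risk model: all risk scores equal, median split impossible",
          class = "icplnc_config_error")
  list(score = s,
       group = factor(ifelse(s > med, "high", "low"), levels = c("low", "high")))
}

#' Map RECIST codes to responder labels
#'
#' CR and PR are responders; SD and PD are non-responders. Any other code is
#' an ingest error naming the offending sample.
#'
#' @param recist named character vector sample id -> code in
#'   \{CR, PR, SD, PD\}.
#' @return named character vector sample id -> \code{responder} /
#'   \code{non_responder}.
#' @export
label_response <- function(recist) {
  .assert(!is.null(names(recist)), "recist must be named by sample id")
  bad <- !recist %in% c("CR", "PR", "SD", "PD")
  .assert(!any(bad), "unknown RECIST code for sample(s): ",
          paste(names(recist)[bad], " (", recist[bad], ")",
                sep = "", collapse = ", "),
          class = "icplnc_ingest_error")
  stats::setNames(ifelse(recist %in% c("CR", "PR"), "responder",
                         "non_responder"), names(recist))
}

#' Log-rank test (first principles)
#'
#' Two-or-more-group log-rank chi-square computed from the standard
#' observed-minus-expected sums over event times, with the hypergeometric
#' variance. Provided so a median risk split can be evaluated on synthetic
#' survival data without further dependencies.
#'
#' @param time numeric follow-up times.
#' @param event 0/1 event indicator (1 = event).
#' @param group factor (or coercible) group membership.
#' @return list with \code{chisq}, \code{df}, \code{p}, and the per-group
#'   observed/expected table.
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  .assert(k >= 2, "need >=2 groups", class = "icplnc_config_error")
  .assert(length(time) == length(event) && length(time) == length(group),
          "time, event, group must have equal length")
  times <- sort(unique(time[event == 1]))
  O <- E <- stats::setNames(numeric(k), levels(group))
  Vm <- matrix(0, k, k)
  for (t in times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(event == 1 & time == t)
    if (n_t == 0 || d_t == 0) next
    n_j <- tabulate(group[at_risk], nbins = k)
    d_j <- tabulate(group[event == 1 & time == t], nbins = k)
    e_j <- d_t * n_j / n_t
    O <- O + d_j; E <- E + e_j
    if (n_t > 1) {
      c_t <- d_t * (n_t - d_t) / (n_t - 1) / n_t^2
      Vm <- Vm + c_t * (diag(n_j * n_t, nrow = k) - outer(n_j, n_j))
    }
  }
  z <- (O - E)[-1]
  V <- Vm[-1, -1, drop = FALSE]
  chisq <- tryCatch(as.numeric(t(z) %*% solve(V, z)),
                    error = function(e) NA_real_)
  df <- k - 1
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE),
       table = data.frame(group = levels(group), observed = as.numeric(O),
                          expected = as.numeric(E)))
}
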