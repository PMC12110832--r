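# End-to-end orchestration: coexpression -> propagation -> lncRES, with
# intermediate TSVs and an auditable run manifest.

#' Pipeline run configuration
#'
#' Input paths plus the published stage parameters. Defaults are the values
#' the framework was described with: damping 0.85, max_iter 100, tol 1e-6,
#' top_k 200, lncRES threshold 0.995, FDR cut 0.05.
#'
#' @param expr,classes,purity,icp,interactions,gmt input file paths
#'   (expression TSV, feature-class TSV, purity TSV, ICP gene list, candidate
#'   edge TSV, GMT gene sets).
#' @param out_dir output directory (created if needed).
#' @param alpha,min_abs_r co-expression edge thresholds.
#' @param damping,max_iter,tol propagation parameters.
#' @param top_k number of lncRNAs carried into the lncRES stage.
#' @param n_perm,seed permutation settings.
#' @param lncres_thr,fdr_cut significance thresholds.
#' @param rank_universe \code{"genes"} or \code{"all"} (see [lncres_scan()]).
#' @return list of class \code{run_config}.
#' @export
run_config <- function(expr, classes, purity, icp, interactions, gmt, out_dir,
                       alpha = 0.05, min_abs_r = 0, damping = 0.85,
                       max_iter = 100, tol = 1e-6, top_k = 200, n_perm = 1000,
                       seed = 17, lncres_thr = 0.995, fdr_cut = 0.05,
                       rank_universe = "genes") {
  cfg <- as.list(environment())
  .assert(cfg$top_k >= 1, "top_k must be >= 1", class = "icplnc_config_error")
  .assert(cfg$n_perm >= 100, "n_perm must be >= 100",
          class = "icplnc_config_error")
  .assert(cfg$damping >= 0 && cfg$damping < 1, "damping must lie in [0,1)",
          class = "icplnc_config_error")
  .assert(cfg$rank_universe %in% c("genes", "all"),
          "rank_universe must be 'genes' or 'all'",
          class = "icplnc_config_error")
  for (f in c("expr", "classes", "purity", "icp", "interactions", "gmt"))
    .assert(file.exists(cfg[[f]]), "input not readable: ", cfg[[f]],
            class = "icplnc_config_error")
  structure(cfg, class = "run_config")
}

#' Run the four-stage pipeline
#'
#' Executes co-expression network construction, personalized PageRank
#' propagation and the lncRES scan in order, writing intermediate TSVs
#' (\code{network_edges.tsv}, \code{network_nodes.tsv},
#' \code{ranked_lncrnas.tsv}), the final \code{lncres.tsv}, and a
#' \code{manifest.json} (config echo, input checksums, package version, seed,
#' wall time). The manifest is written even when a stage fails, with the error
#' recorded; the error is then re-raised naming the stage.
#'
#' @param config a [run_config()].
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(config) {
  .assert(inherits(config, "run_config"), "config must come from run_config()")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  manifest <- list(
    config = lapply(unclass(config), unname),
    inputs = as.list(tools::md5sum(unlist(config[c(
      "expr", "classes", "purity", "icp", "interactions", "gmt")]))),
    package_version = as.character(utils::packageVersion("icplnc")),
    seed = config$seed, started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    status = "running")
  write_manifest <- function() {
    manifest$wall_time_s <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  stage <- "ingest"
  res <- tryCatch({
    expr <- read_expression(config$expr, read_feature_classes(config$classes))
    purity <- read_purity(config$purity)
    icp <- read_gene_list(config$icp)
    interactions <- read_edges(config$interactions)
    gene_sets <- read_gmt(config$gmt)

    stage <- "coexpression"
    .msg("stage coexpression: ", nrow(interactions), " candidate pairs")
    g <- build_network(expr, icp, interactions, alpha = config$alpha,
                       min_abs_r = config$min_abs_r)
    edf <- igraph::as_data_frame(g, what = "edges")
    write_table(data.frame(node_a = edf$from, node_b = edf$to, r = edf$r,
                           p = edf$p, p_adj = edf$p_adj, weight = edf$weight),
                file.path(config$out_dir, "network_edges.tsv"))
    vdf <- igraph::as_data_frame(g, what = "vertices")
    write_table(data.frame(id = vdf$name, class = vdf$class,
                           is_icp = vdf$is_icp),
                file.path(config$out_dir, "network_nodes.tsv"))

    stage <- "propagation"
    pr <- personalized_pagerank(g, seeds = icp, damping = config$damping,
                                max_iter = config$max_iter, tol = config$tol)
    top <- top_k_lncrnas(pr, g, k = config$top_k)
    .msg("stage propagation: ", length(top), " lncRNAs selected (converged = ",
         pr$converged, ")")
    write_table(data.frame(rank = seq_along(top), lncRNA = top,
                           score = unname(pr$scores[top])),
                file.path(config$out_dir, "ranked_lncrnas.tsv"),
                sort_rows = FALSE)

    stage <- "lncres"
    lr <- lncres_scan(expr, purity, top, gene_sets, n_perm = config$n_perm,
                      seed = config$seed, rank_universe = config$rank_universe,
                      lncres_thr = config$lncres_thr,
                      fdr_cut = config$fdr_cut)
    .msg("stage lncres: ", sum(lr$significant), " significant pair(s) of ",
         nrow(lr))
    write_table(lr, file.path(config$out_dir, "lncres.tsv"))
    manifest$status <- "ok"
    manifest$n_significant <- sum(lr$significant)
    TRUE
  }, error = function(e) e)
  if (inherits(res, "error")) {
    manifest$status <- "error"
    manifest$error <- list(stage = stage, message = conditionMessage(res))
    write_manifest()
    .stop_icplnc("pipeline failed at stage '", stage, "': ",
                 conditionMessage(res), class = "icplnc_pipeline_error")
  }
  write_manifest()
  invisible(config$out_dir)
}
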