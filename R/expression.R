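#' Expression matrix with feature classes
#'
#' Lightweight container for a features-by-samples expression matrix together
#' with a classification of every feature as either a protein-coding
#' \code{"gene"} or a \code{"lncRNA"}. All correlation-based stages of the
#' pipeline operate on this object. Missing values (\code{NA}) are permitted
#' and handled pairwise downstream.
#'
#' @param values numeric matrix, features in rows (unique rownames), samples in
#'   columns (unique colnames).
#' @param feature_class named character vector mapping every feature id to
#'   \code{"gene"} or \code{"lncRNA"}.
#' @return An object of class \code{ExpressionMatrix}: a list with elements
#'   \code{values} and \code{feature_class}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("G1", "G2", "L1"), paste0("S", 1:4)))
#' em <- expression_matrix(m, c(G1 = "gene", G2 = "gene", L1 = "lncRNA"))
#' em_lncrnas(em)
#' @export
expression_matrix <- function(values, feature_class) {
  .assert(is.matrix(values) && is.numeric(values),
          "`values` must be a numeric matrix")
  fid <- rownames(values); sid <- colnames(values)
  .assert(!is.null(fid) && !is.null(sid),
          "`values` must have rownames (features) and colnames (samples)")
  .assert(!anyDuplicated(fid), "duplicate feature ids: ",
          paste(unique(fid[duplicated(fid)]), collapse = ", "),
          class = "icplnc_ingest_error")
  .assert(!anyDuplicated(sid), "duplicate sample ids: ",
          paste(unique(sid[duplicated(sid)]), collapse = ", "),
          class = "icplnc_ingest_error")
  .assert(is.character(feature_class) && !is.null(names(feature_class)),
          "`feature_class` must be a named character vector")
  missing_cls <- setdiff(fid, names(feature_class))
  .assert(length(missing_cls) == 0L,
          "feature_class does not cover: ",
          paste(utils::head(missing_cls, 5), collapse = ", "),
          class = "icplnc_ingest_error")
  feature_class <- feature_class[fid]
  bad <- !feature_class %in% c("gene", "lncRNA")
  .assert(!any(bad), "feature classes must be 'gene' or 'lncRNA'; offending: ",
          paste(utils::head(fid[bad], 5), collapse = ", "),
          class = "icplnc_ingest_error")
  structure(list(values = values, feature_class = feature_class),
            class = "ExpressionMatrix")
}

#' @exportS3Method base::print
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features (%d genes, %d lncRNAs) x %d samples\n",
              nrow(x$values), sum(x$feature_class == "gene"),
              sum(x$feature_class == "lncRNA"), ncol(x$values)))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x an \code{ExpressionMatrix}.
#' @export
em_features <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
em_samples <- function(x) colnames(x$values)

#' @rdname expression_matrix
#' @export
em_genes <- function(x) rownames(x$values)[x$feature_class == "gene"]

#' @rdname expression_matrix
#' @export
em_lncrnas <- function(x) rownames(x$values)[x$feature_class == "lncRNA"]

#' @rdname expression_matrix
#' @param feature a feature id present in the matrix.
#' @export
em_row <- function(x, feature) {
  .assert(feature %in% rownames(x$values), "unknown feature: ", feature)
  x$values[feature, ]
}
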