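# Readers/writers for the plain-text formats the pipeline touches. All tables
# are tab-delimited, UTF-8, LF, one header line. Validation happens on ingest;
# nothing is silently dropped except self-loop edges, which are counted.

#' Read a feature-class map
#'
#' Two-column TSV (feature id, class) with header, classes in
#' \{\code{gene}, \code{lncRNA}\}.
#'
#' @param path file path.
#' @return named character vector feature id -> class.
#' @export
read_feature_classes <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0))
  .assert(ncol(df) >= 2, "feature-class file needs 2 columns: ", path,
          class = "icplnc_ingest_error")
  .assert(!anyDuplicated(df[[1]]), "duplicate feature ids in class map: ",
          paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "),
          class = "icplnc_ingest_error")
  stats::setNames(df[[2]], df[[1]])
}

#' Read an expression matrix
#'
#' TSV/CSV with feature ids in the first column and sample ids in the header.
#' Cells must be numeric or the missing token (default \code{"NA"},
#' case-sensitive).
#'
#' @param path file path.
#' @param feature_class_map either a named character vector (feature -> class)
#'   or a path to a two-column class TSV (see [read_feature_classes()]).
#' @param missing_token string standing for a missing value.
#' @param sep field separator, default tab.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, feature_class_map, missing_token = "NA",
                            sep = "\t") {
  df <- utils::read.delim(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", na.strings = character(0))
  .assert(ncol(df) >= 2, "expression file has no sample columns: ", path,
          class = "icplnc_ingest_error")
  fid <- df[[1]]
  dup <- unique(fid[duplicated(fid)])
  .assert(length(dup) == 0, "duplicate feature id(s): ",
          paste(dup, collapse = ", "), class = "icplnc_ingest_error")
  cells <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(vals) & cells != missing_token, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    .stop_icplnc(sprintf(
      "non-numeric cell at feature '%s', sample '%s': '%s'",
      fid[bad[1, 1]], colnames(cells)[bad[1, 2]], cells[bad[1, , drop = FALSE]]),
      class = "icplnc_ingest_error")
  }
  vals[cells == missing_token] <- NA_real_
  dimnames(vals) <- list(fid, colnames(cells))
  if (is.character(feature_class_map) && length(feature_class_map) == 1 &&
      is.null(names(feature_class_map)) && file.exists(feature_class_map)) {
    feature_class_map <- read_feature_classes(feature_class_map)
  }
  expression_matrix(vals, feature_class_map)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: \code{name<TAB>description<TAB>member...} with at least one
#' member per set and unique set names.
#'
#' @param path file path.
#' @return named list of character vectors (gene ids); the per-set description
#'   is attached as attribute \code{"descriptions"}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    .assert(length(f) >= 3, sprintf("GMT line %d has <3 columns", i),
            class = "icplnc_ingest_error")
    nm <- f[[1]]
    .assert(!nm %in% names(sets), "duplicate gene-set name: ", nm,
            class = "icplnc_ingest_error")
    members <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    .assert(length(members) > 0, sprintf("GMT line %d has no members", i),
            class = "icplnc_ingest_error")
    sets[[nm]] <- members
    desc[[nm]] <- f[[2]]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Read a per-sample tumor purity table
#'
#' Two-column TSV (sample id, purity in \[0,1\]); missing purities allowed via
#' the missing token.
#'
#' @param path file path.
#' @param missing_token string standing for a missing value.
#' @return named numeric vector sample id -> purity.
#' @export
read_purity <- function(path, missing_token = "NA") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0))
  .assert(ncol(df) >= 2, "purity file needs 2 columns: ", path,
          class = "icplnc_ingest_error")
  .assert(!anyDuplicated(df[[1]]), "duplicate sample ids in purity table",
          class = "icplnc_ingest_error")
  p <- suppressWarnings(as.numeric(df[[2]]))
  bad_num <- is.na(p) & df[[2]] != missing_token
  .assert(!any(bad_num), "non-numeric purity for sample(s): ",
          paste(utils::head(df[[1]][bad_num], 5), collapse = ", "),
          class = "icplnc_ingest_error")
  out_of_range <- !is.na(p) & (p < 0 | p > 1)
  .assert(!any(out_of_range), "purity outside [0,1] for sample(s): ",
          paste(utils::head(df[[1]][out_of_range], 5), collapse = ", "),
          class = "icplnc_ingest_error")
  stats::setNames(p, df[[1]])
}

#' Read an interaction edge list
#'
#' Two- or three-column TSV (node_a, node_b, optional weight). Self-loops are
#' dropped with a message reporting the count; nothing else is filtered.
#'
#' @param path file path.
#' @return data.frame with columns \code{node_a}, \code{node_b}, \code{weight}
#'   (NA when absent).
#' @export
read_edges <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0))
  .assert(ncol(df) >= 2, "edge file needs >=2 columns: ", path,
          class = "icplnc_ingest_error")
  out <- data.frame(node_a = df[[1]], node_b = df[[2]],
                    weight = if (ncol(df) >= 3)
                      suppressWarnings(as.numeric(df[[3]])) else NA_real_,
                    stringsAsFactors = FALSE)
  .assert(all(nzchar(out$node_a)) && all(nzchar(out$node_b)),
          "empty node id in edge list", class = "icplnc_ingest_error")
  loops <- out$node_a == out$node_b
  if (any(loops)) {
    .msg(sum(loops), " self-loop(s) dropped from ", basename(path))
    out <- out[!loops, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read a gene list (one id per line)
#'
#' @param path file path; blank lines and lines starting with '#' are skipped.
#' @return character vector of unique ids, input order preserved.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Write a record table as deterministic TSV
#'
#' Header plus data rows, tab-delimited, LF endings. Rows are sorted on the
#' key columns (all character/factor columns, left to right) so outputs are
#' diffable; numeric cells use 15 significant digits so a write/read
#' round-trip is the identity to well below 1e-9.
#'
#' @param records data.frame.
#' @param path output path.
#' @param sort_rows sort rows on the character key columns (default TRUE).
#' @return invisibly, the path.
#' @export
write_table <- function(records, path, sort_rows = TRUE) {
  .assert(is.data.frame(records), "`records` must be a data.frame")
  df <- records
  if (sort_rows && nrow(df) > 1) {
    keys <- df[vapply(df, function(c) is.character(c) || is.factor(c),
                      logical(1))]
    if (length(keys) > 0) {
      ord <- do.call(order, c(unname(lapply(keys, as.character)),
                              list(method = "radix")))
      df <- df[ord, , drop = FALSE]
    }
  }
  fmt <- lapply(df, function(col) {
    if (is.numeric(col)) formatC(col, digits = 15, format = "g") else
      as.character(col)
  })
  out <- do.call(paste, c(fmt, sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(df), collapse = "\t"), out), con, sep = "\n")
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path file path.
#' @return data.frame with numeric columns restored (logical columns written as
#'   TRUE/FALSE are restored too).
#' @export
read_table_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}
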