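# File-format dialects: TSV abundance matrices (rows = peptide_id, columns
# = array/sample ids), CSV manifests, TSV peptide libraries, JSON panels and
# signatures with flat one-id-per-line companions.  Readers validate
# structure and report offending rows/columns by position.

#' Write / read an abundance matrix as TSV
#'
#' @param x Numeric matrix with peptide rownames and sample colnames.
#' @param path File path.
#' @param digits Significant digits for non-integer matrices.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns
#'   the matrix.
#' @export
write_matrix <- function(x, path, digits = 6) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  vals <- if (is.integer(x) || all(x == round(x))) {
    format(x, scientific = FALSE, trim = TRUE)
  } else {
    signif(x, digits)
  }
  df <- data.frame(peptide_id = rownames(x), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("peptide_id", colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2 || colnames(df)[1] != "peptide_id") {
    stop("malformed matrix header in ", path,
         ": first column must be 'peptide_id'")
  }
  if (anyDuplicated(df$peptide_id)) {
    stop("duplicated peptide_id in ", path, ": ",
         df$peptide_id[duplicated(df$peptide_id)][1])
  }
  if (anyDuplicated(colnames(df)[-1])) {
    stop("duplicated sample column in ", path, ": ",
         colnames(df)[-1][duplicated(colnames(df)[-1])][1])
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "numeric")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing or non-numeric cell in ", path, " at data row ", bad[1],
         " (peptide ", df$peptide_id[bad[1]], "), column '",
         colnames(m)[bad[2]], "'")
  }
  rownames(m) <- df$peptide_id
  m
}

#' Write / read a sample manifest as CSV
#'
#' @param manifest A [generate_design()]-shaped data frame.
#' @param path File path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` the
#'   manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("array_id", "subject_id", "group", "cohort", "partition",
            "replicate_index", "batch", "singleton_exempt")
  missing <- setdiff(need, names(df))
  if (base::length(missing) > 0) {
    stop("manifest ", path, " lacks columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$array_id)) {
    stop("duplicated array_id in ", path, ": ",
         df$array_id[duplicated(df$array_id)][1])
  }
  df$singleton_exempt <- as.logical(df$singleton_exempt)
  class(df) <- c("sample_manifest", "data.frame")
  df
}

#' Write / read a peptide library as TSV
#'
#' @param library A [generate_peptide_library()] data frame.
#' @param path File path.
#' @return `write_library` returns `path` invisibly; `read_library` the
#'   library data frame.
#' @export
write_library <- function(library, path) {
  utils::write.table(as.data.frame(library), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide_id", "sequence", "is_control")
  missing <- setdiff(need, names(df))
  if (base::length(missing) > 0) {
    stop("library ", path, " lacks columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sequence)) {
    stop("duplicated sequence in ", path, ": ",
         df$sequence[duplicated(df$sequence)][1])
  }
  df$is_control <- as.logical(df$is_control)
  class(df) <- c("peptide_library", "data.frame")
  df
}

#' Write / read a peptide panel, list or signature as JSON
#'
#' The JSON carries the name, defining parameters and ordered peptide ids;
#' a flat one-id-per-line text file is written alongside
#' (`<path>.ids.txt`).
#'
#' @param panel A `peptide_list`, `peptide_panel` or `candidate_signature`.
#' @param path JSON file path.
#' @return `write_panel` returns `path` invisibly; `read_panel` a plain
#'   list with the stored fields.
#' @export
write_panel <- function(panel, path) {
  obj <- unclass(panel)
  obj$class <- class(panel)[1]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(panel$peptide_ids, paste0(path, ".ids.txt"))
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$peptide_ids)) obj$peptide_ids <- character(0)
  obj$peptide_ids <- as.character(obj$peptide_ids)
  obj
}
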