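# File formats: survival tables and data matrices as TSV/CSV, result tables
# as TSV, run metadata as JSON. TSV is the lingua franca so outputs feed
# directly into external plotting tools.

#' Read a survival table
#'
#' Expects a header `time,event,<covariate columns...>` (comma- or
#' tab-separated, chosen by file extension). Every validation failure names
#' the offending row.
#'
#' @param path Path to a CSV/TSV file.
#' @return A [survival_dataset()].
#' @export
read_survival_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(d) < 3L || names(d)[1] != "time" || names(d)[2] != "event") {
    stop("header must be `time,event,<markers...>`")
  }
  for (j in seq_along(d)) {
    v <- suppressWarnings(as.numeric(d[[j]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric or missing value in column '%s' at row %d",
                   names(d)[j], bad[1]))
    }
    d[[j]] <- v
  }
  bad_t <- which(d$time <= 0)
  if (length(bad_t)) stop(sprintf("non-positive time at row %d", bad_t[1]))
  bad_e <- which(!d$event %in% c(0, 1))
  if (length(bad_e)) stop(sprintf("event not in {0,1} at row %d", bad_e[1]))
  X <- as.matrix(d[, -(1:2), drop = FALSE])
  survival_dataset(d$time, d$event, X)
}

#' Write a survival table
#'
#' @param dataset A [survival_dataset()].
#' @param path Output path (`.tsv` writes tab-separated, otherwise CSV).
#' @return `path`, invisibly.
#' @export
write_survival_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "survival_dataset"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  d <- data.frame(time = dataset$time, event = dataset$event,
                  dataset$covariates, check.names = FALSE)
  utils::write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a data matrix with row and column headers
#'
#' TSV with the first column holding row labels; column order is preserved
#' verbatim. Ragged rows or missing cells are errors naming the coordinates.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  d <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                      check.names = FALSE),
    error = function(e) stop(sprintf("malformed matrix file: %s",
                                     conditionMessage(e)))
  )
  M <- as.matrix(d)
  if (!is.numeric(M)) stop("matrix contains non-numeric cells")
  if (anyNA(M)) {
    idx <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop(sprintf("missing cell at row '%s', column '%s'",
                 rownames(M)[idx[1]], colnames(M)[idx[2]]))
  }
  M
}

#' Write a data matrix with row and column headers
#'
#' @param X Numeric matrix.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(X, path) {
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("row_", seq_len(nrow(X)))
  d <- data.frame(id = rownames(X), X, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write result tables and run metadata
#'
#' Writes each table as `<name>.tsv` under `outdir` and the metadata (always
#' including the package version) as `metadata.json`. Re-running with the
#' same configuration and seed reproduces byte-identical tables.
#'
#' @param tables Named list of data frames.
#' @param metadata Named list (should include the seed and resolved
#'   configuration).
#' @param outdir Output directory; created if absent.
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(tables, metadata, outdir) {
  stopifnot(is.list(tables), is.list(metadata))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(outdir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  metadata$package_version <- as.character(utils::packageVersion("genbayes"))
  mp <- file.path(outdir, "metadata.json")
  jsonlite::write_json(metadata, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, mp))
}
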