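# Table and matrix I/O: square TSV with ROI labels in the header row and the
# first column, plus an optional JSON sidecar describing provenance.

#' Write a connectivity matrix as labelled square TSV
#'
#' @param m a [connectivity_matrix()] or plain symmetric matrix.
#' @param path output file.
#' @param sidecar optional named list written to `<path>.json` (kind, subject,
#'   timepoint, construction parameters, ...).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, sidecar = NULL) {
  vals <- if (inherits(m, "connectivity_matrix")) cm_values(m) else m
  check_square_symmetric(vals, "m")
  if (is.null(rownames(vals))) {
    dimnames(vals) <- list(roi_labels_for(nrow(vals)),
                           roi_labels_for(nrow(vals)))
  }
  # %.17g keeps the full double precision so read-back is bit-exact
  chr <- matrix(sprintf("%.17g", vals), nrow(vals),
                dimnames = dimnames(vals))
  df <- data.frame(roi = rownames(vals), chr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (inherits(m, "connectivity_matrix") && is.null(sidecar)) {
    sidecar <- list(kind = attr(m, "kind"))
  }
  if (!is.null(sidecar)) {
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a labelled square matrix TSV
#'
#' Validates squareness, label agreement between header and first column, and
#' symmetry to 1e-8. When `labels` is supplied the matrix is permuted to that
#' label order (all labels must be present).
#'
#' @param path file written by [write_matrix_tsv()].
#' @param labels optional label order to return.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path, labels = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  rn <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (nrow(vals) != ncol(vals)) {
    stop(sprintf("matrix in '%s' is not square (%d x %d)", path,
                 nrow(vals), ncol(vals)), call. = FALSE)
  }
  if (!identical(as.character(rn), colnames(vals))) {
    stop(sprintf("row/column labels disagree in '%s'", path), call. = FALSE)
  }
  rownames(vals) <- rn
  if (max(abs(vals - t(vals))) > 1e-8) {
    stop(sprintf("matrix in '%s' is asymmetric beyond 1e-8", path),
         call. = FALSE)
  }
  if (!is.null(labels)) {
    if (!all(labels %in% rn)) {
      stop(sprintf("requested labels missing from '%s': %s", path,
                   paste(setdiff(labels, rn), collapse = ", ")),
           call. = FALSE)
    }
    vals <- vals[labels, labels, drop = FALSE]
  }
  vals
}

write_table_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_table_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

config_hash <- function(config) {
  plain <- unclass(config)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = 15,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

file_inventory <- function(paths, root) {
  data.frame(
    file = sub(paste0("^", root, "/?"), "", paths),
    md5 = unname(tools::md5sum(paths)),
    row.names = NULL
  )
}
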