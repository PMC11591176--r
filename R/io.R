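## CSV dialect and manifest I/O.
##
## Signal matrices travel as headerless comma-separated files, one row per
## channel (12 x 5000 full records, 12 x 1500 strips, C x 375 beat tensors),
## values in millivolts with a period decimal. Manifests are tab-separated
## text with a header.

#' Read a channels-by-samples CSV signal file
#'
#' @param path Existing file.
#' @param expectedRows Required number of rows (channels); the file is
#'   rejected, with row/column diagnostics, if the row count differs, any row
#'   is ragged, or any cell is non-numeric/non-finite.
#' @return Numeric matrix with exactly `expectedRows` rows.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeRecordCsv(matrix(rnorm(24), 2), f)
#' dim(readRecordCsv(f, expectedRows = 2))
readRecordCsv <- function(path, expectedRows = 12L) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = ",", quote = "")
  if (length(nf) != expectedRows)
    stop(sprintf("%s: expected %d rows, found %d", path, expectedRows,
                 length(nf)))
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != stats::median(nf))[1L]
    stop(sprintf("%s: ragged rows (row %d has %d fields, expected %d)",
                 path, bad, nf[bad], stats::median(nf)))
  }
  dt <- suppressWarnings(
    data.table::fread(path, header = FALSE, sep = ",",
                      colClasses = "numeric", data.table = FALSE,
                      showProgress = FALSE))
  m <- suppressWarnings(
    matrix(as.numeric(as.matrix(dt)), nrow(dt), ncol(dt)))
  if (!is.numeric(m) || anyNA(m) || any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1L, , drop = TRUE]
    stop(sprintf("%s: non-numeric or non-finite value at row %d, column %d",
                 path, bad[1L], bad[2L]))
  }
  dimnames(m) <- NULL
  m
}

#' Write a channels-by-samples CSV signal file
#'
#' Values are written with full double precision (round-trips are
#' value-preserving well beyond 6 significant digits). Non-finite matrices
#' are rejected.
#'
#' @param x Numeric matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeRecordCsv <- function(x, path) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("x must be a numeric matrix")
  if (anyNA(x) || any(!is.finite(x)))
    stop("matrix contains non-finite values; refusing to write")
  data.table::fwrite(data.table::as.data.table(x), path,
                     col.names = FALSE, sep = ",")
  invisible(path)
}

#' Write a cohort as per-record CSV files plus a manifest
#'
#' Each record's 12 x 5000 signal goes to `<case_id>.csv` under `dir`; the
#' manifest (`manifest.tsv`) lists case id, relative path, LVEF, EF class,
#' AF status and split role.
#'
#' @param cohort An [EcgCohort-class].
#' @param dir Output directory (created if needed).
#' @param splitRoles Optional named character (`train`/`dev`/`test`/
#'   `external`) per case id; defaults to `"train"`.
#' @return The manifest data.frame, invisibly.
#' @export
writeCohortCsv <- function(cohort, dir, splitRoles = NULL) {
  stopifnot(is(cohort, "EcgCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohortManifest(cohort)
  man$path <- paste0(man$case_id, ".csv")
  man$split_role <- if (is.null(splitRoles)) "train"
                    else unname(splitRoles[man$case_id])
  for (r in cohortRecords(cohort))
    writeRecordCsv(signalMatrix(r), file.path(dir, paste0(caseId(r), ".csv")))
  man <- man[, c("case_id", "path", "lvef", "ef_class", "af", "split_role")]
  writeManifest(man, file.path(dir, "manifest.tsv"))
  invisible(man)
}

#' Read/write a cohort manifest (TSV with header)
#'
#' @param path Manifest file.
#' @param checkPaths Verify that every referenced signal file exists
#'   (relative to the manifest's directory).
#' @return `readManifest`: the manifest data.frame.
#' @export
readManifest <- function(path, checkPaths = TRUE) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("case_id", "path", "lvef", "ef_class")
  if (!all(need %in% names(man)))
    stop("manifest lacks required columns: ",
         paste(setdiff(need, names(man)), collapse = ", "))
  if (anyDuplicated(man$case_id))
    stop("duplicate case ids in manifest")
  if (checkPaths) {
    full <- file.path(dirname(path), man$path)
    missing <- !file.exists(full)
    if (any(missing))
      stop("manifest references missing files: ",
           paste(man$path[missing], collapse = ", "))
  }
  man
}

#' @rdname readManifest
#' @param man Manifest data.frame.
#' @return `writeManifest`: `path`, invisibly.
#' @export
writeManifest <- function(man, path) {
  utils::write.table(man, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
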