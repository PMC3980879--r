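#' Write a table to CSV at full double precision
#'
#' Numeric columns are serialized with 17 significant digits so that a
#' write/read round trip reproduces every value bit-for-bit; column order and
#' row count are preserved; \code{NA}/\code{NaN} survive the trip.
#'
#' @param df a data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_table_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]]) & !is.nan(out[[j]])] <- NA
      v[is.nan(out[[j]])] <- "NaN"
      out[[j]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a CSV written by \code{\link{write_table_csv}}
#'
#' @param path input path.
#' @param numeric_cols columns to coerce to double; by default every column
#'   that parses fully as numeric (empty fields become NA, "NaN" becomes
#'   NaN).
#' @return data.frame.
#' @export
read_table_csv <- function(path, numeric_cols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- tryCatch(utils::count.fields(path, sep = ",", quote = "\""),
                 error = function(e) stop("malformed CSV: ", conditionMessage(e)))
  if (length(unique(nf[!is.na(nf)])) > 1) {
    bad <- which(nf != nf[1])[1]
    stop("malformed CSV at line ", bad, ": inconsistent field count")
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  if (is.null(numeric_cols)) {
    numeric_cols <- names(d)[vapply(d, function(x) {
      xx <- x[!(x %in% c("", "NA", "NaN"))]
      length(xx) == 0 ||
        !anyNA(suppressWarnings(as.numeric(xx)))
    }, logical(1))]
  }
  for (j in numeric_cols) {
    v <- d[[j]]
    v[v == ""] <- NA
    d[[j]] <- as.numeric(v)
  }
  d
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a deterministic pipeline stage:
#' the full parameter set, the seeds in use, and the package version.
#'
#' @param path output JSON path.
#' @param p an \code{\link{il2_params}} object.
#' @param seeds named list/vector of seeds used by the run.
#' @param extra optional named list of additional metadata.
#' @return \code{path}, invisibly.
#' @export
write_run_manifest <- function(path, p, seeds, extra = list()) {
  man <- c(list(package_version =
                  as.character(utils::packageVersion("il2cohort")),
                seeds = as.list(seeds),
                params = unclass(p)),
           extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
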