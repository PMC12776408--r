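#' Parcellated ROI time series
#'
#' The container every stage of the pipeline consumes and produces: a real
#' matrix with one row per region of interest (ROI) and one column per
#' timepoint, together with the sampling interval (TR, seconds) and ROI
#' labels. Values are in arbitrary signal units (BOLD-like).
#'
#' @param values numeric matrix \[n_roi x n_time\]; all entries finite.
#' @param tr sampling interval in seconds (> 0).
#' @param roi_labels character vector of ROI identifiers; defaults to
#'   `ROI001 ...`.
#' @return an object of class `roi_ts`: the matrix with attributes `tr` and
#'   rownames set to the labels.
#' @export
roi_ts <- function(values, tr, roi_labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("roi_ts values must be a finite numeric matrix")
  if (ncol(values) < 2) stop("roi_ts needs at least 2 timepoints")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("tr must be a single positive number (seconds)")
  if (is.null(roi_labels))
    roi_labels <- rownames(values)
  if (is.null(roi_labels))
    roi_labels <- sprintf("ROI%03d", seq_len(nrow(values)))
  if (length(roi_labels) != nrow(values))
    stop("roi_labels length must equal the number of rows")
  rownames(values) <- roi_labels
  structure(values, tr = as.numeric(tr), class = c("roi_ts", "matrix", "array"))
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> %d ROIs x %d timepoints, TR = %g s (%.1f s total)\n",
              nrow(x), ncol(x), tr_of(x), ncol(x) * tr_of(x)))
  invisible(x)
}

#' Sampling interval of a time-series object
#' @param x an `roi_ts` or template object carrying a `tr` attribute.
#' @return TR in seconds.
#' @export
tr_of <- function(x) attr(x, "tr")

# rebuild an roi_ts around new values, keeping tr/labels unless overridden
replace_values <- function(x, values, tr = tr_of(x)) {
  roi_ts(values, tr = tr, roi_labels = rownames(x))
}

#' Read / write ROI time series as TSV
#'
#' The on-disk dialect is plain text: a first header line `# TR=<seconds>`,
#' then one row per ROI whose first column is the ROI label followed by the
#' signal values, tab-separated.
#'
#' @param x an `roi_ts`.
#' @param path file path.
#' @return `write_roi_tsv` returns `path` invisibly; `read_roi_tsv` returns
#'   an `roi_ts`.
#' @export
write_roi_tsv <- function(x, path) {
  stopifnot(inherits(x, "roi_ts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# TR=%.10g", tr_of(x)), con)
  df <- data.frame(roi = rownames(x), unclass(x), check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_tsv
#' @export
read_roi_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("^# TR=", header))
    stop("missing '# TR=<seconds>' header line in ", path)
  tr <- as.numeric(sub("^# TR=", "", header))
  df <- read.table(path, sep = "\t", skip = 1L, header = FALSE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  dimnames(values) <- NULL
  roi_ts(values, tr = tr, roi_labels = df[[1]])
}

#' Read / write event-time index files
#'
#' Events are 1-based integer timepoint indices, one per line.
#'
#' @param events integer vector.
#' @param path file path.
#' @export
write_events <- function(events, path) {
  writeLines(as.character(as.integer(events)), path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  x <- readLines(path)
  as.integer(x[nzchar(x)])
}
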