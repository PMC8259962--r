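# Text round-trip for ensembles and recordings: a delimited matrix
# (column 1 = time in ms, remaining columns = sweeps in pA) plus a JSON
# sidecar (<path>.json) carrying the metadata.

sidecar_path <- function(path) paste0(path, ".json")

meta_to_json <- function(meta, path) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
}

meta_from_json <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing sidecar metadata file: ", sp)
  m <- jsonlite::read_json(sp, simplifyVector = TRUE)
  # scalars come back as length-1 vectors already; keep numeric vectors
  m
}

#' Write / read a sweep ensemble as delimited text plus JSON sidecar
#'
#' The data file is tab-separated with a header row: column `time_ms`
#' followed by one `sweep_<k>` column per sweep (pA).  All metadata goes
#' to `<path>.json`.  `read_ensemble(write_ensemble(x, path))` reproduces
#' the samples to better than 1e-9 pA and all metadata.
#'
#' @param x A [trace_ensemble()].
#' @param path Output file path.
#' @return `write_ensemble` returns `path` invisibly; `read_ensemble`
#'   returns a [trace_ensemble()].
#' @export
write_ensemble <- function(x, path) {
  stopifnot(inherits(x, "trace_ensemble"))
  tab <- cbind(time_ms = trace_time(x), x$current)
  colnames(tab) <- c("time_ms", paste0("sweep_", seq_len(n_sweeps(x))))
  utils::write.table(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta_to_json(c(list(dt = x$dt, kind = "ensemble"), x$meta), path)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "numeric", fill = TRUE)
  if (anyNA(tab)) stop("ragged or malformed trace matrix in ", path)
  if (ncol(tab) < 2) stop("trace matrix needs a time column and >= 1 sweep")
  m <- meta_from_json(path)
  dt <- m$dt
  m$dt <- NULL
  m$kind <- NULL
  if (is.null(dt)) dt <- diff(tab[[1]][1:2])
  trace_ensemble(as.matrix(tab[, -1, drop = FALSE]), dt, meta = m)
}

#' Write / read a gap-free recording (single data column dialect)
#'
#' Same dialect as [write_ensemble()] with exactly one sweep column.
#'
#' @param x An [ep_recording()].
#' @param path Output file path.
#' @export
write_recording <- function(x, path) {
  stopifnot(inherits(x, "ep_recording"))
  tab <- data.frame(time_ms = trace_time(x), current_pA = x$current)
  utils::write.table(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta_to_json(c(list(dt = x$dt, kind = "recording"), x$annotations), path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "numeric", fill = TRUE)
  if (anyNA(tab) || ncol(tab) != 2) stop("malformed recording file: ", path)
  m <- meta_from_json(path)
  dt <- m$dt
  m$dt <- NULL
  m$kind <- NULL
  do.call(ep_recording, c(list(current = tab[[2]], dt = dt), m))
}
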