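#' Multivariate time-series container
#'
#' A `dcov_ts` is a numeric nodes-by-time matrix with unique node labels
#' (rownames), a sampling interval `dt` in seconds and a `kind` tag
#' recording what stage of the pipeline the traces belong to: raw neural
#' activity (`"neural"`), haemodynamic BOLD output (`"bold"`),
#' backward-reconstructed surrogate neural signal (`"reconstructed"`) or
#' a numerical derivative (`"derivative"`).
#'
#' @param values numeric matrix, one row per node, one column per sample.
#' @param dt sampling interval in seconds.
#' @param kind one of `"neural"`, `"bold"`, `"reconstructed"`,
#'   `"derivative"`.
#' @param labels optional character vector of node names; defaults to
#'   `node01`, `node02`, ...
#' @return a `dcov_ts` object (a matrix with attributes).
#' @export
dcov_ts <- function(values, dt, kind = c("neural", "bold", "reconstructed",
                                         "derivative"),
                    labels = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("time-series values must be numeric")
  if (ncol(values) < 2) stop("need at least 2 time points")
  if (any(!is.finite(values))) stop("time series contains non-finite values")
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stop("dt must be a positive scalar (seconds)")
  }
  rownames(values) <- check_labels(labels %||% rownames(values), nrow(values))
  structure(values, class = c("dcov_ts", "matrix", "array"),
            dt = dt, kind = kind)
}

#' @export
print.dcov_ts <- function(x, ...) {
  cat(sprintf("<dcov_ts> %d nodes x %d samples, dt = %g s, kind = %s\n",
              nrow(x), ncol(x), ts_dt(x), ts_kind(x)))
  invisible(x)
}

ts_dt <- function(ts) attr(ts, "dt")
ts_kind <- function(ts) attr(ts, "kind")
ts_labels <- function(ts) rownames(ts)

# Strip class/attributes, keep dimnames.
ts_values <- function(ts) {
  m <- unclass(ts)
  attr(m, "dt") <- NULL
  attr(m, "kind") <- NULL
  m
}

#' Downsample a time series to a coarser repetition time
#'
#' Keeps every `TR/dt`-th sample, emulating acquisition at repetition
#' time `TR`.  `TR` must be an integer multiple of the current sampling
#' interval.
#'
#' @param ts a [dcov_ts()].
#' @param TR target sampling interval in seconds.
#' @return a `dcov_ts` with updated `dt`.
#' @export
downsample <- function(ts, TR) {
  stopifnot(inherits(ts, "dcov_ts"))
  dt <- ts_dt(ts)
  ratio <- TR / dt
  if (abs(ratio - round(ratio)) > 1e-8 || round(ratio) < 1) {
    stop("TR (", TR, ") must be an integer multiple of dt (", dt, ")")
  }
  ratio <- round(ratio)
  idx <- seq(1, ncol(ts), by = ratio)
  dcov_ts(ts_values(ts)[, idx, drop = FALSE], dt = dt * ratio,
          kind = ts_kind(ts), labels = ts_labels(ts))
}

#' Read / write time series as TSV with a JSON sidecar
#'
#' The TSV has one row per node: first column the node label, remaining
#' columns the samples.  A sidecar `<path>.json` stores `dt` and `kind`.
#'
#' @param ts a [dcov_ts()].
#' @param path file path of the TSV.
#' @return `write_ts_tsv()` returns `path` invisibly; `read_ts_tsv()`
#'   returns a `dcov_ts`.
#' @export
write_ts_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "dcov_ts"))
  df <- data.frame(label = ts_labels(ts), ts_values(ts),
                   check.names = FALSE)
  colnames(df) <- c("label", sprintf("t%d", seq_len(ncol(ts))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(dt = ts_dt(ts), kind = ts_kind(ts)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ts_tsv
#' @export
read_ts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  m <- as.matrix(df[, -1, drop = FALSE])
  colnames(m) <- NULL
  dcov_ts(m, dt = as.numeric(meta$dt), kind = as.character(meta$kind),
          labels = df[[1]])
}
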