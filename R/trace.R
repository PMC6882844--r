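#' Binary measurement trace
#'
#' One trace is the string of bits produced by `n` repeated
#' initialize-evolve-measure cycles of duration `dt` under a continuous
#' signal; bit `j` is the outcome of the measurement concluding at time
#' `t_j = j * dt`. Times are implied by `dt` and recovered with
#' [trace_times()].
#'
#' @param bits integer (or logical) vector of 0/1 outcomes.
#' @param dt interrogation interval, s.
#' @param label optional hypothesis tag (any scalar).
#' @return an object of class `"nmr_trace"`.
#' @export
nmr_trace <- function(bits, dt, label = NULL) {
  bits <- as.integer(bits)
  if (length(bits) < 1L) stop("a trace needs at least one bit")
  if (anyNA(bits) || any(bits != 0L & bits != 1L))
    stop("'bits' must contain only 0 and 1")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a positive scalar")
  structure(list(bits = bits, dt = dt, label = label), class = "nmr_trace")
}

#' @rdname nmr_trace
#' @param trace an `nmr_trace`.
#' @return `trace_times()`: the measurement times `(1:n) * dt` in seconds.
#' @export
trace_times <- function(trace) seq_along(trace$bits) * trace$dt

#' @export
print.nmr_trace <- function(x, ...) {
  n <- length(x$bits)
  cat(sprintf("<nmr_trace> %d bits, dt = %g s, T_tot = %g s, <x> = %.4f%s\n",
              n, x$dt, n * x$dt, mean(x$bits),
              if (is.null(x$label)) "" else paste0(", label = ", x$label)))
  invisible(x)
}

#' @export
length.nmr_trace <- function(x) length(x$bits)

#' Labelled collection of traces
#'
#' Traces are stored as the rows of an integer matrix (all traces share `dt`
#' and length), which is the layout every batch operation in the package
#' works on. `labels` tags each row with its generating hypothesis.
#'
#' @param bits integer matrix, one trace per row.
#' @param dt shared interrogation interval, s.
#' @param labels vector of per-trace hypothesis tags (length `nrow(bits)`),
#'   or `NULL` for unlabelled data.
#' @param metadata list of generating parameters (free-form; carried along
#'   and written to the sidecar file on export).
#' @return an object of class `"nmr_dataset"`.
#' @export
nmr_dataset <- function(bits, dt, labels = NULL, metadata = list()) {
  if (!is.matrix(bits)) stop("'bits' must be a matrix (one trace per row)")
  storage.mode(bits) <- "integer"
  if (anyNA(bits) || any(bits != 0L & bits != 1L))
    stop("'bits' must contain only 0 and 1")
  if (!is.null(labels) && length(labels) != nrow(bits))
    stop("'labels' must have one entry per trace")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a positive scalar")
  structure(list(bits = bits, dt = dt, labels = labels, metadata = metadata),
            class = "nmr_dataset")
}

#' @export
print.nmr_dataset <- function(x, ...) {
  cat(sprintf("<nmr_dataset> %d traces x %d bits, dt = %g s\n",
              nrow(x$bits), ncol(x$bits), x$dt))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("%s (n=%d)", names(tab), tab),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname nmr_dataset
#' @param ds an `nmr_dataset`.
#' @param i trace index.
#' @return `get_trace()`: the `i`-th trace as an [nmr_trace()].
#' @export
get_trace <- function(ds, i) {
  nmr_trace(ds$bits[i, ], ds$dt,
            label = if (is.null(ds$labels)) NULL else ds$labels[i])
}

#' @rdname nmr_dataset
#' @return `n_traces()`: the number of traces.
#' @export
n_traces <- function(ds) nrow(ds$bits)

#' Segment a raw detection stream into fixed-length traces
#'
#' Long acquisition runs are windowed into consecutive, non-overlapping
#' traces so that the signal phase of each window is effectively an
#' independent uniform draw. The trailing remainder shorter than one window
#' is discarded.
#'
#' @param bits raw 0/1 vector (or a single character string of 0s and 1s).
#' @param window window length in bits (>= 1).
#' @param dt interrogation interval of the stream, s.
#' @param label optional label applied to every window.
#' @return an [nmr_dataset()] whose metadata records the window length and
#'   the number of discarded bits.
#' @export
#' @examples
#' segment_raw_stream(rbinom(100, 1, 0.5), window = 25, dt = 1e-5)
segment_raw_stream <- function(bits, window, dt, label = NULL) {
  if (is.character(bits) && length(bits) == 1L)
    bits <- as.integer(strsplit(bits, "")[[1]])
  bits <- as.integer(bits)
  window <- as.integer(window)
  if (window < 1L) stop("'window' must be at least 1")
  k <- length(bits) %/% window
  if (k < 1L) stop("stream is shorter than one window; no traces produced")
  used <- bits[seq_len(k * window)]
  m <- matrix(used, nrow = k, ncol = window, byrow = TRUE)
  nmr_dataset(m, dt,
              labels = if (is.null(label)) NULL else rep(label, k),
              metadata = list(window = window, dt = dt,
                              discarded_bits = length(bits) - k * window))
}

#' Read a raw 0/1 detection stream from a text file
#'
#' Accepts one 0/1 token per line, whitespace-separated tokens, or one or
#' more contiguous 0/1 strings.
#'
#' @param path path to a plain-text file.
#' @return integer vector of bits.
#' @export
read_raw_stream <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE)
  bits <- suppressWarnings(unlist(lapply(toks, function(s) {
    if (nchar(s) > 1L) as.integer(strsplit(s, "")[[1]]) else as.integer(s)
  }), use.names = FALSE))
  if (anyNA(bits) || any(bits != 0L & bits != 1L))
    stop("stream contains tokens other than 0/1")
  bits
}

#' Write / read a dataset
#'
#' Two plain-text layouts are supported. `"compact"` writes one trace per
#' line as a contiguous 0/1 string, with `dt`, labels, and all generating
#' metadata in a JSON sidecar at `<path>.json`; it is the layout to use for
#' long traces. `"csv"` writes the long columnar form
#' `trace_id,t,bit` (times in seconds) with the same sidecar.
#'
#' @param ds an [nmr_dataset()].
#' @param path output file path.
#' @param format `"compact"` or `"csv"`.
#' @return `write_dataset()`: `path`, invisibly. `read_dataset()`: the
#'   reconstructed `nmr_dataset`.
#' @export
write_dataset <- function(ds, path, format = c("compact", "csv")) {
  format <- match.arg(format)
  meta <- list(format = format, dt = ds$dt, n_meas = ncol(ds$bits),
               n_traces = nrow(ds$bits), labels = ds$labels,
               metadata = ds$metadata)
  if (format == "compact") {
    writeLines(apply(ds$bits, 1L, paste, collapse = ""), path)
  } else {
    n <- ncol(ds$bits)
    df <- data.frame(
      trace_id = rep(seq_len(nrow(ds$bits)), each = n),
      t = rep(seq_len(n) * ds$dt, times = nrow(ds$bits)),
      bit = as.integer(t(ds$bits))
    )
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (identical(meta$format, "compact")) {
    lines <- readLines(path)
    m <- do.call(rbind, lapply(lines, function(s)
      as.integer(strsplit(s, "")[[1]])))
  } else {
    df <- utils::read.csv(path)
    ids <- unique(df$trace_id)
    m <- do.call(rbind, lapply(ids, function(i)
      as.integer(df$bit[df$trace_id == i])))
  }
  labels <- meta$labels
  if (is.null(labels) || length(labels) == 0L) labels <- NULL
  nmr_dataset(m, meta$dt, labels = labels,
              metadata = as.list(meta$metadata))
}
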