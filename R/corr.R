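#' Autocorrelation vector of a trace
#'
#' Bits are mapped `{0,1} -> {-1,+1}` and the lag-`k` autocorrelation
#' `C_k = <s_i s_{i+k}>_i` is averaged over all `n - k` valid positions,
#' for `k = 1 ... k_max`. The frequency information of a random-phase
#' signal lives entirely in these two-point correlations, which is what
#' makes the vector a useful classification feature.
#'
#' @param trace an [nmr_trace()] (or a plain 0/1 vector).
#' @param k_max maximum lag; must be < trace length. Default: all lags.
#' @param lag_stride keep every `lag_stride`-th lag only (subsampling for
#'   very long traces, where the full vector is too expensive downstream);
#'   default 1 (all lags up to `k_max`).
#' @return an object of class `"correlation_vector"`: numeric vector of the
#'   `C_k`, each in `[-1, 1]`, with attribute `lags`.
#' @export
#' @examples
#' correlation_vector(nmr_trace(c(1, 0, 1, 0, 1, 0), dt = 1), k_max = 2)
correlation_vector <- function(trace, k_max = NULL, lag_stride = 1L) {
  bits <- if (inherits(trace, "nmr_trace")) trace$bits else as.integer(trace)
  n <- length(bits)
  if (is.null(k_max)) k_max <- n - 1L
  k_max <- as.integer(k_max)
  if (k_max < 1L || k_max >= n)
    stop("'k_max' must lie in [1, trace length - 1]")
  lags <- seq.int(1L, k_max, by = as.integer(lag_stride))
  s <- 2 * bits - 1
  # <s_i s_{i+k}> via the autocovariance of the raw +-1 sequence
  vals <- vapply(lags, function(k)
    sum(s[seq_len(n - k)] * s[(k + 1L):n]) / (n - k), numeric(1))
  structure(vals, lags = lags, class = "correlation_vector")
}

#' @export
print.correlation_vector <- function(x, ...) {
  cat(sprintf("<correlation_vector> %d lags, range [%.3f, %.3f]\n",
              length(x), min(x), max(x)))
  invisible(x)
}

#' Class-averaged correlation templates
#'
#' For each of the two hypotheses in a labelled training set, the
#' element-wise mean of the per-trace correlation vectors is the class
#' template against which test traces are matched.
#'
#' @param train a labelled [nmr_dataset()] containing both classes.
#' @param k_max,lag_stride passed to [correlation_vector()].
#' @return an object of class `"class_templates"`: list with `templates`
#'   (list of two numeric vectors, in label order), `labels`, `counts`,
#'   `k_max`, `lag_stride`.
#' @export
fit_templates <- function(train, k_max = NULL, lag_stride = 1L) {
  stopifnot(inherits(train, "nmr_dataset"))
  if (is.null(train$labels)) stop("training set must be labelled")
  labs <- sort(unique(train$labels))
  if (length(labs) != 2L)
    stop("training set must contain exactly two classes")
  n <- ncol(train$bits)
  if (is.null(k_max)) k_max <- n - 1L
  tmpl <- lapply(labs, function(l) {
    rows <- which(train$labels == l)
    acc <- 0
    for (i in rows)
      acc <- acc + as.numeric(correlation_vector(train$bits[i, ], k_max,
                                                 lag_stride))
    acc / length(rows)
  })
  structure(list(templates = tmpl, labels = labs,
                 counts = as.integer(table(factor(train$labels, labs))),
                 k_max = as.integer(k_max),
                 lag_stride = as.integer(lag_stride)),
            class = "class_templates")
}

#' @export
print.class_templates <- function(x, ...) {
  cat(sprintf(
    "<class_templates> classes %s (n = %s), k_max = %d, lag_stride = %d\n",
    paste(x$labels, collapse = "/"), paste(x$counts, collapse = "/"),
    x$k_max, x$lag_stride))
  invisible(x)
}

#' Nearest-template classification of one trace
#'
#' The trace's correlation vector is compared to the two class templates in
#' the L2 norm; the label with the smaller distance wins. Ties go to the
#' second class (the "otherwise" branch of the decision rule).
#'
#' @param trace an [nmr_trace()] (or 0/1 vector) on the training grid.
#' @param templates a [fit_templates()] result.
#' @return the winning label, with attributes `D1`, `D2` (the distances).
#' @export
classify_corr <- function(trace, templates) {
  stopifnot(inherits(templates, "class_templates"))
  cv <- as.numeric(correlation_vector(trace, templates$k_max,
                                      templates$lag_stride))
  D1 <- sqrt(sum((cv - templates$templates[[1]])^2))
  D2 <- sqrt(sum((cv - templates$templates[[2]])^2))
  structure(if (D1 < D2) templates$labels[1] else templates$labels[2],
            D1 = D1, D2 = D2)
}

#' Nearest-template classification of a whole dataset
#'
#' @inheritParams classify_corr
#' @param ds an [nmr_dataset()].
#' @return a data.frame with one row per trace: `pred` (label), `D1`, `D2`,
#'   and `score = D2 - D1` (larger favours class 1; useful for ROC curves).
#' @export
classify_corr_dataset <- function(ds, templates) {
  stopifnot(inherits(ds, "nmr_dataset"))
  res <- t(vapply(seq_len(nrow(ds$bits)), function(i) {
    cv <- as.numeric(correlation_vector(ds$bits[i, ], templates$k_max,
                                        templates$lag_stride))
    c(sqrt(sum((cv - templates$templates[[1]])^2)),
      sqrt(sum((cv - templates$templates[[2]])^2)))
  }, numeric(2)))
  D1 <- res[, 1]; D2 <- res[, 2]
  data.frame(pred = ifelse(D1 < D2, templates$labels[1],
                           templates$labels[2]),
             D1 = D1, D2 = D2, score = D2 - D1)
}
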