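# Time-series expression datasets: uniform time grid, strictly positive
# genes x time-points matrix, one object per replicate.

#' Construct a time-series dataset
#'
#' @param times increasing numeric vector with uniform step; delays are
#'   counted in multiples of that step.
#' @param values genes x time-points matrix of positive expression levels;
#'   row names are gene ids (default `g1..gN`).
#' @param replicate_id identifier for the replicate.
#' @return object of class `time_series_dataset`.
#' @export
time_series_dataset <- function(times, values, replicate_id = 1L) {
  values <- as.matrix(values)
  if (length(times) != ncol(values))
    stop("length(times) must equal ncol(values)")
  if (length(times) < 2) stop("need at least two time points")
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (max(abs(dt - dt[1])) > 1e-8 * dt[1])
    stop("nonuniform time grid: delays require a constant sampling interval")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("expression levels must be finite and positive")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  structure(list(times = as.numeric(times), values = values,
                 replicate_id = replicate_id),
            class = "time_series_dataset")
}

#' @export
print.time_series_dataset <- function(x, ...) {
  cat(sprintf("time_series_dataset: %d genes x %d time points, t in [%g, %g], replicate %s\n",
              nrow(x$values), length(x$times), min(x$times), max(x$times),
              format(x$replicate_id)))
  invisible(x)
}

#' Delayed expression lookup with linear interpolation
#'
#' Returns the level of gene `j` at time `t - tau * dt`, linearly
#' interpolated between samples; times before the first sample return the
#' first sample (constant-history convention).
#'
#' @param ds a [time_series_dataset()].
#' @param gene 1-based gene index.
#' @param t query time (same units as `ds$times`).
#' @param tau integer lag in sampling intervals.
#' @return expression level.
#' @export
delayed_value <- function(ds, gene, t, tau = 0) {
  if (gene < 1 || gene > nrow(ds$values)) stop("gene index out of range")
  dt <- ds$times[2] - ds$times[1]
  tq <- t - tau * dt
  s <- (tq - ds$times[1]) / dt
  T <- length(ds$times)
  if (s <= 0) return(unname(ds$values[gene, 1]))
  if (s >= T - 1) return(unname(ds$values[gene, T]))
  k <- floor(s)
  w <- s - k
  unname((1 - w) * ds$values[gene, k + 1] + w * ds$values[gene, k + 2])
}
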