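#' Spike raster
#'
#' A binary spike array for one trial: an `N x L` integer matrix whose rows
#' are neurons and whose columns are consecutive time steps
#' `n_min, n_min+1, ..., n_min+L-1`.  `n_min` is the history start (often
#' negative: the burn-in period precedes the analysis clock that starts at
#' `n = 1`).
#'
#' @param omega matrix of 0/1 values, neurons in rows.
#' @param n_min time index of the first column.
#' @return An object of class `spike_raster`.
#' @export
spike_raster <- function(omega, n_min = 1L) {
  omega <- as.matrix(omega)
  if (!all(omega %in% c(0L, 1L))) stop("raster entries must be 0 or 1")
  storage.mode(omega) <- "integer"
  structure(omega, n_min = as.integer(n_min), class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d neurons x %d steps, times %d..%d, %d spikes\n",
              nrow(x), ncol(x), raster_n_min(x), raster_n_max(x), sum(x)))
  invisible(x)
}

#' @rdname spike_raster
#' @param raster a `spike_raster`.
#' @export
raster_n_min <- function(raster) attr(raster, "n_min")

#' @rdname spike_raster
#' @export
raster_n_max <- function(raster) attr(raster, "n_min") + ncol(raster) - 1L

# time index -> column index, with range check
raster_col <- function(raster, n) {
  j <- n - raster_n_min(raster) + 1L
  if (any(j < 1L) || any(j > ncol(raster)))
    stop("time index out of raster range")
  j
}

#' Last reset time
#'
#' Returns \eqn{\tau_k(n,\omega) = \max\{l \le n : \omega_k(l) = 1\}}, the
#' most recent time at or before `n` at which neuron `k` spiked (and its
#' voltage was reset to zero).  If the neuron never spiked up to `n`, the
#' sentinel `n_min - 1` is returned, meaning "integrate from the history
#' start".
#'
#' @param raster a [spike_raster()].
#' @param k neuron index (1-based).
#' @param n time index within the raster range.
#' @return Integer time, or `n_min - 1` if no spike exists.
#' @export
last_reset_time <- function(raster, k, n) {
  j <- raster_col(raster, n)
  cols <- which(raster[k, seq_len(j)] == 1L)
  if (length(cols) == 0L) return(raster_n_min(raster) - 1L)
  raster_n_min(raster) + cols[length(cols)] - 1L
}

#' Read and write sparse spike-event files
#'
#' Rasters serialize as sparse event triplets with a header row
#' `trial,neuron,time`, 0-based neuron and time indices, one row per spike.
#' `write_spike_events()` accepts a single raster or a `trial_ensemble`;
#' `read_spike_events()` reconstructs the dense ensemble, which requires the
#' time range and neuron count (events carry no shape).
#'
#' @param x a `spike_raster` or `trial_ensemble`.
#' @param file path of the CSV file.
#' @export
write_spike_events <- function(x, file) {
  if (inherits(x, "spike_raster")) {
    rasters <- list(x)
    n_min <- raster_n_min(x)
  } else if (inherits(x, "trial_ensemble")) {
    rasters <- lapply(seq_len(x$M), function(m) ensemble_raster(x, m))
    n_min <- x$n_min
  } else stop("unsupported object")
  rows <- lapply(seq_along(rasters), function(m) {
    idx <- which(unclass(rasters[[m]]) == 1L, arr.ind = TRUE)
    if (nrow(idx) == 0L)
      return(data.frame(trial = integer(), neuron = integer(), time = integer()))
    data.frame(trial = m - 1L, neuron = idx[, 1L] - 1L,
               time = idx[, 2L] - 1L + n_min)
  })
  write.csv(do.call(rbind, rows), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_spike_events
#' @param N neuron count of the dense raster to rebuild.
#' @param n_min,n_max time range of the dense raster to rebuild.
#' @return `read_spike_events()` returns a list of [spike_raster()] objects,
#'   one per trial present in the file.
#' @export
read_spike_events <- function(file, N, n_min, n_max) {
  ev <- read.csv(file)
  stopifnot(all(c("trial", "neuron", "time") %in% names(ev)))
  L <- n_max - n_min + 1L
  trials <- if (nrow(ev)) sort(unique(ev$trial)) else integer()
  lapply(trials, function(tr) {
    omega <- matrix(0L, N, L)
    sel <- ev[ev$trial == tr, , drop = FALSE]
    omega[cbind(sel$neuron + 1L, sel$time - n_min + 1L)] <- 1L
    spike_raster(omega, n_min)
  })
}
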