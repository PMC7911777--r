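#' Stimulus field
#'
#' Per-neuron, per-time stimulus values on the simulation grid: an `N x L`
#' matrix whose columns are times `n_min .. n_min + L - 1`, identically zero
#' before the onset step `t0`.  Values requested outside the stored window
#' are zero.
#'
#' @param S numeric matrix, neurons in rows.
#' @param n_min time index of the first column.
#' @param t0 onset step (no non-zero entries before it).
#' @param meta optional named list of generating parameters.
#' @return An object of class `stimulus_field`.
#' @export
stimulus_field <- function(S, n_min = 1L, t0 = 1L, meta = list()) {
  S <- as.matrix(S)
  if (!all(is.finite(S))) stop("stimulus values must be finite")
  pre <- seq_len(min(ncol(S), max(0L, t0 - n_min)))
  if (length(pre) && any(S[, pre] != 0))
    stop("stimulus must be zero before t0")
  structure(S, n_min = as.integer(n_min), t0 = as.integer(t0),
            meta = meta, class = "stimulus_field")
}

#' @export
print.stimulus_field <- function(x, ...) {
  cat(sprintf("<stimulus_field> %d neurons x %d steps, times %d..%d, t0=%d, max=%g\n",
              nrow(x), ncol(x), attr(x, "n_min"),
              attr(x, "n_min") + ncol(x) - 1L, attr(x, "t0"), max(x)))
  invisible(x)
}

#' Values of a stimulus field at arbitrary times
#'
#' @param stimulus a [stimulus_field()] or `NULL`.
#' @param times integer vector of time indices.
#' @return `N x length(times)` matrix; zero outside the stored window, or
#'   for a `NULL` stimulus a 0-row matrix is not returned -- callers pass
#'   `NULL` through explicitly.
#' @keywords internal
#' @export
stimulus_values <- function(stimulus, times) {
  n_min <- attr(stimulus, "n_min")
  L <- ncol(stimulus)
  out <- matrix(0, nrow(stimulus), length(times))
  j <- times - n_min + 1L
  ok <- j >= 1L & j <= L
  if (any(ok)) out[, ok] <- unclass(stimulus)[, j[ok], drop = FALSE]
  out
}

# align a stimulus field onto a raster's column grid (zero-padded)
stimulus_matrix <- function(stimulus, raster) {
  if (is.null(stimulus)) return(matrix(0, nrow(raster), ncol(raster)))
  if (nrow(stimulus) != nrow(raster))
    stop("stimulus and raster disagree on neuron count")
  stimulus_values(stimulus, raster_n_min(raster) + seq_len(ncol(raster)) - 1L)
}

#' Moving Gaussian stimulus on a 1-D lattice
#'
#' Samples the travelling pulse
#' \deqn{S(x, t) = \frac{A}{\sqrt{2\pi}\,\Delta}
#'       \exp\Big(-\frac{(x - x_{start} - v t)^2}{2\Delta^2}\Big)}
#' onto the neuron/time grid: neuron `k` sits at \eqn{x_k = k\,dx} and the
#' pulse clock starts at onset, \eqn{t = (n - t_0)\, b} for step
#' \eqn{n \ge t_0}; the field is zero before `t0`.  Only the ratio
#' \eqn{v\,b/dx} matters on the grid.  The spatial integral of the pulse is
#' `A` (Gaussian normalization).
#'
#' @param A amplitude (>= 0); `A = 0` gives an all-zero field.
#' @param Delta spatial width (mm), standard deviation of the pulse.
#' @param v propagation speed (mm/s), left to right.
#' @param dx lattice spacing (mm).
#' @param b duration of one time step (s).
#' @param N number of lattice neurons.
#' @param t0 onset step on the analysis clock.
#' @param T_steps last time step of the field (the grid covers
#'   `1 - burn_in .. T_steps`).
#' @param burn_in number of pre-analysis steps included (all-zero columns).
#' @param x_start pulse centre position (mm) at onset; default 0, i.e. just
#'   left of the lattice.
#' @return A [stimulus_field()].
#' @export
moving_gaussian_stimulus <- function(A, Delta, v, dx, b, N, t0, T_steps,
                                     burn_in = 0L, x_start = 0) {
  stopifnot(A >= 0, Delta > 0, b > 0, dx > 0, T_steps >= t0)
  n_min <- 1L - as.integer(burn_in)
  times <- n_min:T_steps
  S <- matrix(0, N, length(times))
  xk <- seq_len(N) * dx
  on <- times >= t0
  tt <- (times[on] - t0) * b
  centre <- x_start + v * tt
  S[, on] <- (A / (sqrt(2 * pi) * Delta)) *
    exp(-outer(xk, centre, "-")^2 / (2 * Delta^2))
  stimulus_field(S, n_min = n_min, t0 = t0,
                 meta = list(A = A, Delta = Delta, v = v, dx = dx, b = b,
                             x_start = x_start))
}

#' Write a stimulus field as a CSV matrix
#'
#' Neurons in rows, one column per time step; column names carry the time
#' index (`t<n>`).
#' @param stimulus a [stimulus_field()].
#' @param file output path.
#' @export
write_stimulus_csv <- function(stimulus, file) {
  M <- unclass(stimulus)
  colnames(M) <- paste0("t", attr(stimulus, "n_min") + seq_len(ncol(M)) - 1L)
  write.csv(cbind(neuron = seq_len(nrow(M)) - 1L, as.data.frame(M)), file,
            row.names = FALSE, quote = FALSE)
  invisible(file)
}
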