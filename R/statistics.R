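#' Response trace container
#'
#' A tidy record of a time-dependent change in an observable average:
#' a data frame with columns `n` (time step), `value`, `stderr` (NA for
#' exact/deterministic traces), `method` (one of `"empirical"`, `"order1"`,
#' `"hc1"`, `"exact"`) and `observable`.
#'
#' @param n,value,stderr,method,observable column values.
#' @return A `data.frame` with class `response_trace` prepended.
#' @export
response_trace <- function(n, value, stderr = NA_real_, method = "empirical",
                           observable = "observable") {
  out <- data.frame(n = as.integer(n), value = as.numeric(value),
                    stderr = stderr, method = method, observable = observable)
  class(out) <- c("response_trace", "data.frame")
  out
}

#' Ensemble average of an observable
#'
#' Trial average \eqn{(1/M)\sum_m f(n, \omega^{(m)})} at each requested
#' time, with its standard error \eqn{s/\sqrt{M}}.  This is the estimator
#' for non-stationary (stimulus-evoked) averages, where time averaging is
#' not available.
#'
#' @param f observable (see [eval_observable()]).
#' @param ensemble a `trial_ensemble`.
#' @param times anchor time(s).
#' @return Data frame with columns `n`, `value`, `stderr`.
#' @export
ensemble_average <- function(f, ensemble, times) {
  if (ensemble$M < 1L) stop("empty ensemble")
  v <- eval_observable(f, ensemble, times)
  se <- if (ensemble$M > 1L) apply(v, 1, sd) / sqrt(ensemble$M) else NA_real_
  data.frame(n = as.integer(times), value = rowMeans(v), stderr = se)
}

#' Spontaneous (stationary) correlation
#'
#' Centered lagged correlation under the spontaneous measure,
#' \eqn{C^{(sp)}[f(t+m,\cdot), g(t,\cdot)] = E[f(t+m)\,g(t)] - E[f]E[g]},
#' estimated by pooling over trials *and* over all valid anchor times
#' (stationarity of the spontaneous chain).  The standard error comes from
#' the dispersion of per-trial estimates (time samples within a trial are
#' autocorrelated, trials are independent).
#'
#' @param f,g observables (see [eval_observable()]).
#' @param lag non-negative integer `m`: `f` anchored `m` steps after `g`.
#' @param ensemble a spontaneous `trial_ensemble`.
#' @param times anchor times for `g`; default all post-burn-in times that
#'   keep `f`'s window inside the raster.
#' @return List with `value`, `stderr`, `n_anchors`.
#' @export
spontaneous_correlation <- function(f, g, lag, ensemble, times = NULL) {
  stopifnot(lag >= 0)
  if (is.null(times)) {
    lo <- max(1L, ensemble$n_min + observable_max_lag(g))
    hi <- ensemble$T_steps - lag
    if (hi < lo) stop("window too short for this lag")
    times <- lo:hi
  }
  fv <- eval_observable(f, ensemble, times + lag)   # T' x M
  gv <- eval_observable(g, ensemble, times)
  fbar <- mean(fv); gbar <- mean(gv)
  per_trial <- colMeans(fv * gv) - fbar * gbar
  list(value = mean(colMeans(fv * gv)) - fbar * gbar,
       stderr = if (ensemble$M > 1) sd(per_trial) / sqrt(ensemble$M) else NA_real_,
       n_anchors = length(times))
}

#' Empirical response to a stimulus
#'
#' \eqn{\delta\mu^{(exp)}_f(n) = \langle f(n)\rangle_{stim} -
#' \langle f \rangle_{sp}}: the per-time trial average over the
#' stimulus-driven ensemble minus the stationary spontaneous average
#' (pooled over trials and time).  The trace is zero (within CLT bands)
#' before the stimulus onset.
#'
#' @param f observable.
#' @param spont_ensemble,stim_ensemble spontaneous and stimulus-driven
#'   `trial_ensemble`s sharing parameters and grid.
#' @param times evaluation times; default the post-burn-in window.
#' @return A [response_trace()] with method `"empirical"`; the combined
#'   standard error adds the (small) spontaneous-baseline error in
#'   quadrature.
#' @export
empirical_response <- function(f, spont_ensemble, stim_ensemble, times = NULL) {
  p1 <- spont_ensemble$params; p2 <- stim_ensemble$params
  if (!isTRUE(all.equal(p1, p2)))
    stop("ensembles must share network parameters")
  if (spont_ensemble$n_min != stim_ensemble$n_min)
    stop("ensembles must share the time grid")
  if (is.null(times)) {
    lo <- max(1L, stim_ensemble$n_min + observable_max_lag(f))
    times <- lo:stim_ensemble$T_steps
  }
  stim_avg <- ensemble_average(f, stim_ensemble, times)
  base_times <- max(1L, spont_ensemble$n_min + observable_max_lag(f)):
    spont_ensemble$T_steps
  fv <- eval_observable(f, spont_ensemble, base_times)
  base <- mean(fv)
  base_se <- if (spont_ensemble$M > 1)
    sd(colMeans(fv)) / sqrt(spont_ensemble$M) else 0
  response_trace(times, stim_avg$value - base,
                 stderr = sqrt(stim_avg$stderr^2 + base_se^2),
                 method = "empirical", observable = observable_label(f))
}

#' Squared distance between two response traces
#'
#' \eqn{d^2(a, b) = \sum_n (a(n) - b(n))^2} over the common time window --
#' no square root and no normalization.
#'
#' @param trace_a,trace_b [response_trace()] objects (or data frames with
#'   columns `n`, `value`).
#' @return Non-negative scalar.
#' @export
d2_distance <- function(trace_a, trace_b) {
  common <- intersect(trace_a$n, trace_b$n)
  if (length(common) == 0L) stop("traces share no time window")
  a <- trace_a$value[match(common, trace_a$n)]
  b <- trace_b$value[match(common, trace_b$n)]
  sum((a - b)^2)
}

#' Write traces or kernels as tidy CSV
#'
#' @param x a [response_trace()] (written as-is) or a `response_kernel`
#'   (long format: columns `neuron`, `m`, `value`, `method`, `observable`).
#' @param file output path.
#' @export
write_trace_csv <- function(x, file) {
  if (inherits(x, "response_kernel")) {
    long <- data.frame(neuron = rep(seq_len(nrow(x$K)), ncol(x$K)),
                       m = rep(seq_len(ncol(x$K)), each = nrow(x$K)),
                       value = as.vector(x$K),
                       method = x$method, observable = x$observable)
    write.csv(long, file, row.names = FALSE, quote = FALSE)
  } else {
    write.csv(as.data.frame(x), file, row.names = FALSE, quote = FALSE)
  }
  invisible(file)
}
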