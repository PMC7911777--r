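# Shared internal machinery: conditional-mean voltage fields across a whole
# ensemble, vectorized over trials (the recursion runs over time only).
# Returns, for each requested anchor time t (spike step), arrays indexed
# [neuron, time, trial]:
#   x_sp    spontaneous threshold distance X^sp deciding the spike at t
#   delta_x stimulus part (NULL when the ensemble carries no stimulus matrix)
#   s       integrated-noise std
#   omega   the spikes at t
ensemble_fields <- function(ensemble, times, stimulus = NULL) {
  p <- ensemble$params
  N <- p$N; M <- ensemble$M; g <- p$gamma
  L <- dim(ensemble$omega)[2]
  all_times <- ensemble$n_min + seq_len(L) - 1L
  stopifnot(all(times %in% all_times[-1L]))   # need one step of history
  S <- if (is.null(stimulus)) NULL else
    stimulus_values(stimulus, all_times)
  nt <- length(times)
  x_sp <- s_arr <- om <- array(0, dim = c(N, nt, M))
  dx <- if (is.null(S)) NULL else array(0, dim = c(N, nt, M))
  v <- matrix(0, N, M); vS <- matrix(0, N, M); s2 <- matrix(0, N, M)
  keep_idx <- match(times, all_times)
  out_pos <- 1L
  for (j in 2:L) {
    om_prev <- matrix(ensemble$omega[, j - 1L, ], N, M)
    keep <- 1 - om_prev
    v <- g * v * keep + p$W %*% om_prev + p$I0
    s2 <- g^2 * s2 * keep + p$sigma_B^2
    if (!is.null(S)) vS <- g * vS * keep + S[, j - 1L]
    if (out_pos <= nt && j == keep_idx[out_pos]) {
      s_here <- sqrt(s2)
      x_sp[, out_pos, ] <- (p$theta - v) / s_here
      if (!is.null(S)) dx[, out_pos, ] <- -vS / s_here
      s_arr[, out_pos, ] <- s_here
      om[, out_pos, ] <- ensemble$omega[, j, ]
      out_pos <- out_pos + 1L
    }
  }
  list(x_sp = x_sp, delta_x = dx, s = s_arr, omega = om, times = times)
}

#' Per-neuron susceptibility of the potential
#'
#' \eqn{\zeta_k(r-1,\omega) = H^{(1)}_k(r,\omega) / \sigma_k(r-1,\omega)}
#' with \eqn{H^{(1)}_k(r,\omega) = \omega_k(r)\, a^{(1)}(X^{sp}_k(r-1,\omega))
#' + (1-\omega_k(r))\, b^{(1)}(X^{sp}_k(r-1,\omega))}: the derivative of the
#' normalized potential of neuron `k` at step `r` with respect to a unit
#' stimulus-induced voltage shift, evaluated on a spontaneous raster.
#'
#' @param params a [network_params()].
#' @param raster a spontaneous [spike_raster()].
#' @param k neuron index.
#' @param r spike step; the label of the returned value is `r - 1`.
#' @return Scalar.
#' @export
zeta <- function(params, raster, k, r) {
  x <- x_threshold_distance(params, raster, NULL, k, r - 1L)
  d <- derivative_a_b(1, x)
  wk <- unclass(raster)[k, raster_col(raster, r)]
  h1 <- if (wk == 1) d$a else d$b
  h1 / integrated_noise_std(params, raster, k, r - 1L)
}

# zeta over an ensemble: array [neuron, anchor, trial]; anchor t reads the
# spike at t and the spontaneous history through t - 1
zeta_array <- function(ensemble, times) {
  fl <- ensemble_fields(ensemble, times)
  d <- derivative_a_b(1, fl$x_sp)
  (fl$omega * d$a + (1 - fl$omega) * d$b) / fl$s
}

new_response_kernel <- function(K, method, observable, nu, horizon, D, params) {
  structure(list(K = K, method = method, observable = observable, nu = nu,
                 horizon = horizon, D = D, gamma = params$gamma,
                 params = params),
            class = "response_kernel")
}

#' @export
print.response_kernel <- function(x, ...) {
  cat(sprintf("<response_kernel> method=%s, %d neurons x %d columns (D=%d), observable: %s\n",
              x$method, nrow(x$K), ncol(x$K), x$D, x$observable))
  invisible(x)
}

# shared estimator for both kernels: correlate f (anchored m - 1 steps after
# the susceptibility) with a per-neuron susceptibility array over trials+time
estimate_kernel <- function(f, ensemble, D, susc, anchors) {
  N <- ensemble$params$N
  K <- matrix(0, N, D + 1L)
  f_all <- eval_observable(f, ensemble, c(outer(anchors, 0:D, "+")))
  nt <- length(anchors)
  for (m in seq_len(D + 1L)) {
    rows <- (m - 1L) * nt + seq_len(nt)
    fm <- f_all[rows, , drop = FALSE]            # f at anchors + m - 1
    fbar <- mean(fm)
    for (k in seq_len(N)) {
      z <- matrix(susc[k, , ], nt, ncol(fm))
      K[k, m] <- mean(z * fm) - mean(z) * fbar
    }
  }
  K
}

kernel_anchor_times <- function(f, ensemble, D) {
  lo <- max(1L, ensemble$n_min + 1L)
  hi <- ensemble$T_steps - D
  if (hi < lo) stop("ensemble window too short for depth D")
  lo:hi
}

#' First-order response kernel
#'
#' The `N x (D+1)` matrix of spontaneous correlations
#' \eqn{K^{(1)}_{k,m} = C^{(sp)}[f(m,\cdot), \zeta_k(0,\cdot)]} between the
#' target observable anchored `m - 1` steps ahead and the potential
#' susceptibility [zeta()], estimated by pooling trials and anchor times of
#' a spontaneous ensemble.  Firing rates \eqn{\nu_k} and mean-field horizons
#' are attached for use by [predict_order1()].
#'
#' @param f target observable (monomial, timed observable, or function).
#' @param spont_ensemble spontaneous `trial_ensemble`.
#' @param D truncation depth of the response sum (kernel columns
#'   `m = 1..D+1`).
#' @param horizon_cap clip for the mean-field horizon; default `10 * D`.
#' @return A `response_kernel` with method `"order1"`.
#' @export
kernel_order1 <- function(f, spont_ensemble, D = 10L,
                          horizon_cap = 10L * D) {
  anchors <- kernel_anchor_times(f, spont_ensemble, D)
  z <- zeta_array(spont_ensemble, anchors)
  K <- estimate_kernel(f, spont_ensemble, D, z, anchors)
  rates <- estimate_firing_rates(spont_ensemble, horizon_cap)
  new_response_kernel(K, "order1", observable_label(f), rates$nu,
                      rates$horizon, as.integer(D), spont_ensemble$params)
}

#' Lowest-order Hammersley-Clifford kernel
#'
#' Same construction as [kernel_order1()] with the susceptibility replaced
#' by the bare spike variable:
#' \eqn{K^{(HC1)}_{k,m} = C^{(sp)}[f(m,\cdot), \omega_k(0,\cdot)]} -- plain
#' spike-observable correlations, obtainable without knowing the potential.
#'
#' @inheritParams kernel_order1
#' @return A `response_kernel` with method `"hc1"`.
#' @export
kernel_hc1 <- function(f, spont_ensemble, D = 10L, horizon_cap = 10L * D) {
  anchors <- kernel_anchor_times(f, spont_ensemble, D)
  cols <- ensemble_cols(spont_ensemble, anchors)
  om <- spont_ensemble$omega[, cols, , drop = FALSE]
  K <- estimate_kernel(f, spont_ensemble, D, om, anchors)
  rates <- estimate_firing_rates(spont_ensemble, horizon_cap)
  new_response_kernel(K, "hc1", observable_label(f), rates$nu,
                      rates$horizon, as.integer(D), spont_ensemble$params)
}

#' HC1 effective threshold and prefactor
#'
#' Mean-field constants of the lowest-order Hammersley-Clifford predictor:
#' stationary noise scale \eqn{\sigma_\infty = \sigma_B/\sqrt{1-\gamma^2}},
#' effective threshold \eqn{\theta_L = (\theta - I_0/(1-\gamma))/\sigma_\infty}
#' and \eqn{\gamma^{(1)} = a^{(1)}(\theta_L) - b^{(1)}(\theta_L)} (the
#' coefficient of the degree-1 monomial in the HC expansion of \eqn{\zeta};
#' the constant term drops because centered correlations annihilate it).
#'
#' @param params a [network_params()].
#' @return List with `sigma_inf`, `theta_L`, `gamma1`, and the trace
#'   prefactor `scale = gamma1 / sigma_inf`.
#' @export
hc1_prefactor <- function(params) {
  sigma_inf <- params$sigma_B / sqrt(1 - params$gamma^2)
  theta_L <- (params$theta - params$I0 / (1 - params$gamma)) / sigma_inf
  d <- derivative_a_b(1, theta_L)
  gamma1 <- d$a - d$b
  list(sigma_inf = sigma_inf, theta_L = theta_L, gamma1 = gamma1,
       scale = gamma1 / sigma_inf)
}

# core predictor:
#   delta_mu(n) = -scale * sum_k sum_{m=1}^{D+1} sum_{l=0}^{h_k}
#                  gamma^l K[k, m] S_k(n - m - l)
predict_from_kernel <- function(kernel, stimulus, times, scale = 1) {
  g <- kernel$gamma
  N <- nrow(kernel$K)
  if (nrow(stimulus) != N) stop("kernel and stimulus disagree on N")
  out <- numeric(length(times))
  for (k in seq_len(N)) {
    for (m in seq_len(ncol(kernel$K))) {
      if (kernel$K[k, m] == 0) next
      for (l in 0:kernel$horizon[k]) {
        gl <- if (l == 0L) 1 else g^l
        if (gl == 0) break
        sv <- stimulus_values(stimulus, times - m - l)[k, ]
        out <- out - scale * gl * kernel$K[k, m] * sv
      }
    }
  }
  out
}

#' First-order linear-response prediction
#'
#' Convolves the stimulus with the first-order kernel:
#' \deqn{\delta\mu^{(1)}_f(n) = -\sum_{k=1}^N \sum_{m=1}^{D+1}
#'  \sum_{l=0}^{h_k} \gamma^l K^{(1)}_{k,m} S_k(n-m-l),}
#' where the inner geometric sum implements the mean-field replacement of
#' the last reset time by the mean inter-spike interval \eqn{h_k \approx
#' 1/\nu_k}.  The trace is exactly linear in the stimulus amplitude and
#' exactly zero before the onset `t0` (the sums only touch the stimulus at
#' earlier times).
#'
#' @param kernel a `response_kernel` from [kernel_order1()] (or an
#'   oracle-exact kernel with method `"order1"`).
#' @param stimulus a [stimulus_field()].
#' @param times evaluation times; default `1 ..` end of the stimulus grid.
#' @return A [response_trace()] with method `"order1"`.
#' @export
predict_order1 <- function(kernel, stimulus, times = NULL) {
  stopifnot(kernel$method == "order1")
  if (is.null(times))
    times <- 1:(attr(stimulus, "n_min") + ncol(stimulus) - 1L)
  response_trace(times, predict_from_kernel(kernel, stimulus, times, 1),
                 stderr = NA_real_, method = "order1",
                 observable = kernel$observable)
}

#' Lowest-order Hammersley-Clifford prediction
#'
#' \deqn{\delta\mu^{(HC1)}_f(n) = -\frac{\gamma^{(1)}}{\sigma_\infty}
#'  \sum_{k}\sum_{m=1}^{D+1}\sum_{l=0}^{h_k}\gamma^l K^{(HC1)}_{k,m}
#'  S_k(n-m-l),}
#' the fluctuation-dissipation-like predictor that only needs plain spike
#' correlations plus the mean-field constants of [hc1_prefactor()].
#'
#' @param f target observable.
#' @param spont_ensemble spontaneous `trial_ensemble`.
#' @param params a [network_params()] (for the prefactor).
#' @param stimulus a [stimulus_field()].
#' @param D truncation depth.
#' @param kernel optionally a precomputed `"hc1"` kernel (skips estimation).
#' @param times evaluation times; default as in [predict_order1()].
#' @return A [response_trace()] with method `"hc1"`.
#' @export
predict_hc1 <- function(f, spont_ensemble, params, stimulus, D = 10L,
                        kernel = NULL, times = NULL) {
  if (is.null(kernel)) kernel <- kernel_hc1(f, spont_ensemble, D)
  stopifnot(kernel$method == "hc1")
  if (is.null(times))
    times <- 1:(attr(stimulus, "n_min") + ncol(stimulus) - 1L)
  pf <- hc1_prefactor(params)
  response_trace(times, predict_from_kernel(kernel, stimulus, times, pf$scale),
                 stderr = NA_real_, method = "hc1",
                 observable = kernel$observable)
}

#' Model-agnostic first-order response
#'
#' Implements the general fluctuation-dissipation form
#' \eqn{\delta^{(1)} f(n) = \sum_{r=n-D}^{n} C^{(sp)}[f(n,\cdot),
#' \delta\phi(r,\cdot)]} for a user-supplied potential perturbation
#' \eqn{\delta\phi}, estimated over a spontaneous ensemble (trial pooling
#' only: \eqn{\delta\phi} carries explicit time dependence).
#'
#' @param f target observable.
#' @param delta_phi either a function `(raster, times) -> vector` or a list
#'   `list(values = matrix, times = vector)` with one row per time, one
#'   column per trial (as produced by [lif_delta_phi_order1()]).
#' @param spont_ensemble spontaneous `trial_ensemble`.
#' @param times evaluation times.
#' @param D truncation depth of the `r`-sum.
#' @return A [response_trace()] with method `"order1"`.
#' @export
general_response <- function(f, delta_phi, spont_ensemble, times, D = 10L) {
  r_times <- (min(times) - D):max(times)
  if (min(r_times) - 1L < spont_ensemble$n_min + 1L)
    stop("window exceeds ensemble history")
  if (is.function(delta_phi)) {
    dp <- matrix(0, length(r_times), spont_ensemble$M)
    for (m in seq_len(spont_ensemble$M))
      dp[, m] <- delta_phi(ensemble_raster(spont_ensemble, m), r_times)
  } else {
    idx <- match(r_times, delta_phi$times)
    if (anyNA(idx)) stop("delta_phi does not cover the required window")
    dp <- delta_phi$values[idx, , drop = FALSE]
  }
  fv <- eval_observable(f, spont_ensemble, times)
  M <- spont_ensemble$M
  vals <- numeric(length(times))
  cum <- apply(dp, 2, cumsum)
  for (i in seq_along(times)) {
    hi <- match(times[i], r_times)
    lo <- hi - D
    win <- cum[hi, ] - if (lo > 1L) cum[lo - 1L, ] else 0
    vals[i] <- mean(fv[i, ] * win) - mean(fv[i, ]) * mean(win)
  }
  response_trace(times, vals, stderr = NA_real_, method = "order1",
                 observable = observable_label(f))
}

#' First-order LIF potential perturbation over an ensemble
#'
#' Builds \eqn{\delta\phi^{(1)}(r,\omega) = -\sum_k \zeta_k(r-1,\omega)
#' \sum_{l=0}^{h_k} \gamma^l S_k(r-1-l)} on every trial of a spontaneous
#' ensemble, for use with [general_response()].
#'
#' @param spont_ensemble spontaneous `trial_ensemble`.
#' @param stimulus a [stimulus_field()].
#' @param times the potential time steps `r` to cover.
#' @param horizon per-neuron mean-field horizon; default from
#'   [estimate_firing_rates()].
#' @return List with `values` (times x trials) and `times`.
#' @export
lif_delta_phi_order1 <- function(spont_ensemble, stimulus, times,
                                 horizon = NULL) {
  p <- spont_ensemble$params
  if (is.null(horizon)) horizon <- estimate_firing_rates(spont_ensemble)$horizon
  z <- zeta_array(spont_ensemble, times)         # N x T x M
  cvec <- matrix(0, p$N, length(times))          # integrated stimulus weight
  for (k in seq_len(p$N)) {
    for (l in 0:horizon[k]) {
      gl <- if (l == 0L) 1 else p$gamma^l
      if (gl == 0) break
      cvec[k, ] <- cvec[k, ] + gl * stimulus_values(stimulus, times - 1L - l)[k, ]
    }
  }
  vals <- matrix(0, length(times), spont_ensemble$M)
  for (k in seq_len(p$N))
    vals <- vals - matrix(z[k, , ], length(times)) * cvec[k, ]
  list(values = vals, times = times)
}

#' Linear-response validity diagnostics
#'
#' Reports (i) the fraction of (neuron, time, trial) points at which the
#' spike probability \eqn{\Pi(X_k)} leaves the band
#' \eqn{[\epsilon, 1-\epsilon]} (the sigmoid saturates there and the
#' expansion of the potential degrades), and (ii) the fraction violating the
#' second-order smallness condition
#' \eqn{|\delta X_k| \le slack \cdot 2|X^{sp}_k + a^{(1)}(X^{sp}_k)|}.
#' With no stimulus the second fraction is exactly zero.
#'
#' @param ensemble a `trial_ensemble` (typically stimulus-driven).
#' @param stimulus the stimulus applied to it (or `NULL`).
#' @param epsilon saturation band parameter (default 0.01).
#' @param slack admissible ratio before a point is flagged (default 0.1).
#' @param times evaluation times; default the post-burn-in window.
#' @param max_trials subsample cap on trials (diagnostics only need
#'   moderate precision).
#' @return List with `frac_saturated`, `frac_expansion_violated`,
#'   `n_points`.
#' @export
validity_diagnostics <- function(ensemble, stimulus = NULL, epsilon = 0.01,
                                 slack = 0.1, times = NULL,
                                 max_trials = 200L) {
  if (is.null(times)) times <- seq_len(ensemble$T_steps)
  ens <- ensemble
  if (ensemble$M > max_trials) {
    keep <- seq_len(max_trials)
    ens <- ensemble
    ens$omega <- ensemble$omega[, , keep, drop = FALSE]
    ens$M <- as.integer(max_trials)
  }
  fl <- ensemble_fields(ens, times, stimulus = stimulus)
  dx <- if (is.null(fl$delta_x)) 0 * fl$x_sp else fl$delta_x
  x <- fl$x_sp + dx
  p <- pi_tail(x)
  a1 <- derivative_a_b(1, fl$x_sp)$a
  bound <- 2 * abs(fl$x_sp + a1)
  list(frac_saturated = mean(p < epsilon | p > 1 - epsilon),
       frac_expansion_violated = mean(abs(dx) > slack * bound),
       n_points = length(p))
}
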