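#' Default experiment configuration
#'
#' The lattice study: `N = 30` neurons on a chain with nearest-neighbour
#' excitation `w+ = 0.2` and second-neighbour inhibition `w- = 2`
#' (magnitude), `theta = 1`, `gamma = 0.6` (decay time
#' \eqn{\tau_\gamma \approx 2} steps), response truncation depth `D = 10`,
#' lattice spacing `dx = 1` mm and time bin `b = 10` ms.  The baseline input
#' `I0` is calibrated to a target spontaneous rate (0.3/step by default) and
#' the noise scale defaults to `sigma_B = 1`, comparable to the threshold,
#' so that the strong second-neighbour inhibition modulates activity rather
#' than silencing joint spikes outright (the delayed-pairwise observable
#' needs a non-degenerate baseline).  Run sizes default to the
#' reduced scale (`M = 2000` trials of `T = 200` steps, minutes on one CPU);
#' pass `full_scale = TRUE` for `M = 10000`.  The pulse speed default
#' (16 mm/s) makes the Gaussian pulse traverse the 30 mm lattice within the
#' 200-step window (speed and window only enter through `v * b / dx`).
#'
#' Observables: the firing rate of the centre neuron
#' \eqn{f(n,\omega) = \omega_{k_c}(n)}, and the delayed pairwise product
#' \eqn{\omega_{k_c-2}(n-3)\,\omega_{k_c}(n)}, with `kc = N/2`.
#'
#' @param full_scale use `M = 10000` trials.
#' @return Nested configuration list.
#' @export
default_experiment_config <- function(full_scale = FALSE) {
  list(
    network = list(N = 30L, dx_mm = 1, w_plus = 0.2, w_minus = 2,
                   gamma = 0.6, theta = 1, sigma_B = 1,
                   I0 = NULL, target_rate = 0.3),
    stimulus = list(Delta_mm = 1, v_mm_per_s = 16, b_ms = 10,
                    t0 = 11L, x_start_mm = 0),
    observables = list(
      list(name = "rate_center", neurons = 15L, lags = 0L),
      list(name = "pair_delay3", neurons = c(13L, 15L), lags = c(3L, 0L))),
    run = list(T = 200L, M = if (full_scale) 10000L else 2000L,
               burn_in = NULL, D = 10L, master_seed = 1L),
    amplitudes = c(0.5, 1, 1.5, 2))
}

#' Read an experiment configuration file
#'
#' YAML or JSON (by extension), merged over [default_experiment_config()]
#' so partial files only need to state what they change.
#'
#' @param path configuration file.
#' @return Configuration list.
#' @export
read_experiment_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  # YAML 1.1 reads a bare `N:` key as boolean FALSE; undo that
  if (!is.null(cfg$network) && "FALSE" %in% names(cfg$network))
    names(cfg$network)[names(cfg$network) == "FALSE"] <- "N"
  base <- default_experiment_config()
  for (sec in c("network", "stimulus", "run"))
    if (!is.null(cfg[[sec]])) base[[sec]] <- modifyList(base[[sec]], cfg[[sec]])
  if (!is.null(cfg$observables)) base$observables <- cfg$observables
  if (!is.null(cfg$amplitudes)) base$amplitudes <- cfg$amplitudes
  base
}

config_params <- function(config) {
  nw <- config$network
  I0 <- nw$I0
  if (is.null(I0))
    I0 <- calibrate_baseline_input(nw$target_rate, nw$gamma, nw$theta,
                                   nw$sigma_B)
  network_params(N = nw$N, W = lattice_weights(nw$N, nw$w_plus, nw$w_minus),
                 gamma = nw$gamma, theta = nw$theta, I0 = I0,
                 sigma_B = nw$sigma_B)
}

config_observable <- function(spec) {
  monomial(spec$neurons, spec$lags, label = spec$name)
}

#' Run a configuration-driven response experiment
#'
#' Full pipeline: simulate a spontaneous ensemble, estimate both response
#' kernels for every configured observable, then for every stimulus
#' amplitude simulate a stimulus-driven ensemble and compute the empirical
#' response, the two predicted responses, their `d2` distances to the
#' empirical trace, and the validity diagnostics.  All randomness derives
#' from `config$run$master_seed`, so identical configurations reproduce
#' identical outputs.
#'
#' @param config a list shaped like [default_experiment_config()].
#' @param verbose log progress to stderr.
#' @return A bundle: list with `config`, `params`, `rates`, `results` (one
#'   row per observable x amplitude with `d2_order1`, `d2_hc1`, diagnostics)
#'   and `traces` (named list of [response_trace()] data frames, methods
#'   stacked).
#' @export
run_experiment <- function(config = default_experiment_config(),
                           verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  params <- config_params(config)
  run <- config$run
  burn_in <- if (is.null(run$burn_in))
    default_burn_in(params, run$D) else run$burn_in
  st <- config$stimulus
  say("spontaneous ensemble: M=%d T=%d burn_in=%d", run$M, run$T, burn_in)
  spont <- simulate_ensemble(params, run$T, burn_in, NULL, run$M,
                             run$master_seed)
  rates <- estimate_firing_rates(spont, horizon_cap = 10L * run$D)
  obs <- lapply(config$observables, config_observable)
  say("estimating kernels (D=%d)", run$D)
  k1 <- lapply(obs, kernel_order1, spont_ensemble = spont, D = run$D)
  kh <- lapply(obs, kernel_hc1, spont_ensemble = spont, D = run$D)
  results <- NULL
  traces <- list()
  for (ai in seq_along(config$amplitudes)) {
    A <- config$amplitudes[ai]
    stim <- moving_gaussian_stimulus(
      A = A, Delta = st$Delta_mm, v = st$v_mm_per_s, dx = config$network$dx_mm,
      b = st$b_ms / 1000, N = params$N, t0 = st$t0, T_steps = run$T,
      burn_in = burn_in, x_start = st$x_start_mm)
    say("amplitude %g: stimulus ensemble", A)
    stim_ens <- simulate_ensemble(params, run$T, burn_in, stim, run$M,
                                  run$master_seed + ai * (run$M + 1000L))
    diag <- validity_diagnostics(stim_ens, stim)
    for (oi in seq_along(obs)) {
      f <- obs[[oi]]
      times <- max(1L, 1L + observable_max_lag(f)):run$T
      emp <- empirical_response(f, spont, stim_ens, times)
      o1 <- predict_order1(k1[[oi]], stim, times)
      oh <- predict_hc1(f, spont, params, stim, run$D, kernel = kh[[oi]],
                        times = times)
      key <- sprintf("%s_A%g", f$label, A)
      traces[[key]] <- rbind(emp, o1, oh)
      results <- rbind(results, data.frame(
        observable = f$label, A = A,
        d2_order1 = d2_distance(o1, emp), d2_hc1 = d2_distance(oh, emp),
        frac_saturated = diag$frac_saturated,
        frac_expansion_violated = diag$frac_expansion_violated))
    }
  }
  list(config = config, params = params, rates = rates,
       kernels = list(order1 = k1, hc1 = kh), results = results,
       traces = traces)
}

#' Write an experiment bundle to disk
#'
#' Emits tidy CSVs (one trace file per observable/amplitude, one kernel
#' file per observable/method, a `d2_table.csv`) plus a JSON run manifest
#' carrying the full configuration, seeds and rate estimates -- enough
#' provenance to re-run exactly.
#'
#' @param bundle a [run_experiment()] result.
#' @param dir output directory (created if needed).
#' @export
write_experiment <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(bundle$results, file.path(dir, "d2_table.csv"),
            row.names = FALSE, quote = FALSE)
  for (key in names(bundle$traces))
    write_trace_csv(bundle$traces[[key]],
                    file.path(dir, paste0("trace_", key, ".csv")))
  for (mth in names(bundle$kernels))
    for (kn in bundle$kernels[[mth]])
      write_trace_csv(kn, file.path(
        dir, sprintf("kernel_%s_%s.csv", mth, kn$observable)))
  manifest <- list(config = bundle$config,
                   I0 = bundle$params$I0,
                   rates = bundle$rates$nu,
                   horizons = bundle$rates$horizon,
                   written = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Deterministic test fixtures
#'
#' Small, seed-reproducible assets used by the test-suite and for quick
#' demos:
#' * `"tiny-net"`: an oracle-checkable two-neuron network (`N = 2`,
#'   `gamma = 0`, asymmetric coupling) with chain depth `D = 2`, for which
#'   the depth-2 Markov oracle is exact, plus the parameters of a slow
#'   two-site Gaussian pulse.
#' * `"iid-raster"`: an independent Bernoulli(`p = 0.3`) raster (3 neurons,
#'   400 steps).
#' * `"lattice-demo"`: a reduced copy of [default_experiment_config()]
#'   (`N = 12`, `M = 200`, `T = 80`) for smoke tests.
#'
#' @param kind one of `"tiny-net"`, `"iid-raster"`, `"lattice-demo"`.
#' @param seed integer seed.
#' @return Fixture object (list or [spike_raster()]).
#' @export
make_fixture <- function(kind = c("tiny-net", "iid-raster", "lattice-demo"),
                         seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "tiny-net") {
    params <- network_params(
      N = 2L, W = rbind(c(0, 0.5), c(-0.3, 0)), gamma = 0,
      theta = 1, I0 = 0.6, sigma_B = 0.5)
    return(list(params = params, D = 2L,
                stimulus_spec = list(Delta = 1.5, v = 0.5, dx = 1, b = 1,
                                     x_start = 0),
                seed = as.integer(seed)))
  }
  if (kind == "iid-raster") {
    set.seed(seed)
    p <- 0.3
    omega <- matrix(as.integer(runif(3 * 400) < p), 3, 400)
    return(spike_raster(omega, n_min = 1L))
  }
  cfg <- default_experiment_config()
  cfg$network$N <- 12L
  cfg$observables <- list(
    list(name = "rate_center", neurons = 6L, lags = 0L))
  cfg$run$T <- 80L
  cfg$run$M <- 200L
  cfg$run$master_seed <- as.integer(seed)
  cfg
}

#' Build the tiny-network stimulus
#'
#' The two-site travelling pulse matching `make_fixture("tiny-net")`.
#'
#' @param fixture a `"tiny-net"` fixture.
#' @param A amplitude.
#' @param t0 onset step.
#' @param T_steps last step.
#' @param burn_in history steps.
#' @return A [stimulus_field()].
#' @export
tiny_net_stimulus <- function(fixture, A, t0, T_steps, burn_in = 0L) {
  ss <- fixture$stimulus_spec
  moving_gaussian_stimulus(A = A, Delta = ss$Delta, v = ss$v, dx = ss$dx,
                           b = ss$b, N = fixture$params$N, t0 = t0,
                           T_steps = T_steps, burn_in = burn_in,
                           x_start = ss$x_start)
}
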