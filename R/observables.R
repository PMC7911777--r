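#' Monomial observables
#'
#' A monomial is a product of spike variables
#' \eqn{m(t,\omega) = \prod_{(i,\tau) \in E} \omega_i(t - \tau)}: the
#' indicator that every listed neuron spiked at its stated lag before the
#' anchor time `t`.  The empty event set is the constant-1 monomial.  The
#' number of events is the monomial's degree and `1 + max(lag)` its range.
#'
#' @param neurons integer vector of neuron indices (1-based).
#' @param lags integer vector of the same length; lag `tau >= 0` means
#'   "`tau` steps before the anchor time" (so lag 0 reads the anchor step).
#' @param label optional identifier used in outputs.
#' @return Object of class `monomial`.
#' @examples
#' m <- monomial(c(1, 3), c(0, 3))  # omega_1(t) * omega_3(t-3)
#' @export
monomial <- function(neurons = integer(), lags = integer(), label = NULL) {
  neurons <- as.integer(neurons); lags <- as.integer(lags)
  stopifnot(length(neurons) == length(lags))
  if (length(neurons)) {
    stopifnot(all(neurons >= 1L), all(lags >= 0L))
    if (anyDuplicated(cbind(neurons, lags))) stop("duplicate events")
    o <- order(lags, neurons)
    neurons <- neurons[o]; lags <- lags[o]
  }
  if (is.null(label)) {
    label <- if (length(neurons) == 0L) "1" else
      paste(sprintf("w%d(t-%d)", neurons, lags), collapse = "*")
  }
  structure(list(neurons = neurons, lags = lags, label = label),
            class = "monomial")
}

#' @export
print.monomial <- function(x, ...) {
  cat(sprintf("<monomial> degree %d, range %d: %s\n", length(x$neurons),
              monomial_range(x), x$label))
  invisible(x)
}

monomial_range <- function(m) if (length(m$lags) == 0L) 1L else max(m$lags) + 1L

#' Evaluate a monomial on a raster
#'
#' @param m a [monomial()].
#' @param raster a [spike_raster()].
#' @param t anchor time(s); every `t - lag` must lie in the raster range.
#' @return 0/1 vector, one value per anchor time.
#' @export
monomial_eval <- function(m, raster, t) {
  out <- rep(1L, length(t))
  for (e in seq_along(m$neurons)) {
    cols <- raster_col(raster, t - m$lags[e])
    out <- out * unclass(raster)[m$neurons[e], cols]
  }
  out
}

#' Monomial index encoding
#'
#' Bijection between monomials over `N` neurons and range `R` (lags
#' `0..R-1`) and the integers `0 .. 2^(N*R)-1`: event `(i, tau)` occupies
#' bit `(i - 1) + N * tau`, and the index is the sum of `2^bit` over the
#' events.  The empty monomial maps to 0.
#'
#' @param m a [monomial()].
#' @param N neuron count of the encoding.
#' @param R range of the encoding (must be >= the monomial's range).
#' @return Integer index (as a double; exact up to `N*R <= 53` bits, guarded
#'   at 24).
#' @export
monomial_index <- function(m, N, R = monomial_range(m)) {
  stopifnot(N * R <= 24)
  if (length(m$neurons) == 0L) return(0)
  stopifnot(all(m$neurons <= N), all(m$lags < R))
  sum(2 ^ ((m$neurons - 1L) + N * m$lags))
}

#' @rdname monomial_index
#' @param l integer index in `0 .. 2^(N*R) - 1`.
#' @return `monomial_decode()` returns the [monomial()] with the events of
#'   the set bits of `l`.
#' @export
monomial_decode <- function(l, N, R) {
  stopifnot(N * R <= 24, l >= 0, l < 2^(N * R))
  bits <- which(bitwAnd(as.integer(l), bitwShiftL(1L, 0:(N * R - 1L))) != 0L) - 1L
  monomial(neurons = bits %% N + 1L, lags = bits %/% N)
}

# decode a configuration index into an N x R block matrix; column r holds
# lag R - r (last column = lag 0, the anchor step)
block_from_index <- function(l, N, R) {
  bits <- bitwAnd(bitwShiftR(as.integer(l), 0:(N * R - 1L)), 1L)
  lagmat <- matrix(bits, nrow = N)          # column tau+1 = lag tau
  lagmat[, R:1, drop = FALSE]
}

#' Hammersley-Clifford decomposition
#'
#' Writes an arbitrary function of spike blocks of range `R` over `N`
#' neurons exactly as a linear combination of the `2^(N*R)` monomials:
#' \eqn{f(\omega) = \sum_l f_l m_l(\omega)}.  Coefficients come from Mobius
#' inversion over the Boolean lattice of spike configurations:
#' \eqn{f_S = \sum_{T \subseteq S} (-1)^{|S|-|T|} f(T)}, where `f(T)` is `f`
#' evaluated on the block whose 1s sit exactly on `T`.
#'
#' @param f function taking an `N x R` 0/1 block matrix (columns oldest to
#'   newest, last column = anchor step) and returning a scalar.
#' @param N,R block dimensions; guarded at `N * R <= 24` bits.
#' @return Object of class `hc_decomposition`: list with `coefficients`
#'   (vector indexed by monomial index + 1), `N`, `R`.
#' @export
hc_decompose <- function(f, N, R) {
  nb <- N * R
  stopifnot(nb <= 24)
  vals <- vapply(0:(2^nb - 1), function(l) f(block_from_index(l, N, R)),
                 numeric(1))
  # in-place Mobius transform over subsets
  coef <- vals
  for (b in 0:(nb - 1L)) {
    stride <- 2^b
    idx <- which(bitwAnd(0:(2^nb - 1L), stride) != 0L)  # configs with bit b
    coef[idx] <- coef[idx] - coef[idx - stride]
  }
  structure(list(coefficients = coef, N = N, R = R),
            class = "hc_decomposition")
}

#' @export
print.hc_decomposition <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("<hc_decomposition> N=%d R=%d, %d of %d coefficients non-zero\n",
              x$N, x$R, nz, length(x$coefficients)))
  invisible(x)
}

#' Reconstruct a function value from its HC decomposition
#'
#' @param hc an [hc_decompose()] result.
#' @param block `N x R` 0/1 block matrix (columns oldest to newest).
#' @return The reconstructed scalar \eqn{\sum_l f_l m_l(block)}.
#' @export
hc_reconstruct <- function(hc, block) {
  # block index: bit (i-1) + N*tau set iff block[i, R - tau] == 1
  lagmat <- block[, hc$R:1, drop = FALSE]
  l <- sum(2 ^ (which(lagmat == 1) - 1L))
  u <- as.integer(l)
  idx <- 0:(2^(hc$N * hc$R) - 1L)
  sub <- which(bitwAnd(idx, u) == idx)       # monomials with events within block
  sum(hc$coefficients[sub])
}

#' Timed observables
#'
#' Wraps a monomial, a list of monomials with coefficients, or an
#' [hc_decompose()] result into an evaluable time-dependent observable
#' `f(t, omega)`, optionally modulated by a scalar time profile `c(t)`.
#' Causality is inherent: monomial lags are non-negative, so evaluation only
#' reads times `<= t`.
#'
#' @param base a `monomial`, a list of monomials, or an `hc_decomposition`.
#' @param coefficients numeric vector matching a list of monomials
#'   (default all 1).
#' @param profile `NULL` or a function of the anchor time returning a scalar
#'   multiplier.
#' @param label optional identifier.
#' @return Object of class `timed_observable` with fields `monomials`,
#'   `coefficients`, `profile`.
#' @export
timed_observable <- function(base, coefficients = NULL, profile = NULL,
                             label = NULL) {
  if (inherits(base, "monomial")) {
    mons <- list(base)
    coefs <- if (is.null(coefficients)) 1 else coefficients
    stopifnot(length(coefs) == 1L)
  } else if (inherits(base, "hc_decomposition")) {
    nz <- which(base$coefficients != 0)
    mons <- lapply(nz - 1L, monomial_decode, N = base$N, R = base$R)
    coefs <- base$coefficients[nz]
  } else if (is.list(base)) {
    stopifnot(all(vapply(base, inherits, logical(1), "monomial")))
    mons <- base
    coefs <- if (is.null(coefficients)) rep(1, length(base)) else coefficients
    stopifnot(length(coefs) == length(mons))
  } else stop("unsupported base")
  if (is.null(label))
    label <- paste(vapply(mons, `[[`, character(1), "label"), collapse = " + ")
  structure(list(monomials = mons, coefficients = coefs, profile = profile,
                 label = label),
            class = "timed_observable")
}

observable_label <- function(f) {
  if (inherits(f, "monomial") || inherits(f, "timed_observable")) f$label
  else if (is.function(f)) "function" else "observable"
}

observable_max_lag <- function(f) {
  if (inherits(f, "monomial"))
    return(if (length(f$lags)) max(f$lags) else 0L)
  if (inherits(f, "timed_observable"))
    return(max(vapply(f$monomials, observable_max_lag, integer(1))))
  0L
}

#' Evaluate an observable over a trial ensemble
#'
#' @param f a [monomial()], [timed_observable()], or a function
#'   `f(raster, t)` vectorized over `t`.
#' @param ensemble a `trial_ensemble`.
#' @param times anchor times (each `t - lag` must be within range).
#' @return `length(times) x M` matrix of observable values.
#' @export
eval_observable <- function(f, ensemble, times) {
  M <- ensemble$M
  if (inherits(f, "monomial")) {
    out <- matrix(1, length(times), M)
    for (e in seq_along(f$neurons)) {
      cols <- ensemble_cols(ensemble, times - f$lags[e])
      out <- out * ensemble$omega[f$neurons[e], cols, , drop = TRUE]
    }
    return(matrix(out, length(times), M))
  }
  if (inherits(f, "timed_observable")) {
    out <- matrix(0, length(times), M)
    for (i in seq_along(f$monomials))
      out <- out + f$coefficients[i] *
        eval_observable(f$monomials[[i]], ensemble, times)
    if (!is.null(f$profile))
      out <- out * vapply(times, f$profile, numeric(1))
    return(out)
  }
  if (is.function(f)) {
    out <- matrix(0, length(times), M)
    for (m in seq_len(M)) out[, m] <- f(ensemble_raster(ensemble, m), times)
    return(out)
  }
  stop("unsupported observable")
}
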