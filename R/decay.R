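#' Time binning of a TCSPC histogram
#'
#' Defines the periodic arrival-time axis: `n_bins` bins of width
#' `bin_width_ns` tiling one excitation period `period_ns`. Pulsed
#' excitation at ~20 MHz corresponds to a 50 ns period; typical TCSPC
#' electronics digitize it into 4096 bins (~12.2 ps each), but coarser
#' grids are valid and much faster to fit.
#'
#' @param n_bins Number of bins (>= 8).
#' @param period_ns Excitation repetition period in ns (default 50).
#' @return A `time_binning` object with fields `n_bins`, `bin_width_ns`,
#'   `period_ns`.
#' @examples
#' time_binning(256)          # 50 ns / 256 bins
#' time_binning(4096, 50)
#' @export
time_binning <- function(n_bins = 4096L, period_ns = 50) {
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 8 ||
      n_bins != round(n_bins))
    stop("time_binning: 'n_bins' must be a single integer >= 8", call. = FALSE)
  if (!is.numeric(period_ns) || length(period_ns) != 1L || period_ns <= 0)
    stop("time_binning: 'period_ns' must be positive", call. = FALSE)
  structure(
    list(n_bins = as.integer(n_bins),
         bin_width_ns = period_ns / n_bins,
         period_ns = period_ns),
    class = "time_binning"
  )
}

#' @export
print.time_binning <- function(x, ...) {
  cat(sprintf("<time_binning> %d bins x %.4g ps over %.4g ns period\n",
              x$n_bins, 1000 * x$bin_width_ns, x$period_ns))
  invisible(x)
}

bin_left_edges <- function(binning) (seq_len(binning$n_bins) - 1) * binning$bin_width_ns

same_binning <- function(a, b) {
  a$n_bins == b$n_bins && isTRUE(all.equal(a$period_ns, b$period_ns))
}

stop_binning_mismatch <- function(a, b, what) {
  stop(sprintf("%s: binning mismatch (%d bins / %.6g ns vs %d bins / %.6g ns)",
               what, a$n_bins, a$period_ns, b$n_bins, b$period_ns), call. = FALSE)
}

#' Construct a TCSPC decay histogram
#'
#' @param counts Non-negative integer photon counts, one per bin.
#' @param binning A [time_binning()] with `n_bins == length(counts)`.
#' @param meta Named list of free-form annotations (cell id, group label, ...).
#' @return A `decay_histogram` object.
#' @export
decay_histogram <- function(counts, binning, meta = list()) {
  if (!inherits(binning, "time_binning"))
    stop("decay_histogram: 'binning' must be a time_binning", call. = FALSE)
  if (length(counts) != binning$n_bins)
    stop(sprintf("decay_histogram: length(counts) == %d but binning has %d bins",
                 length(counts), binning$n_bins), call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("decay_histogram: counts must be non-negative integers", call. = FALSE)
  structure(list(binning = binning, counts = as.numeric(counts), meta = meta),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("<decay_histogram> %d bins, %.4g ns period, %s photons\n",
              x$binning$n_bins, x$binning$period_ns,
              format(sum(x$counts), big.mark = ",")))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Construct an instrument response function
#'
#' Per-bin weights of the excitation/detection temporal response on the
#' same periodic grid as the histograms it will be used with. Weights are
#' normalized to sum to one on construction; raw IRF counts are accepted.
#'
#' @param weights Non-negative per-bin values (counts or density).
#' @param binning A [time_binning()].
#' @return An `instrument_response` object with normalized `weights`.
#' @export
instrument_response <- function(weights, binning) {
  if (!inherits(binning, "time_binning"))
    stop("instrument_response: 'binning' must be a time_binning", call. = FALSE)
  if (length(weights) != binning$n_bins)
    stop(sprintf("instrument_response: length(weights) == %d but binning has %d bins",
                 length(weights), binning$n_bins), call. = FALSE)
  if (any(weights < 0) || any(!is.finite(weights)))
    stop("instrument_response: weights must be finite and non-negative", call. = FALSE)
  s <- sum(weights)
  if (s <= 0)
    stop("instrument_response: weights must have a positive sum", call. = FALSE)
  structure(list(binning = binning, weights = as.numeric(weights) / s),
            class = "instrument_response")
}

#' @export
print.instrument_response <- function(x, ...) {
  peak <- which.max(x$weights)
  cat(sprintf("<instrument_response> %d bins, peak at %.4g ns\n",
              x$binning$n_bins, (peak - 0.5) * x$binning$bin_width_ns))
  invisible(x)
}

#' Two-component decay parameters
#'
#' The parameters of the biexponential TCSPC model
#' `I(t) = C [alpha exp(-t/tau1) + (1 - alpha) exp(-t/tau2)] (*) IRF(t) + D`:
#' overall amplitude `C` (expected signal photons per excitation window),
#' amplitude fraction `alpha` of component 1, the two lifetimes, and a flat
#' background `D` (expected counts per bin). Components are kept in the
#' canonical order `tau1 <= tau2`; constructing with `tau1 > tau2` swaps the
#' labels and replaces `alpha` by `1 - alpha`, which leaves the model
#' invariant.
#'
#' @param amplitude Total signal amplitude `C` (> 0).
#' @param fraction Amplitude share `alpha` of component 1, in `[0, 1]`.
#' @param tau1_ns,tau2_ns Lifetimes in ns (> 0).
#' @param offset Background `D` per bin (>= 0).
#' @return A `decay_params` object.
#' @examples
#' decay_params(1e5, 0.7, 1.4, 2.9, offset = 2)
#' @export
decay_params <- function(amplitude, fraction, tau1_ns, tau2_ns, offset = 0) {
  if (!is.numeric(amplitude) || amplitude <= 0)
    stop("decay_params: 'amplitude' must be > 0", call. = FALSE)
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("decay_params: 'fraction' must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(tau1_ns) || tau1_ns <= 0 || !is.numeric(tau2_ns) || tau2_ns <= 0)
    stop("decay_params: lifetimes must be > 0", call. = FALSE)
  if (!is.numeric(offset) || offset < 0)
    stop("decay_params: 'offset' must be >= 0", call. = FALSE)
  if (tau1_ns > tau2_ns) {  # canonical order: swap labels
    tmp <- tau1_ns; tau1_ns <- tau2_ns; tau2_ns <- tmp
    fraction <- 1 - fraction
  }
  structure(list(amplitude = amplitude, fraction = fraction,
                 tau1_ns = tau1_ns, tau2_ns = tau2_ns, offset = offset),
            class = "decay_params")
}

#' @export
print.decay_params <- function(x, ...) {
  cat(sprintf(
    "<decay_params> C = %.4g, alpha = %.3f, tau1 = %.4g ns, tau2 = %.4g ns, D = %.4g\n",
    x$amplitude, x$fraction, x$tau1_ns, x$tau2_ns, x$offset))
  invisible(x)
}

#' Circular convolution of two per-bin vectors
#'
#' Realizes the periodic convolution of the decay model with the IRF: under
#' pulsed excitation every signal wraps around the repetition period, so
#' the convolution is circular. Computed via FFT in O(N log N).
#'
#' @param signal,kernel Numeric vectors of equal length.
#' @return `out[j] = sum_m signal[m] * kernel[(j - m) mod N]` (1-based bins
#'   holding lags 0..N-1).
#' @export
convolve_periodic <- function(signal, kernel) {
  if (length(signal) != length(kernel))
    stop(sprintf("convolve_periodic: length mismatch (%d vs %d)",
                 length(signal), length(kernel)), call. = FALSE)
  n <- length(signal)
  Re(stats::fft(stats::fft(signal) * stats::fft(kernel), inverse = TRUE)) / n
}

# Per-bin mass of a periodic exponential decay with lifetime tau, integrated
# over each bin (not midpoint-sampled) and including all periodic wraps via
# the geometric closed form:
#   sum_k exp(-(t + kT)/tau) = exp(-t/tau) / (1 - exp(-T/tau)).
# Normalized to sum to 1 over the period. expm1 keeps short bins accurate.
periodic_decay_bins <- function(tau_ns, binning) {
  t0 <- bin_left_edges(binning)
  dt <- binning$bin_width_ns
  T <- binning$period_ns
  exp(-t0 / tau_ns) * expm1(-dt / tau_ns) / expm1(-T / tau_ns)
}

#' Expected TCSPC counts under the two-component reconvolution model
#'
#' Evaluates the periodic forward model: the bin-integrated biexponential
#' decay (including the wrap-around of incomplete decay across excitation
#' periods, in closed form), circularly convolved with the IRF, scaled by
#' the amplitude, plus the flat background. The decay component is
#' normalized so its per-period total is `amplitude`; with `offset = D` the
#' expected histogram total is `amplitude + n_bins * D`.
#'
#' @param params A [decay_params()].
#' @param irf An [instrument_response()] on the same binning.
#' @return Numeric vector of expected counts per bin (deterministic).
#' @export
forward_model <- function(params, irf) {
  if (!inherits(params, "decay_params"))
    stop("forward_model: 'params' must be a decay_params", call. = FALSE)
  if (!inherits(irf, "instrument_response"))
    stop("forward_model: 'irf' must be an instrument_response", call. = FALSE)
  b <- irf$binning
  d <- params$fraction * periodic_decay_bins(params$tau1_ns, b) +
    (1 - params$fraction) * periodic_decay_bins(params$tau2_ns, b)
  mu <- params$amplitude * convolve_periodic(d, irf$weights) + params$offset
  # FFT round-off can leave tiny negatives below the background floor
  pmax(mu, params$offset)
}

#' Simulate a TCSPC histogram with Poisson counting noise
#'
#' Draws each bin independently from a Poisson law with mean
#' `n_windows * forward_model(params, irf)`, the photon-counting noise
#' model of TCSPC acquisition.
#'
#' @param params A [decay_params()] (per-excitation-window scale).
#' @param irf An [instrument_response()].
#' @param n_windows Number of excitation windows accumulated (>= 1).
#' @param seed Integer seed; the draw is reproducible.
#' @param meta Annotations forwarded to the histogram.
#' @return A [decay_histogram()].
#' @export
simulate_histogram <- function(params, irf, n_windows, seed = 1L, meta = list()) {
  if (!is.numeric(n_windows) || length(n_windows) != 1L || n_windows < 1)
    stop("simulate_histogram: 'n_windows' must be >= 1", call. = FALSE)
  mu <- n_windows * forward_model(params, irf)
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)
  counts <- stats::rpois(length(mu), mu)
  decay_histogram(counts, irf$binning, meta = meta)
}

#' Effective donor lifetime under FRET quenching
#'
#' FRET opens a second, independent de-excitation channel with time
#' constant `tau_fret`; the excited-state survival becomes
#' `exp(-(1/tau0 + 1/tau_fret) t)`, so the measured lifetime is the
#' harmonic combination `tau0 * tau_fret / (tau0 + tau_fret)`, always
#' below the unquenched `tau0`.
#'
#' @param tau0_ns Unquenched donor lifetime (ns, > 0).
#' @param tau_fret_ns FRET time constant (ns, > 0; `Inf` means no FRET).
#' @return Quenched lifetime in ns.
#' @examples
#' quenched_lifetime(2.79, Inf)    # 2.79, no FRET
#' quenched_lifetime(2.79, 2.79)   # 1.395, channel as fast as emission
#' @export
quenched_lifetime <- function(tau0_ns, tau_fret_ns) {
  if (!is.numeric(tau0_ns) || any(tau0_ns <= 0))
    stop("quenched_lifetime: 'tau0_ns' must be > 0", call. = FALSE)
  if (!is.numeric(tau_fret_ns) || any(tau_fret_ns <= 0))
    stop("quenched_lifetime: 'tau_fret_ns' must be > 0", call. = FALSE)
  ifelse(is.infinite(tau_fret_ns), tau0_ns,
         tau0_ns * tau_fret_ns / (tau0_ns + tau_fret_ns))
}

#' FRET efficiency from donor lifetimes
#'
#' The efficiency is the fraction of donor de-excitations routed through
#' FRET, `E = (tau0 - tau) / tau0`, identical to the relative intensity
#' loss `(S0 - S)/S0` since total intensity is proportional to `C * tau`.
#' The implied FRET time constant `tau' = tau0 * tau / (tau0 - tau)` is
#' returned alongside (`Inf` when `tau == tau0`).
#'
#' @param tau0_ns Unquenched (donor-only) lifetime, ns.
#' @param tau_ns Quenched (donor + acceptor) lifetime, ns; must satisfy
#'   `0 < tau_ns <= tau0_ns` — a donor-only control measuring *longer* than
#'   the reference must be handled by the caller (see
#'   [estimate_group_fret()]).
#' @return A `fret_quantities` object: `tau0_ns`, `tau_ns`, `tau_fret_ns`,
#'   `efficiency` in `[0, 1)`, and the relative intensities
#'   `intensity_unquenched`, `intensity_quenched` (with unit amplitude).
#' @examples
#' fret_efficiency(2.79, 2.69)$efficiency  # 0.0358... -> prints as 3.6%
#' fret_efficiency(2.78, 2.16)$efficiency  # 0.223     -> 22%
#' @export
fret_efficiency <- function(tau0_ns, tau_ns) {
  if (!is.numeric(tau0_ns) || tau0_ns <= 0)
    stop("fret_efficiency: 'tau0_ns' must be > 0", call. = FALSE)
  if (!is.numeric(tau_ns) || tau_ns <= 0)
    stop("fret_efficiency: 'tau_ns' must be > 0", call. = FALSE)
  if (tau_ns > tau0_ns)
    stop("fret_efficiency: 'tau_ns' exceeds 'tau0_ns'; negative efficiency is not returned",
         call. = FALSE)
  eff <- (tau0_ns - tau_ns) / tau0_ns
  tau_fret <- if (eff > 0) tau0_ns * tau_ns / (tau0_ns - tau_ns) else Inf
  structure(
    list(tau0_ns = tau0_ns, tau_ns = tau_ns, tau_fret_ns = tau_fret,
         efficiency = eff,
         intensity_unquenched = tau0_ns, intensity_quenched = tau_ns,
         note = NULL),
    class = "fret_quantities"
  )
}

#' @export
print.fret_quantities <- function(x, ...) {
  cat(sprintf("<fret_quantities> tau0 = %.4g ns, tau = %.4g ns -> E = %.1f%%",
              x$tau0_ns, x$tau_ns, 100 * x$efficiency))
  if (is.finite(x$tau_fret_ns)) cat(sprintf(" (tau' = %.4g ns)", x$tau_fret_ns))
  if (!is.null(x$note)) cat(" [", x$note, "]", sep = "")
  cat("\n")
  invisible(x)
}
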