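# Mean-rate linear/ReLU approximation of the neuron.  On time scales of
# many spikes the synaptic drive is proportional to the weight-normalized
# sum of input train rates (the "effective rate"), and the output rate is a
# rectified linear function of the net excitatory-minus-inhibitory
# effective drive with a single gain-scaling factor fitted at the nominal
# weight.

#' Rate-model parameters
#'
#' @param G_wnom gain-scaling factor at the nominal weight: output rate per
#'   unit of net effective input rate (dimensionless, >= 0).
#' @param w_nom nominal digital weight code (default 80).
#' @return list of class \code{"ifat_rate_model"}.
#' @export
rate_model_params <- function(G_wnom = 1, w_nom = 80) {
  stopifnot(is.numeric(G_wnom), G_wnom >= 0, w_nom > 0)
  structure(list(G_wnom = G_wnom, w_nom = w_nom), class = "ifat_rate_model")
}

#' Effective input rate of a set of weighted spike trains
#'
#' Weight-normalized sum \code{sum(f_n * w_n) / w_nom}: a set of input
#' trains is equivalent, in the mean-rate model, to a single train at the
#' effective rate carried at the nominal weight.
#'
#' @param rates input train rates, Hz.
#' @param weights linear synaptic weights, one per train (code units).
#' @param w_nom nominal weight code (> 0).
#' @return effective rate, Hz.
#' @examples
#' effective_rate(c(1000, 1000), c(40, 120), 80)  # 2000 Hz
#' @export
effective_rate <- function(rates, weights, w_nom = 80) {
  if (length(rates) != length(weights)) stop("length mismatch")
  stopifnot(w_nom > 0)
  if (length(rates) == 0) return(0)
  sum(rates * weights) / w_nom
}

#' Rectified-linear output rate
#'
#' \code{f_out = max(0, G_wnom * (f_ext_eff - f_inh_eff))}: linear in the
#' net effective drive above threshold, zero when inhibition meets or
#' exceeds excitation.
#'
#' @param f_ext_eff,f_inh_eff effective excitatory and inhibitory input
#'   rates, Hz (vectorized).
#' @param p [rate_model_params()].
#' @return output rate(s), Hz.
#' @export
relu_rate <- function(f_ext_eff, f_inh_eff = 0, p = rate_model_params()) {
  stopifnot(all(f_ext_eff >= 0), all(f_inh_eff >= 0))
  pmax(0, p$G_wnom * (f_ext_eff - f_inh_eff))
}

#' Fit the gain-scaling factor from (input, output) rate pairs
#'
#' Least-squares gain through the origin on pairs from the linear regime.
#' Saturated pairs are excluded: the output of a driven neuron flattens at
#' its ceiling (each input producing one output spike, or the refractory
#' bound), so points whose output exceeds \code{sat_fraction} of the
#' largest observed output are dropped before the fit, mirroring the
#' linear-regime convention of the calibration module.
#'
#' @param f_in net effective input rates, Hz.
#' @param f_out measured output rates, Hz.
#' @param w_nom nominal weight code the pairs were measured at.
#' @param sat_fraction saturation cutoff as a fraction of the maximum
#'   observed output rate (default 0.5; use \code{Inf} to keep all pairs).
#' @return [rate_model_params()] with the fitted \code{G_wnom}.
#' @export
fit_gain <- function(f_in, f_out, w_nom = 80, sat_fraction = 0.5) {
  stopifnot(length(f_in) == length(f_out), length(f_in) >= 3)
  keep <- f_in > 0 & f_out <= sat_fraction * max(f_out)
  x <- f_in[keep]; y <- f_out[keep]
  if (length(x) < 1 || all(y == 0)) stop("degenerate input: no usable pairs")
  rate_model_params(G_wnom = sum(x * y) / sum(x * x), w_nom = w_nom)
}

#' @export
print.ifat_rate_model <- function(x, ...) {
  cat(sprintf("<ifat_rate_model> G_wnom = %.4g at w_nom = %g\n",
              x$G_wnom, x$w_nom))
  invisible(x)
}

#' Fit a neuron's rate-model gain with the event engine
#'
#' Measures the neuron's activation with single Poisson trains at weight
#' code \code{strength} over a sweep of input rates, converts the input
#' rates to effective rates at the nominal weight
#' (\code{f_eff = f * dG(strength) / dG(w_nom)}), and fits the gain
#' through the origin.  Fitting at a high-exponent code lets the sweep
#' span the effective-drive range of a 225-synapse patch projection with
#' modest event counts.  The result is the neuron's calibrated mean-rate
#' model, used by the vision demos to predict projection outputs.
#'
#' @param neuron [neuron_params()].
#' @param w_nom nominal weight code (default 80).
#' @param rates input rates to sweep, Hz.
#' @param strength strength code used for the measurement (default
#'   \code{w_nom}).
#' @param duration seconds per rate.
#' @param dt membrane substep.
#' @param seed RNG seed.
#' @param burn_in discarded transient, seconds.
#' @return [rate_model_params()].
#' @export
fit_neuron_gain <- function(neuron, w_nom = 80,
                            rates = c(250, 500, 1000, 1500, 2000),
                            strength = w_nom, duration = 0.5, dt = 1e-5,
                            seed = NULL, burn_in = 0.1) {
  act <- measure_activation(neuron, "poisson", rates, strength = strength,
                            duration = duration, dt = dt, seed = seed,
                            burn_in = burn_in)
  f_eff <- act$input_rate * STEP_TABLE[strength + 1L] / STEP_TABLE[w_nom + 1L]
  fit_gain(f_eff, act$output_rate, w_nom = w_nom, sat_fraction = Inf)
}
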