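# Per-neuron analog mismatch: generation, response-curve synthesis,
# offset/slope estimation, and single-point digital offset calibration.
#
# The response of a neuron to a weight sweep at fixed input rate is, in its
# linear regime, a straight line in (code, log10 rate) space.  Transistor
# mismatch shifts that line horizontally (a digital-weight offset, from
# threshold-voltage mismatch in the spike-generation circuit) and tilts it
# (a per-neuron slope, decades of output rate per code unit).  Offsets are
# estimated as the code where the response gain crosses a criterion, and
# compensated by pre-distorting the routing-table strengths.

#' Draw per-neuron mismatch
#'
#' Offsets are Normal(\code{mu_off}, \code{sigma_off}) in code units; slopes
#' are Normal(\code{mu_slope}, \code{sigma_slope}) in decades of output rate
#' per code unit, truncated to three standard deviations and to strictly
#' positive values (at the default parameters the plain 3-sigma interval
#' dips marginally below zero, so the positive floor is also enforced).
#' Draws are reproducible under a fixed seed.
#'
#' @param n number of neurons (>= 1).
#' @param mu_off,sigma_off offset distribution, code units (defaults 0, 8).
#' @param mu_slope,sigma_slope slope distribution, decades per code unit
#'   (defaults 0.0185, 0.0068).
#' @param seed optional integer seed.
#' @return data.frame of class \code{c("ifat_mismatch", "data.frame")} with
#'   columns \code{neuron} (0-based), \code{offset_w}, \code{slope_s}.
#' @export
sample_mismatch <- function(n, mu_off = 0, sigma_off = 8,
                            mu_slope = 0.0185, sigma_slope = 0.0068,
                            seed = NULL) {
  stopifnot(n >= 1, sigma_off >= 0, sigma_slope >= 0)
  with_seed(seed, {
    offs <- stats::rnorm(n, mu_off, sigma_off)
    lo <- max(mu_slope - 3 * sigma_slope, 1e-4)
    hi <- mu_slope + 3 * sigma_slope
    slopes <- stats::rnorm(n, mu_slope, sigma_slope)
    bad <- which(slopes < lo | slopes > hi)
    while (length(bad)) {
      slopes[bad] <- stats::rnorm(length(bad), mu_slope, sigma_slope)
      bad <- bad[slopes[bad] < lo | slopes[bad] > hi]
    }
    structure(data.frame(neuron = seq_len(n) - 1L, offset_w = offs,
                         slope_s = slopes),
              class = c("ifat_mismatch", "data.frame"))
  })
}

#' Synthesize weight-sweep response curves for a mismatched core
#'
#' Rate-model shortcut for the per-neuron weight sweep: each neuron's gain
#' (output rate / input rate) follows the log-linear law
#' \code{gain(w) = gain_criterion * 10^(slope_s * (w - w_nom_cross -
#' offset_w))}, capped at 1 (one output spike per input spike) and floored
#' at \code{gain_floor} below which the leaky membrane never reaches
#' threshold and the output is 0.  With \code{stochastic = TRUE} each
#' (neuron, code) measurement is a Poisson spike count over
#' \code{duration}, emulating a counting measurement with Poisson input.
#'
#' @param mm [sample_mismatch()] draw.
#' @param codes weight codes to sweep (default 0:255).
#' @param input_rate input spike rate, Hz (default 10 kHz).
#' @param duration measurement time per code, seconds (default 1).
#' @param w_nom_cross nominal code at which a zero-mismatch neuron crosses
#'   the gain criterion (default 60).
#' @param gain_criterion gain at the crossing (default 0.1).
#' @param gain_floor gain below which the output is zero (default 1e-3).
#' @param correction optional per-neuron integer code correction from
#'   [calibrate()]; the applied code becomes \code{w - correction}
#'   (clamped to 0--255), which moves each neuron's criterion crossing to
#'   the core mean.
#' @param stochastic Poisson counting noise on the measured rates?
#' @param seed optional seed for the counting noise.
#' @return list of class \code{"ifat_curves"}: \code{codes}, \code{rates}
#'   (matrix, neurons x codes, Hz), \code{input_rate}.
#' @export
synth_response_curves <- function(mm, codes = 0:255, input_rate = 1e4,
                                  duration = 1, w_nom_cross = 60,
                                  gain_criterion = 0.1, gain_floor = 1e-3,
                                  correction = NULL, stochastic = TRUE,
                                  seed = NULL) {
  codes <- check_int_range(codes, 0L, 255L, "codes")
  n <- nrow(mm)
  w_eff <- outer(rep(1, n), as.numeric(codes))
  if (!is.null(correction)) {
    stopifnot(length(correction) == n)
    w_eff <- pmin(pmax(w_eff - correction, 0), 255)
  }
  lg <- log10(gain_criterion) +
    mm$slope_s * (w_eff - w_nom_cross - mm$offset_w)
  gain <- pmin(10^lg, 1)
  gain[gain < gain_floor] <- 0
  rate <- gain * input_rate
  if (stochastic) {
    rate <- with_seed(seed, {
      matrix(stats::rpois(length(rate), rate * duration) / duration,
             nrow = n)
    })
  }
  structure(list(codes = codes, rates = rate, input_rate = input_rate),
            class = "ifat_curves")
}

#' @export
print.ifat_curves <- function(x, ...) {
  cat("<ifat_curves> ", nrow(x$rates), " neuron(s) x ", length(x$codes),
      " weight codes at ", x$input_rate, " Hz input\n", sep = "")
  invisible(x)
}

#' @export
plot.ifat_curves <- function(x, which = seq_len(min(nrow(x$rates), 32)), ...) {
  graphics::matplot(x$codes, t(pmax(x$rates[which, , drop = FALSE], 1)),
                    type = "l", lty = 1, log = "y",
                    xlab = "digital weight code", ylab = "output rate (Hz)", ...)
  invisible(x)
}

#' Measure a weight-sweep response curve with the event engine
#'
#' Drives one neuron through [run_simulation()] for each weight code and
#' returns the measured output rates.  This is the slow, mechanistic
#' counterpart of [synth_response_curves()].
#'
#' @param neuron [neuron_params()].
#' @param codes weight codes to sweep.
#' @param input_rate input rate, Hz.
#' @param kind input train kind.
#' @param duration seconds per code.
#' @param dt membrane substep.
#' @param seed RNG seed.
#' @param syn_index target synapse (default 2).
#' @return \code{"ifat_curves"} object with one row.
#' @export
measure_response_curve <- function(neuron, codes, input_rate = 1e4,
                                   kind = "poisson", duration = 0.5,
                                   dt = 1e-5, seed = NULL, syn_index = 2L) {
  codes <- check_int_range(codes, 0L, 255L, "codes")
  rates <- with_seed(seed, vapply(codes, function(w) {
    ev <- gen_event_train(kind, input_rate, duration, syn_type = syn_index,
                          strength = w)
    sim <- run_simulation(neuron, ev, duration, dt = dt)
    nrow(sim$spikes) / duration
  }, numeric(1)))
  structure(list(codes = codes, rates = matrix(rates, nrow = 1),
                 input_rate = input_rate),
            class = "ifat_curves")
}

# pull one neuron's (codes, rates) out of an ifat_curves object
curve_row <- function(curves, i) {
  list(codes = curves$codes, rates = curves$rates[i, ],
       input_rate = curves$input_rate)
}

#' Estimate the digital-weight offset of a response curve
#'
#' The offset is the (fractional) code at which the response gain crosses
#' \code{gain_criterion}: linear interpolation in (code, log10 rate) at
#' \code{rate = gain_criterion * input_rate}, using the first upward
#' crossing.  A curve that never crosses (or starts above the criterion) is
#' uncalibratable and yields \code{NA} with a warning.
#'
#' @param curves an \code{"ifat_curves"} object.
#' @param gain_criterion gain at the crossing (default 0.1; at 10 kHz input
#'   the criterion rate is 1,000 Hz).
#' @return numeric vector of fractional offset codes, one per neuron
#'   (\code{NA} where uncalibratable).
#' @export
estimate_offset <- function(curves, gain_criterion = 0.1) {
  r_star <- gain_criterion * curves$input_rate
  n <- nrow(curves$rates)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    r <- curves$rates[i, ]; w <- curves$codes
    pos <- which(r > 0)
    if (length(pos) < 2) next
    r <- r[pos]; w <- w[pos]
    above <- which(r >= r_star)
    if (length(above) == 0 || above[1] == 1) next    # no upward crossing
    j <- above[1]
    lr0 <- log10(r[j - 1]); lr1 <- log10(r[j])
    out[i] <- w[j - 1] + (w[j] - w[j - 1]) *
      (log10(r_star) - lr0) / (lr1 - lr0)
  }
  if (anyNA(out)) warning(sum(is.na(out)), " neuron(s) uncalibratable")
  out
}

#' Estimate the response slope of a curve
#'
#' Least-squares slope of log10(rate) versus weight code over the linear
#' regime, defined as measured rates between \code{gain_criterion} and
#' \code{sat_fraction} times the input rate (above the offset criterion,
#' below saturation).  Curves with fewer than \code{min_points} points in
#' the window yield \code{NA} with a warning.
#'
#' @param curves an \code{"ifat_curves"} object.
#' @param gain_criterion lower edge of the fit window as a gain (default 0.1).
#' @param sat_fraction upper edge of the fit window as a gain (default 0.5).
#' @param min_points minimum points required in the window (default 4).
#' @return numeric vector of slopes, decades per code unit.
#' @export
estimate_slope <- function(curves, gain_criterion = 0.1, sat_fraction = 0.5,
                           min_points = 4L) {
  lo <- gain_criterion * curves$input_rate
  hi <- sat_fraction * curves$input_rate
  n <- nrow(curves$rates)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    r <- curves$rates[i, ]; w <- as.numeric(curves$codes)
    keep <- which(r >= lo & r <= hi)
    if (length(keep) < min_points) next
    x <- w[keep]; y <- log10(r[keep])
    xm <- mean(x); ym <- mean(y)
    out[i] <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  }
  if (anyNA(out)) {
    warning(sum(is.na(out)), " neuron(s) with too few points in the linear regime")
  }
  out
}

#' Single-point digital offset calibration
#'
#' Aligns the response curves of a core to their mean: the correction for
#' neuron i is \code{round(mean(offsets) - offsets[i])} code units.  A
#' neuron whose criterion crossing sits below the mean (too sensitive)
#' gets a positive correction; pre-distortion subtracts the correction
#' from the strengths addressed to it (clamped to 0--255 at application
#' time), moving every crossing onto the mean.  Calibration is idempotent
#' up to rounding.
#'
#' @param offsets numeric vector of estimated offsets, code units
#'   (\code{NA}s are ignored for the mean and yield correction 0).
#' @return data.frame of class \code{c("ifat_calibration", "data.frame")}
#'   with columns \code{neuron} (0-based), \code{offset_est},
#'   \code{correction}.
#' @export
calibrate <- function(offsets) {
  m <- mean(offsets, na.rm = TRUE)
  corr <- ifelse(is.na(offsets), 0L, as.integer(round(m - offsets)))
  structure(data.frame(neuron = seq_along(offsets) - 1L,
                       offset_est = offsets, correction = corr),
            class = c("ifat_calibration", "data.frame"))
}

#' End-to-end core calibration
#'
#' Draws (or accepts) a mismatched core, synthesizes its weight-sweep
#' response curves, estimates per-neuron offsets and slopes, and computes
#' the offset corrections aligning the core to its mean response.
#'
#' @param n number of neurons (used if \code{mm} is NULL).
#' @param mm optional [sample_mismatch()] draw.
#' @param codes,input_rate,duration,seed passed to [synth_response_curves()].
#' @param ... further arguments to [synth_response_curves()].
#' @return \code{"ifat_calibration"} data.frame with columns \code{neuron},
#'   \code{offset_est}, \code{slope_est}, \code{correction}; the mismatch
#'   draw is attached as attribute \code{"mismatch"}.
#' @export
calibrate_core <- function(n = 256, mm = NULL, codes = 0:255,
                           input_rate = 1e4, duration = 1, seed = NULL, ...) {
  if (is.null(mm)) mm <- sample_mismatch(n, seed = seed)
  curves <- synth_response_curves(mm, codes = codes, input_rate = input_rate,
                                  duration = duration,
                                  seed = if (is.null(seed)) NULL else seed + 1L,
                                  ...)
  offs <- estimate_offset(curves)
  slopes <- estimate_slope(curves)
  cal <- calibrate(offs)
  cal$slope_est <- slopes
  cal <- cal[, c("neuron", "offset_est", "slope_est", "correction")]
  class(cal) <- c("ifat_calibration", "data.frame")
  attr(cal, "mismatch") <- mm
  cal
}

#' Apply offset corrections to routing-table strengths
#'
#' Pre-distorts a routing table: each entry targeting neuron with global id
#' \code{id} gets that neuron's correction subtracted from its strength
#' byte, clamped to 0--255.  Corrections are indexed by target global id
#' through \code{ids}.
#'
#' @param table [routing_table()].
#' @param cal \code{"ifat_calibration"} object.
#' @param ids global ids corresponding to \code{cal$neuron} (default
#'   \code{cal$neuron} itself).
#' @return corrected routing table.
#' @export
apply_calibration <- function(table, cal, ids = cal$neuron) {
  tgt <- global_id(table$core, table$neuron)
  k <- match(tgt, ids)
  corr <- ifelse(is.na(k), 0L, cal$correction[k])
  table$strength <- as.integer(pmin(pmax(table$strength - corr, 0L), 255L))
  table
}
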