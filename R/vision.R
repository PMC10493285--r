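# Orientation tuning and boundary detection on the simulated array:
# stimulus/kernel generators, intensity-to-rate and intensity-to-weight
# encoders, and projection of a 15x15 patch onto one neuron either through
# the mean-rate ReLU model or through the event engine.
#
# Image convention: matrices are indexed [row, col] = [y, x]; an "angle"
# is the orientation of a bar or of a Gabor kernel's stripes, in degrees,
# measured from the horizontal (x) axis, 180-degree periodic.

#' Oriented Gabor kernel
#'
#' Zero-mean (DC-subtracted) Gabor patch: an isotropic Gaussian envelope
#' times a cosine carrier running perpendicular to the stripe orientation
#' \code{theta}.  With even-symmetric phase the kernel is 180-degree
#' periodic in \code{theta}, and the 0- and 90-degree kernels are exact
#' transposes of each other on the discrete grid.
#'
#' @param theta stripe orientation, degrees.
#' @param size odd patch side, pixels (default 15).
#' @param wavelength carrier wavelength, pixels (default 10).
#' @param sigma Gaussian envelope s.d., pixels (default 4).
#' @param phase carrier phase, radians (default 0, even-symmetric).
#' @return size x size numeric matrix summing to zero.
#' @export
gabor_patch <- function(theta, size = 15, wavelength = 10, sigma = 4,
                        phase = 0) {
  stopifnot(size %% 2 == 1, wavelength > 0, sigma > 0)
  c0 <- (size + 1) / 2
  x <- matrix(rep(seq_len(size) - c0, each = size), nrow = size)  # col index
  y <- matrix(rep(seq_len(size) - c0, times = size), nrow = size) # row index
  th <- theta * pi / 180
  u <- -x * sin(th) + y * cos(th)      # coordinate across the stripes
  g <- exp(-(x^2 + y^2) / (2 * sigma^2)) * cos(2 * pi * u / wavelength + phase)
  g - mean(g)
}

#' Oriented bar stimulus
#'
#' Bright anti-aliased bar of the given width through the patch center at
#' orientation \code{theta}, on a dark background; intensities 0--255.
#' The bar is windowed to the patch's inscribed disc so its total
#' intensity is rotation-invariant (an unwindowed bar is longer on the
#' diagonal of a square patch).
#'
#' @param theta bar orientation, degrees (180-degree periodic).
#' @param size patch side, pixels (default 15).
#' @param width bar width, pixels (>= 1, default 3).
#' @return size x size numeric matrix in [0, 255].
#' @export
bar_stimulus <- function(theta, size = 15, width = 3) {
  stopifnot(width >= 1)
  c0 <- (size + 1) / 2
  x <- matrix(rep(seq_len(size) - c0, each = size), nrow = size)
  y <- matrix(rep(seq_len(size) - c0, times = size), nrow = size)
  th <- theta * pi / 180
  d <- abs(-x * sin(th) + y * cos(th))   # distance to the bar's center line
  disc <- pmin(pmax((size - 1) / 2 + 0.5 - sqrt(x^2 + y^2), 0), 1)
  255 * pmin(pmax(width / 2 + 0.5 - d, 0), 1) * disc
}

#' Encode a stimulus patch as per-pixel input rates
#'
#' Pixel intensities map linearly to 6-bit rate codes 0 (darkest) to 63
#' (brightest), each worth \code{rate_unit} Hz; the default 31.25 Hz puts
#' the top code at about 2 kHz, the input range of the mean-rate model.
#'
#' @param patch non-negative intensity matrix.
#' @param rate_unit Hz per rate code (default 31.25).
#' @param max_intensity intensity mapped to code 63 (default
#'   \code{max(patch)}; an all-zero patch yields all-zero rates).
#' @return matrix of rates, Hz, same shape as \code{patch}.
#' @export
encode_stimulus <- function(patch, rate_unit = 31.25,
                            max_intensity = max(patch)) {
  stopifnot(all(patch >= 0))
  if (max_intensity <= 0) return(patch * 0)
  round(63 * patch / max_intensity) * rate_unit
}

#' Encode a signed kernel as synaptic weights
#'
#' Kernel magnitudes map linearly to effective synaptic weights with the
#' largest magnitude at \code{2 * w_nom} (so mid-scale intensity carries
#' the nominal weight 80).  Each target weight is realized as the 8-bit
#' PWAM code whose conductance step is nearest the target; the returned
#' effective weight is the weight actually realized by that code
#' (\code{w_nom * dG(code) / dG(w_nom)}), so the mean-rate model and the
#' event engine see the same synapse.  Positive kernel values become
#' excitatory weights, negative ones inhibitory; magnitudes below half the
#' smallest conductance step are dropped (no synapse).
#'
#' @param patch signed kernel matrix.
#' @param w_nom nominal weight code (default 80).
#' @param w_max effective weight assigned to the largest magnitude
#'   (default \code{2 * w_nom}).
#' @return list of class \code{"ifat_kernel_code"}: \code{weight} (signed
#'   effective weights, same shape), \code{byte} (realized strength codes,
#'   \code{NA} where no synapse), \code{w_nom}.
#' @export
encode_kernel <- function(patch, w_nom = 80, w_max = 2 * w_nom) {
  amax <- max(abs(patch))
  if (amax == 0) stop("all-zero kernel")
  step_nom <- STEP_TABLE[w_nom + 1L]
  target <- abs(patch) / amax * w_max / w_nom * step_nom  # in g0 units
  code <- matrix(NA_integer_, nrow(patch), ncol(patch))
  weight <- matrix(0, nrow(patch), ncol(patch))
  use <- target >= STEP_TABLE[1L] / 2
  if (any(use)) {
    idx <- vapply(target[use], function(tg) which.min(abs(STEP_TABLE - tg)),
                  integer(1))
    code[use] <- idx - 1L
    weight[use] <- sign(patch[use]) * w_nom * STEP_TABLE[idx] / step_nom
  }
  structure(list(weight = weight, byte = code, w_nom = w_nom),
            class = "ifat_kernel_code")
}

#' Neuron configuration for the vision demos
#'
#' The demo neuron is programmed into the regime where the mean-rate ReLU
#' model is accurate, i.e. where the synapses act as near-ideal current
#' sources: reversal potentials far beyond the operating voltages
#' (+10 V / -10 V, symmetric so inhibition subtracts rather than merely
#' shunts), a low threshold (0.02 V) so the driving forces are nearly
#' constant over the spike cycle, a small leak (5 pS), the distal
#' compartment decoupled (G_comp = 0, unused by the demos), a short 1 us
#' dead time, and the membrane floored at the 0 V supply rail so
#' inhibition-dominant fluctuations rectify at the rail instead of
#' driving the voltage deep negative.  The conductance quantum is 0.4 fS because
#' a projection sums 225 weighted input trains: the effective drive
#' reaches tens of kilohertz and the small quantum keeps the neuron in
#' its linear range instead of pinning it at the refractory ceiling.
#'
#' @param ... overrides passed to [neuron_params()].
#' @export
vision_neuron <- function(...) {
  neuron_params(V_thresh = 0.02, G_comp = 0, t_refr = 1e-6, V_floor = 0,
                proximal = compartment_params(1e-12, 5e-12, 0),
                synapses = default_synapses(E_exc = 10, E_inh = -10,
                                            g0 = 4e-16), ...)
}

#' Project a stimulus patch onto one neuron
#'
#' Computes the neuron's output rate for a stimulus (as per-pixel rates)
#' seen through a signed kernel.  \code{"rate_model"} mode evaluates the
#' rectified weighted sum via [relu_rate()]; \code{"event_sim"} mode wires
#' one Poisson train per active pixel to the proximal excitatory or
#' inhibitory synapse (by weight sign, with the realized strength byte)
#' and measures the output rate with [run_simulation()].
#'
#' @param rates per-pixel input rates, Hz ([encode_stimulus()] output).
#' @param kernel an \code{"ifat_kernel_code"} from [encode_kernel()].
#' @param mode \code{"rate_model"} or \code{"event_sim"}.
#' @param p [rate_model_params()] (rate-model mode).
#' @param neuron [neuron_params()] (event mode; default [vision_neuron()]).
#' @param duration trial length, seconds (event mode).
#' @param dt membrane substep (event mode).
#' @param seed RNG seed (event mode).
#' @param burn_in initial interval excluded from the rate measurement,
#'   seconds (event mode; default 0.05, a few synaptic time constants, so
#'   the conductance build-up transient does not bias short trials).
#' @return output rate, Hz.
#' @export
project_patch <- function(rates, kernel, mode = c("rate_model", "event_sim"),
                          p = rate_model_params(), neuron = vision_neuron(),
                          duration = 1, dt = 1e-5, seed = NULL,
                          burn_in = 0.05) {
  mode <- match.arg(mode)
  if (!identical(dim(rates), dim(kernel$weight))) {
    stop("stimulus and kernel shapes differ")
  }
  w <- kernel$weight
  if (mode == "rate_model") {
    exc <- w > 0; inh <- w < 0
    fe <- effective_rate(rates[exc], w[exc], kernel$w_nom)
    fi <- effective_rate(rates[inh], -w[inh], kernel$w_nom)
    return(relu_rate(fe, fi, p))
  }
  act <- which(!is.na(kernel$byte) & rates > 0)
  if (length(act) == 0) return(0)
  evs <- with_seed(seed, lapply(act, function(k) {
    gen_event_train("poisson", rates[k], duration,
                    syn_type = if (w[k] > 0) 2L else 3L,
                    strength = kernel$byte[k])
  }))
  ev <- do.call(rbind, evs)
  ev <- ev[order(ev$t), , drop = FALSE]
  class(ev) <- c("ifat_events", "data.frame")
  stopifnot(burn_in < duration)
  sim <- run_simulation(neuron, ev, duration, dt = dt)
  sum(sim$spikes$t > burn_in) / (duration - burn_in)
}

#' Orientation tuning curve
#'
#' Projects oriented bar stimuli through a Gabor kernel onto one neuron
#' over a sweep of bar angles, with repeated Poisson trials in event mode,
#' and reports the per-angle mean and standard deviation of the output
#' rate.  If a fitted rate model is supplied, its prediction is attached
#' per angle.
#'
#' @param kernel_theta Gabor kernel orientation, degrees.
#' @param angles stimulus angles, degrees (default 0--180 in 5-degree
#'   steps, 37 angles).
#' @param trials trials per angle (default 30).
#' @param trial_duration seconds per trial (default 1).
#' @param neuron [neuron_params()] for event mode.
#' @param p optional [rate_model_params()]; adds a \code{model} column.
#' @param seed RNG seed.
#' @param mode \code{"event_sim"} (default) or \code{"rate_model"} (then
#'   trials collapse to one deterministic evaluation).
#' @param dt membrane substep.
#' @param burn_in per-trial transient excluded from the rate, seconds.
#' @param ... stimulus/kernel options: \code{size}, \code{width},
#'   \code{wavelength}, \code{sigma}, \code{rate_unit}.
#' @return data.frame of class \code{c("ifat_tuning", "data.frame")} with
#'   columns \code{angle}, \code{mean}, \code{sd} (and \code{model}).
#' @export
tuning_curve <- function(kernel_theta, angles = seq(0, 180, by = 5),
                         trials = 30, trial_duration = 1,
                         neuron = vision_neuron(), p = NULL, seed = NULL,
                         mode = c("event_sim", "rate_model"), dt = 1e-5,
                         burn_in = 0.05, size = 15, width = 3,
                         wavelength = 10, sigma = 4, rate_unit = 31.25) {
  mode <- match.arg(mode)
  kern <- encode_kernel(gabor_patch(kernel_theta, size = size,
                                    wavelength = wavelength, sigma = sigma))
  res <- with_seed(seed, lapply(angles, function(a) {
    rates <- encode_stimulus(bar_stimulus(a, size = size, width = width),
                             rate_unit = rate_unit, max_intensity = 255)
    if (mode == "rate_model") {
      stopifnot(!is.null(p))
      r <- project_patch(rates, kern, mode = "rate_model", p = p)
      return(c(mean = r, sd = 0))
    }
    rs <- vapply(seq_len(trials), function(i) {
      project_patch(rates, kern, mode = "event_sim", neuron = neuron,
                    duration = trial_duration, dt = dt, burn_in = burn_in)
    }, numeric(1))
    c(mean = mean(rs), sd = stats::sd(rs))
  }))
  out <- data.frame(angle = angles,
                    mean = vapply(res, `[[`, numeric(1), "mean"),
                    sd = vapply(res, `[[`, numeric(1), "sd"))
  if (!is.null(p) && mode == "event_sim") {
    out$model <- vapply(angles, function(a) {
      rates <- encode_stimulus(bar_stimulus(a, size = size, width = width),
                               rate_unit = rate_unit, max_intensity = 255)
      project_patch(rates, kern, mode = "rate_model", p = p)
    }, numeric(1))
  }
  structure(out, class = c("ifat_tuning", "data.frame"))
}

#' @export
plot.ifat_tuning <- function(x, ...) {
  ylim <- range(0, x$mean + x$sd, if (!is.null(x$model)) x$model)
  graphics::plot(x$angle, x$mean, type = "b", pch = 16, ylim = ylim,
                 xlab = "stimulus angle (deg)", ylab = "output rate (Hz)", ...)
  graphics::arrows(x$angle, x$mean - x$sd, x$angle, x$mean + x$sd,
                   angle = 90, code = 3, length = 0.02)
  if (!is.null(x$model)) graphics::lines(x$angle, x$model, col = 2)
  invisible(x)
}

#' Boundary detection over an image
#'
#' Slides a 15x15 window over the image (stride 1, valid region only) and
#' projects each patch through each oriented kernel, producing one rate
#' map per kernel plus 8-bit renderings normalized jointly across kernels.
#'
#' @param image grayscale intensity matrix (rows x cols), at least 15x15.
#' @param thetas kernel orientations, degrees (default 0, 45, 90, 135).
#' @param mode \code{"rate_model"} (default) or \code{"event_sim"}.
#' @param p [rate_model_params()] for rate-model projections.
#' @param neuron [neuron_params()] for event mode.
#' @param duration seconds per window in event mode.
#' @param seed RNG seed (event mode).
#' @param dt membrane substep (event mode).
#' @param burn_in per-window transient excluded from the rate, seconds.
#' @param phase kernel carrier phase, radians: 0 (even, bar-selective) or
#'   \code{pi/2} (odd, edge-selective and edge-localized).
#' @param size,wavelength,sigma,rate_unit stimulus/kernel options.
#' @return list of class \code{"ifat_boundary"}: \code{rates} (list of
#'   per-kernel rate maps, Hz), \code{maps} (same normalized to 0--255),
#'   \code{thetas}.
#' @export
detect_boundaries <- function(image, thetas = c(0, 45, 90, 135),
                              mode = c("rate_model", "event_sim"),
                              p = rate_model_params(), neuron = vision_neuron(),
                              duration = 0.1, seed = NULL, dt = 1e-5,
                              burn_in = 0.05, size = 15, wavelength = 10,
                              sigma = 4, phase = 0, rate_unit = 31.25) {
  mode <- match.arg(mode)
  if (nrow(image) < size || ncol(image) < size) stop("image smaller than kernel")
  kerns <- lapply(thetas, function(th) {
    encode_kernel(gabor_patch(th, size = size, wavelength = wavelength,
                              sigma = sigma, phase = phase))
  })
  nr <- nrow(image) - size + 1L
  nc <- ncol(image) - size + 1L
  imax <- max(image)
  rates_img <- encode_stimulus(image, rate_unit = rate_unit,
                               max_intensity = if (imax > 0) imax else 1)
  out <- with_seed(seed, lapply(kerns, function(kern) {
    m <- matrix(0, nr, nc)
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        r <- rates_img[i:(i + size - 1L), j:(j + size - 1L)]
        m[i, j] <- project_patch(r, kern, mode = mode, p = p,
                                 neuron = neuron, duration = duration,
                                 dt = dt, burn_in = burn_in)
      }
    }
    m
  }))
  peak <- max(unlist(lapply(out, max)), 1e-12)
  maps <- lapply(out, function(m) round(255 * m / peak))
  structure(list(rates = out, maps = maps, thetas = thetas),
            class = "ifat_boundary")
}

#' @export
print.ifat_boundary <- function(x, ...) {
  cat("<ifat_boundary> ", length(x$maps), " kernel map(s) of ",
      nrow(x$maps[[1]]), " x ", ncol(x$maps[[1]]), "\n", sep = "")
  invisible(x)
}

#' @export
plot.ifat_boundary <- function(x, which = seq_along(x$maps), ...) {
  op <- graphics::par(mfrow = c(1, length(which)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (k in which) {
    m <- x$maps[[k]]
    graphics::image(t(m[rev(seq_len(nrow(m))), ]), axes = FALSE,
                    col = grDevices::gray.colors(64, 0, 1),
                    main = paste0(x$thetas[k], " deg"))
  }
  invisible(x)
}

#' Synthetic grayscale test scene
#'
#' Deterministic scene generator used by the boundary-detection demo in
#' place of a photographic input: a dark background with a bright
#' rectangle, a diagonal band and a filled disc, giving edges at several
#' orientations.
#'
#' @param width,height image size in pixels (defaults 113 x 75).
#' @return height x width intensity matrix in [0, 255].
#' @export
synthetic_test_image <- function(width = 113, height = 75) {
  x <- matrix(rep(seq_len(width), each = height), nrow = height)
  y <- matrix(rep(seq_len(height), times = width), nrow = height)
  img <- matrix(20, height, width)
  img[y > 0.15 * height & y < 0.6 * height &
      x > 0.1 * width & x < 0.45 * width] <- 220
  band <- abs((x - 0.55 * width) - (y - 0.2 * height)) < 0.05 * (width + height) / 2
  img[band & x > 0.5 * width] <- 160
  disc <- (x - 0.8 * width)^2 + (y - 0.7 * height)^2 < (0.12 * (width + height) / 2)^2
  img[disc] <- 255
  img
}
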