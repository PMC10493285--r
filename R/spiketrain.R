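#' Generate a spike train
#'
#' Regular trains are equally spaced at \code{1/rate} starting at
#' \code{1/rate}; Poisson trains have i.i.d. exponential inter-spike
#' intervals with mean \code{1/rate}.  Both are truncated to
#' \code{(0, duration]} and are reproducible under a fixed seed (the
#' caller's RNG state is left untouched).
#'
#' @param kind \code{"poisson"} or \code{"regular"}.
#' @param rate mean rate, Hz (>= 0; 0 gives an empty train).
#' @param duration train length, seconds (> 0).
#' @param seed optional integer seed for the Poisson draw.
#' @return numeric vector of strictly increasing spike times, seconds.
#' @examples
#' gen_spike_train("regular", 1000, 1)      # exactly 1000 spikes
#' gen_spike_train("poisson", 100, 1, seed = 1)
#' @export
gen_spike_train <- function(kind = c("poisson", "regular"), rate, duration,
                            seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(rate) || rate < 0) stop("'rate' must be >= 0")
  stopifnot(duration > 0)
  if (rate == 0) return(numeric(0))
  if (kind == "regular") {
    n <- floor(rate * duration + 1e-9)
    return(seq_len(n) / rate)
  }
  with_seed(seed, {
    # draw in blocks until the cumulative time passes 'duration'
    times <- numeric(0)
    t_end <- 0
    repeat {
      block <- max(64L, ceiling(1.2 * rate * (duration - t_end)))
      isi <- stats::rexp(block, rate)
      times <- c(times, t_end + cumsum(isi))
      t_end <- times[length(times)]
      if (t_end > duration) break
    }
    times[times <= duration]
  })
}

# Evaluate 'expr' under a temporary RNG state seeded with 'seed' (if
# non-NULL), restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = env)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Spike train of input events for one synaptic target
#'
#' Convenience wrapper combining [gen_spike_train()] with a fixed synaptic
#' target: every spike becomes one input event carrying the given strength.
#'
#' @inheritParams gen_spike_train
#' @param core,neuron,syn_type,strength target fields (scalars).
#' @return an [input_events()] data frame.
#' @export
gen_event_train <- function(kind, rate, duration, core = 0L, neuron = 0L,
                            syn_type = 2L, strength = 80L, seed = NULL) {
  tt <- gen_spike_train(kind, rate, duration, seed = seed)
  if (length(tt) == 0) return(empty_events())
  input_events(t = tt, core = core, neuron = neuron,
               syn_type = syn_type, strength = strength)
}
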