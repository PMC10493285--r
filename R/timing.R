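#' Pipeline timing parameters
#'
#' The two-tier micro-pipeline model: a serial front end that handshakes
#' one event at a time (latency \code{T_latency}) and 64 per-row PWAM
#' circuits, each able to hold one pulse.  An event's pulse width is
#' \code{dt_pulse_base * (1 + W/16)} where \code{W} is the mantissa of its
#' strength byte.  Hardware values are unpublished; defaults (50 ns, 10 us)
#' are free parameters of the model.
#'
#' @param T_latency per-event handshake latency, seconds (> 0).
#' @param dt_pulse_base pulse width at mantissa W = 0, seconds (>= 0).
#' @param row_count rows per core (64).
#' @return list of class \code{"ifat_timing"}.
#' @export
timing_params <- function(T_latency = 50e-9, dt_pulse_base = 10e-6,
                          row_count = 64L) {
  stopifnot(is.numeric(T_latency), T_latency > 0,
            is.numeric(dt_pulse_base), dt_pulse_base >= 0,
            row_count >= 1)
  structure(list(T_latency = T_latency, dt_pulse_base = dt_pulse_base,
                 row_count = as.integer(row_count)),
            class = "ifat_timing")
}

#' Pulse width of a mantissa code
#'
#' \code{dt = dt_pulse_base * (1 + W/16)}: the pulse width carries the
#' linear mantissa of the strength code (the amplitude carries the
#' exponent, which does not affect timing).
#'
#' @param W mantissa 0--15 (vectorized).
#' @param p [timing_params()].
#' @return pulse width(s), seconds.
#' @export
pulse_width <- function(W, p = timing_params()) {
  W <- check_int_range(W, 0L, 15L, "W")
  p$dt_pulse_base * (1 + W / 16)
}

#' Schedule event deliveries through the two-tier pipeline
#'
#' In-order, non-preemptive service model.  The front end handshakes one
#' event at a time; a handshake takes \code{T_latency} and cannot begin
#' before the previous event's handshake completed.  The handshake of an
#' event whose target row still holds a previous pulse is not acknowledged:
#' the event blocks the head of the line until the row frees.  After the
#' handshake the pulse occupies the row's PWAM circuit for its pulse width.
#'
#' Service start of event i:
#' \code{h_i = max(arrival_i, h_{i-1} + T_latency, row_free[row_i])};
#' the pulse then runs over \code{[h_i + T_latency, h_i + T_latency + dt_i)}.
#'
#' @param events an [input_events()] data frame (times sorted); the row is
#'   \code{neuron \%/\% 32} and the mantissa \code{strength \%\% 16}.
#' @param p [timing_params()].
#' @return data.frame of class \code{c("ifat_trace", "data.frame")} with
#'   columns \code{arrival}, \code{row}, \code{start} (handshake start),
#'   \code{end} (pulse end).
#' @export
schedule_deliveries <- function(events, p = timing_params()) {
  if (is.unsorted(events$t)) stop("events must be time-sorted")
  n <- nrow(events)
  row <- events$neuron %/% 32L
  width <- pulse_width(events$strength %% 16L, p)
  start <- numeric(n); end <- numeric(n)
  row_free <- rep(-Inf, p$row_count)
  front_free <- -Inf
  for (i in seq_len(n)) {
    r <- row[i] + 1L
    h <- max(events$t[i], front_free, row_free[r])
    pulse_on <- h + p$T_latency
    start[i] <- h
    end[i] <- pulse_on + width[i]
    row_free[r] <- pulse_on + width[i]
    front_free <- h + p$T_latency
  }
  structure(data.frame(arrival = events$t, row = row,
                       start = start, end = end),
            class = c("ifat_trace", "data.frame"))
}

#' Throughput of a service trace
#'
#' Events per second actually sustained: \code{N / (last pulse end - first
#' arrival)}.  Under saturated input this matches the pipeline's
#' \code{1 / (mean handshake latency + mean row wait)} law: with every
#' event on one busy row it tends to \code{1 / (T_latency + dt)}, and with
#' waits fully hidden by row interleaving it tends to \code{1 / T_latency}.
#'
#' @param trace an \code{"ifat_trace"} from [schedule_deliveries()].
#' @return events per second.
#' @export
throughput_estimate <- function(trace) {
  if (nrow(trace) == 0) stop("empty trace")
  span <- max(trace$end) - min(trace$arrival)
  nrow(trace) / span
}

#' Throughput versus row interleaving
#'
#' Builds a saturated workload (all arrivals at t = 0) of \code{n_events}
#' events addressed round-robin over the first \code{rows} rows at a fixed
#' mantissa, schedules it, and reports the sustained throughput.  Sweeping
#' \code{rows} reproduces the qualitative throughput-versus-interleaving
#' shape of the two-tier pipeline.
#'
#' @param rows integer vector of interleaving factors (1--64 each).
#' @param W pulse-width mantissa 0--15 applied to every event.
#' @param p [timing_params()].
#' @param n_events events per workload.
#' @return data.frame with columns \code{rows}, \code{throughput}.
#' @export
throughput_sweep <- function(rows = c(1, 2, 4, 8, 16, 32, 64), W = 15,
                             p = timing_params(), n_events = 512) {
  stopifnot(all(rows >= 1), all(rows <= p$row_count))
  thr <- vapply(rows, function(k) {
    ev <- input_events(t = rep(0, n_events), core = 0L,
                       neuron = (seq_len(n_events) - 1L) %% as.integer(k) * 32L,
                       syn_type = 0L, strength = as.integer(W))
    throughput_estimate(schedule_deliveries(ev, p))
  }, numeric(1))
  data.frame(rows = as.integer(rows), throughput = thr)
}
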