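# Event-driven network engine.
#
# Between events the system is piecewise linear: synaptic conductances decay
# analytically and the two compartment voltages advance by exponential-Euler
# substeps no longer than dt.  External events, recurrently routed events and
# probe sampling instants all become time barriers; at each barrier the due
# conductance steps are applied.  Fired spikes are routed through the table
# and re-enqueued on a priority queue.  Everything is deterministic for fixed
# inputs.

# conductance-step ladder for all 256 strength codes, in units of g0
STEP_TABLE <- (1 + (0:255 %% 16) / 16) * 2^(0:255 %/% 16)

#' Run an event-driven network simulation
#'
#' Simulates a set of two-compartment neurons driven by timed external
#' synaptic events, with optional recurrent connectivity through a routing
#' table.  Neurons are identified by their global quadrant id
#' (\code{core * 2048 + neuron}); the simulated set is the union of ids
#' addressed by the events, the routing table and the probes.
#'
#' @param neurons a single [neuron_params()] shared by all neurons, or a
#'   named list mapping global id (as character) to per-neuron params.
#' @param events external input events ([input_events()]), time-sorted.
#'   Events beyond \code{duration} are dropped with a warning.
#' @param duration simulated time, seconds.
#' @param dt maximum membrane substep, seconds (default 10 us).
#' @param routing optional [routing_table()] for recurrent/virtual wiring.
#' @param axonal_delay delay added to routed events, seconds (default 0).
#' @param probe optional integer vector of global ids whose voltage and
#'   conductance traces are recorded.
#' @param probe_dt trace sampling interval, seconds (default 0.1 ms).
#' @return object of class \code{"ifat_sim"}: list with \code{spikes}
#'   (data.frame \code{t}, \code{id}, \code{core}, \code{neuron}),
#'   \code{traces} (named list of data.frames, one per probed id),
#'   \code{duration}, \code{ids}.
#' @export
run_simulation <- function(neurons, events, duration, dt = 1e-5,
                           routing = NULL, axonal_delay = 0,
                           probe = NULL, probe_dt = 1e-4) {
  stopifnot(duration > 0, dt > 0)
  if (is.null(events) || nrow(events) == 0) events <- empty_events()
  if (is.unsorted(events$t)) stop("external events must be time-sorted")
  if (any(events$t > duration)) {
    warning("dropping events beyond 'duration'")
    events <- events[events$t <= duration, , drop = FALSE]
  }

  ev_id <- if (nrow(events)) global_id(events$core, events$neuron) else integer(0)
  rt_ids <- if (!is.null(routing) && nrow(routing)) {
    c(routing$pre_id, global_id(routing$core, routing$neuron))
  } else integer(0)
  ids <- sort(unique(c(ev_id, rt_ids, as.integer(probe))))
  if (length(ids) == 0) stop("no neurons addressed; nothing to simulate")
  N <- length(ids)

  getp <- function(id) {
    if (inherits(neurons, "ifat_neuron")) return(neurons)
    p <- neurons[[as.character(id)]]
    if (is.null(p)) stop(sprintf("no params for neuron id %d", id))
    p
  }
  plist <- lapply(ids, getp)
  pull <- function(f) vapply(plist, f, numeric(1))
  C0 <- pull(function(p) p$distal$C_mem);  C1 <- pull(function(p) p$proximal$C_mem)
  GL0 <- pull(function(p) p$distal$G_leak); GL1 <- pull(function(p) p$proximal$G_leak)
  EL0 <- pull(function(p) p$distal$E_leak); EL1 <- pull(function(p) p$proximal$E_leak)
  Gc <- pull(function(p) p$G_comp)
  Vth <- pull(function(p) p$V_thresh); Vres <- pull(function(p) p$V_reset)
  trefr <- pull(function(p) p$t_refr)
  Vfl <- pull(function(p) if (is.null(p$V_floor)) -Inf else p$V_floor)
  has_floor <- any(is.finite(Vfl))
  Esyn <- sapply(1:4, function(j) pull(function(p) p$synapses[[j]]$E_rev))
  tau <- sapply(1:4, function(j) pull(function(p) p$synapses[[j]]$tau_syn))
  g0s <- sapply(1:4, function(j) pull(function(p) p$synapses[[j]]$g0))
  Esyn <- matrix(Esyn, nrow = N); tau <- matrix(tau, nrow = N)
  g0s <- matrix(g0s, nrow = N)

  # state
  V0 <- EL0; V1 <- EL1
  G <- matrix(0, nrow = N, ncol = 4)
  refr_until <- rep(-Inf, N)
  dec_dt <- exp(-dt / tau)                 # cached decay for full substeps

  # external events as flat vectors
  ev_t <- events$t
  ev_idx <- match(ev_id, ids)
  ev_syn <- events$syn_type + 1L
  ev_dG <- STEP_TABLE[events$strength + 1L] *
    g0s[cbind(ev_idx, ev_syn)]
  n_ev <- length(ev_t)

  # routing lookup: list of target batches per pre id
  route <- NULL
  if (!is.null(routing) && nrow(routing)) {
    tgt_idx <- match(global_id(routing$core, routing$neuron), ids)
    tgt_syn <- routing$syn_type + 1L
    tgt_dG <- STEP_TABLE[routing$strength + 1L] * g0s[cbind(tgt_idx, tgt_syn)]
    route <- split(data.frame(idx = tgt_idx, syn = tgt_syn, dG = tgt_dG),
                   factor(routing$pre_id, levels = ids))
  }

  # min-heap of recurrent event batches keyed by (t, insertion seq)
  hp_t <- numeric(0); hp_seq <- integer(0); hp_batch <- list(); hp_n <- 0L
  seq_ctr <- 0L
  heap_push <- function(tt, batch) {
    hp_n <<- hp_n + 1L; seq_ctr <<- seq_ctr + 1L
    hp_t[hp_n] <<- tt; hp_seq[hp_n] <<- seq_ctr; hp_batch[[hp_n]] <<- batch
    i <- hp_n
    while (i > 1L) {
      par <- i %/% 2L
      if (hp_t[par] < hp_t[i] ||
          (hp_t[par] == hp_t[i] && hp_seq[par] < hp_seq[i])) break
      swap_heap(par, i); i <- par
    }
  }
  swap_heap <- function(i, j) {
    tmp <- hp_t[i]; hp_t[i] <<- hp_t[j]; hp_t[j] <<- tmp
    tmpi <- hp_seq[i]; hp_seq[i] <<- hp_seq[j]; hp_seq[j] <<- tmpi
    tmpb <- hp_batch[[i]]; hp_batch[[i]] <<- hp_batch[[j]]; hp_batch[[j]] <<- tmpb
  }
  heap_pop <- function() {
    top <- hp_batch[[1L]]
    hp_t[1L] <<- hp_t[hp_n]; hp_seq[1L] <<- hp_seq[hp_n]
    hp_batch[[1L]] <<- hp_batch[[hp_n]]
    hp_n <<- hp_n - 1L
    i <- 1L
    repeat {
      l <- 2L * i; r <- l + 1L; m <- i
      if (l <= hp_n && (hp_t[l] < hp_t[m] ||
          (hp_t[l] == hp_t[m] && hp_seq[l] < hp_seq[m]))) m <- l
      if (r <= hp_n && (hp_t[r] < hp_t[m] ||
          (hp_t[r] == hp_t[m] && hp_seq[r] < hp_seq[m]))) m <- r
      if (m == i) break
      swap_heap(i, m); i <- m
    }
    top
  }

  # probes
  probe_idx <- if (length(probe)) match(as.integer(probe), ids) else integer(0)
  do_probe <- length(probe_idx) > 0
  if (do_probe) {
    pr_times <- seq(0, duration, by = probe_dt)
    pr_n <- length(pr_times)
    pr_V0 <- matrix(NA_real_, pr_n, length(probe_idx))
    pr_V1 <- matrix(NA_real_, pr_n, length(probe_idx))
    pr_G <- array(NA_real_, c(pr_n, length(probe_idx), 4))
    pr_next <- 1L
  }

  # spike buffers
  sp_t <- numeric(256); sp_i <- integer(256); sp_n <- 0L
  push_spikes <- function(idxs, tt) {
    k <- length(idxs)
    if (sp_n + k > length(sp_t)) {
      newlen <- max(2L * length(sp_t), sp_n + k)
      length(sp_t) <<- newlen; length(sp_i) <<- newlen
    }
    sp_t[(sp_n + 1L):(sp_n + k)] <<- tt
    sp_i[(sp_n + 1L):(sp_n + k)] <<- idxs
    sp_n <<- sp_n + k
  }

  t <- 0
  record_probe <- function(tt) {
    # record all probe instants due at or before tt
    while (do_probe && pr_next <= pr_n && pr_times[pr_next] <= tt + 1e-15) {
      pr_V0[pr_next, ] <<- V0[probe_idx]
      pr_V1[pr_next, ] <<- V1[probe_idx]
      pr_G[pr_next, , ] <<- G[probe_idx, , drop = FALSE]
      pr_next <<- pr_next + 1L
    }
  }

  handle_spikes <- function(tt) {
    # small slack so a lockout ending exactly on a substep boundary is not
    # missed to floating-point accumulation
    fired <- which(V1 >= Vth & tt >= refr_until - 1e-12)
    if (length(fired) == 0) return(invisible())
    push_spikes(fired, tt)
    V1[fired] <<- Vres[fired]
    refr_until[fired] <<- tt + trefr[fired]
    if (!is.null(route)) {
      for (f in fired) {
        b <- route[[f]]
        if (!is.null(b) && nrow(b)) heap_push(tt + axonal_delay, b)
      }
    }
  }

  # apply all queued recurrent batches due at (or before) the current time
  drain_due <- function() {
    while (hp_n > 0L && hp_t[1L] <= t + 1e-15) {
      b <- heap_pop()
      for (k in seq_len(nrow(b))) {
        G[b$idx[k], b$syn[k]] <<- G[b$idx[k], b$syn[k]] + b$dG[k]
      }
    }
  }

  advance_to <- function(t_target) {
    while (t < t_target - 1e-15) {
      h <- min(dt, t_target - t)
      if (hp_n > 0L) {
        gap <- hp_t[1L] - t
        if (gap <= 1e-15) { drain_due(); next }   # due now (zero delay)
        h <- min(h, gap)                          # stop at the next delivery
      }
      gt0 <- G[, 1] + G[, 2] + GL0 + Gc
      gt1 <- G[, 3] + G[, 4] + GL1 + Gc
      num0 <- G[, 1] * Esyn[, 1] + G[, 2] * Esyn[, 2] + GL0 * EL0 + Gc * V1
      num1 <- G[, 3] * Esyn[, 3] + G[, 4] * Esyn[, 4] + GL1 * EL1 + Gc * V0
      ok0 <- gt0 > 0; ok1 <- gt1 > 0
      vinf0 <- ifelse(ok0, num0 / pmax(gt0, 1e-300), V0)
      vinf1 <- ifelse(ok1, num1 / pmax(gt1, 1e-300), V1)
      nV0 <- vinf0 + (V0 - vinf0) * exp(-gt0 * h / C0)
      nV1 <- vinf1 + (V1 - vinf1) * exp(-gt1 * h / C1)
      if (has_floor) {
        nV0 <- pmax(nV0, Vfl); nV1 <- pmax(nV1, Vfl)
      }
      V0 <<- nV0; V1 <<- nV1
      if (h == dt) G <<- G * dec_dt else G <<- G * exp(-h / tau)
      t <<- t + h
      handle_spikes(t)
      drain_due()
      record_probe(t)
    }
  }

  if (do_probe) record_probe(0)
  ei <- 1L
  repeat {
    t_ext <- if (ei <= n_ev) ev_t[ei] else Inf
    t_rec <- if (hp_n > 0L) hp_t[1L] else Inf
    t_pr <- if (do_probe && pr_next <= pr_n) pr_times[pr_next] else Inf
    t_next <- min(t_ext, t_rec, t_pr, duration)
    advance_to(t_next)
    if (t_next >= duration - 1e-15 && t_ext > duration && t_rec > duration) {
      advance_to(duration)
      break
    }
    # apply all conductance steps due exactly now: external first (stream
    # order), then routed batches in insertion order
    while (ei <= n_ev && ev_t[ei] <= t + 1e-15) {
      j <- ev_idx[ei]; s <- ev_syn[ei]
      G[j, s] <- G[j, s] + ev_dG[ei]
      ei <- ei + 1L
    }
    drain_due()
    handle_spikes(t)
    record_probe(t)
    if (t >= duration - 1e-15) break
  }

  spikes <- if (sp_n > 0) {
    sid <- ids[sp_i[seq_len(sp_n)]]
    data.frame(t = sp_t[seq_len(sp_n)], id = sid,
               core = sid %/% 2048L, neuron = sid %% 2048L)
  } else {
    data.frame(t = numeric(0), id = integer(0),
               core = integer(0), neuron = integer(0))
  }

  traces <- NULL
  if (do_probe) {
    traces <- lapply(seq_along(probe_idx), function(k) {
      data.frame(t = pr_times, V_mem0 = pr_V0[, k], V_mem1 = pr_V1[, k],
                 G_syn0 = pr_G[, k, 1], G_syn1 = pr_G[, k, 2],
                 G_syn2 = pr_G[, k, 3], G_syn3 = pr_G[, k, 4])
    })
    names(traces) <- as.character(ids[probe_idx])
  }

  structure(list(spikes = spikes, traces = traces, duration = duration,
                 ids = ids, final = list(V_mem0 = V0, V_mem1 = V1, G_syn = G)),
            class = "ifat_sim")
}

#' @export
print.ifat_sim <- function(x, ...) {
  cat("<ifat_sim> ", length(x$ids), " neuron(s), ",
      nrow(x$spikes), " output spike(s) over ", x$duration, " s\n", sep = "")
  if (nrow(x$spikes)) {
    cat("  mean output rate: ",
        format(nrow(x$spikes) / x$duration / length(x$ids), digits = 4),
        " Hz per neuron\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.ifat_sim <- function(x, trace = NULL, ...) {
  if (!is.null(trace) && !is.null(x$traces)) {
    tr <- x$traces[[as.character(trace)]]
    if (is.null(tr)) stop("no trace recorded for id ", trace)
    graphics::plot(tr$t * 1e3, tr$V_mem1, type = "l", xlab = "time (ms)",
                   ylab = "V (V)", ...)
    graphics::lines(tr$t * 1e3, tr$V_mem0, lty = 2)
    graphics::legend("topright", legend = c("proximal", "distal"),
                     lty = c(1, 2), bty = "n")
  } else {
    graphics::plot(x$spikes$t * 1e3, x$spikes$id, pch = "|",
                   xlab = "time (ms)", ylab = "neuron id",
                   xlim = c(0, x$duration * 1e3), ...)
  }
  invisible(x)
}

#' Measure an activation curve
#'
#' Output rate versus input rate for one neuron driven by a single spike
#' train on one synapse, one simulation per rate.  A burn-in transient is
#' discarded before counting output spikes.
#'
#' @param neuron [neuron_params()].
#' @param kind input train kind, \code{"regular"} or \code{"poisson"}.
#' @param rates input rates to sweep, Hz.
#' @param strength strength byte applied to every input event.
#' @param syn_index target synapse (default 2, proximal excitatory).
#' @param duration seconds per rate (default 1).
#' @param dt membrane substep, seconds.
#' @param seed RNG seed (Poisson input only).
#' @param burn_in discarded initial interval, seconds (default 0.1).
#' @return data.frame of class \code{c("ifat_activation", "data.frame")}
#'   with columns \code{input_rate}, \code{output_rate}.
#' @export
measure_activation <- function(neuron, kind, rates, strength = 80L,
                               syn_index = 2L, duration = 1, dt = 1e-5,
                               seed = NULL, burn_in = 0.1) {
  stopifnot(all(rates >= 0), burn_in < duration)
  out <- with_seed(seed, vapply(rates, function(r) {
    ev <- gen_event_train(kind, r, duration, core = 0L, neuron = 0L,
                          syn_type = syn_index, strength = strength)
    if (nrow(ev) == 0) return(0)
    sim <- run_simulation(neuron, ev, duration, dt = dt)
    sum(sim$spikes$t > burn_in) / (duration - burn_in)
  }, numeric(1)))
  structure(data.frame(input_rate = rates, output_rate = out),
            class = c("ifat_activation", "data.frame"))
}

#' @export
plot.ifat_activation <- function(x, ...) {
  graphics::plot(x$input_rate, x$output_rate, type = "b",
                 xlab = "input rate (Hz)", ylab = "output rate (Hz)", ...)
  invisible(x)
}
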