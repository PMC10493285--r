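# Independent brute-force oracles.
#
# dense_sim: fixed-step forward-Euler integrator for a small set of
# two-compartment neurons.  No event queue, no analytic membrane update:
# every step integrates dV/dt = I/C explicitly, events are applied at the
# step boundary at or after their timestamp, threshold/reset and
# refractory semantics as in the model definition.  Deliberately shares no
# code with the event-driven engine.

dense_sim <- function(neuron, events, duration, h, routing = NULL,
                      record_v = FALSE) {
  ids <- sort(unique(c(
    if (nrow(events)) events$core * 2048L + events$neuron else integer(0),
    if (!is.null(routing) && nrow(routing))
      c(routing$pre_id, routing$core * 2048L + routing$neuron) else integer(0),
    0L)))
  N <- length(ids)
  getp <- function(id) {
    if (inherits(neuron, "ifat_neuron")) neuron else neuron[[as.character(id)]]
  }
  P <- lapply(ids, getp)
  num <- function(f) vapply(P, f, numeric(1))
  C0 <- num(function(p) p$distal$C_mem); C1 <- num(function(p) p$proximal$C_mem)
  GL0 <- num(function(p) p$distal$G_leak); GL1 <- num(function(p) p$proximal$G_leak)
  EL0 <- num(function(p) p$distal$E_leak); EL1 <- num(function(p) p$proximal$E_leak)
  Gc <- num(function(p) p$G_comp)
  Vth <- num(function(p) p$V_thresh); Vre <- num(function(p) p$V_reset)
  trf <- num(function(p) p$t_refr)
  Vfl <- num(function(p) if (is.null(p$V_floor)) -Inf else p$V_floor)
  E <- t(vapply(P, function(p) vapply(p$synapses, function(s) s$E_rev, 0),
                numeric(4)))
  tau <- t(vapply(P, function(p) vapply(p$synapses, function(s) s$tau_syn, 0),
                  numeric(4)))
  g0 <- t(vapply(P, function(p) vapply(p$synapses, function(s) s$g0, 0),
                 numeric(4)))
  dim(E) <- c(N, 4); dim(tau) <- c(N, 4); dim(g0) <- c(N, 4)
  dec <- exp(-h / tau)

  V0 <- EL0; V1 <- EL1
  G <- matrix(0, N, 4)
  refr <- rep(-Inf, N)
  n_steps <- ceiling(duration / h - 1e-9)
  ev_step <- ceiling(events$t / h - 1e-9)
  ev_id <- match(events$core * 2048L + events$neuron, ids)
  ev_syn <- events$syn_type + 1L
  ev_dG <- (1 + (events$strength %% 16L) / 16) * 2^(events$strength %/% 16L) *
    g0[cbind(ev_id, ev_syn)]
  ev_by_step <- split(seq_len(nrow(events)), ev_step)
  spikes_t <- numeric(0); spikes_i <- integer(0)
  vtrace <- if (record_v) matrix(NA_real_, n_steps + 1, 2) else NULL
  if (record_v) vtrace[1, ] <- c(V0[1], V1[1])
  rt_by_pre <- if (!is.null(routing) && nrow(routing)) {
    split(seq_len(nrow(routing)), routing$pre_id)
  } else NULL

  for (s in seq_len(n_steps)) {
    due <- ev_by_step[[as.character(s - 1L)]]
    if (!is.null(due)) {
      for (k in due) G[ev_id[k], ev_syn[k]] <- G[ev_id[k], ev_syn[k]] + ev_dG[k]
    }
    I0 <- G[, 1] * (E[, 1] - V0) + G[, 2] * (E[, 2] - V0) +
      GL0 * (EL0 - V0) + Gc * (V1 - V0)
    I1 <- G[, 3] * (E[, 3] - V1) + G[, 4] * (E[, 4] - V1) +
      GL1 * (EL1 - V1) + Gc * (V0 - V1)
    V0 <- pmax(V0 + h * I0 / C0, Vfl)
    V1 <- pmax(V1 + h * I1 / C1, Vfl)
    G <- G * dec
    t_now <- s * h
    fired <- which(V1 >= Vth & t_now >= refr - 1e-12)
    if (length(fired)) {
      spikes_t <- c(spikes_t, rep(t_now, length(fired)))
      spikes_i <- c(spikes_i, ids[fired])
      V1[fired] <- Vre[fired]
      refr[fired] <- t_now + trf[fired]
      if (!is.null(rt_by_pre)) {
        for (f in fired) {
          rows <- rt_by_pre[[as.character(ids[f])]]
          for (r in rows) {
            tgt <- match(routing$core[r] * 2048L + routing$neuron[r], ids)
            jj <- routing$syn_type[r] + 1L
            G[tgt, jj] <- G[tgt, jj] +
              (1 + (routing$strength[r] %% 16L) / 16) *
              2^(routing$strength[r] %/% 16L) * g0[tgt, jj]
          }
        }
      }
    }
    if (record_v) vtrace[s + 1, ] <- c(V0[1], V1[1])
  }
  list(spikes = data.frame(t = spikes_t, id = spikes_i), V = vtrace,
       t = (0:n_steps) * h)
}

# Brute-force continuous-time state-machine oracle for the two-tier
# pipeline: the head-of-line event begins its handshake once it has
# arrived, the front end is free, and its target row has released the
# previous pulse; the handshake takes T_latency and the pulse then holds
# the row for its width.  Independently coded from schedule_deliveries.
queue_oracle <- function(events, p) {
  n <- nrow(events)
  row <- events$neuron %/% 32L
  width <- p$dt_pulse_base * (1 + (events$strength %% 16L) / 16)
  clock <- -Inf
  rows_busy <- rep(-Inf, p$row_count)
  start <- numeric(n); end <- numeric(n)
  for (i in seq_len(n)) {
    t_begin <- max(events$t[i], clock, rows_busy[row[i] + 1L])
    t_pulse <- t_begin + p$T_latency
    rows_busy[row[i] + 1L] <- t_pulse + width[i]
    clock <- t_pulse
    start[i] <- t_begin
    end[i] <- t_pulse + width[i]
  }
  data.frame(arrival = events$t, row = row, start = start, end = end)
}
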