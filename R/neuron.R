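#' Synapse parameters
#'
#' One of the four first-order conductance synapses of an IFAT neuron.
#' Synapses 0 and 1 feed the distal compartment, synapses 2 and 3 the
#' proximal compartment.  Each synapse is a conductance \code{G} decaying
#' exponentially with time constant \code{tau_syn} toward zero and driving
#' current \code{G * (E_rev - V)} into its compartment.  An incoming address
#' event increments \code{G} by [conductance_step()] of its strength byte.
#'
#' @param syn_index integer 0--3.
#' @param E_rev reversal potential, volts.  Determines the synapse type:
#'   above rest it is excitatory; at or near rest it is shunting/inhibitory.
#' @param tau_syn conductance decay time constant, seconds (> 0).
#' @param g0 conductance-step quantum, siemens (> 0).
#' @return list of class \code{"ifat_synapse"}.
#' @export
synapse_params <- function(syn_index, E_rev, tau_syn, g0) {
  syn_index <- check_int_range(syn_index, 0L, 3L, "syn_index")
  stopifnot(is.numeric(E_rev), is.finite(E_rev),
            is.numeric(tau_syn), tau_syn > 0,
            is.numeric(g0), g0 > 0)
  structure(list(syn_index = syn_index, E_rev = E_rev,
                 tau_syn = tau_syn, g0 = g0),
            class = "ifat_synapse")
}

#' Compartment parameters
#'
#' Passive membrane of one compartment: capacitance, leak conductance and
#' leak reversal potential.
#'
#' @param C_mem membrane capacitance, farads (> 0).
#' @param G_leak leak conductance, siemens (>= 0).
#' @param E_leak leak reversal potential, volts.
#' @return list of class \code{"ifat_compartment"}.
#' @export
compartment_params <- function(C_mem, G_leak, E_leak) {
  stopifnot(is.numeric(C_mem), C_mem > 0,
            is.numeric(G_leak), G_leak >= 0,
            is.numeric(E_leak), is.finite(E_leak))
  structure(list(C_mem = C_mem, G_leak = G_leak, E_leak = E_leak),
            class = "ifat_compartment")
}

#' Two-compartment neuron parameters
#'
#' Full parameter set of one two-compartment conductance-based leaky
#' integrate-and-fire neuron.  The distal compartment (voltage
#' \code{V_mem0}, synapses 0--1) couples to the proximal compartment
#' (voltage \code{V_mem1}, synapses 2--3) through \code{G_comp}.  Spiking
#' is abstracted as threshold crossing on the proximal voltage followed by
#' an instantaneous reset: when \code{V_mem1 >= V_thresh} outside the
#' refractory lockout, a spike is emitted, \code{V_mem1} is set to
#' \code{V_reset}, and the distal voltage and all conductances are left
#' untouched.
#'
#' Defaults give a 20 ms membrane time constant (1 pF / 50 pS), excitatory
#' reversal at 1 V, inhibitory (shunting) reversal at rest (0 V), 5 ms
#' synaptic decay, threshold 0.5 V and a 100 us refractory period.  The
#' refractory period models the dead time of the spike-generation and
#' event-registration circuit; it bounds the output rate at 10 kHz, so
#' that under saturating drive each input spike of a 10 kHz train yields
#' exactly one output spike (gain saturates to one) instead of the
#' threshold-reset abstraction free-running at the numerical step rate.
#' All values are plain SI numbers and fully overridable.
#'
#' @param distal,proximal [compartment_params()] for the two compartments.
#' @param G_comp inter-compartment coupling conductance, siemens (>= 0).
#' @param V_thresh firing threshold on the proximal voltage, volts.
#' @param V_reset post-spike proximal voltage, volts (< \code{V_thresh}).
#' @param t_refr refractory period, seconds (>= 0).
#' @param V_floor lower membrane rail, volts (default \code{-Inf}, i.e. no
#'   rail).  A silicon membrane cannot swing below its supply rail; setting
#'   a floor bounds the hyperpolarizing excursion of strongly inhibited
#'   compartments.
#' @param synapses list of four [synapse_params()] with indices 0,1,2,3.
#' @return list of class \code{"ifat_neuron"}.
#' @examples
#' np <- neuron_params()
#' np$synapses[[3]]$E_rev   # proximal excitatory synapse
#' @export
neuron_params <- function(distal = compartment_params(1e-12, 50e-12, 0),
                          proximal = compartment_params(1e-12, 50e-12, 0),
                          G_comp = 1e-9,
                          V_thresh = 0.5,
                          V_reset = 0,
                          t_refr = 1e-4,
                          V_floor = -Inf,
                          synapses = default_synapses()) {
  stopifnot(inherits(distal, "ifat_compartment"),
            inherits(proximal, "ifat_compartment"),
            is.numeric(G_comp), G_comp >= 0,
            V_reset < V_thresh, t_refr >= 0,
            is.list(synapses), length(synapses) == 4)
  idx <- vapply(synapses, function(s) s$syn_index, integer(1))
  if (!identical(sort(idx), 0:3)) {
    stop("'synapses' must contain indices 0, 1, 2 and 3 exactly once")
  }
  synapses <- synapses[order(idx)]
  stopifnot(V_floor <= V_reset)
  structure(list(distal = distal, proximal = proximal, G_comp = G_comp,
                 V_thresh = V_thresh, V_reset = V_reset, t_refr = t_refr,
                 V_floor = V_floor, synapses = synapses),
            class = "ifat_neuron")
}

#' Default synapse set
#'
#' Synapses 0 (distal) and 2 (proximal) excitatory with 1 V reversal;
#' synapses 1 (distal) and 3 (proximal) shunting with reversal at rest.
#'
#' @param E_exc,E_inh excitatory and inhibitory reversal potentials, volts.
#' @param tau_syn synaptic time constant, seconds.
#' @param g0 conductance-step quantum, siemens.
#' @return list of four [synapse_params()].
#' @export
default_synapses <- function(E_exc = 1, E_inh = 0, tau_syn = 5e-3, g0 = 1e-12) {
  list(synapse_params(0L, E_exc, tau_syn, g0),
       synapse_params(1L, E_inh, tau_syn, g0),
       synapse_params(2L, E_exc, tau_syn, g0),
       synapse_params(3L, E_inh, tau_syn, g0))
}

#' @export
print.ifat_neuron <- function(x, ...) {
  cat("<ifat_neuron> two-compartment conductance-based LIF\n")
  cat(sprintf("  distal:   C = %.3g F, G_leak = %.3g S, E_leak = %.3g V\n",
              x$distal$C_mem, x$distal$G_leak, x$distal$E_leak))
  cat(sprintf("  proximal: C = %.3g F, G_leak = %.3g S, E_leak = %.3g V\n",
              x$proximal$C_mem, x$proximal$G_leak, x$proximal$E_leak))
  cat(sprintf("  G_comp = %.3g S, V_thresh = %.3g V, V_reset = %.3g V, t_refr = %.3g s\n",
              x$G_comp, x$V_thresh, x$V_reset, x$t_refr))
  for (s in x$synapses) {
    cat(sprintf("  syn %d (%s): E_rev = %.3g V, tau = %.3g s, g0 = %.3g S\n",
                s$syn_index, if (s$syn_index < 2) "distal" else "proximal",
                s$E_rev, s$tau_syn, s$g0))
  }
  invisible(x)
}

#' Neuron state
#'
#' Instantaneous state of one neuron: the two compartment voltages, the
#' four synaptic conductances, the time of the last update and the end of
#' the refractory lockout.
#'
#' @param V_mem0,V_mem1 distal and proximal voltages, volts.
#' @param G_syn numeric length-4 vector of synaptic conductances, siemens
#'   (all >= 0), ordered by synapse index.
#' @param t_last time of last state update, seconds.
#' @param t_refr_until end of refractory lockout, seconds.
#' @return list of class \code{"ifat_state"}.
#' @export
neuron_state <- function(V_mem0 = 0, V_mem1 = 0, G_syn = numeric(4),
                         t_last = 0, t_refr_until = -Inf) {
  stopifnot(is.finite(V_mem0), is.finite(V_mem1),
            length(G_syn) == 4, all(G_syn >= 0))
  structure(list(V_mem0 = V_mem0, V_mem1 = V_mem1, G_syn = as.numeric(G_syn),
                 t_last = t_last, t_refr_until = t_refr_until),
            class = "ifat_state")
}

#' Decay synaptic conductances analytically
#'
#' Each conductance is first-order linear, so over an event-free interval
#' \code{dt} it decays exactly: \code{G <- G * exp(-dt / tau_syn)}.
#' \code{t_last} advances by \code{dt}.
#'
#' @param state [neuron_state()].
#' @param dt interval, seconds (>= 0).
#' @param params [neuron_params()].
#' @return updated state.
#' @export
decay_conductances <- function(state, dt, params) {
  if (!is.numeric(dt) || dt < 0) stop("'dt' must be >= 0")
  tau <- vapply(params$synapses, function(s) s$tau_syn, numeric(1))
  state$G_syn <- state$G_syn * exp(-dt / tau)
  state$t_last <- state$t_last + dt
  state
}

#' Apply one synaptic event
#'
#' Increments the conductance of the addressed synapse by the conductance
#' step of the strength byte.  The PWAM drive pulse is collapsed to this
#' instantaneous step; no other state changes.
#'
#' @param state [neuron_state()].
#' @param syn_index synapse 0--3.
#' @param byte strength code 0--255.
#' @param params [neuron_params()].
#' @return updated state.
#' @export
apply_synaptic_event <- function(state, syn_index, byte, params) {
  syn_index <- check_int_range(syn_index, 0L, 3L, "syn_index")
  dG <- conductance_step(decode_strength(byte), params$synapses[[syn_index + 1L]]$g0)
  state$G_syn[syn_index + 1L] <- state$G_syn[syn_index + 1L] + dG
  state
}

#' Advance the compartment voltages one step
#'
#' One exponential-Euler step of the coupled two-compartment system with
#' the synaptic conductances (and the opposite compartment's voltage in the
#' coupling term) frozen at their start-of-step values.  Each voltage moves
#' toward its instantaneous equilibrium
#' \code{V_inf = (sum G_j E_j + G_leak E_leak + G_comp V_other) / G_tot}
#' with rate \code{G_tot / C_mem}, which keeps every voltage inside the
#' convex hull of the active reversal potentials and the starting values
#' for any step size.  The spike-generation feedback current is excluded
#' (threshold-and-reset abstraction, see [fire_and_reset()]).
#'
#' @param state [neuron_state()].
#' @param params [neuron_params()].
#' @param dt step, seconds (> 0).
#' @return updated state (voltages and \code{t_last}; conductances are not
#'   decayed here -- compose with [decay_conductances()]).
#' @export
integrate_step <- function(state, params, dt) {
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be > 0")
  E <- vapply(params$synapses, function(s) s$E_rev, numeric(1))
  G <- state$G_syn
  d <- params$distal; p <- params$proximal; Gc <- params$G_comp

  gt0 <- G[1] + G[2] + d$G_leak + Gc
  gt1 <- G[3] + G[4] + p$G_leak + Gc
  V0 <- state$V_mem0; V1 <- state$V_mem1
  vinf0 <- if (gt0 > 0) (G[1] * E[1] + G[2] * E[2] + d$G_leak * d$E_leak + Gc * V1) / gt0 else V0
  vinf1 <- if (gt1 > 0) (G[3] * E[3] + G[4] * E[4] + p$G_leak * p$E_leak + Gc * V0) / gt1 else V1
  fl <- if (is.null(params$V_floor)) -Inf else params$V_floor
  state$V_mem0 <- max(vinf0 + (V0 - vinf0) * exp(-gt0 * dt / d$C_mem), fl)
  state$V_mem1 <- max(vinf1 + (V1 - vinf1) * exp(-gt1 * dt / p$C_mem), fl)
  state$t_last <- state$t_last + dt
  state
}

#' Threshold test and reset
#'
#' If the proximal voltage has reached threshold and the neuron is not in
#' refractory lockout, emit a spike at time \code{t}: the proximal voltage
#' is reset to \code{V_reset} and the lockout extended to
#' \code{t + t_refr}.  The distal compartment and the conductances are
#' unchanged.
#'
#' @param state [neuron_state()] already advanced to time \code{t}.
#' @param params [neuron_params()].
#' @param t current time, seconds.
#' @return list with \code{state} (possibly reset) and \code{spike}
#'   (\code{NULL}, or the spike time \code{t}).
#' @export
fire_and_reset <- function(state, params, t) {
  spike <- NULL
  if (state$V_mem1 >= params$V_thresh && t >= state$t_refr_until) {
    spike <- t
    state$V_mem1 <- params$V_reset
    state$t_refr_until <- t + params$t_refr
  }
  list(state = state, spike = spike)
}
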