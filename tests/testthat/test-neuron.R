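# single-neuron dynamics: synaptic decay, event application, exponential
# Euler stepping, threshold/reset

test_that("conductance decay is exact and composes as a semigroup", {
  np <- test_neuron()
  st <- neuron_state(G_syn = rep(1e-9, 4))
  expect_identical(decay_conductances(st, 0, np)$G_syn, st$G_syn)

  tau <- np$synapses[[1]]$tau_syn
  st1 <- decay_conductances(st, tau, np)
  expect_equal(st1$G_syn, rep(1e-9 * exp(-1), 4))

  set.seed(1)
  for (i in 1:10) {
    d1 <- runif(1, 0, 0.02); d2 <- runif(1, 0, 0.02)
    a <- decay_conductances(decay_conductances(st, d1, np), d2, np)
    b <- decay_conductances(st, d1 + d2, np)
    expect_equal(a$G_syn, b$G_syn, tolerance = 1e-12)
  }
  expect_error(decay_conductances(st, -1e-3, np), "dt")
})

test_that("synaptic events add conductance steps and validate their index", {
  np <- test_neuron()
  g0 <- np$synapses[[3]]$g0
  st <- apply_synaptic_event(neuron_state(), 2L, 0L, np)
  expect_equal(st$G_syn[3], g0)
  st <- apply_synaptic_event(st, 2L, 0L, np)
  expect_equal(st$G_syn[3], 2 * g0)

  np_f <- neuron_params(synapses = default_synapses(g0 = 1e-15))
  st <- apply_synaptic_event(neuron_state(), 0L, 255L, np_f)
  expect_equal(st$G_syn[1], 63488e-15)
  expect_error(apply_synaptic_event(neuron_state(), 4L, 0L, np), "range")
})

test_that("coupled compartments relax to the analytic fixed point", {
  # equal leak reversals: unique fixed point at E for any coupling
  np <- neuron_params(distal = compartment_params(1e-12, 50e-12, 0.2),
                      proximal = compartment_params(1e-12, 50e-12, 0.2),
                      V_thresh = 10)
  st <- neuron_state(V_mem0 = 0, V_mem1 = 0.5)
  for (i in 1:5000) st <- integrate_step(st, np, 1e-4)
  expect_equal(st$V_mem0, 0.2, tolerance = 1e-6)
  expect_equal(st$V_mem1, 0.2, tolerance = 1e-6)

  # leak-only 2x2 system: V0 = 1/30, V1 = 2/30 volts
  np2 <- neuron_params(distal = compartment_params(1e-12, 1e-9, 0),
                       proximal = compartment_params(1e-12, 1e-9, 0.1),
                       G_comp = 1e-9, V_thresh = 10)
  st <- neuron_state()
  for (i in 1:20000) st <- integrate_step(st, np2, 1e-5)
  expect_equal(st$V_mem0, 1 / 30, tolerance = 1e-5)
  expect_equal(st$V_mem1, 2 / 30, tolerance = 1e-5)

  expect_error(integrate_step(st, np2, 0), "dt")
  expect_error(integrate_step(st, np2, -1e-5), "dt")
})

test_that("voltages stay inside the hull of reversal potentials", {
  # constant strong excitation toward E_rev = 1 V never overshoots it
  np <- neuron_params(V_thresh = 10)   # disable spiking
  st <- neuron_state(G_syn = c(0, 0, 1e-8, 0))
  vmax <- -Inf
  for (i in 1:2000) {
    st <- integrate_step(st, np, 1e-4)   # no decay: worst case
    vmax <- max(vmax, st$V_mem1, st$V_mem0)
  }
  expect_lt(vmax, 1 + 1e-12)
  expect_gt(st$V_mem1, 0.99)   # and it does approach the reversal

  # random event barrage: hull of {E_rev, E_leak, V_init} = [0, 1]
  set.seed(42)
  st <- neuron_state()
  for (i in 1:500) {
    st <- apply_synaptic_event(st, sample(0:3, 1), sample(0:255, 1), np)
    st <- integrate_step(st, np, runif(1, 1e-6, 1e-4))
    st <- decay_conductances(st, runif(1, 0, 1e-3), np)
    expect_true(st$V_mem0 >= -1e-12 && st$V_mem0 <= 1 + 1e-12)
    expect_true(st$V_mem1 >= -1e-12 && st$V_mem1 <= 1 + 1e-12)
    expect_true(all(st$G_syn >= 0))
  }
})

test_that("threshold crossing spikes, resets and honors the lockout", {
  np <- test_neuron()
  st <- neuron_state(V_mem1 = np$V_thresh - 1e-9)
  r <- fire_and_reset(st, np, 0)
  expect_null(r$spike)
  expect_equal(r$state$V_mem1, np$V_thresh - 1e-9)

  st <- neuron_state(V_mem0 = 0.3, V_mem1 = np$V_thresh,
                     G_syn = c(1e-9, 0, 0, 0))
  r <- fire_and_reset(st, np, 0.5)
  expect_equal(r$spike, 0.5)
  expect_equal(r$state$V_mem1, np$V_reset)
  expect_equal(r$state$V_mem0, 0.3)          # distal untouched
  expect_equal(r$state$G_syn, st$G_syn)      # conductances untouched

  # a second crossing inside t_refr is suppressed, after t_refr it fires
  r$state$V_mem1 <- np$V_thresh
  r2 <- fire_and_reset(r$state, np, 0.5 + np$t_refr / 2)
  expect_null(r2$spike)
  r3 <- fire_and_reset(r$state, np, 0.5 + np$t_refr)
  expect_equal(r3$spike, 0.5 + np$t_refr)
})

test_that("exponential-Euler voltages track a dense brute-force integrator", {
  np <- test_neuron(V_thresh = 10)   # subthreshold comparison
  ev <- random_events(100, 0.1, seed = 7, n_neurons = 1L)
  sim <- run_simulation(np, ev, 0.1, dt = 5e-5, probe = 0L, probe_dt = 1e-3)
  dense <- dense_sim(np, ev, 0.1, h = 5e-5 / 16, record_v = TRUE)
  tr <- sim$traces[["0"]]
  idx <- match(round(tr$t, 10), round(dense$t, 10))
  scale <- max(abs(dense$V[, 2]))
  err <- abs(tr$V_mem1 - dense$V[idx, 2]) / scale
  expect_lt(max(err, na.rm = TRUE), 0.01)
  err0 <- abs(tr$V_mem0 - dense$V[idx, 1]) / max(abs(dense$V[, 1]))
  expect_lt(max(err0, na.rm = TRUE), 0.01)
})
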