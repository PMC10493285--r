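# spike-train generators and the event-driven engine

test_that("spike trains have the stated counts, spacing and statistics", {
  tr <- gen_spike_train("regular", 1000, 1)
  expect_length(tr, 1000)
  expect_equal(tr[1], 1e-3)
  expect_equal(diff(tr), rep(1e-3, 999), tolerance = 1e-12)
  expect_length(gen_spike_train("regular", 0, 1), 0)
  expect_length(gen_spike_train("poisson", 0, 1), 0)
  expect_error(gen_spike_train("regular", -1, 1), "rate")

  tp <- gen_spike_train("poisson", 1000, 100, seed = 9)
  expect_lt(abs(length(tp) - 1e5), 3 * sqrt(1e5))
  isi <- diff(tp)
  expect_lt(abs(stats::sd(isi) / mean(isi) - 1), 0.03)
  expect_true(all(diff(tp) > 0))
  expect_identical(tp, gen_spike_train("poisson", 1000, 100, seed = 9))
})

test_that("a silent network ends at its leak equilibrium", {
  np <- test_neuron(distal = compartment_params(1e-12, 50e-12, 0.12),
                    proximal = compartment_params(1e-12, 50e-12, 0.12))
  sim <- run_simulation(np, NULL, duration = 0.3, dt = 1e-4, probe = 0L)
  expect_equal(nrow(sim$spikes), 0)
  expect_equal(sim$final$V_mem0, 0.12, tolerance = 1e-9)
  expect_equal(sim$final$V_mem1, 0.12, tolerance = 1e-9)
})

test_that("simulation is deterministic and warns on late events", {
  ev <- gen_event_train("poisson", 3000, 0.2, syn_type = 2L,
                        strength = 150L, seed = 12)
  s1 <- run_simulation(test_neuron(), ev, 0.2, dt = 1e-5)
  s2 <- run_simulation(test_neuron(), ev, 0.2, dt = 1e-5)
  expect_identical(s1$spikes, s2$spikes)
  expect_gt(nrow(s1$spikes), 0)

  late <- input_events(c(0.1, 0.5), 0, 0, 2, 100)
  expect_warning(run_simulation(test_neuron(), late, 0.2), "beyond")
})

test_that("event engine spike times match the dense oracle within one dt", {
  # driven layer 0-3 fans out through the routing table to layer 4-7;
  # strong brief synapses (tau 20 us) lock every spike to its triggering
  # event, and the deep reset keeps residual conductance from re-firing
  np <- neuron_params(distal = compartment_params(1e-12, 5e-10, 0),
                      proximal = compartment_params(1e-12, 5e-10, 0),
                      V_reset = -0.3,
                      synapses = default_synapses(tau_syn = 2e-5))
  tab <- routing_table(pre_id = 0:3, core = 0L, neuron = 4:7,
                       syn_type = 2L, strength = 255L)
  rates <- c(310, 317, 331, 347)
  drive <- do.call(rbind, lapply(0:3, function(id) {
    as.data.frame(gen_event_train("regular", rates[id + 1], 0.1,
                                  neuron = id, syn_type = 2L,
                                  strength = 255L))
  }))
  drive <- drive[order(drive$t), ]
  drive <- input_events(drive$t, drive$core, drive$neuron, drive$syn_type,
                        drive$strength)
  dt <- 2e-5
  sim <- run_simulation(np, drive, 0.1, dt = dt, routing = tab)
  dense <- dense_sim(np, drive, 0.1, h = dt / 16, routing = tab)
  expect_gt(nrow(sim$spikes), 100)
  expect_gt(sum(sim$spikes$id >= 4), 50)   # routed layer is active
  expect_equal(nrow(sim$spikes), nrow(dense$spikes))
  ord_e <- order(sim$spikes$id, sim$spikes$t)
  ord_d <- order(dense$spikes$id, dense$spikes$t)
  expect_equal(sim$spikes$id[ord_e], dense$spikes$id[ord_d])
  expect_lt(max(abs(sim$spikes$t[ord_e] - dense$spikes$t[ord_d])), dt + 1e-12)
})

test_that("shunting inhibition silences firing only during its window", {
  np <- test_neuron()
  exc <- gen_event_train("regular", 2000, 0.15, syn_type = 0L,
                         strength = 200L)
  inh <- gen_event_train("regular", 2000, 0.15, syn_type = 3L,
                         strength = 255L)
  inh <- inh[inh$t >= 0.05 & inh$t <= 0.08, ]
  ev <- rbind(as.data.frame(exc), as.data.frame(inh))
  ev <- ev[order(ev$t), ]
  ev <- input_events(ev$t, ev$core, ev$neuron, ev$syn_type, ev$strength)
  sim <- run_simulation(np, ev, 0.15, dt = 1e-5)
  sp <- sim$spikes$t
  expect_gt(sum(sp > 0.02 & sp < 0.05), 10)     # firing before
  expect_equal(sum(sp >= 0.053 & sp <= 0.08), 0) # silenced in the window
  expect_gt(sum(sp > 0.085), 10)                 # firing resumes
})

test_that("activation is threshold-linear for regular input, smoothed for Poisson", {
  np <- test_neuron()
  # below the deterministic threshold the output is exactly zero
  act0 <- measure_activation(np, "regular", c(200, 400), strength = 80L,
                             duration = 0.3, burn_in = 0.1)
  expect_equal(act0$output_rate, c(0, 0))
  # above threshold the curve is linear within 5 percent
  act <- measure_activation(np, "regular",
                            c(1500, 2500, 4000, 6000, 8000, 10000),
                            strength = 80L, duration = 0.4, burn_in = 0.1)
  expect_true(all(diff(act$output_rate) > 0))
  fit <- stats::lm(output_rate ~ input_rate, data = act)
  expect_lt(max(abs(stats::resid(fit)) / stats::fitted(fit)), 0.05)
  # Poisson fluctuations smooth the threshold: activity below the
  # deterministic threshold rate
  actp <- measure_activation(np, "poisson", 500, strength = 80L,
                             duration = 1, seed = 3, burn_in = 0.1)
  expect_gt(actp$output_rate, 0)
})

test_that("output rate is monotone in the strength byte", {
  np <- test_neuron()
  rates <- vapply(c(60L, 90L, 130L, 200L, 255L), function(w) {
    measure_activation(np, "regular", 4000, strength = w,
                       duration = 0.3, burn_in = 0.1)$output_rate
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("probe traces are sampled on the requested grid", {
  ev <- test_events(c(0.01, 0.02), strength = 200L)
  sim <- run_simulation(test_neuron(), ev, 0.05, dt = 1e-5, probe = 0L,
                        probe_dt = 1e-3)
  tr <- sim$traces[["0"]]
  expect_equal(tr$t, seq(0, 0.05, by = 1e-3))
  expect_false(anyNA(tr$V_mem1))
  expect_true(all(tr$G_syn2 >= 0))
})
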