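# shared fixtures built in code

# default two-compartment neuron used across engine tests
test_neuron <- function(...) neuron_params(...)

# small deterministic event stream hitting one neuron's proximal synapse
test_events <- function(times, strength = 80L, syn = 2L, core = 0L,
                        neuron = 0L) {
  input_events(times, core = core, neuron = neuron, syn_type = syn,
               strength = strength)
}

# random-but-reproducible event stream over a handful of neurons; strength
# codes capped at 160 so the accumulated conductance stays well inside the
# stability region of the explicit-Euler test oracle
random_events <- function(n, duration, seed, n_neurons = 4L) {
  set.seed(seed)
  input_events(sort(runif(n, 0, duration)),
               core = 0L,
               neuron = sample.int(n_neurons, n, replace = TRUE) - 1L,
               syn_type = sample(0:3, n, replace = TRUE),
               strength = sample(0:160, n, replace = TRUE))
}
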