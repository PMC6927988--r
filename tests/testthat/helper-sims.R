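# Shared, lazily-built simulations (memoized so several test files can use
# the same traces without re-integrating).

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# purely passive cell: all active conductances zero
passive_params <- function(g_leak = 10, e_leak = -65) {
  neuron_params(leak_conductance = g_leak, leak_reversal = e_leak,
                gNa_ais = 0, gNa_soma = 0, gK_dr = 0, gSK = 0, gH = 0)
}

short_protocol <- function(amps, duration = 300, onset = 50, post = 50,
                           rate = 50000) {
  protocol_spec(step_amplitudes = amps, step_onset = onset,
                step_duration = duration, post_baseline = post,
                sampling_rate = rate)
}

# default excitable cell on a small ladder (shared fixture)
default_cell <- function() cached("default_cell", {
  simulate_cell(neuron_params(),
                short_protocol(c(-100, seq(50, 450, 50)), duration = 500),
                seed = 7)
})
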