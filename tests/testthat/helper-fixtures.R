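# Small configurations shared across tests. Networks are built in code at
# test time; nothing is loaded from disk.

tiny_network_config <- function(...) {
  network_config(N_exc = 20, N_inh = 5, N_input = 10, dt = 1e-4, ...)
}

# Benchmark scaled down for fast end-to-end checks (not the acceptance one).
tiny_benchmark <- function(seed = 1) {
  default_benchmark(n_train_beats = 8, n_test_beats = 8, n_anomalies = 2,
                    seed = seed)
}

# Forward-Euler reference integrator for the LIF membrane (independent
# oracle for the exact-exponential update).
euler_vmem <- function(V0, I_in, dt, n, params) {
  tau <- params$R * params$C
  V <- V0
  for (i in seq_len(n)) V <- V + dt * (I_in * params$R - V) / tau
  V
}
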