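test_that("network construction follows the wiring rules", {
  set.seed(1)
  net <- build_network(network_config())
  expect_equal(net$cfg$N_exc, 160)
  expect_equal(net$cfg$N_inh, 40)
  # plastic projection initialized at exactly 1.0; no autapses
  expect_true(all(net$w_ee[net$m_ee] == 1.0))
  expect_true(all(diag(net$m_ee) == FALSE))
  # static projections drawn in (0, Wmax)
  expect_true(all(net$w_in[net$m_in] > 0 & net$w_in[net$m_in] < 2))
  # thresholds initialized at 0.2 V everywhere
  expect_true(all(net$Vthr == 0.2))

  # P_EE = 0 disables the recurrent excitatory projection
  set.seed(2)
  net0 <- build_network(network_config(P_EE = 0))
  expect_false(any(net0$m_ee))

  expect_error(network_config(N_input = 0), "N_input")
  expect_error(network_config(P_II = 0.1), "P_II")
})

test_that("edge counts match the Bernoulli means across seeds", {
  counts <- vapply(1:30, function(s) {
    set.seed(s)
    net <- build_network(tiny_network_config(P_EE = 0.2))
    sum(net$m_ee)
  }, numeric(1))
  n_pairs <- 20 * 19  # autapses excluded
  expected <- 0.2 * n_pairs
  se <- sqrt(n_pairs * 0.2 * 0.8 / 30)
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("wiring and simulation are deterministic given the seed", {
  run_once <- function() {
    set.seed(42)
    net <- build_network(tiny_network_config())
    enc <- encoding_config(F_poisson = 150, T_bin = 0.05, dt = 1e-4)
    raster <- gen_input_raster(rep(120, 20), enc, 10)
    run_network(net, raster, 1, plasticity_on = TRUE)
  }
  a <- run_once(); b <- run_once()
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$network$w_ee, b$network$w_ee)
  expect_identical(a$network$Vthr, b$network$Vthr)
})

test_that("zero input from rest produces no spikes", {
  set.seed(3)
  net <- build_network(tiny_network_config())
  run <- run_network(net, NULL, 0.5, plasticity_on = TRUE)
  expect_equal(nrow(run$spikes), 0)
})

test_that("a frozen run leaves weights and thresholds bitwise unchanged", {
  set.seed(4)
  net <- build_network(tiny_network_config())
  enc <- encoding_config(F_poisson = 150, T_bin = 0.05, dt = 1e-4)
  raster <- gen_input_raster(rep(150, 40), enc, 10)
  run <- run_network(net, raster, 2, plasticity_on = FALSE)
  expect_identical(run$network$w_ee, net$w_ee)
  expect_identical(run$network$Vthr, net$Vthr)
  expect_gt(nrow(run$spikes), 0)  # the network did spike
})

test_that("a single strong synapse makes the output follow input spikes", {
  # one input neuron wired to one excitatory neuron with a weight large
  # enough that each input spike crosses threshold within a few steps
  cfg <- network_config(N_exc = 1, N_inh = 1, N_input = 1, P_in = 1,
                        P_EE = 0, P_EI = 0, P_IE = 0, dt = 1e-4)
  plast <- plasticity_config(Wmax = 100)
  set.seed(5)
  net <- build_network(cfg, plast)
  net$w_in[1, 1] <- 50  # PSP ~ 0.5 V >> Vthr = 0.2 V
  in_steps <- c(100L, 1000L, 2500L)
  raster <- data.frame(step = in_steps, neuron = 0L)
  run <- run_network(net, raster, 0.4, plasticity_on = FALSE)
  out <- run$spikes[run$spikes$neuron == 0, ]
  in_times <- (in_steps + 1) * 1e-4
  # an output spike follows each input spike within 2 ms (the large PSP
  # may also produce post-refractory rebound spikes while it decays)
  for (ti in in_times)
    expect_true(any(out$time >= ti & out$time <= ti + 2e-3))
  # and nothing fires before the first input arrives
  expect_true(all(out$time >= in_times[1]))
})

test_that("no emitted raster violates the refractory period", {
  set.seed(6)
  net <- build_network(tiny_network_config(),
                       neuron = neuron_params(tref = 3e-3))
  enc <- encoding_config(F_poisson = 300, T_bin = 0.05, dt = 1e-4)
  raster <- gen_input_raster(rep(300, 40), enc, 10)
  run <- run_network(net, raster, 2, plasticity_on = TRUE)
  expect_gt(nrow(run$spikes), 10)
  for (j in unique(run$spikes$neuron)) {
    tj <- run$spikes$time[run$spikes$neuron == j]
    if (length(tj) > 1) expect_true(all(diff(tj) >= 3e-3 - 1e-9))
  }
})

test_that("disabling inhibition does not reduce excitatory activity", {
  set.seed(7)
  cfg <- tiny_network_config(P_IE = 0.5, P_EI = 0.3)
  net <- build_network(cfg)
  enc <- encoding_config(F_poisson = 200, T_bin = 0.05, dt = 1e-4)
  set.seed(8)
  raster <- gen_input_raster(rep(200, 40), enc, 10)
  with_inh <- run_network(net, raster, 2, plasticity_on = FALSE)
  net_no <- net
  net_no$w_ie[] <- 0
  without <- run_network(net_no, raster, 2, plasticity_on = FALSE)
  n_exc_with <- sum(with_inh$spikes$neuron < 20)
  n_exc_without <- sum(without$spikes$neuron < 20)
  expect_gte(n_exc_without, n_exc_with)
})

test_that("per-bin rates count spikes per neuron over bins", {
  spikes <- data.frame(time = c(0.01, 0.05, 0.12, 0.14, 0.16, 0.29),
                       neuron = c(0, 0, 0, 1, 0, 1))
  r <- bin_rates(spikes, T_bin = 0.15, T = 0.3, n_neurons = 2)
  # 3 spikes for neuron 0 in bin 1 -> 20 fires/s
  expect_equal(r[1, 1], 20)
  expect_equal(r[1, 2], 1 / 0.15)
  expect_equal(r[2, 1], 1 / 0.15)
  expect_equal(r[2, 2], 1 / 0.15)
  # conservation: sum(rates) * T_bin equals the spike count
  expect_equal(sum(r) * 0.15, nrow(spikes))
  # empty raster gives all zeros
  r0 <- bin_rates(spikes[0, ], 0.15, 0.3, 2)
  expect_true(all(r0 == 0))
  # subsetting selects and orders neurons
  r1 <- bin_rates(spikes, 0.15, 0.3, 2, neurons = 1)
  expect_equal(ncol(r1), 1)
  expect_equal(r1[1, 1], 1 / 0.15)
})

test_that("the R step functions reproduce the compiled single-neuron path", {
  # dual route: one neuron, one input synapse, fixed spike train; the pure-R
  # composition of step_syn_current / on_presyn_spike_current /
  # step_membrane / check_fire must reproduce the compiled loop's spikes.
  cfg <- network_config(N_exc = 1, N_inh = 1, N_input = 1, P_in = 1,
                        P_EE = 0, P_EI = 0, P_IE = 0, dt = 1e-4)
  plast <- plasticity_config(ip_enabled = FALSE, sdsp_enabled = FALSE)
  np <- neuron_params(); sp <- synapse_params(alpha = 5e-12)
  set.seed(9)
  net <- build_network(cfg, plast, np, sp)
  net$w_in[1, 1] <- 1.5
  set.seed(10)
  in_steps <- sort(sample(0:4999, 400))
  raster <- data.frame(step = in_steps, neuron = 0L)
  run <- run_network(net, raster, 0.5, plasticity_on = FALSE)
  cpp_times <- run$spikes$time[run$spikes$neuron == 0]

  dt <- 1e-4
  s <- neuron_state(Vmem = 0, Vthr = 0.2)
  I <- 0
  r_times <- numeric(0)
  spikes_at <- rep(FALSE, 5000)
  spikes_at[in_steps + 1] <- TRUE
  for (t in seq_len(5000)) {
    I <- step_syn_current(I, dt, sp)
    if (spikes_at[t]) I <- on_presyn_spike_current(I, 1.5, sp)
    s <- step_membrane(s, I, dt, np, now = (t - 1) * dt)
    cf <- check_fire(s, np, now = t * dt)
    s <- cf$state
    if (cf$fired) r_times <- c(r_times, t * dt)
  }
  expect_gt(length(r_times), 3)
  expect_equal(r_times, cpp_times, tolerance = 1e-9)
})

test_that("halving dt with identical input spikes barely moves the rates", {
  # the same physical input spike train is presented at dt and dt/2, so any
  # difference comes from the integrator, not the Poisson realization
  wf <- generate_waveform(waveform_spec(n_beats = 2, noise_sd = 0))
  enc <- encoding_config(F_poisson = 150, T_bin = 0.05, dt = 1e-4)
  F_in <- encode_rate(wf$series[1:30], enc)
  set.seed(13)
  raster <- gen_input_raster(F_in, enc, 10)
  rates <- list()
  for (half in c(FALSE, TRUE)) {
    cfg <- network_config(N_exc = 20, N_inh = 5, N_input = 10,
                          dt = if (half) 5e-5 else 1e-4)
    set.seed(12)
    net <- build_network(cfg)
    r_in <- raster
    if (half) r_in$step <- r_in$step * 2L
    run <- run_network(net, r_in, 30 * 0.05, plasticity_on = FALSE)
    r <- bin_rates(run$spikes, 0.05, 1.5, 25, neurons = 0:19)
    rates[[length(rates) + 1]] <- rowMeans(r)
  }
  a <- rates[[1]]; b <- rates[[2]]
  expect_gt(mean(a), 0)
  expect_lt(mean(abs(a - b)) / mean(a), 0.02)
})
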