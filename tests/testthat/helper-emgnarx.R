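# Shared fixtures, all generated in code.

# a small but paper-shaped synthetic trial (defaults except duration)
short_plant <- function(duration_s = 40, seed = 7, ...) {
  arm_plant_config(duration_s = duration_s, seed = seed, ...)
}

# quick training options for tests that only need a working fit
fast_opts <- function(seed = 1, ...) {
  narx_options(max_iters = 150, restarts = 2, refine_iters = 30,
               seed = seed, ...)
}

# a teacher network with bounded, well-scaled weights
make_teacher <- function(config = narx_config(), seed = 42) {
  narx_model(config, init_parameters(config, seed))
}

# smooth positive envelope-like exogenous input at the decoding rate
make_smooth_inputs <- function(n, n_channels = 6, seed = 1, fs = 20) {
  with_seed <- emgnarx:::with_seed
  with_seed(seed, {
    raw <- matrix(stats::rnorm(n * n_channels), n, n_channels)
    sm <- apply(raw, 2, function(x) stats::filter(x, rep(1 / 15, 15),
                                                  sides = 1))
    sm[is.na(sm)] <- 0
    0.5 + 0.4 * sm / max(abs(sm), 1e-12)
  })
}

# closed-loop data generated by a teacher network: realizable ground truth
teacher_data <- function(n = 600, config = narx_config(), teacher_seed = 42,
                         input_seed = 1) {
  teacher <- make_teacher(config, teacher_seed)
  X <- make_smooth_inputs(n, config$n_inputs, seed = input_seed)
  burn <- emgnarx:::narx_burn_in(config)
  init <- matrix(0, burn, config$n_outputs)
  Y <- predict(teacher, X, mode = "closed_loop", init_angles = init)
  list(teacher = teacher, envelopes = X, angles = Y, burn = burn)
}
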