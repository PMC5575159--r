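# NARX architecture, forward passes and training.

test_that("parameter enumeration matches the architecture", {
  expect_identical(count_parameters(narx_config()), 51L)
  expect_identical(
    count_parameters(narx_config(n_inputs = 1, n_outputs = 1, n_hidden = 1,
                                 input_taps = 1, feedback_taps = 1)), 5L)
  # a literal 3-tap reading of both delay lines would give 96
  expect_identical(
    count_parameters(narx_config(input_taps = 3, feedback_taps = 3)), 96L)
})

test_that("initialization is seeded and consistent with the count", {
  cfg <- narx_config()
  p1 <- init_parameters(cfg, 11)
  p2 <- init_parameters(cfg, 11)
  p3 <- init_parameters(cfg, 12)
  expect_identical(p1, p2)
  expect_false(all(emgnarx:::pack_params(p1) == emgnarx:::pack_params(p3)))
  expect_identical(length(emgnarx:::pack_params(p1)),
                   count_parameters(cfg))
  expect_identical(length(coef(narx_model(cfg, p1))), 51L)
})

test_that("forward pass closed forms hold", {
  cfg <- narx_config()
  p <- init_parameters(cfg, 1)
  p$A[] <- 0; p$B[] <- 0; p$C[] <- 0
  p$b2 <- c(10, 20, 30)
  model <- narx_model(cfg, p)
  X <- matrix(0.5, 50, 6)
  Y <- matrix(1, 50, 3)
  burn <- emgnarx:::narx_burn_in(cfg)

  pred <- predict(model, X, angles = Y, mode = "teacher_forced")
  expect_true(all(is.na(pred[seq_len(burn), ])))
  expect_equal(unname(pred[-seq_len(burn), ]),
               matrix(rep(c(10, 20, 30), each = 50 - burn), ncol = 3))

  # zero envelopes, zero weights: constant b2-driven closed-loop output
  sim <- predict(model, matrix(0, 50, 6), mode = "closed_loop",
                 init_angles = Y[1:burn, , drop = FALSE])
  expect_equal(unname(sim[-seq_len(burn), ]),
               matrix(rep(c(10, 20, 30), each = 50 - burn), ncol = 3))

  # too-short input violates the burn-in contract
  expect_error(predict(model, X[seq_len(burn), ], angles = Y[seq_len(burn), ],
                       mode = "teacher_forced"),
               class = "emgnarx_input_error")
})

test_that("teacher self-consistency: both modes reproduce teacher data", {
  td <- teacher_data(n = 400)
  burn <- td$burn
  # closed loop with matching initial taps reproduces exactly
  sim <- predict(td$teacher, td$envelopes, mode = "closed_loop",
                 init_angles = td$angles[seq_len(burn), , drop = FALSE])
  expect_lt(max(abs(sim[-seq_len(burn), ] - td$angles[-seq_len(burn), ])),
            1e-10)
  # teacher-forced on its own trajectory is also exact
  pred <- predict(td$teacher, td$envelopes, angles = td$angles,
                  mode = "teacher_forced")
  expect_lt(max(abs(pred[-seq_len(burn), ] - td$angles[-seq_len(burn), ])),
            1e-10)
})

test_that("with inert feedback weights the two modes coincide", {
  cfg <- narx_config()
  p <- init_parameters(cfg, 5)
  p$B[] <- 0
  model <- narx_model(cfg, p)
  X <- make_smooth_inputs(200, seed = 9)
  Yany <- matrix(stats::rnorm(200 * 3), 200, 3)
  burn <- emgnarx:::narx_burn_in(cfg)
  tf <- predict(model, X, angles = Yany, mode = "teacher_forced")
  cl <- predict(model, X, mode = "closed_loop",
                init_angles = Yany[seq_len(burn), , drop = FALSE])
  expect_equal(tf[-seq_len(burn), ], cl[-seq_len(burn), ])
})

test_that("forward pass is shift-equivariant", {
  td <- teacher_data(n = 300)
  burn <- td$burn
  s <- 25
  full <- predict(td$teacher, td$envelopes, angles = td$angles,
                  mode = "teacher_forced")
  shifted <- predict(td$teacher, td$envelopes[(s + 1):300, ],
                     angles = td$angles[(s + 1):300, ],
                     mode = "teacher_forced")
  expect_equal(shifted[-seq_len(burn), ],
               full[(s + burn + 1):300, ])
})

test_that("compiled closed-loop recursion matches the plain-R reference", {
  cfg <- narx_config()
  p <- init_parameters(cfg, 31)
  X <- make_smooth_inputs(250, seed = 4)
  init <- matrix(stats::runif(12, -0.5, 0.5), 4, 3)
  Yn_init <- rbind(init, matrix(0, 246, 3))
  a <- emgnarx:::simulate_closed(p, cfg, X, Yn_init)
  b <- emgnarx:::simulate_closed_r(p, cfg, X, Yn_init)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("training recovers a realizable teacher function", {
  cfg <- narx_config()
  td <- teacher_data(n = 1800, config = cfg, teacher_seed = 21,
                     input_seed = 2)
  n_train <- 1400
  opts <- narx_options(max_iters = 200, restarts = 2, seed = 4,
                       feedback_jitter_sd = 0, refine_iters = 30)
  fit <- narx(td$envelopes[1:n_train, ], td$angles[1:n_train, ], cfg, opts)

  # held-out series-parallel VAF >= 99.9% per output on noiseless data
  Xv <- td$envelopes[(n_train + 1):1800, ]
  Yv <- td$angles[(n_train + 1):1800, ]
  pred <- predict(fit, Xv, angles = Yv, mode = "teacher_forced")
  keep <- (td$burn + 1):nrow(Yv)
  for (j in 1:3) expect_gte(vaf(Yv[keep, j], pred[keep, j]), 99.9)

  # accepted-step MSE trajectory is non-increasing
  expect_true(all(diff(fit$report$mse_trajectory) <= 0))
  expect_true(all(diff(fit$report$refine_trajectory) <= 0))
  # training never ends worse than the best random initialization
  worst_init <- min(vapply(seq_len(opts$restarts), function(r) {
    p0 <- init_parameters(cfg, opts$seed + r - 1)
    p0 <- emgnarx:::fit_normalizers(p0, td$envelopes[1:n_train, ],
                                    td$angles[1:n_train, ])
    d <- emgnarx:::build_design(emgnarx:::norm_x(p0, td$envelopes[1:n_train, ]),
                                emgnarx:::norm_y(p0, td$angles[1:n_train, ]),
                                cfg)
    mean((emgnarx:::eval_network(p0, cfg, d$Z) - d$target)^2)
  }, numeric(1)))
  expect_lt(fit$report$final_mse, worst_init)
})

test_that("training is deterministic given identical inputs and seed", {
  cfg <- narx_config()
  td <- teacher_data(n = 560, config = cfg)
  opts <- narx_options(max_iters = 40, restarts = 2, seed = 3,
                       refine_iters = 5)
  f1 <- narx(td$envelopes, td$angles, cfg, opts)
  f2 <- narx(td$envelopes, td$angles, cfg, opts)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$report, f2$report)
})

test_that("training length must exceed the identifiability floor", {
  cfg <- narx_config()
  X <- matrix(0.5, 100, 6)
  Y <- matrix(1, 100, 3)
  expect_error(narx(X, Y, cfg), class = "emgnarx_training_error")
})

test_that("LM matches an independent optimizer on a small least-squares fit", {
  skip_if_not_installed("minpack.lm")
  # a tiny realizable network fit: both optimizers should reach ~zero MSE
  cfg <- narx_config(n_inputs = 2, n_outputs = 1, n_hidden = 2,
                     input_taps = 1, feedback_taps = 0)
  td <- teacher_data(n = 400, config = cfg, teacher_seed = 8, input_seed = 3)
  p0 <- init_parameters(cfg, 1)
  p0 <- emgnarx:::fit_normalizers(p0, td$envelopes, td$angles)
  d <- emgnarx:::build_design(emgnarx:::norm_x(p0, td$envelopes),
                              emgnarx:::norm_y(p0, td$angles), cfg)
  rfun <- function(theta) {
    p <- emgnarx:::unpack_theta(theta, cfg, p0)
    as.numeric(emgnarx:::eval_network(p, cfg, d$Z) - d$target)
  }
  theta0 <- emgnarx:::pack_params(init_parameters(cfg, 2))
  ours <- emgnarx:::lm_minimize(
    rfun, theta0,
    narx_options(rel_tol = 1e-14, grad_tol = 1e-10, mse_tol = 1e-14), 200)
  ref <- minpack.lm::nls.lm(par = theta0, fn = rfun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))
  ref_mse <- mean(ref$fvec^2)
  # both descend into the same near-noiseless flat valley (neither is
  # fully converged there); agreement within an order of magnitude
  expect_lt(ref_mse, 1e-6)
  expect_lt(ours$mse, 1e-6)
  expect_lt(ours$mse, 10 * ref_mse + 1e-10)
})

test_that("JSON serialization round-trips a fitted decoder", {
  cfg <- narx_config()
  td <- teacher_data(n = 560, config = cfg)
  fit <- narx(td$envelopes, td$angles, cfg, fast_opts())
  path <- withr::local_tempfile(fileext = ".json")
  write_narx(fit, path)
  back <- read_narx(path)
  expect_equal(coef(back), coef(fit))
  expect_equal(back$parameters$input_scale, fit$parameters$input_scale)
  burn <- emgnarx:::narx_burn_in(cfg)
  p1 <- predict(fit, td$envelopes, mode = "closed_loop",
                init_angles = td$angles[seq_len(burn), ])
  p2 <- predict(back, td$envelopes, mode = "closed_loop",
                init_angles = td$angles[seq_len(burn), ])
  expect_equal(p1, p2)
})
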