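# The NARX recurrent decoder.
#
# A small nonlinear autoregressive network with exogenous inputs maps six
# EMG linear envelopes to three joint angles. Hidden layer: H tanh nodes
# fed by tapped delay lines on the envelopes (T_x taps) and on the output
# feedback (T_y taps), both offset by the embedding delay m; output layer:
# linear. At the defaults (H = 3, N_x = 6, T_x = 1, N_y = 3, T_y = 2) the
# network has exactly 51 trainable parameters, and the prediction interval
# is tau = m * dt = 100 ms at the 20 Hz decoding rate.
#
# Hidden node n at step t:
#   U_n(t) = tanh( sum_{i,k} A_ni(k) X_i(t-m-k)
#                - sum_{j,k} B_nj(k) Y_j(t-m-k) + b1_n )
# Output j:
#   Y_j(t) = sum_n C_jn U_n(t) + b2_j
#
# In series-parallel (teacher-forced) mode the Y lags are measured angles;
# in parallel (closed-loop) mode they are the model's own past predictions
# and only the EMG drives the trajectory.

#' NARX architecture configuration
#'
#' @param n_inputs number of exogenous (envelope) channels, `N_x`.
#' @param n_outputs number of decoded joints, `N_y`.
#' @param n_hidden hidden tanh nodes, `H`.
#' @param input_taps taps per envelope channel, `T_x`.
#' @param feedback_taps taps per output feedback, `T_y` (0 disables
#'   feedback).
#' @param m embedding lag count; the prediction interval is
#'   `tau = m * dt_s`.
#' @param dt_s decoding step in seconds (default 0.05, i.e. 20 Hz).
#' @return An object of class `"narx_config"`. The element `tau_ms` gives
#'   the prediction interval in milliseconds (100 at the defaults).
#' @export
narx_config <- function(n_inputs = 6, n_outputs = 3, n_hidden = 3,
                        input_taps = 1, feedback_taps = 2,
                        m = 2, dt_s = 0.05) {
  if (!is_count(n_inputs) || !is_count(n_outputs) || !is_count(n_hidden) ||
      !is_count(input_taps) || !is_count(feedback_taps, min = 0L) ||
      !is_count(m))
    stop_emg("all architecture counts must be positive integers (feedback_taps may be 0)",
             "emgnarx_parameter_error")
  if (!is.numeric(dt_s) || dt_s <= 0)
    stop_emg("dt_s must be positive", "emgnarx_parameter_error")
  structure(list(n_inputs = as.integer(n_inputs),
                 n_outputs = as.integer(n_outputs),
                 n_hidden = as.integer(n_hidden),
                 input_taps = as.integer(input_taps),
                 feedback_taps = as.integer(feedback_taps),
                 m = as.integer(m), dt_s = dt_s,
                 tau_ms = m * dt_s * 1000,
                 hidden_activation = "tanh", output_activation = "linear"),
            class = "narx_config")
}

#' @export
print.narx_config <- function(x, ...) {
  cat(sprintf("NARX config: %d inputs (%d taps), %d outputs (%d feedback taps), %d hidden, m = %d (tau = %g ms)\n",
              x$n_inputs, x$input_taps, x$n_outputs, x$feedback_taps,
              x$n_hidden, x$m, x$tau_ms))
  cat("  trainable parameters:", count_parameters(x), "\n")
  invisible(x)
}

#' Count the trainable parameters of a NARX configuration
#'
#' `H * (N_x*T_x + N_y*T_y + 1) + N_y * (H + 1)`: hidden weights on all
#' input and feedback taps plus hidden biases, output weights plus output
#' biases. The default architecture gives 51. Note that a literal 3-tap
#' reading of both delay lines (`input_taps = 3, feedback_taps = 3`) would
#' give 96; the default tap counts are the minimal feedback-bearing choice
#' consistent with a 51-parameter network.
#'
#' @param config a [narx_config()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(config) {
  stopifnot(inherits(config, "narx_config"))
  with(config,
       n_hidden * (n_inputs * input_taps + n_outputs * feedback_taps + 1L) +
         n_outputs * (n_hidden + 1L))
}

# number of leading samples that cannot be predicted (delay-line fill)
narx_burn_in <- function(config) {
  config$m + max(config$input_taps, config$feedback_taps)
}

#' Random initial parameters
#'
#' Weights are drawn uniformly in `[-0.5, 0.5]` scaled by `1/sqrt(fan-in)`
#' of the receiving layer; normalizers are the identity until fitted by
#' [narx()].
#'
#' @param config a [narx_config()].
#' @param seed integer seed; the draw is reproducible per seed.
#' @return An object of class `"narx_parameters"` with weight tensors
#'   `A` (`H x N_x x T_x`), `B` (`H x N_y x T_y`), `C` (`N_y x H`), biases
#'   `b1`, `b2`, and per-channel affine normalizers `input_scale`,
#'   `output_center`, `output_halfwidth`.
#' @export
init_parameters <- function(config, seed) {
  stopifnot(inherits(config, "narx_config"))
  H <- config$n_hidden; Nx <- config$n_inputs; Ny <- config$n_outputs
  Tx <- config$input_taps; Ty <- config$feedback_taps
  fan_h <- Nx * Tx + Ny * Ty
  with_seed(seed, {
    p <- list(
      A = array(stats::runif(H * Nx * Tx, -0.5, 0.5) / sqrt(fan_h),
                dim = c(H, Nx, Tx)),
      B = array(if (Ty > 0) stats::runif(H * Ny * Ty, -0.5, 0.5) / sqrt(fan_h)
                else numeric(0), dim = c(H, Ny, Ty)),
      C = matrix(stats::runif(Ny * H, -0.5, 0.5) / sqrt(H), Ny, H),
      b1 = stats::runif(H, -0.5, 0.5) / sqrt(fan_h),
      b2 = stats::runif(Ny, -0.5, 0.5) / sqrt(H),
      input_scale = rep(1, Nx),
      output_center = rep(0, Ny),
      output_halfwidth = rep(1, Ny))
    class(p) <- "narx_parameters"
    p
  })
}

# ---- parameter packing -----------------------------------------------------

pack_params <- function(p) c(p$A, p$B, p$C, p$b1, p$b2)

unpack_theta <- function(theta, config, template) {
  H <- config$n_hidden; Nx <- config$n_inputs; Ny <- config$n_outputs
  Tx <- config$input_taps; Ty <- config$feedback_taps
  nA <- H * Nx * Tx; nB <- H * Ny * Ty; nC <- Ny * H
  p <- template
  p$A <- array(theta[seq_len(nA)], dim = c(H, Nx, Tx))
  p$B <- array(theta[nA + seq_len(nB)], dim = c(H, Ny, Ty))
  p$C <- matrix(theta[nA + nB + seq_len(nC)], Ny, H)
  p$b1 <- theta[nA + nB + nC + seq_len(H)]
  p$b2 <- theta[nA + nB + nC + H + seq_len(Ny)]
  p
}

# effective hidden weight matrix over the design columns
# (input lags first, tap-major; then feedback lags with the literal minus)
hidden_weight_matrix <- function(p, config) {
  H <- config$n_hidden
  Wx <- matrix(p$A, H, config$n_inputs * config$input_taps)
  if (config$feedback_taps > 0) {
    Wy <- matrix(p$B, H, config$n_outputs * config$feedback_taps)
    cbind(Wx, -Wy)
  } else Wx
}

# ---- normalization ---------------------------------------------------------

norm_x <- function(p, X) sweep(X, 2, p$input_scale, "/")
norm_y <- function(p, Y)
  sweep(sweep(Y, 2, p$output_center, "-"), 2, p$output_halfwidth, "/")
denorm_y <- function(p, Yn)
  sweep(sweep(Yn, 2, p$output_halfwidth, "*"), 2, p$output_center, "+")

fit_normalizers <- function(p, X, Y) {
  sc <- apply(X, 2, max)
  p$input_scale <- ifelse(sc > 0, sc, 1)       # keep invertible
  lo <- apply(Y, 2, min); hi <- apply(Y, 2, max)
  p$output_center <- (lo + hi) / 2
  hw <- (hi - lo) / 2
  p$output_halfwidth <- ifelse(hw > 0, hw, 1)  # keep invertible
  p
}

# ---- forward passes (normalized space) -------------------------------------

# lagged design for teacher-forced prediction over one contiguous block:
# row r corresponds to step idx[r]; columns are X_i(t-m-k) for k in
# 0..Tx-1, then Y_j(t-m-k) for k in 0..Ty-1
build_design <- function(Xn, Yn, config) {
  n <- nrow(Xn); burn <- narx_burn_in(config)
  if (n <= burn)
    stop_emg(sprintf("block of %d steps is not longer than the burn-in (%d)",
                     n, burn), "emgnarx_input_error")
  idx <- (burn + 1L):n
  cols <- vector("list", config$input_taps + config$feedback_taps)
  ci <- 0L
  for (k in seq_len(config$input_taps) - 1L) {
    ci <- ci + 1L; cols[[ci]] <- Xn[idx - config$m - k, , drop = FALSE]
  }
  if (config$feedback_taps > 0)
    for (k in seq_len(config$feedback_taps) - 1L) {
      ci <- ci + 1L; cols[[ci]] <- Yn[idx - config$m - k, , drop = FALSE]
    }
  list(Z = do.call(cbind, cols), target = Yn[idx, , drop = FALSE], idx = idx)
}

# static network evaluation on a design matrix
eval_network <- function(p, config, Z) {
  W <- hidden_weight_matrix(p, config)
  U <- tanh(Z %*% t(W) + matrix(p$b1, nrow(Z), config$n_hidden, byrow = TRUE))
  U %*% t(p$C) + matrix(p$b2, nrow(Z), config$n_outputs, byrow = TRUE)
}

# closed-loop recursion over one contiguous block; Yn_init seeds the first
# burn-in rows, everything after is driven by the envelopes alone.
# The sequential loop is compiled (src/simulate.cpp); simulate_closed_r is
# the plain-R reference used as a cross-check in the tests.
simulate_closed <- function(p, config, Xn, Yn_init, clamp = c(-Inf, Inf)) {
  n <- nrow(Xn); burn <- narx_burn_in(config)
  if (n <= burn)
    stop_emg(sprintf("block of %d steps is not longer than the burn-in (%d)",
                     n, burn), "emgnarx_input_error")
  .narx_simulate_cpp(hidden_weight_matrix(p, config), p$b1, p$C, p$b2,
                     Xn, Yn_init[seq_len(n), , drop = FALSE],
                     config$m, config$input_taps, config$feedback_taps,
                     burn, clamp[1], clamp[2])
}

simulate_closed_r <- function(p, config, Xn, Yn_init, clamp = c(-Inf, Inf)) {
  n <- nrow(Xn); burn <- narx_burn_in(config)
  W <- hidden_weight_matrix(p, config)
  m <- config$m; Tx <- config$input_taps; Ty <- config$feedback_taps
  Y <- matrix(0, n, config$n_outputs)
  Y[seq_len(burn), ] <- Yn_init[seq_len(burn), , drop = FALSE]
  for (t in (burn + 1L):n) {
    zx <- as.numeric(t(Xn[t - m - (seq_len(Tx) - 1L), , drop = FALSE]))
    zy <- if (Ty > 0)
      as.numeric(t(Y[t - m - (seq_len(Ty) - 1L), , drop = FALSE])) else numeric(0)
    u <- tanh(W %*% c(zx, zy) + p$b1)
    Y[t, ] <- pmin(pmax(p$C %*% u + p$b2, clamp[1]), clamp[2])
  }
  Y
}

# ---- Levenberg-Marquardt ---------------------------------------------------

#' Training options for [narx()]
#'
#' Levenberg-Marquardt with the classic damping schedule: damping `mu`
#' shrinks by `lm_mu_down` after an accepted step and grows by `lm_mu_up`
#' when a step is rejected. The Jacobian is computed by forward
#' differences (the network is small, so full numerical Jacobians are
#' cheap). Training runs `restarts` seeded initializations and keeps the
#' best by training MSE.
#'
#' Two additions stabilize the closed-loop behaviour of the decoder (see
#' the methods vignette): Gaussian noise of sd `feedback_jitter_sd`
#' (normalized units) is injected into the feedback regressors during
#' teacher-forced training, and the best restart is refined for up to
#' `refine_iters` LM iterations on the closed-loop (parallel) residuals.
#'
#' @param max_iters maximum LM iterations per restart (default 500).
#' @param lm_mu0 initial damping (default 1e-3).
#' @param lm_mu_up,lm_mu_down damping multipliers on reject/accept
#'   (defaults 10, 0.1).
#' @param grad_tol gradient infinity-norm stopping tolerance (default
#'   1e-7).
#' @param mse_tol MSE stopping tolerance (default 1e-10).
#' @param restarts number of seeded initializations (default 5).
#' @param seed base seed; restart r uses `seed + r - 1`.
#' @param feedback_jitter_sd sd of the feedback-regressor noise injection
#'   in normalized units (default 0.02; 0 disables).
#' @param refine_iters maximum closed-loop refinement iterations (default
#'   300, normally cut short by the stall tolerance; 0 disables refinement).
#' @param rel_tol relative MSE-decrease stall tolerance (default 1e-8).
#' @return An object of class `"narx_options"`.
#' @export
narx_options <- function(max_iters = 500, lm_mu0 = 1e-3, lm_mu_up = 10,
                         lm_mu_down = 0.1, grad_tol = 1e-7, mse_tol = 1e-10,
                         restarts = 5, seed = 1,
                         feedback_jitter_sd = 0.02, refine_iters = 300,
                         rel_tol = 1e-8) {
  vals <- c(max_iters = max_iters, lm_mu0 = lm_mu0, lm_mu_up = lm_mu_up,
            lm_mu_down = lm_mu_down, grad_tol = grad_tol, mse_tol = mse_tol,
            restarts = restarts, rel_tol = rel_tol)
  if (any(!is.finite(vals)) || any(vals <= 0) || restarts < 1)
    stop_emg("all training options must be positive and restarts >= 1",
             "emgnarx_parameter_error")
  if (feedback_jitter_sd < 0 || refine_iters < 0)
    stop_emg("feedback_jitter_sd and refine_iters must be nonnegative",
             "emgnarx_parameter_error")
  structure(list(max_iters = as.integer(max_iters), lm_mu0 = lm_mu0,
                 lm_mu_up = lm_mu_up, lm_mu_down = lm_mu_down,
                 grad_tol = grad_tol, mse_tol = mse_tol,
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 feedback_jitter_sd = feedback_jitter_sd,
                 refine_iters = as.integer(refine_iters), rel_tol = rel_tol),
            class = "narx_options")
}

# generic LM on a residual function; deterministic, no RNG
lm_minimize <- function(resid_fun, theta0, opts, max_iters) {
  theta <- theta0
  r <- resid_fun(theta)
  if (!all(is.finite(r)))
    stop_emg("non-finite loss at the initial point", "emgnarx_numerical_error")
  mse <- mean(r^2)
  traj <- mse
  mu <- opts$lm_mu0
  np <- length(theta)
  it <- 0L
  while (it < max_iters) {
    it <- it + 1L
    J <- matrix(0, length(r), np)
    h <- sqrt(.Machine$double.eps) * pmax(abs(theta), 1)
    for (k in seq_len(np)) {
      tk <- theta; tk[k] <- tk[k] + h[k]
      J[, k] <- (resid_fun(tk) - r) / h[k]
    }
    g <- crossprod(J, r)
    if (max(abs(g)) < opts$grad_tol) break
    JtJ <- crossprod(J)
    dj <- pmax(diag(JtJ), 1e-12)
    accepted <- FALSE
    for (try in 1:40) {
      step <- tryCatch(solve(JtJ + mu * diag(dj, np), -g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        cand <- theta + as.numeric(step)
        rc <- resid_fun(cand)
        mc <- mean(rc^2)
        if (is.finite(mc) && mc < mse) {
          rel <- (mse - mc) / mse
          theta <- cand; r <- rc; mse <- mc
          traj <- c(traj, mse)
          mu <- mu * opts$lm_mu_down
          accepted <- TRUE
          if (rel < opts$rel_tol || mse < opts$mse_tol)
            return(list(theta = theta, mse = mse, iterations = it,
                        trajectory = traj))
          break
        }
      }
      mu <- mu * opts$lm_mu_up
      if (mu > 1e12) break
    }
    if (!accepted) break
  }
  list(theta = theta, mse = mse, iterations = it, trajectory = traj)
}

# ---- fitting ---------------------------------------------------------------

# coerce envelope/angle inputs to a list of contiguous blocks
as_block_list <- function(x) {
  if (is.list(x) && !is.data.frame(x)) lapply(x, as_matrix)
  else list(as_matrix(x))
}

#' Fit a NARX decoder
#'
#' Trains the network on one or more contiguous blocks of envelope/angle
#' data. Normalizers are fitted on the training data only (envelopes to
#' `[0, 1]` by the per-channel maximum, angles to `[-1, 1]` by min/max).
#' Training minimizes the teacher-forced mean squared error jointly over
#' all outputs by Levenberg-Marquardt from `restarts` seeded
#' initializations, keeping the best restart by (clean) training MSE;
#' optionally the winner is refined on the closed-loop residuals (see
#' [narx_options()]). Delay-line state is never carried across blocks:
#' each block contributes its own burn-in.
#'
#' @param envelopes matrix `n x n_inputs` of EMG envelopes, or a list of
#'   such matrices (contiguous blocks).
#' @param angles matching matrix or list of measured joint angles in
#'   degrees.
#' @param config a [narx_config()].
#' @param options a [narx_options()].
#' @return An object of class `"narx"` with elements `config`,
#'   `parameters`, `report` (final MSEs, iteration counts, accepted-step
#'   MSE trajectories, selected restart) and `call`. Supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `fitted()`, `residuals()`,
#'   `simulate()` and `plot()`.
#' @seealso [predict.narx()], [cross_validate()], [write_narx()]
#' @export
narx <- function(envelopes, angles, config = narx_config(),
                 options = narx_options()) {
  stopifnot(inherits(config, "narx_config"), inherits(options, "narx_options"))
  Xb <- as_block_list(envelopes)
  Yb <- as_block_list(angles)
  if (length(Xb) != length(Yb) ||
      any(vapply(Xb, nrow, 1L) != vapply(Yb, nrow, 1L)))
    stop_emg("envelopes and angles must come in matching blocks",
             "emgnarx_input_error")
  np <- count_parameters(config)
  burn <- narx_burn_in(config)
  n_eff <- sum(pmax(vapply(Xb, nrow, 1L) - burn, 0L))
  if (n_eff <= 10L * np)
    stop_emg(sprintf("training length (%d effective steps) must exceed 10 x %d parameters",
                     n_eff, np), "emgnarx_training_error")

  p0 <- init_parameters(config, options$seed)
  p0 <- fit_normalizers(p0, do.call(rbind, Xb), do.call(rbind, Yb))
  Xn <- lapply(Xb, function(x) norm_x(p0, x))
  Yn <- lapply(Yb, function(y) norm_y(p0, y))
  designs <- lapply(seq_along(Xn),
                    function(i) build_design(Xn[[i]], Yn[[i]], config))
  Z <- do.call(rbind, lapply(designs, `[[`, "Z"))
  target <- do.call(rbind, lapply(designs, `[[`, "target"))

  fb_cols <- if (config$feedback_taps > 0)
    config$n_inputs * config$input_taps +
      seq_len(config$n_outputs * config$feedback_taps) else integer(0)

  sp_resid <- function(Zm) function(theta) {
    p <- unpack_theta(theta, config, p0)
    as.numeric(eval_network(p, config, Zm) - target)
  }
  clean_mse <- function(theta) mean(sp_resid(Z)(theta)^2)
  # joint-limit guard for parallel-mode runs: the calibrated angle range
  # (normalized to [-1, 1] on the training folds) inflated by 20%
  clamp_norm <- c(-1.2, 1.2)
  cl_resid <- function(theta) {
    p <- unpack_theta(theta, config, p0)
    unlist(lapply(seq_along(Xn), function(i) {
      Yp <- simulate_closed(p, config, Xn[[i]], Yn[[i]], clamp_norm)
      as.numeric(Yp[-seq_len(burn), ] - Yn[[i]][-seq_len(burn), ])
    }))
  }
  # restart selection happens on the loss that matters downstream: the
  # closed-loop training MSE when the decoder will be refined and
  # deployed in parallel mode, the teacher-forced MSE otherwise
  refining <- config$feedback_taps > 0 && options$refine_iters > 0
  selection_mse <- function(theta) {
    if (refining) mean(cl_resid(theta)^2) else clean_mse(theta)
  }

  best <- NULL
  for (rst in seq_len(options$restarts)) {
    seed_r <- options$seed + rst - 1L
    theta0 <- pack_params(init_parameters(config, seed_r))
    Zr <- Z
    if (length(fb_cols) && options$feedback_jitter_sd > 0) {
      jit <- with_seed(seed_r + 99991L,
                       matrix(stats::rnorm(nrow(Z) * length(fb_cols), 0,
                                           options$feedback_jitter_sd),
                              nrow(Z)))
      Zr[, fb_cols] <- Zr[, fb_cols] + jit
    }
    fit <- lm_minimize(sp_resid(Zr), theta0, options, options$max_iters)
    fit$restart <- rst
    fit$selection_mse <- selection_mse(fit$theta)
    if (is.null(best) || fit$selection_mse < best$selection_mse) best <- fit
  }

  refine <- NULL
  if (refining)
    refine <- lm_minimize(cl_resid, best$theta, options, options$refine_iters)

  theta_final <- if (is.null(refine)) best$theta else refine$theta
  params <- unpack_theta(theta_final, config, p0)

  fitted_n <- eval_network(params, config, Z)
  report <- list(
    final_mse = mean((fitted_n - target)^2),
    closed_loop_mse = if (is.null(refine)) NA_real_ else refine$mse,
    iterations = best$iterations +
      if (is.null(refine)) 0L else refine$iterations,
    restart_index_selected = best$restart,
    mse_trajectory = best$trajectory,
    refine_trajectory = if (is.null(refine)) numeric(0) else refine$trajectory)

  obj <- structure(list(config = config, parameters = params,
                        report = report, call = match.call(),
                        clamp = clamp_norm,
                        n_blocks = length(Xb), n_steps = n_eff),
                   class = "narx")
  obj$fitted_values <- denorm_y(params, fitted_n)
  obj$residual_values <- do.call(rbind, lapply(Yb, function(y)
    y[-seq_len(burn), , drop = FALSE])) - obj$fitted_values
  obj
}

#' Wrap a configuration and explicit parameters as a NARX model
#'
#' Builds an unfitted `"narx"` object (e.g. a teacher network from
#' [init_parameters()], or parameters loaded with [read_narx()]) so the
#' prediction methods can be used without training.
#'
#' @param config a [narx_config()].
#' @param parameters a `"narx_parameters"` object.
#' @return An object of class `"narx"`.
#' @export
narx_model <- function(config, parameters) {
  stopifnot(inherits(config, "narx_config"),
            inherits(parameters, "narx_parameters"))
  structure(list(config = config, parameters = parameters,
                 report = NULL, call = match.call(),
                 n_blocks = 0L, n_steps = 0L),
            class = "narx")
}
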