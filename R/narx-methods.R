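# S3 methods for fitted "narx" objects.

#' Predict joint angles from EMG envelopes
#'
#' Runs the decoder over a contiguous block of envelope data in one of two
#' modes. In `"teacher_forced"` (series-parallel) mode the feedback taps
#' are filled from `angles`, the measured trajectory; every predicted step
#' is therefore a static function of measured data. In `"closed_loop"`
#' (parallel) mode only the first burn-in samples of measured angles seed
#' the delay lines and the recursion then feeds back its own predictions —
#' the decoder is driven by the EMG alone, which is the headline
#' evaluation mode.
#'
#' @param object a fitted or constructed `"narx"` object.
#' @param envelopes matrix `n x n_inputs` of EMG envelopes.
#' @param angles measured angles (degrees): required in full for
#'   teacher-forced mode; in closed-loop mode only the first burn-in rows
#'   are used (alternatively pass `init_angles`).
#' @param mode `"closed_loop"` (default) or `"teacher_forced"`.
#' @param init_angles optional `burn_in x n_outputs` matrix of measured
#'   angles seeding the closed-loop recursion.
#' @param ... unused.
#' @return Matrix `n x n_outputs` of predicted angles in degrees. The
#'   first `burn_in = m + max(T_x, T_y)` rows are `NA` in teacher-forced
#'   mode and the measured seed in closed-loop mode.
#' @export
predict.narx <- function(object, envelopes, angles = NULL,
                         mode = c("closed_loop", "teacher_forced"),
                         init_angles = NULL, ...) {
  mode <- match.arg(mode)
  cfg <- object$config
  p <- object$parameters
  X <- as_matrix(envelopes)
  if (ncol(X) != cfg$n_inputs)
    stop_emg("envelope column count does not match the configuration",
             "emgnarx_input_error")
  burn <- narx_burn_in(cfg)
  n <- nrow(X)
  if (n <= burn)
    stop_emg(sprintf("need more than burn-in = %d samples", burn),
             "emgnarx_input_error")
  Xn <- norm_x(p, X)
  out <- matrix(NA_real_, n, cfg$n_outputs)
  if (mode == "teacher_forced") {
    if (is.null(angles))
      stop_emg("teacher-forced prediction requires measured angles",
               "emgnarx_input_error")
    Yn <- norm_y(p, as_matrix(angles))
    d <- build_design(Xn, Yn, cfg)
    out[d$idx, ] <- denorm_y(p, eval_network(p, cfg, d$Z))
  } else {
    seed <- if (!is.null(init_angles)) as_matrix(init_angles)
            else if (!is.null(angles)) as_matrix(angles)
            else stop_emg("closed-loop prediction requires init_angles (or angles) for the burn-in",
                          "emgnarx_input_error")
    if (nrow(seed) < burn)
      stop_emg(sprintf("need %d initial angle samples", burn),
               "emgnarx_input_error")
    Yn0 <- norm_y(p, seed[seq_len(burn), , drop = FALSE])
    Yn0 <- rbind(Yn0, matrix(0, n - burn, cfg$n_outputs))
    # fitted decoders carry a joint-limit guard on the calibrated range;
    # bare models (teacher networks, loaded parameters) run unclamped
    clamp <- object$clamp %||% c(-Inf, Inf)
    out[] <- denorm_y(p, simulate_closed(p, cfg, Xn, Yn0, clamp))
  }
  colnames(out) <- JOINTS[seq_len(min(cfg$n_outputs, length(JOINTS)))]
  out
}

#' Closed-loop simulation of a NARX decoder
#'
#' Convenience wrapper around [predict.narx()] with
#' `mode = "closed_loop"`: the decoder trajectory is generated from the
#' envelopes alone after the measured burn-in seed. The run is
#' deterministic, so `nsim` and `seed` are accepted for generic
#' compatibility but ignored.
#'
#' @param object a `"narx"` object.
#' @param nsim,seed ignored (the recursion is deterministic).
#' @param envelopes matrix of EMG envelopes.
#' @param init_angles measured angles seeding the burn-in.
#' @param ... unused.
#' @return Matrix of simulated joint angles in degrees.
#' @export
simulate.narx <- function(object, nsim = 1, seed = NULL,
                          envelopes, init_angles, ...) {
  predict(object, envelopes, mode = "closed_loop",
          init_angles = init_angles)
}

#' @export
coef.narx <- function(object, ...) {
  p <- object$parameters
  cfg <- object$config
  nm <- c(
    as.vector(outer(outer(paste0("A[h", seq_len(cfg$n_hidden)), paste0(",x", seq_len(cfg$n_inputs)), paste0),
                    paste0(",k", seq_len(cfg$input_taps) - 1L, "]"), paste0)),
    if (cfg$feedback_taps > 0)
      as.vector(outer(outer(paste0("B[h", seq_len(cfg$n_hidden)), paste0(",y", seq_len(cfg$n_outputs)), paste0),
                      paste0(",k", seq_len(cfg$feedback_taps) - 1L, "]"), paste0)),
    as.vector(outer(paste0("C[y", seq_len(cfg$n_outputs)), paste0(",h", seq_len(cfg$n_hidden), "]"), paste0)),
    paste0("b1[h", seq_len(cfg$n_hidden), "]"),
    paste0("b2[y", seq_len(cfg$n_outputs), "]"))
  stats::setNames(pack_params(p), nm)
}

#' @export
fitted.narx <- function(object, ...) object$fitted_values

#' @export
residuals.narx <- function(object, ...) object$residual_values

#' @export
print.narx <- function(x, ...) {
  cat("NARX decoder\n")
  print(x$config)
  if (!is.null(x$report)) {
    cat(sprintf("  trained on %d blocks (%d effective steps)\n",
                x$n_blocks, x$n_steps))
    cat(sprintf("  teacher-forced training MSE (normalized): %.3g\n",
                x$report$final_mse))
    if (is.finite(x$report$closed_loop_mse))
      cat(sprintf("  closed-loop training MSE (normalized):   %.3g\n",
                  x$report$closed_loop_mse))
  } else cat("  (parameters set directly, not trained)\n")
  invisible(x)
}

#' @export
summary.narx <- function(object, ...) {
  s <- list(config = object$config,
            n_parameters = count_parameters(object$config),
            burn_in = narx_burn_in(object$config),
            report = object$report,
            train_vaf = if (!is.null(object$report)) {
              meas <- object$fitted_values + object$residual_values
              vapply(seq_len(ncol(meas)), function(j)
                vaf(meas[, j], object$fitted_values[, j]), numeric(1))
            })
  class(s) <- "summary.narx"
  s
}

#' @export
print.summary.narx <- function(x, ...) {
  print(x$config)
  cat("  burn-in:", x$burn_in, "steps\n")
  if (!is.null(x$report)) {
    cat(sprintf("  selected restart: %d (of the seeded initializations)\n",
                x$report$restart_index_selected))
    cat(sprintf("  LM iterations: %d; final normalized MSE: %.3g\n",
                x$report$iterations, x$report$final_mse))
    if (length(x$train_vaf))
      cat("  training VAF (teacher-forced, %):",
          paste(sprintf("%.2f", x$train_vaf), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.narx <- function(x, which = seq_len(x$config$n_outputs), ...) {
  if (is.null(x$report))
    stop_emg("plot() needs a fitted decoder", "emgnarx_input_error")
  meas <- x$fitted_values + x$residual_values
  old <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  tt <- (seq_len(nrow(meas)) - 1) * x$config$dt_s
  nm <- colnames(x$fitted_values)
  for (j in which) {
    graphics::plot(tt, meas[, j], type = "l", col = "grey40",
                   xlab = "time (s)", ylab = "angle (deg)",
                   main = if (!is.null(nm)) nm[j] else paste("joint", j), ...)
    graphics::lines(tt, x$fitted_values[, j], col = "firebrick")
  }
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

#' Save a NARX decoder as JSON
#'
#' Writes the configuration, every weight tensor (with its dimensions) and
#' the fitted normalizers to a self-contained, versioned JSON document.
#'
#' @param object a `"narx"` object.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_narx <- function(object, path) {
  stopifnot(inherits(object, "narx"))
  p <- object$parameters
  tensor <- function(x) list(dim = dim(x) %||% length(x), data = as.vector(x))
  doc <- list(
    format_version = 1L,
    clamp = object$clamp,
    config = unclass(object$config),
    parameters = list(A = tensor(p$A), B = tensor(p$B), C = tensor(p$C),
                      b1 = tensor(p$b1), b2 = tensor(p$b2),
                      input_scale = p$input_scale,
                      output_center = p$output_center,
                      output_halfwidth = p$output_halfwidth))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a NARX decoder saved by [write_narx()]
#'
#' @param path JSON file written by [write_narx()].
#' @return A `"narx"` object (prediction-ready, no training report).
#' @export
read_narx <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format_version) || doc$format_version != 1L)
    stop_emg("unrecognized model format version", "emgnarx_format_error")
  cf <- doc$config
  config <- narx_config(cf$n_inputs, cf$n_outputs, cf$n_hidden,
                        cf$input_taps, cf$feedback_taps, cf$m, cf$dt_s)
  arr <- function(t) array(t$data, dim = t$dim)
  pp <- doc$parameters
  p <- structure(list(A = arr(pp$A), B = arr(pp$B),
                      C = matrix(pp$C$data, pp$C$dim[1], pp$C$dim[2]),
                      b1 = as.numeric(pp$b1$data), b2 = as.numeric(pp$b2$data),
                      input_scale = as.numeric(pp$input_scale),
                      output_center = as.numeric(pp$output_center),
                      output_halfwidth = as.numeric(pp$output_halfwidth)),
                 class = "narx_parameters")
  obj <- narx_model(config, p)
  if (!is.null(doc$clamp)) obj$clamp <- as.numeric(doc$clamp)
  obj
}
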