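# Raw EMG -> linear envelopes at the decoding rate.
#
# The envelope chain follows standard myoelectric practice: full-wave
# rectification, a causal 6th-order low-pass Butterworth at 4 Hz, then
# decimation from the acquisition rate (1000 Hz) to the 20 Hz decoding
# rate. Filtering is single-pass (causal) because the decoder targets
# real-time control; the filter's group delay is absorbed by the NARX lag
# structure rather than removed by zero-phase filtering.

#' Full-wave rectification
#'
#' @param x numeric vector or matrix of raw EMG.
#' @return `abs(x)`, same shape.
#' @export
rectify <- function(x) {
  x <- as_matrix(x)
  if (!all(is.finite(x)))
    stop_emg("rectify requires finite values", "emgnarx_data_error")
  abs(x)
}

# Butterworth low-pass realized as cascaded second-order sections
# (biquads). The single transfer-function form of a 6th-order filter with
# a 4 Hz cutoff at 1000 Hz is numerically ill-conditioned (numerator
# coefficients ~1e-11 against denominator coefficients ~19); the cascade
# keeps every section well-scaled, each with an exactly unit DC gain.
# Analog prototype poles on the Butterworth circle, pre-warped cutoff,
# bilinear transform per section.
butter_lowpass <- function(fs, order, cutoff) {
  if (cutoff >= fs / 2)
    stop_emg("cutoff must be below the Nyquist frequency fs/2",
             "emgnarx_parameter_error")
  wc <- 2 * fs * tan(pi * cutoff / fs)      # pre-warped analog cutoff
  k <- seq_len(order)
  theta <- pi * (2 * k + order - 1) / (2 * order)
  poles <- wc * exp(1i * theta)             # left-half-plane, conj. pairs
  # pair complex-conjugate poles; an odd order leaves one real pole
  pairs <- list()
  used <- rep(FALSE, order)
  for (i in k) {
    if (used[i]) next
    j <- which(!used & abs(poles - Conj(poles[i])) <
                 1e-9 * wc & seq_along(poles) != i)[1]
    if (Im(poles[i]) == 0 || is.na(j)) {
      pairs[[length(pairs) + 1L]] <- poles[i]; used[i] <- TRUE
    } else {
      pairs[[length(pairs) + 1L]] <- c(poles[i], poles[j])
      used[c(i, j)] <- TRUE
    }
  }
  sections <- lapply(pairs, function(p) {
    zp <- (1 + p / (2 * fs)) / (1 - p / (2 * fs))   # bilinear transform
    if (length(p) == 2) {
      a <- c(1, -2 * Re(zp[1]), Mod(zp[1])^2)
      b <- (sum(a) / 4) * c(1, 2, 1)                # zeros at z = -1
    } else {
      a <- c(1, -Re(zp))
      b <- (sum(a) / 2) * c(1, 1)
    }
    list(b = b, a = a)
  })
  sections
}

# low-frequency group delay of the envelope filter, in seconds, from the
# phase slope of the section cascade near DC
envelope_group_delay <- function(fs, order = 6, cutoff = 4) {
  sections <- butter_lowpass(fs, order, cutoff)
  w <- 2 * pi * 0.05 / fs          # 0.05 Hz: deep in the flat band
  ph <- function(w) sum(vapply(sections, function(s) {
    z <- exp(-1i * w * (seq_along(s$b) - 1))
    Arg(sum(s$b * z) / sum(s$a * z))
  }, numeric(1)))
  -(ph(2 * w) - ph(w)) / w / fs
}

filter_causal <- function(sections, x) {
  # per-column causal cascade with steady-state init at the first sample
  # (each section has unit DC gain, so constant inputs pass unchanged)
  apply(as_matrix(x), 2, function(col) {
    x0 <- col[1]
    for (s in sections) {
      col <- as.numeric(signal::filter(
        s$b, s$a, col,
        init.x = rep(x0, length(s$b) - 1L),
        init.y = rep(x0, length(s$a) - 1L)))
    }
    col
  })
}

#' EMG linear envelope
#'
#' Applies a causal low-pass Butterworth filter per channel to an already
#' rectified signal. Filter state is initialized to the steady state
#' matching the first sample, suppressing start-up transients; small
#' negative filter transients are clipped to zero since an envelope
#' represents activation intensity.
#'
#' @param x rectified EMG, vector or matrix (columns are channels).
#' @param fs sampling rate in Hz.
#' @param order filter order (default 6).
#' @param cutoff cutoff frequency in Hz (default 4); must be below `fs/2`.
#' @return Matrix of nonnegative envelopes, same shape as `x`.
#' @export
linear_envelope <- function(x, fs, order = 6, cutoff = 4) {
  coef <- butter_lowpass(fs, order, cutoff)
  y <- filter_causal(coef, x)
  pmax(y, 0)
}

#' Decimate a signal to a lower rate by sample picking
#'
#' Keeps every `(fs_in/fs_out)`-th row starting at the first. No
#' anti-alias filter is applied: the 4 Hz envelope is already band-limited
#' far below the 10 Hz Nyquist of the 20 Hz decoding rate.
#'
#' @param x vector or matrix (rows are samples).
#' @param fs_in input sampling rate in Hz; must be an integer multiple of
#'   `fs_out`.
#' @param fs_out output rate in Hz (default 20).
#' @return The decimated matrix.
#' @export
decimate_to <- function(x, fs_in, fs_out = 20) {
  r <- fs_in / fs_out
  if (abs(r - round(r)) > 1e-9 || r < 1)
    stop_emg("fs_in must be an integer multiple of fs_out",
             "emgnarx_parameter_error")
  x <- as_matrix(x)
  x[seq(1L, nrow(x), by = round(r)), , drop = FALSE]
}

#' Preprocessed trial at the decoding rate
#'
#' Container for EMG linear envelopes and joint angles at the decoding
#' rate (default 20 Hz). Envelopes are nonnegative; angles are decimated
#' without filtering (self-paced reaching is band-limited far below the
#' decimated Nyquist).
#'
#' @param envelopes matrix `n_steps x n_channels`, nonnegative.
#' @param angles matrix `n_steps x n_joints`, degrees.
#' @param fs decoding rate in Hz.
#' @return An object of class `"envelope_trial"` with fields `envelopes`,
#'   `angles`, `fs` and `dt` (= `1/fs`, seconds).
#' @export
envelope_trial <- function(envelopes, angles, fs) {
  envelopes <- as_matrix(envelopes)
  angles <- as_matrix(angles)
  if (nrow(envelopes) != nrow(angles))
    stop_emg("envelopes and angles must have the same number of rows",
             "emgnarx_format_error")
  if (any(envelopes < 0))
    stop_emg("envelopes must be nonnegative", "emgnarx_data_error")
  structure(list(envelopes = envelopes, angles = angles,
                 fs = fs, dt = 1 / fs),
            class = "envelope_trial")
}

#' @export
print.envelope_trial <- function(x, ...) {
  cat("Envelope trial:", nrow(x$envelopes), "steps at", x$fs, "Hz",
      sprintf("(%.1f s), %d channels, %d joints\n",
              nrow(x$envelopes) / x$fs, ncol(x$envelopes), ncol(x$angles)))
  invisible(x)
}

#' Preprocess a raw trial to the decoding rate
#'
#' Runs the full envelope chain — rectify, causal Butterworth low-pass,
#' decimate — on the EMG, and decimates the joint angles (unfiltered) to
#' the same rate. Per-channel scaling is deferred to training so that
#' normalization constants are fitted on training folds only.
#'
#' @param trial a [trial_record()].
#' @param order,cutoff envelope filter settings (defaults 6, 4 Hz).
#' @param fs_out decoding rate in Hz (default 20); `trial$fs` must be an
#'   integer multiple.
#' @return An [envelope_trial()].
#' @export
preprocess_trial <- function(trial, order = 6, cutoff = 4, fs_out = 20) {
  stopifnot(inherits(trial, "trial_record"))
  env <- linear_envelope(rectify(trial$emg), trial$fs, order, cutoff)
  envelope_trial(envelopes = decimate_to(env, trial$fs, fs_out),
                 angles = decimate_to(trial$angles, trial$fs, fs_out),
                 fs = fs_out)
}
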