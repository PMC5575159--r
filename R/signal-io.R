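# Reading, writing and synchronizing trial recordings.
#
# A trial is a pair of synchronized streams sampled at a common rate:
# six-channel surface EMG (millivolts) and three joint-angle traces
# (degrees) for shoulder horizontal ab/adduction, elbow flexion-extension
# and wrist flexion-extension.

EMG_CHANNELS <- c("adelt", "pdelt", "bic", "tri", "fcr", "ecr")
JOINTS <- c("shoulder", "elbow", "wrist")
TRIAL_HEADER <- c("time", paste0("emg_", EMG_CHANNELS), paste0("ang_", JOINTS))

#' Construct a trial recording
#'
#' Bundles synchronized raw EMG and joint-angle streams with their sampling
#' metadata. Both matrices must have the same number of rows and contain
#' only finite values.
#'
#' @param emg numeric matrix, `n_samples x n_channels`, EMG in millivolts.
#' @param angles numeric matrix, `n_samples x n_joints`, angles in degrees.
#' @param fs sampling rate in Hz (must be positive).
#' @param channel_names labels for the EMG channels; defaults to the six
#'   arm muscles (anterior/posterior deltoid, biceps, triceps long head,
#'   flexor/extensor carpi radialis).
#' @param joint_names labels for the joints.
#' @param trigger_index optional 1-based sample index of the
#'   synchronization trigger.
#' @return An object of class `"trial_record"`.
#' @export
trial_record <- function(emg, angles, fs,
                         channel_names = EMG_CHANNELS,
                         joint_names = JOINTS,
                         trigger_index = NULL) {
  emg <- as_matrix(emg)
  angles <- as_matrix(angles)
  if (nrow(emg) != nrow(angles))
    stop_emg("emg and angles must have the same number of rows",
             "emgnarx_format_error")
  if (nrow(emg) == 0L)
    stop_emg("a trial must contain at least one sample",
             "emgnarx_format_error")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_emg("fs must be a single positive number", "emgnarx_sampling_error")
  if (anyNA(emg) || anyNA(angles) || !all(is.finite(emg)) ||
      !all(is.finite(angles)))
    stop_emg("trial contains non-finite values", "emgnarx_data_error")
  if (length(channel_names) != ncol(emg))
    stop_emg("channel_names length must match EMG columns",
             "emgnarx_format_error")
  if (length(joint_names) != ncol(angles))
    stop_emg("joint_names length must match angle columns",
             "emgnarx_format_error")
  colnames(emg) <- channel_names
  colnames(angles) <- joint_names
  structure(list(emg = emg, angles = angles, fs = fs,
                 channel_names = channel_names, joint_names = joint_names,
                 trigger_index = trigger_index),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat("Trial recording:", nrow(x$emg), "samples at", x$fs, "Hz",
      sprintf("(%.1f s)\n", nrow(x$emg) / x$fs))
  cat("  EMG channels:", paste(x$channel_names, collapse = ", "), "\n")
  cat("  Joints:      ", paste(x$joint_names, collapse = ", "), "\n")
  invisible(x)
}

#' Read a trial recording from disk
#'
#' Reads a comma-separated trial with the canonical header
#' `time,emg_adelt,emg_pdelt,emg_bic,emg_tri,emg_fcr,emg_ecr,`
#' `ang_shoulder,ang_elbow,ang_wrist` (time in seconds from trial start).
#' The sampling rate is inferred from the time column, which must advance
#' with a constant step (to within 1 ppm).
#'
#' @param path file to read.
#' @param format only `"csv"` is supported; `"hdf5"` is recognized but not
#'   available in this build.
#' @return A [trial_record()].
#' @export
read_trial <- function(path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop_emg("HDF5 trials are not supported by this build; use CSV",
             "emgnarx_format_error")
  if (!file.exists(path))
    stop_emg(paste0("file not found: ", path), "emgnarx_io_error")
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(TRIAL_HEADER, names(df))
  if (length(missing))
    stop_emg(paste0("missing columns: ", paste(missing, collapse = ", ")),
             "emgnarx_format_error")
  df <- df[TRIAL_HEADER]
  if (anyNA(df))
    stop_emg("trial file contains missing values", "emgnarx_data_error")
  tm <- df$time
  if (length(tm) < 2L)
    stop_emg("need at least two samples to infer the sampling rate",
             "emgnarx_sampling_error")
  dt <- diff(tm)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * mean(dt))
    stop_emg("time column is not uniformly sampled (beyond 1 ppm)",
             "emgnarx_sampling_error")
  fs <- 1 / mean(dt)
  trial_record(emg = as.matrix(df[paste0("emg_", EMG_CHANNELS)]),
               angles = as.matrix(df[paste0("ang_", JOINTS)]),
               fs = fs)
}

#' Write a trial recording to disk
#'
#' Inverse of [read_trial()]: writes the canonical CSV dialect with enough
#' precision that a read/write round trip reproduces every field to 1e-9.
#'
#' @param trial a [trial_record()].
#' @param path destination file.
#' @param format only `"csv"` is supported.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop_emg("HDF5 trials are not supported by this build; use CSV",
             "emgnarx_format_error")
  stopifnot(inherits(trial, "trial_record"))
  n <- nrow(trial$emg)
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop_emg(paste0("directory does not exist: ", dir), "emgnarx_io_error")
  tm <- (seq_len(n) - 1) / trial$fs
  m <- cbind(tm, trial$emg, trial$angles)
  lines <- c(paste(TRIAL_HEADER, collapse = ","),
             apply(m, 1, function(r) paste(sprintf("%.12g", r),
                                           collapse = ",")))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok)
    stop_emg(paste0("cannot write: ", path), "emgnarx_io_error")
  invisible(path)
}

#' Synchronize EMG and angle streams on a shared trigger
#'
#' Both acquisition systems receive the same trigger pulse; the streams are
#' cropped so the trigger samples coincide at the first retained sample and
#' truncated to their common remaining length.
#'
#' @param emg_stream EMG matrix (rows are samples).
#' @param angle_stream angle matrix (rows are samples).
#' @param trigger_emg,trigger_angles 1-based trigger sample index in each
#'   stream.
#' @param fs shared sampling rate in Hz.
#' @inheritParams trial_record
#' @return A [trial_record()] with `trigger_index = 1`.
#' @export
align_streams <- function(emg_stream, angle_stream,
                          trigger_emg, trigger_angles, fs,
                          channel_names = EMG_CHANNELS,
                          joint_names = JOINTS) {
  emg_stream <- as_matrix(emg_stream)
  angle_stream <- as_matrix(angle_stream)
  for (chk in list(c(trigger_emg, nrow(emg_stream)),
                   c(trigger_angles, nrow(angle_stream)))) {
    if (!is_count(chk[1]) || chk[1] > chk[2])
      stop_emg("trigger index outside the stream", "emgnarx_alignment_error")
  }
  n <- min(nrow(emg_stream) - trigger_emg, nrow(angle_stream) - trigger_angles) + 1L
  trial_record(emg = emg_stream[trigger_emg + seq_len(n) - 1L, , drop = FALSE],
               angles = angle_stream[trigger_angles + seq_len(n) - 1L, , drop = FALSE],
               fs = fs, channel_names = channel_names,
               joint_names = joint_names, trigger_index = 1L)
}
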