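# Decoder scoring: VAF, contiguous five-fold cross-validation, the
# prediction-interval sweep, and the across-joint repeated-measures
# comparison.

#' Variance accounted for (VAF)
#'
#' `100 * (1 - Var(measured - predicted) / Var(measured))` with the
#' population (biased) variance convention. 100 is a perfect fit; the
#' value can be negative for predictors worse than the measured mean.
#'
#' @param measured,predicted numeric vectors of equal length (>= 2).
#' @return VAF in percent.
#' @export
vaf <- function(measured, predicted) {
  if (length(measured) != length(predicted) || length(measured) < 2L)
    stop_emg("measured and predicted must have equal length >= 2",
             "emgnarx_input_error")
  vm <- pop_var(measured)
  if (vm == 0)
    stop_emg("VAF is undefined for a zero-variance measured signal",
             "emgnarx_metric_error")
  100 * (1 - pop_var(measured - predicted) / vm)
}

#' Contiguous k-fold partition
#'
#' Splits `1:n_samples` into `k` contiguous, disjoint validation blocks
#' covering all samples; any remainder (`n mod k`) is appended to the
#' final block. Folds are contiguous time segments, never shuffled
#' samples, so autocorrelated neighbours cannot leak between training and
#' validation.
#'
#' @param n_samples total sample count.
#' @param k number of folds (default 5).
#' @return List of `k` elements, each `list(train = ..., validation = ...)`
#'   of 1-based indices.
#' @export
make_folds <- function(n_samples, k = 5) {
  if (!is_count(n_samples) || !is_count(k, min = 2L) || n_samples < 2L * k)
    stop_emg("n_samples too small to partition into k contiguous folds",
             "emgnarx_partition_error")
  base <- n_samples %/% k
  starts <- (seq_len(k) - 1L) * base + 1L
  ends <- starts + base - 1L
  ends[k] <- n_samples                 # remainder goes to the final block
  lapply(seq_len(k), function(f) {
    val <- starts[f]:ends[f]
    list(train = setdiff(seq_len(n_samples), val), validation = val)
  })
}

# split an index vector into runs of consecutive indices
contiguous_runs <- function(idx) {
  unname(split(idx, cumsum(c(1L, diff(idx) != 1L))))
}

#' Contiguous five-fold cross-validation of the decoder
#'
#' For each fold a fresh decoder is trained on the four remaining
#' segments (kept as separate contiguous blocks, so delay-line state is
#' reset at every splice) and scored by per-joint VAF on the held-out
#' segment, excluding the burn-in samples. Closed-loop mode seeds the
#' validation recursion with the first burn-in measured samples and then
#' decodes from EMG alone.
#'
#' @param config a [narx_config()].
#' @param trial an [envelope_trial()].
#' @param options a [narx_options()]; fold `f` trains with seed
#'   `options$seed + 1000 * f` for reproducibility.
#' @param mode `"closed_loop"` (default) or `"teacher_forced"`.
#' @param k number of folds (default 5).
#' @return An object of class `"narx_cv"`: `vaf_table` (`k x n_joints`,
#'   percent), `mean_vaf`, `sd_vaf`, `mode`, `config`, `seeds`.
#' @export
cross_validate <- function(config, trial, options = narx_options(),
                           mode = c("closed_loop", "teacher_forced"),
                           k = 5) {
  mode <- match.arg(mode)
  stopifnot(inherits(trial, "envelope_trial"))
  n <- nrow(trial$envelopes)
  folds <- make_folds(n, k)
  burn <- narx_burn_in(config)
  nj <- ncol(trial$angles)
  vt <- matrix(NA_real_, k, nj,
               dimnames = list(paste0("fold", seq_len(k)),
                               colnames(trial$angles) %||%
                                 JOINTS[seq_len(nj)]))
  seeds <- options$seed + 1000L * seq_len(k)
  for (f in seq_len(k)) {
    runs <- contiguous_runs(folds[[f]]$train)
    Xb <- lapply(runs, function(r) trial$envelopes[r, , drop = FALSE])
    Yb <- lapply(runs, function(r) trial$angles[r, , drop = FALSE])
    opts_f <- options
    opts_f$seed <- seeds[f]
    fit <- narx(Xb, Yb, config, opts_f)
    vi <- folds[[f]]$validation
    Xv <- trial$envelopes[vi, , drop = FALSE]
    Yv <- trial$angles[vi, , drop = FALSE]
    pred <- predict(fit, Xv, angles = Yv, mode = mode)
    keep <- (burn + 1L):nrow(Yv)
    for (j in seq_len(nj)) vt[f, j] <- vaf(Yv[keep, j], pred[keep, j])
  }
  structure(list(vaf_table = vt,
                 mean_vaf = colMeans(vt),
                 sd_vaf = apply(vt, 2, stats::sd),
                 mode = mode, config = config, seeds = seeds),
            class = "narx_cv")
}

#' @export
print.narx_cv <- function(x, ...) {
  cat(sprintf("%d-fold contiguous cross-validation (%s mode), tau = %g ms\n",
              nrow(x$vaf_table), x$mode, x$config$tau_ms))
  print(round(x$vaf_table, 2))
  cat("mean VAF (%):",
      paste(sprintf("%s %.2f +/- %.2f", colnames(x$vaf_table),
                    x$mean_vaf, x$sd_vaf), collapse = ", "), "\n")
  invisible(x)
}

#' Sweep the prediction interval
#'
#' Re-runs the cross-validation with the embedding lag `m` set to
#' `tau / dt` for each requested prediction interval `tau` and reports the
#' per-joint mean and sd VAF, plus the interval with the highest
#' grand-mean VAF (ties broken toward the smallest interval).
#'
#' @param config a [narx_config()]; only `m` is varied.
#' @param trial an [envelope_trial()].
#' @param intervals_ms candidate prediction intervals in milliseconds;
#'   each must be a positive multiple of the decoding step
#'   `1000 / trial$fs`.
#' @param options a [narx_options()].
#' @param mode evaluation mode passed to [cross_validate()].
#' @param k number of folds.
#' @return An object of class `"narx_sweep"`: `intervals_ms`,
#'   `vaf_by_interval` (mean and sd per joint and interval),
#'   `grand_mean`, `best_interval_ms`, and the per-interval `"narx_cv"`
#'   reports.
#' @export
sweep_prediction_interval <- function(config, trial,
                                      intervals_ms = seq(50, 300, by = 50),
                                      options = narx_options(),
                                      mode = "closed_loop", k = 5) {
  stopifnot(inherits(trial, "envelope_trial"))
  step_ms <- 1000 / trial$fs
  mm <- intervals_ms / step_ms
  if (any(intervals_ms <= 0) || any(abs(mm - round(mm)) > 1e-9))
    stop_emg(sprintf("every interval must be a positive multiple of %g ms",
                     step_ms), "emgnarx_parameter_error")
  reports <- vector("list", length(intervals_ms))
  means <- sds <- matrix(NA_real_, length(intervals_ms), ncol(trial$angles))
  for (i in seq_along(intervals_ms)) {
    cfg_i <- narx_config(config$n_inputs, config$n_outputs, config$n_hidden,
                         config$input_taps, config$feedback_taps,
                         m = as.integer(round(mm[i])), dt_s = 1 / trial$fs)
    reports[[i]] <- cross_validate(cfg_i, trial, options, mode = mode, k = k)
    means[i, ] <- reports[[i]]$mean_vaf
    sds[i, ] <- reports[[i]]$sd_vaf
  }
  dimnames(means) <- dimnames(sds) <-
    list(paste0(intervals_ms, "ms"), colnames(reports[[1]]$vaf_table))
  grand <- rowMeans(means)
  best <- intervals_ms[which.max(grand)]   # which.max takes the first max
  structure(list(intervals_ms = intervals_ms,
                 vaf_by_interval = list(mean = means, sd = sds),
                 grand_mean = grand, best_interval_ms = best,
                 reports = reports, mode = mode),
            class = "narx_sweep")
}

#' @export
print.narx_sweep <- function(x, ...) {
  cat("Prediction-interval sweep (", x$mode, " mode)\n", sep = "")
  tab <- cbind(x$vaf_by_interval$mean, grand = x$grand_mean)
  print(round(tab, 2))
  cat("best interval:", x$best_interval_ms, "ms\n")
  invisible(x)
}

#' @export
plot.narx_sweep <- function(x, ...) {
  m <- x$vaf_by_interval$mean
  graphics::matplot(x$intervals_ms, m, type = "b", pch = 16, lty = 1,
                    xlab = "prediction interval (ms)", ylab = "mean VAF (%)",
                    ...)
  graphics::legend("bottomright", colnames(m), col = seq_len(ncol(m)),
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}

#' One-way repeated-measures ANOVA
#'
#' Compares conditions (e.g. joints) measured on the same units (e.g.
#' folds or subjects). The sums of squares follow the standard one-way
#' within-subject decomposition: `SS_error = SS_total - SS_subjects -
#' SS_conditions`, `F = (SS_c/df1)/(SS_e/df2)` with `df1 = c - 1`,
#' `df2 = (c - 1)(n - 1)`, and partial eta squared
#' `SS_c / (SS_c + SS_e)`. No sphericity correction is applied. Pairwise
#' Bonferroni-adjusted paired t-tests are attached.
#'
#' @param vaf_by_condition complete numeric matrix, `n_units x
#'   n_conditions`.
#' @return An object of class `"narx_anova"` with `F`, `df1`, `df2`, `p`,
#'   `partial_eta_sq` and `pairwise` (see [bonferroni_pairwise()]).
#' @export
rm_anova <- function(vaf_by_condition) {
  x <- as_matrix(vaf_by_condition)
  n <- nrow(x); cc <- ncol(x)
  if (n < 2L || cc < 2L || anyNA(x))
    stop_emg("need a complete matrix with >= 2 units and >= 2 conditions",
             "emgnarx_input_error")
  grand <- mean(x)
  ss_total <- sum((x - grand)^2)
  ss_subj <- cc * sum((rowMeans(x) - grand)^2)
  ss_cond <- n * sum((colMeans(x) - grand)^2)
  ss_err <- ss_total - ss_subj - ss_cond
  df1 <- cc - 1L
  df2 <- (cc - 1L) * (n - 1L)
  if (ss_cond <= 0) {
    Fv <- 0; p <- 1
  } else {
    Fv <- (ss_cond / df1) / (ss_err / df2)
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  }
  structure(list(F = Fv, df1 = df1, df2 = df2, p = p,
                 partial_eta_sq = if (ss_cond + ss_err > 0)
                   ss_cond / (ss_cond + ss_err) else 0,
                 ss = c(conditions = ss_cond, subjects = ss_subj,
                        error = ss_err, total = ss_total),
                 pairwise = bonferroni_pairwise(x)),
            class = "narx_anova")
}

#' @export
print.narx_anova <- function(x, ...) {
  cat(sprintf("One-way repeated-measures ANOVA: F(%d, %d) = %.3g, p = %.4g, partial eta^2 = %.3g\n",
              x$df1, x$df2, x$F, x$p, x$partial_eta_sq))
  cat("Bonferroni pairwise comparisons:\n")
  print(x$pairwise, digits = 4)
  invisible(x)
}

#' Bonferroni-corrected pairwise paired t-tests
#'
#' Two-sided paired t-test for every condition pair with the Bonferroni
#' cap `p_adj = min(1, p * n_pairs)`. A pair whose difference vector has
#' zero variance is flagged degenerate and assigned `p_adj = 1`.
#'
#' @inheritParams rm_anova
#' @return Data frame with one row per pair: condition labels, `t`, `df`,
#'   raw `p`, adjusted `p_adj`, and a `degenerate` flag.
#' @export
bonferroni_pairwise <- function(vaf_by_condition) {
  x <- as_matrix(vaf_by_condition)
  if (nrow(x) < 2L || ncol(x) < 2L || anyNA(x))
    stop_emg("need a complete matrix with >= 2 units and >= 2 conditions",
             "emgnarx_input_error")
  labs <- colnames(x) %||% paste0("cond", seq_len(ncol(x)))
  pairs <- utils::combn(ncol(x), 2)
  npairs <- ncol(pairs)
  res <- lapply(seq_len(npairs), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    d <- x[, a] - x[, b]
    if (stats::sd(d) == 0) {
      data.frame(a = labs[a], b = labs[b], t = NA_real_,
                 df = length(d) - 1L, p = NA_real_, p_adj = 1,
                 degenerate = TRUE)
    } else {
      tt <- stats::t.test(d)
      data.frame(a = labs[a], b = labs[b], t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 p_adj = min(1, tt$p.value * npairs), degenerate = FALSE)
    }
  })
  do.call(rbind, res)
}
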