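#' @useDynLib tmjmech, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Remove the least-squares linear trend from a series
#'
#' Fits a straight line to the full series by ordinary least squares and
#' subtracts it, leaving zero-mean residuals. A constant series becomes all
#' zeros; a perfect ramp is removed exactly.
#'
#' @param series A [uniform_series()].
#' @return A `uniform_series` of detrended values.
#' @export
detrend <- function(series) {
  stopifnot_series(series)
  n <- length(series$values)
  t <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t), series$values)
  out <- series
  out$values <- unname(fit$residuals)
  out
}

#' Full-wave rectification
#'
#' @param series A [uniform_series()].
#' @return A `uniform_series` of elementwise absolute values.
#' @export
rectify <- function(series) {
  stopifnot_series(series)
  series$values <- abs(series$values)
  series
}

# steady-state direct-form-II-transposed state for constant input 1
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b)) - 1
  bb <- c(b, rep(0, n + 1 - length(b)))
  aa <- c(a, rep(0, n + 1 - length(a)))
  g <- sum(bb) / sum(aa) # DC gain
  z <- numeric(n)
  if (n > 0) {
    z[n] <- bb[n + 1] - aa[n + 1] * g
    if (n > 1) for (i in (n - 1):1) z[i] <- bb[i + 1] - aa[i + 1] * g + z[i + 1]
  }
  z
}

# single-pass IIR with step-matched initial conditions at level x0
lfilter_matched <- function(b, a, x, x0 = x[1]) {
  .lfilter_cpp(b, a, x, lfilter_zi(b, a) * x0)
}

# factor a transfer function into second-order sections (biquads); the
# cascade is far better conditioned than the expanded polynomials for
# narrow normalized cutoffs such as 6 Hz at 2 kHz
tf_to_sos <- function(b, a) {
  z <- polyroot(rev(b / b[1]))
  p <- polyroot(rev(a / a[1]))
  pair_up <- function(r) {
    # sort by imaginary part magnitude so conjugates are adjacent
    r <- r[order(abs(Im(r)), Re(r))]
    out <- list()
    while (length(r) > 0) {
      if (abs(Im(r[1])) < 1e-10) {
        # pair two reals (or a lone real with an implicit zero root)
        if (length(r) >= 2 && abs(Im(r[2])) < 1e-10) {
          out[[length(out) + 1]] <- c(Re(r[1]), Re(r[2]))
          r <- r[-(1:2)]
        } else {
          out[[length(out) + 1]] <- c(Re(r[1]), NA)
          r <- r[-1]
        }
      } else {
        mate <- which.min(abs(r - Conj(r[1]))[-1]) + 1
        out[[length(out) + 1]] <- c(r[1], r[mate])
        r <- r[-c(1, mate)]
      }
    }
    out
  }
  quad <- function(pair) {
    if (length(pair) == 2 && is.na(pair[2]))
      return(c(1, -Re(pair[1]), 0))
    c(1, -Re(pair[1] + pair[2]), Re(pair[1] * pair[2]))
  }
  zp <- pair_up(z)
  pp <- pair_up(p)
  ns <- max(length(zp), length(pp))
  gain <- b[1] / a[1]
  sos <- lapply(seq_len(ns), function(i) {
    bb <- if (i <= length(zp)) quad(zp[[i]]) else c(1, 0, 0)
    aa <- if (i <= length(pp)) quad(pp[[i]]) else c(1, 0, 0)
    list(b = bb, a = aa)
  })
  sos[[1]]$b <- sos[[1]]$b * gain
  sos
}

# forward cascade of biquads with step-matched initial conditions
sosfilt_matched <- function(sos, x) {
  level <- x[1]
  for (s in sos) {
    x <- .lfilter_cpp(s$b, s$a, x, lfilter_zi(s$b, s$a) * level)
    level <- level * sum(s$b) / sum(s$a)
  }
  x
}

#' Zero-phase Butterworth low-pass filter
#'
#' Designs a Butterworth low-pass filter of the given order and applies it
#' forward and backward (zero phase, squared magnitude response). Edge
#' transients are controlled by odd-reflection padding and steady-state
#' initial filter conditions, so a constant series passes unchanged.
#'
#' @param series A [uniform_series()].
#' @param order Filter order (default 4).
#' @param cutoff Cutoff frequency in Hz (default 6); must be below Nyquist.
#' @return The filtered `uniform_series`.
#' @export
lowpass <- function(series, order = 4, cutoff = 6) {
  stopifnot_series(series)
  fs <- series$sample_rate
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  if (cutoff <= 0) stop("cutoff must be positive")
  ba <- signal::butter(order, cutoff / (fs / 2), type = "low")
  sos <- tf_to_sos(ba$b / ba$a[1], ba$a / ba$a[1])
  x <- series$values
  n <- length(x)
  pad <- min(n - 1, 3 * max(length(ba$a), length(ba$b)))
  # odd (point-reflected) extension at both ends
  xe <- c(2 * x[1] - x[pad:1 + 1], x, 2 * x[n] - x[n - seq_len(pad)])
  y <- sosfilt_matched(sos, xe)
  y <- rev(sosfilt_matched(sos, rev(y)))
  out <- series
  out$values <- y[(pad + 1):(pad + n)]
  out
}

#' EMG linear envelope, normalized to a baseline window
#'
#' The function-assessment envelope chain: linear detrending, full-wave
#' rectification, zero-phase Butterworth low-pass (default 4th order, 6 Hz),
#' then division by the mean envelope value inside the supplied baseline
#' window (the plateau of the 20 N bite). The result is dimensionless with
#' mean 1 over the baseline window.
#'
#' @param raw Raw EMG channel, a [uniform_series()].
#' @param baseline_window `[t_start, t_end]` in seconds locating the 20 N
#'   bite plateau used for normalization.
#' @param order,cutoff Passed to [lowpass()].
#' @return A dimensionless `uniform_series` envelope.
#' @export
emg_envelope <- function(raw, baseline_window, order = 4, cutoff = 6) {
  env <- lowpass(rectify(detrend(raw)), order = order, cutoff = cutoff)
  idx <- window_indices(env, baseline_window)
  base <- mean(env$values[idx])
  if (!is.finite(base) || base <= 0)
    stop("baseline mean must be positive; check the baseline window")
  env$values <- env$values / base
  env$units <- ""
  env
}

#' Clip a window and resample it to a fixed duration
#'
#' The windowed segment is linearly interpolated onto `n_out` uniformly
#' spaced samples spanning `duration` seconds: sample `i` takes the value of
#' the original signal at window fraction `(i-1)/(n_out-1)`, so the window's
#' endpoint values are preserved, and the output grid has spacing
#' `duration/n_out` (1 kHz for the default 250 samples over 0.25 s, aligning
#' with the simulator's time step).
#'
#' @param series A [uniform_series()].
#' @param window `[t_start, t_end]` seconds, inside the series span.
#' @param duration Output duration in seconds (default 0.25).
#' @param n_out Number of output samples (default 250).
#' @return A `uniform_series` starting at t = 0.
#' @export
clip_resample <- function(series, window, duration = 0.25, n_out = 250) {
  stopifnot_series(series)
  if (n_out < 2) stop("n_out must be at least 2")
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be [t_start, t_end] with t_end > t_start")
  tt <- series_times(series)
  if (window[1] < tt[1] - 1e-12 || window[2] > tt[length(tt)] + 1e-12)
    stop("window lies outside the series span")
  src_t <- window[1] + (window[2] - window[1]) * (seq_len(n_out) - 1) / (n_out - 1)
  vals <- stats::approx(tt, series$values, xout = src_t, rule = 2)$y
  uniform_series(vals, sample_rate = n_out / duration, start_time = 0,
                 units = series$units)
}

#' Ipsilateral-to-contralateral activation ratio
#'
#' Ratio of the mean ipsilateral envelope to the mean contralateral envelope
#' over a common window. Envelopes are expected to be the normalized outputs
#' of [emg_envelope()].
#'
#' @param ipsi_env,contra_env `uniform_series` envelopes on the same grid.
#' @param window `[t_start, t_end]` seconds; `NULL` uses the full overlap.
#' @return The dimensionless IC ratio.
#' @export
ic_ratio <- function(ipsi_env, contra_env, window = NULL) {
  stopifnot_series(ipsi_env)
  stopifnot_series(contra_env)
  if (abs(ipsi_env$sample_rate - contra_env$sample_rate) > 1e-9 ||
      length(ipsi_env$values) != length(contra_env$values))
    stop("envelopes must share sampling")
  if (is.null(window)) {
    idx <- seq_along(ipsi_env$values)
  } else {
    idx <- window_indices(ipsi_env, window)
  }
  denom <- mean(contra_env$values[idx])
  if (!is.finite(denom) || denom <= 0)
    stop("contralateral mean must be positive")
  mean(ipsi_env$values[idx]) / denom
}

#' Process a bite recording into simulation inputs
#'
#' Runs the complete function-assessment chain on one unilateral-bite
#' recording: EMG envelopes (detrend, rectify, 6 Hz zero-phase low-pass,
#' 20 N-baseline normalization), IC ratios for the temporalis and masseter
#' pairs with the ipsilateral side set by `task_side`, and the force curve
#' (optional rest-window drift correction, low-pass, clip and resample to
#' 0.25 s). The final bite force is the last sample of the processed curve.
#'
#' The force channel is not blanket-detrended: removing a least-squares line
#' from a multi-bite recording would destroy the absolute force level that
#' the simulation tracks. Instead, if `rest_window` locates an unloaded
#' segment, a line fitted there (sensor zero + drift) is subtracted.
#'
#' @param rec A [bite_recording()].
#' @param bite_window `[t_start, t_end]` seconds of the highest-force bite
#'   plateau, clipped and resampled to the task curve.
#' @param baseline_window `[t_start, t_end]` seconds of the 20 N bite plateau
#'   (EMG normalization reference).
#' @param rest_window Optional `[t_start, t_end]` of an unloaded segment used
#'   to remove force-sensor offset/drift; `NULL` (default) applies none.
#' @param duration,n_out Passed to [clip_resample()] for the force curve.
#' @param order,cutoff Filter settings shared by all channels.
#' @return An object of class `processed_task` with elements `force_curve`,
#'   `ic_temporalis`, `ic_masseter`, `final_bite_force`, `task_side`.
#' @export
process_recording <- function(rec, bite_window, baseline_window,
                              rest_window = NULL,
                              duration = 0.25, n_out = 250,
                              order = 4, cutoff = 6) {
  if (!inherits(rec, "bite_recording")) stop("rec must be a bite_recording")
  force <- rec$force
  if (!is.null(rest_window)) {
    idx <- window_indices(force, rest_window)
    t <- seq_along(force$values)
    fit <- stats::lm.fit(cbind(1, t[idx]), force$values[idx])
    force$values <- force$values - cbind(1, t) %*% fit$coefficients
  }
  force <- lowpass(force, order = order, cutoff = cutoff)
  force_curve <- clip_resample(force, bite_window, duration = duration,
                               n_out = n_out)
  env <- lapply(rec$emg, emg_envelope, baseline_window = baseline_window,
                order = order, cutoff = cutoff)
  ipsi <- if (rec$task_side == "left") c("LT", "LM") else c("RT", "RM")
  contra <- if (rec$task_side == "left") c("RT", "RM") else c("LT", "LM")
  out <- list(
    force_curve = force_curve,
    ic_temporalis = ic_ratio(env[[ipsi[1]]], env[[contra[1]]], bite_window),
    ic_masseter = ic_ratio(env[[ipsi[2]]], env[[contra[2]]], bite_window),
    final_bite_force = force_curve$values[length(force_curve$values)],
    task_side = rec$task_side
  )
  class(out) <- "processed_task"
  out
}

#' @export
print.processed_task <- function(x, ...) {
  cat(sprintf(paste0("<processed_task> %s bite: IC temporalis %.3f, ",
                     "IC masseter %.3f, final bite force %.2f N\n"),
              x$task_side, x$ic_temporalis, x$ic_masseter,
              x$final_bite_force))
  invisible(x)
}
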