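#' Uniformly sampled time series
#'
#' A minimal container for a uniformly sampled scalar signal (bite force in
#' newtons or a raw/processed EMG channel). Time of sample `i` is
#' `start_time + (i - 1) / sample_rate`.
#'
#' @param values Numeric vector of samples (length >= 2, all finite).
#' @param sample_rate Sampling frequency in Hz (> 0).
#' @param start_time Time of the first sample in seconds.
#' @param units Optional unit label carried for printing only.
#' @return An object of class `uniform_series`.
#' @export
uniform_series <- function(values, sample_rate, start_time = 0, units = "") {
  values <- as.numeric(values)
  if (length(values) < 2) stop("uniform_series: need at least 2 samples")
  if (!all(is.finite(values))) stop("uniform_series: values must be finite")
  if (!is.finite(sample_rate) || sample_rate <= 0)
    stop("uniform_series: sample_rate must be > 0")
  structure(
    list(values = values, sample_rate = sample_rate,
         start_time = start_time, units = units),
    class = "uniform_series"
  )
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %d samples @ %g Hz, t = [%g, %g] s%s\n",
              length(x$values), x$sample_rate, x$start_time,
              series_end_time(x),
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' Sample times of a series
#' @param x A `uniform_series`.
#' @return Numeric vector of sample times in seconds.
#' @export
series_times <- function(x) {
  x$start_time + (seq_along(x$values) - 1) / x$sample_rate
}

series_end_time <- function(x) {
  x$start_time + (length(x$values) - 1) / x$sample_rate
}

#' Duration of a series in seconds
#' @param x A `uniform_series`.
#' @return Time span from first to last sample, seconds.
#' @export
series_duration <- function(x) (length(x$values) - 1) / x$sample_rate

stopifnot_series <- function(x) {
  if (!inherits(x, "uniform_series")) stop("expected a uniform_series")
  invisible(x)
}

#' Bite-force + EMG recording of one unilateral bite task
#'
#' Bundles the force channel and the four surface-EMG channels (LT/RT left
#' and right temporalis, LM/RM left and right masseter) of a five-bite
#' unilateral clench task, together with the task side and the target force
#' staircase.
#'
#' @param force `uniform_series`, bite force in N.
#' @param emg Named list of four `uniform_series` with names
#'   `LT`, `RT`, `LM`, `RM` (arbitrary units).
#' @param task_side `"left"` or `"right"`.
#' @param target_levels Target force levels in N, default `c(10,20,30,40,50)`.
#' @return An object of class `bite_recording`.
#' @export
bite_recording <- function(force, emg, task_side,
                           target_levels = c(10, 20, 30, 40, 50)) {
  stopifnot_series(force)
  task_side <- match.arg(task_side, c("left", "right"))
  need <- c("LT", "RT", "LM", "RM")
  if (!is.list(emg) || !setequal(names(emg), need) || anyDuplicated(names(emg)))
    stop("emg must be a named list with unique channels LT, RT, LM, RM")
  emg <- emg[need]
  for (ch in emg) {
    stopifnot_series(ch)
    if (abs(ch$sample_rate - force$sample_rate) > 1e-9 ||
        length(ch$values) != length(force$values) ||
        abs(ch$start_time - force$start_time) > 1e-9)
      stop("all channels must share sample rate, start time and length")
  }
  structure(
    list(force = force, emg = emg, task_side = task_side,
         target_levels = target_levels),
    class = "bite_recording"
  )
}

#' @export
print.bite_recording <- function(x, ...) {
  cat(sprintf("<bite_recording> %s task, %d samples @ %g Hz, targets: %s N\n",
              x$task_side, length(x$force$values), x$force$sample_rate,
              paste(x$target_levels, collapse = "/")))
  invisible(x)
}

# window [t0, t1] (seconds) -> integer sample index range, validating bounds
window_indices <- function(x, window) {
  if (length(window) != 2 || !all(is.finite(window)) || window[2] <= window[1])
    stop("window must be a finite [t_start, t_end] with t_end > t_start")
  tt <- series_times(x)
  eps <- 0.5 / x$sample_rate
  if (window[1] < tt[1] - eps || window[2] > tt[length(tt)] + eps)
    stop("window lies outside the series time span")
  idx <- which(tt >= window[1] - eps & tt <= window[2] + eps)
  if (length(idx) < 2) stop("window contains fewer than 2 samples")
  idx
}
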