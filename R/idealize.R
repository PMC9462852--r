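#' Idealization settings
#'
#' Parameters of the trace-to-dwell conversion: post-hoc Gaussian filtering,
#' resampling, half-amplitude threshold crossing, and the level used to flag
#' superimposed (double) openings. Defaults follow common single-channel
#' practice: 3 kHz analysis filter, resampling to 33.3 kHz, half-amplitude
#' discrimination.
#'
#' @param fc_post Post-hoc Gaussian -3 dB cutoff (Hz).
#' @param fs_out Resampled rate (Hz).
#' @param threshold_frac Fraction of the unitary amplitude separating open
#'   from shut, in (0, 1).
#' @param double_open_frac Level, in units of the unitary amplitude, above
#'   which a sample indicates superimposed openings (> 1).
#' @param min_duration_ms Optional minimum dwell duration; dwells shorter
#'   than this are merged into their neighbours. `0` (default) disables it.
#'
#' @return A list of class `idealization_settings`.
#' @export
idealization_settings <- function(fc_post = 3000, fs_out = 1e5 / 3,
                                  threshold_frac = 0.5, double_open_frac = 1.5,
                                  min_duration_ms = 0) {
  if (threshold_frac <= 0 || threshold_frac >= 1) {
    stop_param("`threshold_frac` must lie strictly inside (0, 1).")
  }
  if (double_open_frac <= 1) stop_param("`double_open_frac` must exceed 1.")
  if (min_duration_ms < 0) stop_param("`min_duration_ms` must be >= 0.")
  structure(list(fc_post = fc_post, fs_out = fs_out,
                 threshold_frac = threshold_frac,
                 double_open_frac = double_open_frac,
                 min_duration_ms = min_duration_ms),
            class = "idealization_settings")
}

#' Apply a post-hoc Gaussian low-pass filter to a trace
#'
#' Convolves the trace with the discrete Gaussian kernel (SD `0.1325/fc_post`
#' seconds, truncated at 4 SD, unit DC gain) using symmetric edge padding, so
#' the output has the same length as the input. The trace's effective cutoff
#' is updated to the cascade value `1/sqrt(1/fc^2 + 1/fc_post^2)`.
#'
#' @param trace An `sc_trace`.
#' @param fc_post New -3 dB cutoff (Hz); must be below both the trace's
#'   current cutoff and `fs/2`.
#' @return A filtered `sc_trace`.
#' @examples
#' d <- simulate_dwells(gating_params(n_clusters = 1, seed = 1))
#' tr <- render_trace(d, fs = 1e5, fc = 1e4)
#' gaussian_filter(tr, 3000)
#' @export
gaussian_filter <- function(trace, fc_post) {
  stopifnot(inherits(trace, "sc_trace"))
  if (fc_post >= trace$fs / 2) stop_config("`fc_post` must be below fs/2.")
  if (is.finite(trace$fc) && fc_post >= trace$fc) {
    stop_config("`fc_post` must be below the trace's current cutoff.")
  }
  k <- gaussian_kernel(trace$fs, fc_post)
  fc_eff <- if (is.finite(trace$fc)) {
    1 / sqrt(1 / trace$fc^2 + 1 / fc_post^2)
  } else {
    fc_post
  }
  new_sc_trace(convolve_padded(trace$samples, k), fs = trace$fs, fc = fc_eff,
               baseline = trace$baseline, amp = trace$amp)
}

#' Resample a trace onto a lower uniform sampling grid
#'
#' Linear interpolation of the band-limited trace onto a uniform grid at
#' `fs_out`; total duration is preserved to within one output sample.
#'
#' @param trace An `sc_trace`.
#' @param fs_out Output sampling rate (Hz); must satisfy
#'   `2 * fc < fs_out < fs`.
#' @return A resampled `sc_trace`.
#' @export
resample <- function(trace, fs_out) {
  stopifnot(inherits(trace, "sc_trace"))
  if (fs_out >= trace$fs) stop_config("`fs_out` must be below the current fs.")
  if (is.finite(trace$fc) && fs_out <= 2 * trace$fc) {
    stop_config("`fs_out` must exceed 2 * fc (Nyquist).")
  }
  n <- length(trace$samples)
  t_old <- (seq_len(n) - 0.5) / trace$fs
  m <- max(1L, round(n * fs_out / trace$fs))
  t_new <- (seq_len(m) - 0.5) / fs_out
  y <- approx(t_old, trace$samples, xout = t_new, rule = 2)$y
  new_sc_trace(y, fs = fs_out, fc = trace$fc, baseline = trace$baseline,
               amp = trace$amp)
}

#' Estimate baseline and unitary amplitude from a trace
#'
#' Two-level fit to the all-points amplitude distribution (2-centre k-means
#' on the samples): the more populated centre is taken as the baseline and
#' the signed distance to the other centre as the unitary amplitude. Intended
#' for ingested traces whose metadata lacks calibrated levels.
#'
#' @param trace An `sc_trace`.
#' @return A list with `baseline` and `amp` (pA).
#' @export
estimate_levels <- function(trace) {
  stopifnot(inherits(trace, "sc_trace"))
  km <- stats::kmeans(trace$samples, centers = 2L, nstart = 5L)
  big <- which.max(km$size)
  baseline <- km$centers[big]
  amp <- km$centers[-big] - baseline
  list(baseline = as.numeric(baseline), amp = as.numeric(amp))
}

#' Idealize a trace by threshold crossing
#'
#' Classifies each sample as open when its distance from the baseline is at
#' least `threshold_frac` of the unitary amplitude, merges runs of equal
#' class into dwells, and reports durations in milliseconds. The first and
#' last dwells are flagged as censored: their true durations are truncated
#' by the edges of the recording.
#'
#' @param trace An `sc_trace` carrying `baseline` and `amp` metadata.
#' @param settings An [idealization_settings()] object.
#' @param estimate If `TRUE` and the trace metadata lacks baseline/amplitude,
#'   estimate them with [estimate_levels()]; if `FALSE`, missing levels are a
#'   data error.
#' @param record_id Identifier written to the `record_id` column.
#'
#' @return A dwell tibble with columns `record_id`, `cluster_id` (`NA`;
#'   assigned later by [segment_clusters()]), `state`, `duration_ms`,
#'   `amplitude_pA`, `censored`.
#' @examples
#' d <- simulate_dwells(gating_params(n_clusters = 1, seed = 1))
#' tr <- render_trace(d, fs = 1e5, fc = 1e4)
#' threshold_idealize(tr, idealization_settings(fc_post = 3000))
#' @export
threshold_idealize <- function(trace, settings = idealization_settings(),
                               estimate = FALSE, record_id = "trace") {
  stopifnot(inherits(trace, "sc_trace"),
            inherits(settings, "idealization_settings"))
  baseline <- trace$baseline
  amp <- trace$amp
  if (is.null(baseline) || is.null(amp) || is.na(amp) || amp == 0) {
    if (!estimate) {
      stop_data("Trace lacks baseline/amplitude metadata and estimation is disabled.")
    }
    lv <- estimate_levels(trace)
    baseline <- lv$baseline
    amp <- lv$amp
  }
  open <- abs(trace$samples - baseline) >= settings$threshold_frac * abs(amp)
  r <- rle(open)
  len <- r$lengths
  st <- ifelse(r$values, "open", "shut")
  if (settings$min_duration_ms > 0) {
    min_len <- settings$min_duration_ms * trace$fs / 1000
    # merge sub-threshold dwells into their neighbours, re-running until stable
    repeat {
      drop <- which(len < min_len)
      if (length(drop) == 0L || length(len) == 1L) break
      i <- drop[1L]
      if (i == 1L) {
        len[2L] <- len[2L] + len[1L]
        len <- len[-1L]; st <- st[-1L]
      } else if (i == length(len)) {
        len[i - 1L] <- len[i - 1L] + len[i]
        len <- len[-i]; st <- st[-i]
      } else {
        len[i - 1L] <- len[i - 1L] + len[i] + len[i + 1L]
        len <- len[-c(i, i + 1L)]; st <- st[-c(i, i + 1L)]
      }
    }
  }
  n_dwell <- length(len)
  tibble::tibble(
    record_id = record_id,
    cluster_id = NA_integer_,
    state = st,
    duration_ms = len / trace$fs * 1000,
    amplitude_pA = ifelse(st == "open", amp, 0),
    censored = seq_len(n_dwell) %in% c(1L, n_dwell)
  )
}

#' Flag intervals of superimposed (double) openings
#'
#' Returns the maximal intervals where the current exceeds
#' `double_open_frac` times the unitary amplitude for longer than one filter
#' rise-time (10-90% rise of the Gaussian step response, `0.3321/fc`).
#' Clusters overlapping any flagged interval should be rejected: more than
#' one channel was active.
#'
#' @param trace An `sc_trace`.
#' @param settings An [idealization_settings()] object.
#' @return A tibble with columns `start_ms`, `end_ms` (possibly 0 rows).
#' @export
detect_double_openings <- function(trace, settings = idealization_settings()) {
  stopifnot(inherits(trace, "sc_trace"))
  if (is.null(trace$amp) || is.na(trace$amp) || trace$amp == 0) {
    stop_data("Trace lacks amplitude metadata.")
  }
  thr <- settings$double_open_frac * abs(trace$amp)
  over <- abs(trace$samples - trace$baseline) >= thr
  r <- rle(over)
  fc <- if (is.finite(trace$fc)) trace$fc else trace$fs / 2
  min_samples <- gaussian_rise_time(fc) * trace$fs
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths > min_samples
  tibble::tibble(
    start_ms = (starts[keep] - 1) / trace$fs * 1000,
    end_ms = ends[keep] / trace$fs * 1000
  )
}

#' Match detected open events against ground truth
#'
#' Compares the open dwells of an idealized record against the ground-truth
#' open dwells of the generating record, matching by maximal temporal
#' overlap. Used to quantify idealization fidelity on simulated data.
#'
#' @param truth Dwell tibble with ground-truth labels (e.g. from
#'   [simulate_dwells()]); desensitized dwells count as shut.
#' @param detected Dwell tibble from [threshold_idealize()].
#' @param min_duration_ms Only true open events at least this long are scored.
#'
#' @return A tibble with one row per scored true event: `true_start_ms`,
#'   `true_duration_ms`, `recovered` (logical), `detected_duration_ms`,
#'   `duration_error_ms`.
#' @export
event_recovery <- function(truth, detected, min_duration_ms = 0) {
  intervals <- function(d) {
    end <- cumsum(d$duration_ms)
    start <- end - d$duration_ms
    tibble::tibble(start = start, end = end, state = d$state)
  }
  tr <- dplyr::filter(intervals(truth), .data$state == "open")
  de <- dplyr::filter(intervals(detected), .data$state == "open")
  tr <- dplyr::filter(tr, .data$end - .data$start >= min_duration_ms)
  if (nrow(tr) == 0L) return(tibble::tibble(
    true_start_ms = numeric(0), true_duration_ms = numeric(0),
    recovered = logical(0), detected_duration_ms = numeric(0),
    duration_error_ms = numeric(0)))
  purrr::pmap_dfr(tr, function(start, end, state) {
    ov <- pmin(de$end, end) - pmax(de$start, start)
    j <- which.max(ov)
    hit <- length(j) == 1L && length(ov) > 0L && ov[j] > 0
    det_dur <- if (hit) de$end[j] - de$start[j] else NA_real_
    tibble::tibble(
      true_start_ms = start,
      true_duration_ms = end - start,
      recovered = hit,
      detected_duration_ms = det_dur,
      duration_error_ms = if (hit) abs(det_dur - (end - start)) else NA_real_
    )
  })
}
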