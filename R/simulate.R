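#' Gating parameters for the two-state cluster simulator
#'
#' Bundles the kinetic parameters of the minimal open <-> shut scheme with
#' geometric termination into a long-lived desensitized state. Within a
#' cluster, open dwells are exponential with mean `1/alpha` and shut dwells
#' exponential with mean `1/beta`, so the within-cluster open probability is
#' `beta / (alpha + beta)`. Each shut transition terminates the cluster into
#' desensitization with probability `desens_prob`, giving a geometric number
#' of openings per cluster.
#'
#' @param alpha Channel closing rate (s^-1, > 0); mean open dwell is
#'   `1000/alpha` ms.
#' @param beta Channel opening rate (s^-1, > 0); mean within-cluster shut
#'   dwell is `1000/beta` ms.
#' @param desens_prob Probability that a closure terminates the cluster into
#'   desensitization, in (0, 1].
#' @param mean_desens Mean desensitized dwell duration (seconds, > 0).
#' @param n_clusters Number of clusters to generate (>= 1).
#' @param seed Integer RNG seed, or `NULL` to use the session RNG.
#'
#' @return A validated list of class `gating_params`.
#' @examples
#' gating_params(alpha = 200, beta = 800, desens_prob = 0.02)
#' @export
gating_params <- function(alpha = 200, beta = 800, desens_prob = 0.02,
                          mean_desens = 2, n_clusters = 10, seed = NULL) {
  check_rate <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
      stop_param(sprintf("`%s` must be a single strictly positive number.", name))
    }
  }
  check_rate(alpha, "alpha")
  check_rate(beta, "beta")
  check_rate(mean_desens, "mean_desens")
  if (!is.numeric(desens_prob) || length(desens_prob) != 1L || is.na(desens_prob) ||
      desens_prob <= 0 || desens_prob > 1) {
    stop_param("`desens_prob` must be a single probability in (0, 1].")
  }
  if (!is.numeric(n_clusters) || length(n_clusters) != 1L || is.na(n_clusters) ||
      n_clusters < 1 || n_clusters != round(n_clusters)) {
    stop_param("`n_clusters` must be a single integer >= 1.")
  }
  p <- beta / (alpha + beta)
  if (!(p > 0 && p < 1)) {
    stop_param("Implied open probability beta/(alpha+beta) must lie in (0, 1).")
  }
  structure(
    list(alpha = alpha, beta = beta, desens_prob = desens_prob,
         mean_desens = mean_desens, n_clusters = as.integer(n_clusters),
         seed = seed),
    class = "gating_params"
  )
}

#' @export
print.gating_params <- function(x, ...) {
  cat("<gating_params>\n")
  cat(sprintf("  alpha (close): %g /s   beta (open): %g /s\n", x$alpha, x$beta))
  cat(sprintf("  within-cluster Popen: %.4f\n", x$beta / (x$alpha + x$beta)))
  cat(sprintf("  desens_prob: %g   mean_desens: %g s   n_clusters: %d\n",
              x$desens_prob, x$mean_desens, x$n_clusters))
  invisible(x)
}

#' Simulate an idealized dwell sequence with cluster structure
#'
#' Draws alternating open/shut dwell sequences grouped into exactly
#' `n_clusters` clusters, each terminated by a long desensitized shut period.
#' Clusters begin and end with an open dwell; dwell durations are exponential
#' with means `1/alpha` (open), `1/beta` (within-cluster shut) and
#' `mean_desens` (desensitized). The output carries ground-truth state labels
#' so downstream idealization and cluster segmentation can be validated
#' against the generating process.
#'
#' @param params A [gating_params()] object.
#' @param amp Unitary open-channel current amplitude (pA) recorded in the
#'   dwell table; 5 pA by default (arbitrary: cell-attached unitary amplitude
#'   at +100 mV is setup-dependent).
#' @param record_id Identifier stored in the `record_id` column.
#'
#' @return A tibble with one row per dwell: `record_id`, `cluster_id`,
#'   `state` (`"open"`, `"shut"` or `"desensitized"`), `duration_ms`,
#'   `amplitude_pA`, `truth_state`.
#' @examples
#' d <- simulate_dwells(gating_params(n_clusters = 3, seed = 1))
#' dplyr::count(d, state)
#' @export
simulate_dwells <- function(params, amp = 5, record_id = "sim") {
  if (!inherits(params, "gating_params")) params <- do.call(gating_params, params)
  with_seed(params$seed, {
    pieces <- lapply(seq_len(params$n_clusters), function(k) {
      n_open <- rgeom(1L, params$desens_prob) + 1L
      opens <- rexp(n_open, rate = params$alpha) * 1000
      shuts <- if (n_open > 1L) rexp(n_open - 1L, rate = params$beta) * 1000 else numeric(0)
      desens <- rexp(1L, rate = 1 / params$mean_desens) * 1000
      state <- c(rbind(rep("open", n_open),
                       c(rep("shut", n_open - 1L), "desensitized")))
      duration <- c(rbind(opens, c(shuts, desens)))
      tibble::tibble(cluster_id = k, state = state, duration_ms = duration)
    })
    out <- dplyr::bind_rows(pieces)
    tibble::tibble(
      record_id = record_id,
      cluster_id = out$cluster_id,
      state = out$state,
      duration_ms = out$duration_ms,
      amplitude_pA = ifelse(out$state == "open", amp, 0),
      truth_state = out$state
    )
  })
}

# -3 dB Gaussian cutoff -> kernel SD in seconds (Colquhoun-Sigworth convention)
gaussian_sigma_t <- function(fc) 0.1325 / fc

# Gaussian rise time (10-90%) in seconds for a -3 dB cutoff fc
gaussian_rise_time <- function(fc) 0.3321 / fc

# Discrete Gaussian kernel for cutoff fc at sampling rate fs, truncated at
# +/- 4 sigma and normalized to unit sum (unit DC gain).
gaussian_kernel <- function(fs, fc) {
  sigma_n <- gaussian_sigma_t(fc) * fs
  h <- max(1L, ceiling(4 * sigma_n))
  k <- dnorm(seq(-h, h), sd = sigma_n)
  k / sum(k)
}

# Convolve with symmetric (reflected) edge padding; output length == input.
convolve_padded <- function(x, kernel) {
  h <- (length(kernel) - 1L) %/% 2L
  n <- length(x)
  if (h == 0L) return(x * kernel)
  pad_l <- x[pmin(n, seq(h + 1L, 2L))]
  pad_r <- x[pmax(1L, seq(n - 1L, n - h))]
  xp <- c(pad_l, x, pad_r)
  y <- stats::filter(xp, kernel, method = "convolution", sides = 2L)
  as.numeric(y[(h + 1L):(h + n)])
}

#' Render an idealized dwell sequence as a noisy sampled current trace
#'
#' Emulates the cell-attached recording chain: the dwell sequence becomes a
#' piecewise-constant two-level current, white Gaussian baseline noise of SD
#' `noise_sd` is added, and the sum is low-pass filtered with a Gaussian
#' kernel of -3 dB cutoff `fc` (kernel SD `0.1325/fc`, truncated at 4 SD).
#' Adding the noise before the filter mirrors a real recording, where the
#' anti-alias filter acts on signal and instrumentation noise alike.
#'
#' @param record Dwell tibble as produced by [simulate_dwells()] or
#'   [threshold_idealize()].
#' @param fs Sampling rate (Hz); must exceed `2 * fc`.
#' @param amp Open-channel current step (pA, non-zero); used for dwells whose
#'   `amplitude_pA` is missing.
#' @param noise_sd SD of the additive white noise (pA) before filtering.
#' @param fc Effective -3 dB low-pass cutoff (Hz).
#' @param seed Integer RNG seed for the noise, or `NULL`.
#' @param baseline Shut-level current (pA).
#'
#' @return An `sc_trace` object: list with `samples` (pA), `fs`, `fc`,
#'   `baseline`, `amp`.
#' @examples
#' d <- simulate_dwells(gating_params(n_clusters = 2, seed = 1))
#' tr <- render_trace(d, fs = 1e5, amp = 5, noise_sd = 0.5, fc = 1e4, seed = 2)
#' tr
#' @export
render_trace <- function(record, fs = 1e5, amp = 5, noise_sd = 0, fc = 1e4,
                         seed = NULL, baseline = 0) {
  if (!is.data.frame(record) || nrow(record) == 0L) {
    stop_data("`record` must be a non-empty dwell table.")
  }
  if (!is.numeric(amp) || amp == 0) stop_param("`amp` must be non-zero.")
  if (fs <= 2 * fc) stop_config("`fs` must exceed 2 * fc (Nyquist).")
  dur_ms <- record$duration_ms
  if (any(!is.finite(dur_ms)) || any(dur_ms <= 0)) {
    stop_data("All dwell durations must be strictly positive.")
  }
  level <- ifelse(record$state == "open",
                  baseline + dplyr::coalesce(record$amplitude_pA, amp),
                  baseline)
  edges_s <- cumsum(dur_ms) / 1000
  total_s <- edges_s[length(edges_s)]
  n <- max(1L, round(total_s * fs))
  t_mid <- (seq_len(n) - 0.5) / fs
  idx <- findInterval(t_mid, edges_s, left.open = TRUE) + 1L
  idx[idx > length(level)] <- length(level)
  x <- level[idx]
  samples <- with_seed(seed, {
    if (noise_sd > 0) x <- x + rnorm(n, sd = noise_sd)
    convolve_padded(x, gaussian_kernel(fs, fc))
  })
  new_sc_trace(samples, fs = fs, fc = fc, baseline = baseline, amp = amp)
}

new_sc_trace <- function(samples, fs, fc, baseline, amp) {
  structure(list(samples = as.numeric(samples), fs = fs, fc = fc,
                 baseline = baseline, amp = amp),
            class = "sc_trace")
}

#' @export
print.sc_trace <- function(x, ...) {
  cat("<sc_trace>\n")
  cat(sprintf("  %d samples at %g kHz (%.1f ms), fc = %g kHz\n",
              length(x$samples), x$fs / 1000,
              length(x$samples) / x$fs * 1000, x$fc / 1000))
  cat(sprintf("  baseline %g pA, unitary amplitude %g pA\n", x$baseline, x$amp))
  invisible(x)
}

#' Plot a sampled single-channel trace
#'
#' @param object An `sc_trace`.
#' @param max_points Traces longer than this are thinned for display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sc_trace <- function(object, max_points = 2e5, ...) {
  n <- length(object$samples)
  keep <- if (n > max_points) round(seq(1L, n, length.out = max_points)) else seq_len(n)
  df <- tibble::tibble(time_ms = (keep - 0.5) / object$fs * 1000,
                       current_pA = object$samples[keep])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$current_pA)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "Time (ms)", y = "Current (pA)") +
    ggplot2::theme_minimal()
}

#' Generate per-agonist cluster Popen datasets at target open probabilities
#'
#' For each named target open probability, the opening rate is chosen so that
#' the within-cluster open probability `beta/(alpha+beta)` equals the target
#' (holding `alpha` from the template fixed), a dwell sequence is simulated,
#' and per-cluster Popen values are computed from the ground-truth labels.
#' This emulates the structure of a per-agonist cluster Popen table: one row
#' per cluster of activity.
#'
#' @param targets Named numeric vector of target open probabilities, each in
#'   (0, 1); names are agonist labels.
#' @param kinetics A [gating_params()] template supplying `alpha`,
#'   `desens_prob`, `mean_desens` and `n_clusters`.
#' @param seed Integer seed; per-agonist streams are derived by fixed offsets.
#'
#' @return A tibble with columns `agonist`, `patch_id`, `cluster_id`,
#'   `duration_ms`, `open_time_ms`, `popen`.
#' @examples
#' sets <- make_agonist_dataset(
#'   c(glycine = 0.96, taurine = 0.12),
#'   kinetics = gating_params(alpha = 200, n_clusters = 20), seed = 1
#' )
#' popen_summary(sets)
#' @export
make_agonist_dataset <- function(targets, kinetics = gating_params(), seed = 1) {
  if (is.null(names(targets)) || any(!nzchar(names(targets)))) {
    stop_param("`targets` must be a named numeric vector.")
  }
  if (any(targets <= 0 | targets >= 1)) {
    stop_param("Every target Popen must lie strictly inside (0, 1).")
  }
  if (!inherits(kinetics, "gating_params")) kinetics <- do.call(gating_params, kinetics)
  purrr::imap_dfr(as.list(targets), function(p, agonist) {
    i <- match(agonist, names(targets))
    beta <- kinetics$alpha * p / (1 - p)
    par <- gating_params(alpha = kinetics$alpha, beta = beta,
                         desens_prob = kinetics$desens_prob,
                         mean_desens = kinetics$mean_desens,
                         n_clusters = kinetics$n_clusters,
                         seed = seed + 1000L * i)
    dw <- simulate_dwells(par, record_id = agonist)
    dw |>
      dplyr::filter(.data$state != "desensitized") |>
      dplyr::group_by(.data$cluster_id) |>
      dplyr::summarise(
        open_time_ms = sum(.data$duration_ms[.data$state == "open"]),
        duration_ms = sum(.data$duration_ms),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        agonist = agonist,
        patch_id = "sim",
        popen = .data$open_time_ms / .data$duration_ms
      ) |>
      dplyr::select("agonist", "patch_id", "cluster_id",
                    "duration_ms", "open_time_ms", "popen")
  })
}
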