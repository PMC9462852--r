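#' Per-cluster open probability
#'
#' The ratio of total open time to cluster duration. Vectorized.
#'
#' @param open_time_ms Total open time within each cluster (ms).
#' @param duration_ms Cluster duration (ms, > 0).
#' @return Numeric vector of open probabilities in `[0, 1]`.
#' @examples
#' cluster_popen(80, 100)
#' @export
cluster_popen <- function(open_time_ms, duration_ms) {
  if (any(duration_ms <= 0)) stop_data("Cluster duration must be > 0.")
  if (any(open_time_ms < 0) || any(open_time_ms > duration_ms + 1e-9)) {
    stop_data("Open time must lie in [0, duration].")
  }
  open_time_ms / duration_ms
}

#' Segment an idealized record into clusters of activity
#'
#' Splits a dwell sequence at every non-conducting dwell of duration at least
#' `tcrit` (desensitized gaps); each resulting cluster is trimmed to begin
#' and end with an open dwell, so inter-cluster shut time belongs to no
#' cluster. Records with no openings yield an empty cluster table.
#'
#' Clusters touching the start or end of the record without a bounding long
#' shut period are flagged `censored_edge` (their true extent is unknown);
#' clusters overlapping a supplied double-opening interval are flagged
#' `has_double_opening`.
#'
#' @param dwells Dwell tibble (one record; columns `state`, `duration_ms`,
#'   optionally `record_id`). Desensitized dwells count as non-conducting.
#' @param tcrit Critical shut time (ms, > 0) separating within-cluster
#'   closures from desensitized gaps. The generating time scales should
#'   bracket it by a wide margin; a warning is issued when the shut-time
#'   distribution does not separate cleanly around `tcrit`.
#' @param double_openings Optional tibble of flagged intervals
#'   (`start_ms`, `end_ms`) from [detect_double_openings()].
#'
#' @return A tibble with one row per cluster: `record_id`, `cluster_id`,
#'   `start_ms`, `end_ms`, `duration_ms`, `open_time_ms`, `n_openings`,
#'   `popen`, `censored_edge`, `has_double_opening`, and a `dwells`
#'   list-column holding each cluster's dwell sub-table.
#' @examples
#' d <- simulate_dwells(gating_params(n_clusters = 5, seed = 1))
#' segment_clusters(d, tcrit = 100)
#' @export
segment_clusters <- function(dwells, tcrit = 100, double_openings = NULL) {
  if (!is.data.frame(dwells) || nrow(dwells) == 0L) {
    stop_data("`dwells` must be a non-empty dwell table.")
  }
  if (!is.numeric(tcrit) || tcrit <= 0) stop_param("`tcrit` must be > 0.")
  record_id <- if ("record_id" %in% names(dwells)) dwells$record_id[1L] else "record"
  state <- dwells$state
  dur <- dwells$duration_ms
  conducting <- state == "open"
  if (!any(conducting)) {
    return(empty_cluster_table())
  }
  end_ms <- cumsum(dur)
  start_ms <- end_ms - dur
  separator <- !conducting & dur >= tcrit
  shut_durs <- dur[!conducting]
  if (length(shut_durs) > 3L && !any(separator)) {
    warn(paste0("No shut dwell reaches tcrit = ", tcrit,
                " ms; the whole record forms one cluster."))
  } else if (any(separator) && any(!conducting & !separator)) {
    # diagnostic: the two shut populations should bracket tcrit by ~3x
    below <- max(shut_durs[shut_durs < tcrit])
    above <- min(shut_durs[shut_durs >= tcrit])
    if (above / below < 3) {
      warn(sprintf(paste0(
        "Shut-time distribution is not clearly bimodal around tcrit = %g ms ",
        "(longest within-cluster shut %.3g ms, shortest gap %.3g ms)."),
        tcrit, below, above))
    }
  }
  grp <- cumsum(c(0L, head(separator, -1L)))  # group index per dwell
  n <- nrow(dwells)
  pieces <- split(seq_len(n), grp)
  first_sep <- which(separator)
  clusters <- purrr::imap(pieces, function(rows, key) {
    rows <- rows[!separator[rows]]
    op <- rows[conducting[rows]]
    if (length(op) == 0L) return(NULL)
    rows <- rows[rows >= min(op) & rows <= max(op)]  # trim to open...open
    sub <- dwells[rows, , drop = FALSE]
    open_time <- sum(sub$duration_ms[sub$state == "open"])
    total <- sum(sub$duration_ms)
    # edge-censored: cluster runs to a record edge with no bounding gap
    cens_start <- min(rows) == 1L
    cens_end <- max(rows) == n
    if ("censored" %in% names(dwells)) {
      cens_start <- cens_start && isTRUE(dwells$censored[1L])
      cens_end <- cens_end && isTRUE(dwells$censored[n])
    }
    tibble::tibble(
      start_ms = start_ms[min(rows)],
      end_ms = end_ms[max(rows)],
      duration_ms = total,
      open_time_ms = open_time,
      n_openings = sum(sub$state == "open"),
      popen = open_time / total,
      censored_edge = cens_start || cens_end,
      dwells = list(sub)
    )
  })
  out <- dplyr::bind_rows(clusters)
  if (nrow(out) == 0L) return(empty_cluster_table())
  out <- dplyr::mutate(out, record_id = record_id,
                       cluster_id = dplyr::row_number(), .before = 1)
  dbl <- rep(FALSE, nrow(out))
  if (!is.null(double_openings) && nrow(double_openings) > 0L) {
    dbl <- purrr::map2_lgl(out$start_ms, out$end_ms, function(s, e) {
      any(pmin(double_openings$end_ms, e) - pmax(double_openings$start_ms, s) > 0)
    })
  }
  dplyr::mutate(out, has_double_opening = dbl, .before = "dwells")
}

empty_cluster_table <- function() {
  tibble::tibble(
    record_id = character(0), cluster_id = integer(0), start_ms = numeric(0),
    end_ms = numeric(0), duration_ms = numeric(0), open_time_ms = numeric(0),
    n_openings = integer(0), popen = numeric(0), censored_edge = logical(0),
    has_double_opening = logical(0), dwells = list()
  )
}

#' Apply cluster acceptance filters
#'
#' Keeps clusters at least `min_duration` long, optionally excluding
#' those with double openings and those censored at a recording edge.
#' Rejected clusters are retained with `accepted = FALSE` and a
#' `reject_reason`, so the audit trail survives filtering.
#'
#' @param clusters Cluster tibble from [segment_clusters()].
#' @param min_duration Minimum cluster duration (ms, >= 0); 100 ms default.
#' @param exclude_double Drop clusters flagged `has_double_opening`.
#' @param exclude_censored Drop clusters flagged `censored_edge`.
#'
#' @return The cluster tibble with added `accepted` and `reject_reason`
#'   columns. Use `dplyr::filter(accepted)` for the accepted subset.
#' @export
filter_clusters <- function(clusters, min_duration = 100,
                            exclude_double = TRUE, exclude_censored = TRUE) {
  if (min_duration < 0) stop_param("`min_duration` must be >= 0.")
  if (nrow(clusters) == 0L) {
    return(dplyr::mutate(clusters, accepted = logical(0),
                         reject_reason = character(0)))
  }
  reason <- dplyr::case_when(
    clusters$duration_ms < min_duration ~ "too_short",
    exclude_double & clusters$has_double_opening ~ "has_double_opening",
    exclude_censored & clusters$censored_edge ~ "censored_edge",
    .default = NA_character_
  )
  dplyr::mutate(clusters, accepted = is.na(reason), reject_reason = reason)
}

#' Summarise per-cluster open probabilities
#'
#' Mean, sample SD (n - 1 denominator), median (mean of the two central
#' values for even n) and counts, per agonist when an `agonist` column is
#' present. This is the summary layout of a per-agonist maximum-Popen table:
#' one Popen value per cluster, n patches in parentheses.
#'
#' @param data Tibble with a `popen` column, optionally `agonist` and
#'   `patch_id` columns.
#' @return A tibble with `agonist` (if present), `n_patches` (if patch ids
#'   are present), `n_clusters`, `mean_popen`, `sd_popen`, `median_popen`.
#' @examples
#' popen_summary(tibble::tibble(popen = c(0.2, 0.4, 0.6, 0.8)))
#' @export
popen_summary <- function(data) {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    stop_data("`data` must contain at least one cluster.")
  }
  if (!"popen" %in% names(data)) stop_data("`data` must have a `popen` column.")
  if (any(data$popen < 0 | data$popen > 1)) {
    stop_data("Every popen must lie in [0, 1].")
  }
  grouped <- if ("agonist" %in% names(data)) {
    dplyr::group_by(data, .data$agonist)
  } else {
    data
  }
  out <- dplyr::summarise(
    grouped,
    n_patches = if ("patch_id" %in% names(data)) {
      dplyr::n_distinct(.data$patch_id)
    } else {
      NA_integer_
    },
    n_clusters = dplyr::n(),
    mean_popen = mean(.data$popen),
    sd_popen = sd(.data$popen),
    median_popen = median(.data$popen),
    .groups = "drop"
  )
  out
}

#' Boxplot of per-cluster open probabilities by agonist
#'
#' One point per cluster; boxes show the interquartile range and median,
#' whiskers the 5th and 95th percentiles.
#'
#' @param data Tibble with `agonist` and `popen` columns.
#' @return A ggplot object.
#' @export
plot_popen_boxplot <- function(data) {
  stopifnot(all(c("agonist", "popen") %in% names(data)))
  ggplot2::ggplot(data, ggplot2::aes(x = .data$agonist, y = .data$popen)) +
    ggplot2::stat_summary(
      fun.data = function(y) {
        q <- stats::quantile(y, c(0.05, 0.25, 0.5, 0.75, 0.95))
        data.frame(ymin = q[1], lower = q[2], middle = q[3],
                   upper = q[4], ymax = q[5])
      },
      geom = "boxplot"
    ) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = expression(P[open])) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
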