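dwell_cols <- c("record_id", "cluster_id", "state", "duration_ms", "amplitude_pA")

#' Write / read a dwell table (CSV)
#'
#' The dwell-table dialect is a plain CSV with header columns `record_id`,
#' `cluster_id`, `state`, `duration_ms`, `amplitude_pA` and optionally
#' `truth_state` and `censored`. Readers validate rather than coerce:
#' missing columns, non-positive durations and unknown states are errors
#' naming the offending column or row.
#'
#' @param dwells Dwell tibble ([simulate_dwells()] / [threshold_idealize()]).
#' @param path File path.
#' @return `write_dwell_table()` returns `path` invisibly;
#'   `read_dwell_table()` returns the dwell tibble (all records; group by
#'   `record_id` for multi-record files).
#' @export
write_dwell_table <- function(dwells, path) {
  if (!all(dwell_cols %in% names(dwells))) {
    stop_data(paste0("Dwell table must have columns: ",
                     paste(dwell_cols, collapse = ", "), "."))
  }
  readr::write_csv(dwells, path)
  invisible(path)
}

#' @rdname write_dwell_table
#' @export
read_dwell_table <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("File not found: %s", path))
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(dwell_cols, names(out))
  if (length(missing) > 0L) {
    stop_data(paste0("Missing dwell-table column(s): ",
                     paste(missing, collapse = ", "), "."))
  }
  if (nrow(out) == 0L) {
    warn("Dwell table is empty (valid header, no rows).")
    return(out)
  }
  bad <- which(!is.finite(out$duration_ms) | out$duration_ms <= 0)
  if (length(bad) > 0L) {
    stop_data(sprintf("Non-positive dwell duration at row %d.", bad[1L]))
  }
  bad_state <- which(!out$state %in% c("open", "shut", "desensitized"))
  if (length(bad_state) > 0L) {
    stop_data(sprintf("Unknown state '%s' at row %d.",
                      out$state[bad_state[1L]], bad_state[1L]))
  }
  out
}

#' Write / read a sampled trace (CSV + JSON sidecar)
#'
#' The trace itself is a single-column CSV (`current_pA`); the acquisition
#' metadata (`fs`, `fc`, `baseline`, `amp`) travels in a JSON sidecar at
#' `<path>.json`.
#'
#' @param trace An `sc_trace`.
#' @param path CSV file path; the sidecar is written next to it.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` an
#'   `sc_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sc_trace"))
  readr::write_csv(tibble::tibble(current_pA = trace$samples), path)
  jsonlite::write_json(
    list(fs = trace$fs, fc = trace$fc, baseline = trace$baseline,
         amp = trace$amp),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop_data(sprintf("File not found: %s", path))
  if (!file.exists(sidecar)) stop_data(sprintf("Missing sidecar: %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  samples <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"current_pA" %in% names(samples)) {
    stop_data("Trace CSV must have a `current_pA` column.")
  }
  new_sc_trace(samples$current_pA, fs = meta$fs, fc = meta$fc %||% Inf,
               baseline = meta$baseline %||% 0, amp = meta$amp)
}

#' Read a per-cluster open-probability table
#'
#' Expects the layout of a deposited per-cluster Popen spreadsheet exported
#' to CSV: one row per cluster with columns `agonist`, `patch_id`, `popen`
#' (extra columns pass through). Duplicate rows are preserved - clusters are
#' observations. Out-of-range `popen` values are row-level errors.
#'
#' @param path CSV file path.
#' @return A tibble with one row per cluster; summarise with
#'   [popen_summary()].
#' @export
read_popen_table <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("File not found: %s", path))
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("agonist", "patch_id", "popen"), names(out))
  if (length(missing) > 0L) {
    stop_data(paste0("Missing popen-table column(s): ",
                     paste(missing, collapse = ", "), "."))
  }
  bad <- which(!is.finite(out$popen) | out$popen < 0 | out$popen > 1)
  if (length(bad) > 0L) {
    stop_data(sprintf("popen outside [0, 1] at row %d (value %s).",
                      bad[1L], format(out$popen[bad[1L]])))
  }
  out
}

#' @rdname read_popen_table
#' @param data Tibble with `agonist`, `patch_id`, `popen` columns.
#' @export
write_popen_table <- function(data, path) {
  if (!all(c("agonist", "patch_id", "popen") %in% names(data))) {
    stop_data("Popen table must have `agonist`, `patch_id`, `popen` columns.")
  }
  readr::write_csv(data, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every stage parameter of the simulate -> idealize -> cluster ->
#' cycle pipeline in one validated list. Each stochastic stage derives its
#' seed from the global `seed` by a fixed offset, so one integer makes the
#' whole run reproducible.
#'
#' @param targets Named Popen targets for the four cycle corners (names must
#'   cover the four `roles`).
#' @param kinetics [gating_params()] template for the simulator.
#' @param roles Corner-role mapping passed to [cycle_spec()].
#' @param render If `TRUE`, traces are rendered and re-idealized (slow but
#'   exercises the full chain); if `FALSE` the simulator's ground-truth
#'   dwells feed the cluster stage directly.
#' @param fs,fc,noise_sd Trace rendering parameters (Hz, Hz, pA).
#' @param settings [idealization_settings()] for the idealization stage.
#' @param tcrit,min_duration Cluster segmentation/acceptance parameters (ms).
#' @param n_boot Bootstrap replicates for the cycle stage.
#' @param estimator Per-corner estimator, `"mean"` or `"median"`.
#' @param seed Global integer seed (required).
#' @param out_dir Output directory for stage files, or `NULL` to skip
#'   writing.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(targets = c(glycine = 0.96, `beta-alanine` = 0.54,
                                        AMS = 0.85, taurine = 0.12),
                            kinetics = gating_params(alpha = 200,
                                                     desens_prob = 0.02,
                                                     mean_desens = 2,
                                                     n_clusters = 50),
                            roles = c(reference = "glycine",
                                      lengthened = "beta-alanine",
                                      swapped = "AMS", both = "taurine"),
                            render = FALSE, fs = 1e5, fc = 1e4,
                            noise_sd = 0.5,
                            settings = idealization_settings(),
                            tcrit = 100, min_duration = 100,
                            n_boot = 10000,
                            estimator = "mean", seed = NULL,
                            out_dir = NULL) {
  if (is.null(seed)) stop_config("A global `seed` is required for a pipeline run.")
  if (!all(unname(roles) %in% names(targets))) {
    stop_config("Every corner role must have a matching entry in `targets`.")
  }
  if (!inherits(kinetics, "gating_params")) kinetics <- do.call(gating_params, kinetics)
  structure(
    list(targets = targets, kinetics = kinetics, roles = roles,
         render = render, fs = fs, fc = fc, noise_sd = noise_sd,
         settings = settings, tcrit = tcrit, min_duration = min_duration,
         n_boot = n_boot, estimator = estimator, seed = as.integer(seed),
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Simulates one record per agonist, optionally renders and re-idealizes the
#' traces, segments and filters clusters, assembles the per-agonist Popen
#' table, and runs the bootstrapped thermodynamic-cycle analysis.
#' Alternatively, a user-supplied per-cluster Popen table
#' (`popen_table` path) replaces the simulation stages. When `out_dir` is
#' set, each stage writes its output (dwell CSVs, cluster CSV, popen CSV,
#' summary and cycle JSON) plus a manifest recording the package version,
#' all parameters, seeds and output file hashes.
#'
#' @param config A [pipeline_config()].
#' @param popen_table Optional path to a per-cluster Popen CSV
#'   ([read_popen_table()] layout); skips simulation when given.
#' @return A list bundle: `popen` (per-cluster tibble), `summary`
#'   (per-agonist [popen_summary()]), `clusters` (full audit table or
#'   `NULL`), `cycle` (bootstrapped `thermo_cycle`), `manifest`.
#' @examples
#' cfg <- pipeline_config(kinetics = gating_params(alpha = 200, n_clusters = 15),
#'                        n_boot = 200, seed = 7)
#' res <- run_pipeline(cfg)
#' glance(res$cycle)
#' @export
run_pipeline <- function(config, popen_table = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  clusters_all <- NULL
  if (!is.null(popen_table)) {
    popen <- read_popen_table(popen_table)
  } else if (!config$render) {
    popen <- make_agonist_dataset(config$targets, config$kinetics,
                                  seed = config$seed)
  } else {
    # full chain: simulate -> render -> filter/resample -> idealize -> clusters
    agonists <- names(config$targets)
    pieces <- lapply(seq_along(agonists), function(i) {
      ag <- agonists[[i]]
      p <- config$targets[[ag]]
      par <- gating_params(alpha = config$kinetics$alpha,
                           beta = config$kinetics$alpha * p / (1 - p),
                           desens_prob = config$kinetics$desens_prob,
                           mean_desens = config$kinetics$mean_desens,
                           n_clusters = config$kinetics$n_clusters,
                           seed = config$seed + 1000L * i)
      truth <- simulate_dwells(par, record_id = ag)
      tr <- render_trace(truth, fs = config$fs, noise_sd = config$noise_sd,
                         fc = config$fc, seed = config$seed + 1000L * i + 1L)
      tr <- gaussian_filter(tr, config$settings$fc_post)
      tr <- resample(tr, config$settings$fs_out)
      ideal <- threshold_idealize(tr, config$settings, record_id = ag)
      dbl <- detect_double_openings(tr, config$settings)
      cl <- segment_clusters(ideal, tcrit = config$tcrit,
                             double_openings = dbl)
      filter_clusters(cl, min_duration = config$min_duration) |>
        dplyr::mutate(agonist = ag, patch_id = "sim", .before = 1)
    })
    clusters_all <- dplyr::bind_rows(pieces)
    popen <- clusters_all |>
      dplyr::filter(.data$accepted) |>
      dplyr::select("agonist", "patch_id", "cluster_id",
                    "duration_ms", "open_time_ms", "popen")
  }
  if (!"patch_id" %in% names(popen)) popen$patch_id <- "sim"
  summary <- popen_summary(popen)
  spec <- cycle_spec(popen, roles = config$roles)
  cycle <- bootstrap_cycle(spec, n_boot = config$n_boot,
                           seed = config$seed + 17L,
                           estimator = config$estimator)
  manifest <- list(
    package = "popencycle",
    version = as.character(utils::packageVersion("popencycle")),
    seed = config$seed,
    parameters = list(
      targets = as.list(config$targets),
      alpha = config$kinetics$alpha,
      desens_prob = config$kinetics$desens_prob,
      mean_desens = config$kinetics$mean_desens,
      n_clusters = config$kinetics$n_clusters,
      render = config$render, fs = config$fs, fc = config$fc,
      noise_sd = config$noise_sd, tcrit = config$tcrit,
      min_duration = config$min_duration, n_boot = config$n_boot,
      estimator = config$estimator
    )
  )
  if (!is.null(out_dir)) {
    write_popen_table(popen, file.path(out_dir, "popen_clusters.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "popen_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    cyc <- c(
      list(eeff_point = as.list(cycle$eeff_point)),
      cycle[c("dG1", "dG1p", "dG2", "dG2p", "ddG_int", "closure_residual",
              "n_boot", "seed", "estimator")],
      list(sd_dG = as.list(cycle$sd_dG), sd_ddG = cycle$sd_ddG,
           n_excluded = as.list(cycle$n_excluded))
    )
    jsonlite::write_json(cyc, file.path(out_dir, "cycle_result.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(clusters_all)) {
      readr::write_csv(dplyr::select(clusters_all, -"dwells"),
                       file.path(out_dir, "clusters_audit.csv"))
    }
    files <- list.files(out_dir, full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    manifest$outputs <- lapply(
      setNames(files, basename(files)),
      function(f) unname(tools::md5sum(f))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(popen = popen, summary = summary, clusters = clusters_all,
       cycle = cycle, manifest = manifest)
}
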