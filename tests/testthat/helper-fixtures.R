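# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# A dwell table with known alternating structure (durations in ms).
manual_dwells <- function(open_ms, shut_ms, record_id = "manual", amp = 5) {
  stopifnot(length(open_ms) == length(shut_ms) + 1L)
  n <- length(open_ms) + length(shut_ms)
  state <- rep(c("open", "shut"), length.out = n)
  duration <- numeric(n)
  duration[state == "open"] <- open_ms
  duration[state == "shut"] <- shut_ms
  tibble::tibble(
    record_id = record_id, cluster_id = NA_integer_, state = state,
    duration_ms = duration, amplitude_pA = ifelse(state == "open", amp, 0),
    truth_state = state
  )
}

# Per-agonist cluster Popen tables emulating the published study conditions:
# four agonists at saturating concentration, per-cluster Popen medians
# calibrated to the printed Table values, published cluster counts, and the
# published >= 100 ms cluster-duration acceptance rule. Synthetic stand-in
# for the deposited source-data spreadsheet (which is not redistributed).
synthetic_source_data <- function(seed = 1,
                                  targets = c(glycine = 0.976,
                                              `beta-alanine` = 0.566,
                                              AMS = 0.931,
                                              taurine = 0.060),
                                  counts = c(glycine = 92,
                                             `beta-alanine` = 52,
                                             AMS = 146,
                                             taurine = 37),
                                  min_duration = 100) {
  sets <- purrr::imap_dfr(as.list(targets), function(p, ag) {
    k <- gating_params(alpha = 200, desens_prob = 0.02, mean_desens = 2,
                       n_clusters = counts[[ag]])
    make_agonist_dataset(stats::setNames(p, ag), kinetics = k,
                         seed = seed * 100 + match(ag, names(targets)))
  })
  dplyr::filter(sets, duration_ms >= min_duration)
}
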