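#' Thermodynamic constants for gating free energies
#'
#' @param R Gas constant in cal K^-1 mol^-1 (1.987 by default).
#' @param temperature Absolute temperature in kelvin (295 K by default,
#'   i.e. room temperature).
#' @return A list of class `efficacy_constants` with `R`, `temperature`,
#'   `RT_cal` (cal/mol) and `RT_kcal` (kcal/mol).
#' @examples
#' efficacy_constants()$RT_kcal
#' @export
efficacy_constants <- function(R = 1.987, temperature = 295) {
  if (R <= 0 || temperature <= 0) stop_param("R and temperature must be > 0.")
  rt <- R * temperature
  structure(list(R = R, temperature = temperature,
                 RT_cal = rt, RT_kcal = rt / 1000),
            class = "efficacy_constants")
}

#' Convert open probability to the gating equilibrium constant
#'
#' The maximum open probability within a cluster is linked to the overall
#' gating equilibrium constant E by `Popen = E / (E + 1)`; inverting gives
#' `E = p / (1 - p)`. E lumps all activation steps after full binding
#' (pre-open conformational changes and channel opening) into one constant.
#' `p = 1` maps to `Inf`; callers working with per-cluster values should
#' apply a saturated-cluster policy first (see [cycle_spec()]).
#'
#' @param p Open probability in `[0, 1]`.
#' @return Gating constant `p / (1 - p)`, strictly increasing in `p`.
#' @examples
#' popen_to_eeff(0.976)  # ~40.7
#' popen_to_eeff(0.5)    # 1
#' @export
popen_to_eeff <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_data("`p` must lie in [0, 1].")
  }
  p / (1 - p)
}

#' Convert a gating equilibrium constant to open probability
#'
#' Inverse of [popen_to_eeff()]: `p = E / (E + 1)`.
#'
#' @param e Gating constant (>= 0).
#' @return Open probability in `[0, 1)`.
#' @export
eeff_to_popen <- function(e) {
  if (any(!is.finite(e) & !is.infinite(e)) || any(e < 0)) {
    stop_data("`e` must be >= 0.")
  }
  ifelse(is.infinite(e), 1, e / (e + 1))
}

#' Gating free-energy change between two agonists
#'
#' For a structural modification of the agonist, the change in gating free
#' energy is `dG = -RT * ln(E_mod / E_ref)`, reported in kcal/mol. Positive
#' values mean the modification impairs gating.
#'
#' @param e_ref Gating constant of the reference agonist (> 0).
#' @param e_mod Gating constant of the modified agonist (> 0).
#' @param constants An [efficacy_constants()] object.
#' @return Free-energy change in kcal/mol; antisymmetric in its arguments.
#' @examples
#' free_energy_change(40.7, 1.30)  # ~ +2.02 kcal/mol
#' @export
free_energy_change <- function(e_ref, e_mod, constants = efficacy_constants()) {
  if (any(!is.finite(e_ref)) || any(!is.finite(e_mod)) ||
      any(e_ref <= 0) || any(e_mod <= 0)) {
    stop_data("Gating constants must be finite and strictly positive (apply the saturated-cluster policy first).")
  }
  -constants$RT_kcal * log(e_mod / e_ref)
}

#' Assemble the four corners of an agonist thermodynamic cycle
#'
#' The cycle compares two structural modifications of an agonist: lengthening
#' the backbone by one methylene and swapping the carboxylate for a
#' sulfonate. The corners are the per-cluster open probabilities of the
#' `reference` agonist (glycine), the `lengthened` one (beta-alanine), the
#' `swapped` one (AMS) and the one with `both` modifications (taurine).
#' Edge free energies are `dG1` (reference -> lengthened), `dG1p`
#' (swapped -> both), `dG2` (reference -> swapped) and `dG2p`
#' (lengthened -> both).
#'
#' Clusters at the boundary `popen` 0 or 1 have no finite gating constant.
#' The default policy excludes them (with a recorded count); the
#' `"continuity"` policy instead computes
#' `(open_time + eps) / (duration + 2 * eps)` and requires `open_time_ms`
#' and `duration_ms` columns.
#'
#' @param data Tibble with one row per accepted cluster, columns `agonist`
#'   and `popen` (plus `open_time_ms`, `duration_ms` for the continuity
#'   policy).
#' @param roles Named character vector mapping the four corner roles
#'   (`reference`, `lengthened`, `swapped`, `both`) to agonist labels in
#'   `data`.
#' @param p_policy Handling of saturated (`popen` 1) or silent (`popen` 0)
#'   clusters: `"exclude"` (default) or `"continuity"`.
#' @param eps Continuity correction in ms (used only by `"continuity"`).
#'
#' @return A list of class `cycle_spec`: per-corner E_eff vectors, corner
#'   labels, and counts of excluded clusters.
#' @examples
#' sets <- make_agonist_dataset(
#'   c(glycine = 0.96, `beta-alanine` = 0.54, AMS = 0.85, taurine = 0.12),
#'   kinetics = gating_params(alpha = 200, n_clusters = 30), seed = 1
#' )
#' cycle_spec(sets)
#' @export
cycle_spec <- function(data,
                       roles = c(reference = "glycine",
                                 lengthened = "beta-alanine",
                                 swapped = "AMS",
                                 both = "taurine"),
                       p_policy = c("exclude", "continuity"),
                       eps = 0.5) {
  p_policy <- match.arg(p_policy)
  need <- c("reference", "lengthened", "swapped", "both")
  if (!all(need %in% names(roles))) {
    stop_param("`roles` must name all four corners: reference, lengthened, swapped, both.")
  }
  if (!all(c("agonist", "popen") %in% names(data))) {
    stop_data("`data` must have `agonist` and `popen` columns.")
  }
  missing_ag <- setdiff(unname(roles[need]), unique(data$agonist))
  if (length(missing_ag) > 0L) {
    stop_data(paste0("No clusters for corner agonist(s): ",
                     paste(missing_ag, collapse = ", "), "."))
  }
  corners <- lapply(setNames(need, need), function(role) {
    rows <- data[data$agonist == roles[[role]], , drop = FALSE]
    p <- rows$popen
    n_boundary <- sum(p <= 0 | p >= 1)
    if (p_policy == "continuity" && n_boundary > 0L) {
      if (!all(c("open_time_ms", "duration_ms") %in% names(rows))) {
        stop_data("Continuity policy needs `open_time_ms` and `duration_ms` columns.")
      }
      p <- (rows$open_time_ms + eps) / (rows$duration_ms + 2 * eps)
    } else {
      p <- p[p > 0 & p < 1]
    }
    if (length(p) == 0L) {
      stop_data(sprintf("Corner '%s' (%s) has no usable clusters after the popen policy.",
                        role, roles[[role]]))
    }
    list(eeff = popen_to_eeff(p), n_excluded = if (p_policy == "exclude") n_boundary else 0L)
  })
  structure(
    list(
      eeff = lapply(corners, `[[`, "eeff"),
      labels = roles[need],
      n_excluded = vapply(corners, `[[`, integer(1), "n_excluded"),
      p_policy = p_policy
    ),
    class = "cycle_spec"
  )
}

#' @export
print.cycle_spec <- function(x, ...) {
  cat("<cycle_spec>\n")
  for (role in names(x$eeff)) {
    cat(sprintf("  %-10s %-12s n = %3d clusters (%d excluded at popen 0/1)\n",
                role, x$labels[[role]], length(x$eeff[[role]]),
                x$n_excluded[[role]]))
  }
  invisible(x)
}

cycle_edges <- function(e_ref, e_len, e_swp, e_both, constants) {
  dG1 <- free_energy_change(e_ref, e_len, constants)
  dG1p <- free_energy_change(e_swp, e_both, constants)
  dG2 <- free_energy_change(e_ref, e_swp, constants)
  dG2p <- free_energy_change(e_len, e_both, constants)
  list(dG1 = dG1, dG1p = dG1p, dG2 = dG2, dG2p = dG2p,
       ddG_int = dG1 - dG1p,
       closure = (dG1 + dG2p) - (dG2 + dG1p))
}

corner_estimate <- function(x, estimator) {
  switch(estimator, mean = mean(x), median = median(x))
}

#' Point-estimate thermodynamic-cycle coupling energy
#'
#' Collapses each corner's per-cluster gating constants to a point estimate
#' (mean of per-cluster E_eff by default; median available because the two
#' can differ appreciably for skewed E_eff distributions), computes the four
#' edge free-energy changes, and reports the coupling energy
#' `ddG_int = dG1 - dG1p`. A coupling energy of zero means the two
#' structural modifications act additively; the closure identity
#' `dG1 + dG2p = dG2 + dG1p` holds algebraically and its residual is
#' reported as a numerical check.
#'
#' @param spec A [cycle_spec()].
#' @param estimator `"mean"` or `"median"` of per-cluster E_eff values.
#' @param constants An [efficacy_constants()] object.
#' @return A `thermo_cycle` object; see [tidy.thermo_cycle()].
#' @export
coupling_energy <- function(spec, estimator = c("mean", "median"),
                            constants = efficacy_constants()) {
  stopifnot(inherits(spec, "cycle_spec"))
  estimator <- match.arg(estimator)
  pt <- vapply(spec$eeff, corner_estimate, numeric(1), estimator = estimator)
  edges <- cycle_edges(pt[["reference"]], pt[["lengthened"]],
                       pt[["swapped"]], pt[["both"]], constants)
  alt <- vapply(spec$eeff, corner_estimate, numeric(1),
                estimator = setdiff(c("mean", "median"), estimator))
  structure(
    list(
      eeff_point = pt,
      eeff_alt = alt,
      estimator = estimator,
      dG1 = edges$dG1, dG1p = edges$dG1p, dG2 = edges$dG2, dG2p = edges$dG2p,
      ddG_int = edges$ddG_int,
      closure_residual = edges$closure,
      sd_dG = NULL, sd_ddG = NULL, boot = NULL, n_boot = 0L, seed = NULL,
      labels = spec$labels, n_clusters = lengths(spec$eeff),
      n_excluded = spec$n_excluded, constants = constants
    ),
    class = "thermo_cycle"
  )
}

#' Bootstrap the thermodynamic cycle
#'
#' Resamples each corner's per-cluster gating constants with replacement,
#' independently per corner, recomputing the four edge free energies and the
#' coupling energy for every replicate. Returns the point estimates together
#' with bootstrap standard deviations and the replicate distributions.
#'
#' @param spec A [cycle_spec()].
#' @param n_boot Number of bootstrap replicates (10,000 by default).
#' @param seed Integer RNG seed.
#' @param estimator `"mean"` or `"median"` per-corner estimator.
#' @param constants An [efficacy_constants()] object.
#' @return A `thermo_cycle` object whose `sd_dG`, `sd_ddG` and `boot`
#'   (replicate tibble) fields are filled in.
#' @examples
#' sets <- make_agonist_dataset(
#'   c(glycine = 0.96, `beta-alanine` = 0.54, AMS = 0.85, taurine = 0.12),
#'   kinetics = gating_params(alpha = 200, n_clusters = 30), seed = 1
#' )
#' bootstrap_cycle(cycle_spec(sets), n_boot = 200, seed = 2)
#' @export
bootstrap_cycle <- function(spec, n_boot = 10000, seed = 1,
                            estimator = c("mean", "median"),
                            constants = efficacy_constants()) {
  stopifnot(inherits(spec, "cycle_spec"))
  estimator <- match.arg(estimator)
  if (n_boot < 1) stop_param("`n_boot` must be >= 1.")
  small <- names(spec$eeff)[lengths(spec$eeff) < 2L]
  if (length(small) > 0L) {
    warn(paste0("Corner(s) with fewer than 2 clusters: ",
                paste(small, collapse = ", "),
                "; bootstrap SDs are degenerate."))
  }
  result <- coupling_energy(spec, estimator = estimator, constants = constants)
  reps <- with_seed(seed, {
    lapply(spec$eeff, function(x) {
      n <- length(x)
      idx <- sample.int(n, n * n_boot, replace = TRUE)
      m <- matrix(x[idx], nrow = n, ncol = n_boot)
      if (estimator == "mean") colMeans(m) else apply(m, 2L, median)
    })
  })
  edges <- cycle_edges(reps$reference, reps$lengthened, reps$swapped,
                       reps$both, constants)
  boot <- tibble::tibble(dG1 = edges$dG1, dG1p = edges$dG1p,
                         dG2 = edges$dG2, dG2p = edges$dG2p,
                         ddG_int = edges$ddG_int)
  result$sd_dG <- vapply(boot[c("dG1", "dG1p", "dG2", "dG2p")], sd, numeric(1))
  result$sd_ddG <- sd(boot$ddG_int)
  result$boot <- boot
  result$n_boot <- as.integer(n_boot)
  result$seed <- seed
  result
}

#' @export
print.thermo_cycle <- function(x, ...) {
  cat("<thermo_cycle>", sprintf("(estimator: %s)\n", x$estimator))
  for (role in names(x$eeff_point)) {
    cat(sprintf("  E_eff[%-10s %-12s] = %8.3f  (n = %d clusters)\n",
                role, x$labels[[role]], x$eeff_point[[role]],
                x$n_clusters[[role]]))
  }
  fmt <- function(v, s) {
    if (is.null(s)) sprintf("%+.3f kcal/mol", v)
    else sprintf("%+.3f +/- %.3f kcal/mol", v, s)
  }
  cat("  dG1  (lengthen, -COO-): ", fmt(x$dG1, x$sd_dG[["dG1"]]), "\n")
  cat("  dG1' (lengthen, -SO3-): ", fmt(x$dG1p, x$sd_dG[["dG1p"]]), "\n")
  cat("  dG2  (swap, short):     ", fmt(x$dG2, x$sd_dG[["dG2"]]), "\n")
  cat("  dG2' (swap, long):      ", fmt(x$dG2p, x$sd_dG[["dG2p"]]), "\n")
  cat("  coupling ddG_int:       ", fmt(x$ddG_int, x$sd_ddG),
      sprintf(" (|ddG| = %.3f)\n", abs(x$ddG_int)))
  cat(sprintf("  closure residual: %.2e kcal/mol", x$closure_residual))
  if (x$n_boot > 0L) cat(sprintf("   (bootstrap: %d replicates, seed %s)",
                                 x$n_boot, format(x$seed)))
  cat("\n")
  invisible(x)
}

#' Tidy a thermodynamic-cycle result
#'
#' @param x A `thermo_cycle` object.
#' @param ... Unused.
#' @return A tibble with one row per cycle quantity (`dG1`, `dG1p`, `dG2`,
#'   `dG2p`, `ddG_int`): `term`, `estimate` (kcal/mol), `std.error`
#'   (bootstrap SD, `NA` without bootstrap).
#' @export
tidy.thermo_cycle <- function(x, ...) {
  terms <- c("dG1", "dG1p", "dG2", "dG2p", "ddG_int")
  tibble::tibble(
    term = terms,
    estimate = vapply(terms, function(t) x[[t]], numeric(1)),
    std.error = if (is.null(x$sd_ddG)) rep(NA_real_, 5L) else
      c(x$sd_dG[c("dG1", "dG1p", "dG2", "dG2p")], x$sd_ddG)
  )
}

#' One-row summary of a thermodynamic-cycle result
#'
#' @param x A `thermo_cycle` object.
#' @param ... Unused.
#' @return A one-row tibble: coupling energy and its magnitude, bootstrap
#'   SD, closure residual, estimator, replicate count and seed.
#' @export
glance.thermo_cycle <- function(x, ...) {
  tibble::tibble(
    ddG_int = x$ddG_int,
    abs_ddG_int = abs(x$ddG_int),
    sd_ddG = x$sd_ddG %||% NA_real_,
    closure_residual = x$closure_residual,
    estimator = x$estimator,
    n_boot = x$n_boot,
    seed = x$seed %||% NA_integer_
  )
}

#' Plot the bootstrap distribution of the coupling energy
#'
#' @param object A bootstrapped `thermo_cycle`.
#' @param ... Unused.
#' @return A ggplot object: histogram of the `ddG_int` replicates with the
#'   point estimate marked.
#' @export
autoplot.thermo_cycle <- function(object, ...) {
  if (is.null(object$boot)) {
    stop_data("No bootstrap replicates; run bootstrap_cycle() first.")
  }
  ggplot2::ggplot(object$boot, ggplot2::aes(x = .data$ddG_int)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$ddG_int, colour = "firebrick") +
    ggplot2::labs(x = expression(Delta * Delta * G[int] ~ "(kcal/mol)"),
                  y = "Bootstrap replicates") +
    ggplot2::theme_minimal()
}
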