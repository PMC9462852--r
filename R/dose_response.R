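#' Hill concentration-response function
#'
#' Three-parameter Hill equation with the bottom fixed at zero (peak currents
#' above a subtracted baseline):
#' `I(c) = Imax * c^nH / (c^nH + EC50^nH)`.
#'
#' @param conc Agonist concentration (same units as `ec50`, >= 0).
#' @param imax Maximal response.
#' @param ec50 Half-maximal concentration (> 0).
#' @param nh Hill slope (> 0).
#' @return Predicted response; 0 at `conc = 0`, `imax` as `conc -> Inf`,
#'   strictly increasing in `conc`.
#' @examples
#' hill_response(0.98, imax = 4.3, ec50 = 0.98, nh = 1.2)  # Imax/2
#' @export
hill_response <- function(conc, imax, ec50, nh) {
  if (any(conc < 0)) stop_data("`conc` must be >= 0.")
  cn <- conc^nh
  imax * cn / (cn + ec50^nh)
}

#' Fit the Hill equation to one cell's dose-response data
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt) of the
#' three-parameter Hill equation. The initialization policy is fixed for
#' determinism: `imax` starts at the largest response, `ec50` at the
#' concentration whose response is nearest half-maximum, `nh` at 1.
#' Non-convergence (including degenerate all-zero responses) is reported via
#' `converged = FALSE`, not an error.
#'
#' @param data Tibble of one cell's measurements.
#' @param conc Column with agonist concentrations (default
#'   `concentration_mM`); at least 3 distinct values required.
#' @param response Column with peak responses (default `current_nA`).
#' @param init Optional named list overriding the starting values
#'   (`imax`, `ec50`, `nh`).
#'
#' @return A `hill_fit` object; see [tidy.hill_fit()] and
#'   [glance.hill_fit()].
#' @examples
#' d <- tibble::tibble(
#'   concentration_mM = c(0.1, 0.3, 1, 3, 10, 30),
#'   current_nA = hill_response(concentration_mM, 4.3, 0.98, 1.2)
#' )
#' fit_hill(d)
#' @export
fit_hill <- function(data, conc = "concentration_mM", response = "current_nA",
                     init = NULL) {
  if (!is.data.frame(data)) stop_data("`data` must be a data frame.")
  if (!all(c(conc, response) %in% names(data))) {
    stop_data(sprintf("`data` must have columns `%s` and `%s`.", conc, response))
  }
  x <- data[[conc]]
  y <- data[[response]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (any(x <= 0)) stop_data("Concentrations must be strictly positive.")
  if (length(unique(x)) < 3L) {
    stop_data("At least 3 distinct concentrations are required to fit 3 parameters.")
  }
  start <- list(
    imax = init$imax %||% max(y),
    ec50 = init$ec50 %||% x[which.min(abs(y - max(y) / 2))],
    nh = init$nh %||% 1
  )
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ imax * x^nh / (x^nh + ec50^nh),
      data = df, start = start,
      lower = c(imax = 0, ec50 = 1e-12, nh = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    fit <- tryCatch(
      stats::nls(y ~ imax * x^nh / (x^nh + ec50^nh), data = df, start = start),
      error = function(e) NULL
    )
  }
  degenerate <- max(abs(y)) == 0
  converged <- !is.null(fit) && !degenerate
  est <- if (converged) as.list(stats::coef(fit)) else
    list(imax = NA_real_, ec50 = NA_real_, nh = NA_real_)
  se <- if (converged) {
    tryCatch(sqrt(diag(stats::vcov(fit)))[c("imax", "ec50", "nh")],
             error = function(e) rep(NA_real_, 3L))
  } else {
    rep(NA_real_, 3L)
  }
  resid <- if (converged) y - hill_response(x, est$imax, est$ec50, est$nh) else
    rep(NA_real_, length(y))
  structure(
    list(
      estimates = tibble::tibble(
        term = c("imax", "ec50", "nh"),
        estimate = c(est$imax, est$ec50, est$nh),
        std.error = as.numeric(se)
      ),
      converged = converged,
      data = tibble::tibble(conc = x, response = y),
      residuals = resid,
      fit = fit
    ),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit>", if (!x$converged) "(NOT converged)", "\n")
  e <- setNames(x$estimates$estimate, x$estimates$term)
  cat(sprintf("  Imax = %.4g   EC50 = %.4g   nH = %.3g   (n = %d points)\n",
              e[["imax"]], e[["ec50"]], e[["nh"]], nrow(x$data)))
  invisible(x)
}

#' Tidy a Hill fit
#'
#' @param x A `hill_fit` object.
#' @param ... Unused.
#' @return A tibble with `term` (`imax`, `ec50`, `nh`), `estimate`,
#'   `std.error`.
#' @export
tidy.hill_fit <- function(x, ...) x$estimates

#' One-row summary of a Hill fit
#'
#' @param x A `hill_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `imax`, `ec50`, `nh`, `converged`, residual
#'   SD `sigma`, `n`.
#' @export
glance.hill_fit <- function(x, ...) {
  e <- setNames(x$estimates$estimate, x$estimates$term)
  n <- nrow(x$data)
  tibble::tibble(
    imax = e[["imax"]], ec50 = e[["ec50"]], nh = e[["nh"]],
    converged = x$converged,
    sigma = if (x$converged && n > 3L) {
      sqrt(sum(x$residuals^2) / (n - 3L))
    } else {
      NA_real_
    },
    n = n
  )
}

#' Plot a Hill fit
#'
#' @param object A `hill_fit`.
#' @param ... Unused.
#' @return A ggplot: measured points and the fitted curve on a log
#'   concentration axis.
#' @export
autoplot.hill_fit <- function(object, ...) {
  e <- setNames(object$estimates$estimate, object$estimates$term)
  rng <- range(object$data$conc)
  curve <- tibble::tibble(
    conc = exp(seq(log(rng[1] / 3), log(rng[2] * 3), length.out = 200))
  )
  if (object$converged) {
    curve$response <- hill_response(curve$conc, e[["imax"]], e[["ec50"]], e[["nh"]])
  }
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$conc, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Concentration", y = "Response") +
    ggplot2::theme_minimal()
  if (object$converged) p <- p + ggplot2::geom_line(data = curve)
  p
}

#' Rundown check on interleaved reference responses
#'
#' During a dose-response protocol a saturating reference agonist
#' application is interleaved every few applications to monitor rundown.
#' The decline is measured as `1 - min(later responses) / first response`
#' (clamped at 0 for run-up); cells whose decline exceeds the threshold are
#' discarded.
#'
#' @param reference_responses Ordered numeric vector of reference-agonist
#'   responses (>= 2 values).
#' @param threshold Maximum tolerated fractional decline (0.30 by default).
#' @return A one-row tibble: `keep` (logical), `max_decline` (fraction).
#' @examples
#' check_rundown(c(4.0, 2.6))  # 35% decline: discard
#' @export
check_rundown <- function(reference_responses, threshold = 0.30) {
  if (length(reference_responses) < 2L) {
    stop_data("At least 2 reference responses are required.")
  }
  if (anyNA(reference_responses) || any(reference_responses <= 0)) {
    stop_data("Reference responses must be positive and non-missing.")
  }
  decline <- max(0, 1 - min(reference_responses[-1L]) / reference_responses[1L])
  tibble::tibble(keep = decline <= threshold, max_decline = decline)
}

#' Normalize dose-response curves per cell, pool, and refit
#'
#' Applies the rundown criterion per cell, divides each passing cell's
#' responses either by that cell's own maximum response (`mode = "own_max"`,
#' for same-agonist curves) or by its mean saturating-reference response
#' (`mode = "reference"`, for relative-efficacy curves against the reference
#' agonist), pools the normalized points across cells, and refits the Hill
#' equation. With `mode = "reference"` the pooled `imax` is the agonist's
#' maximal response as a fraction of the reference-agonist maximum.
#'
#' @param data Tibble with columns `cell_id`, `concentration_mM`,
#'   `current_nA` and logical `is_reference` marking interleaved reference
#'   applications (row order within a cell is protocol order).
#' @param mode `"own_max"` or `"reference"`.
#' @param rundown_threshold Maximum tolerated fractional rundown.
#'
#' @return A list of class `pooled_hill`: `fit` (a `hill_fit` on the pooled
#'   normalized points), `pooled` (the normalized point tibble), `audit`
#'   (per-cell keep/decline table).
#' @export
normalize_and_pool <- function(data, mode = c("own_max", "reference"),
                               rundown_threshold = 0.30) {
  mode <- match.arg(mode)
  need <- c("cell_id", "concentration_mM", "current_nA", "is_reference")
  if (!all(need %in% names(data))) {
    stop_data(paste0("`data` must have columns: ", paste(need, collapse = ", "), "."))
  }
  cells <- split(data, data$cell_id)
  audit <- purrr::imap_dfr(cells, function(d, id) {
    refs <- d$current_nA[d$is_reference]
    if (mode == "reference" && length(refs) == 0L) {
      stop_data(sprintf("Cell '%s' has no reference responses.", id))
    }
    rd <- if (length(refs) >= 2L) check_rundown(refs, rundown_threshold) else
      tibble::tibble(keep = TRUE, max_decline = NA_real_)
    tibble::tibble(cell_id = id, keep = rd$keep, max_decline = rd$max_decline)
  })
  kept <- audit$cell_id[audit$keep]
  if (length(kept) == 0L) stop_data("All cells were discarded for rundown.")
  pooled <- purrr::map_dfr(kept, function(id) {
    d <- cells[[id]]
    test_rows <- d[!d$is_reference, , drop = FALSE]
    denom <- if (mode == "own_max") {
      max(test_rows$current_nA)
    } else {
      mean(d$current_nA[d$is_reference])
    }
    tibble::tibble(
      cell_id = id,
      concentration_mM = test_rows$concentration_mM,
      response = test_rows$current_nA / denom
    )
  })
  fit <- fit_hill(pooled, conc = "concentration_mM", response = "response")
  structure(list(fit = fit, pooled = pooled, audit = audit, mode = mode),
            class = "pooled_hill")
}

#' @export
print.pooled_hill <- function(x, ...) {
  cat(sprintf("<pooled_hill> mode = %s; %d/%d cells kept\n",
              x$mode, sum(x$audit$keep), nrow(x$audit)))
  print(x$fit)
  invisible(x)
}

#' @export
tidy.pooled_hill <- function(x, ...) tidy(x$fit)

#' @export
glance.pooled_hill <- function(x, ...) {
  dplyr::mutate(glance(x$fit), n_cells_kept = sum(x$audit$keep),
                n_cells = nrow(x$audit), mode = x$mode)
}

#' Zwitterionic fraction of an amino group at a given pH
#'
#' Henderson-Hasselbalch arithmetic: the fraction of molecules whose amino
#' group is protonated (the stable zwitterion form for an amino sulfonic or
#' amino carboxylic acid) is `1 / (1 + 10^(pH - pKa))`. For
#' aminomethanesulfonic acid (amino pKa 5.75) this is about 2% at
#' physiological pH 7.4 and about 85% at pH 5, which is why an acidic
#' recording protocol is needed to keep the compound stable.
#'
#' @param pH Solution pH.
#' @param pKa Acid dissociation constant of the amino group (5.75 default,
#'   the value for aminomethanesulfonic acid).
#' @return Protonated (zwitterion) fraction in (0, 1); strictly decreasing
#'   in pH, 0.5 at `pH = pKa`.
#' @examples
#' zwitterion_fraction(7.4)  # ~0.022
#' zwitterion_fraction(5.0)  # ~0.85
#' @export
zwitterion_fraction <- function(pH, pKa = 5.75) {
  if (any(!is.finite(pH)) || any(!is.finite(pKa))) {
    stop_param("`pH` and `pKa` must be finite.")
  }
  1 / (1 + 10^(pH - pKa))
}
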