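# Frozen oracle values, computed by direct high-precision evaluation of
# -RT*ln(ratio) with RT = 1.987e-3 * 295 kcal/mol = 0.586165 kcal/mol.
RT_KCAL <- 1.987e-3 * 295

test_that("popen <-> gating-constant conversion matches the published worked examples", {
  # published median Popen values and the gating constants printed for them
  expect_equal(popen_to_eeff(0.976), 40.7, tolerance = 0.05 / 40.7)
  expect_equal(popen_to_eeff(0.566), 1.30, tolerance = 0.005 / 1.30)
  expect_equal(popen_to_eeff(0.931), 13.5, tolerance = 0.05 / 13.5)
  expect_equal(popen_to_eeff(0.060), 0.06, tolerance = 0.005 / 0.06)
  expect_equal(popen_to_eeff(0.5), 1.0)
  expect_equal(eeff_to_popen(1.0), 0.5)
  expect_equal(eeff_to_popen(0), 0)
  # algebraic inverse across four decades
  e <- 10^seq(-2, 2, by = 0.25)
  expect_equal(popen_to_eeff(eeff_to_popen(e)), e, tolerance = 1e-12)
  # strict monotonicity
  p <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(popen_to_eeff(p)) > 0))
  expect_error(popen_to_eeff(-0.1), class = "popencycle_data_error")
  expect_error(popen_to_eeff(1.1), class = "popencycle_data_error")
  expect_error(eeff_to_popen(-1), class = "popencycle_data_error")
  expect_identical(popen_to_eeff(1), Inf)
})

test_that("free-energy changes follow -RT ln(Em/Eref) in kcal/mol", {
  cst <- efficacy_constants()
  expect_equal(cst$RT_kcal, RT_KCAL)
  expect_equal(free_energy_change(7, 7, cst), 0)
  expect_equal(free_energy_change(2, 8, cst), -free_energy_change(8, 2, cst))
  # oracle: direct evaluation of RT * (ln 40.7 - ln 1.30) = 2.018625...
  expect_equal(free_energy_change(40.7, 1.30, cst),
               RT_KCAL * (log(40.7) - log(1.30)))
  expect_equal(free_energy_change(40.7, 1.30, cst), 2.02, tolerance = 0.005)
  # strictly decreasing in the modified gating constant
  dG <- free_energy_change(rep(10, 5), c(1, 2, 5, 10, 20), cst)
  expect_true(all(diff(dG) < 0))
  expect_error(free_energy_change(0, 1), class = "popencycle_data_error")
  expect_error(free_energy_change(1, Inf), class = "popencycle_data_error")
})

corner_data <- function(eeff) {
  # one-cluster-per-corner popen table with exact corner E_eff values
  tibble::tibble(
    agonist = c("glycine", "beta-alanine", "AMS", "taurine"),
    popen = eeff_to_popen(eeff)
  )
}

test_that("a multiplicative (non-interacting) cycle has zero coupling energy", {
  cyc <- coupling_energy(cycle_spec(corner_data(c(10, 1, 10000, 1000))))
  expect_lt(abs(cyc$ddG_int), 1e-12)
  expect_lt(abs(cyc$closure_residual), 1e-12)
})

test_that("the printed corner gating constants give ~1.16 kcal/mol coupling", {
  cyc <- coupling_energy(cycle_spec(corner_data(c(40.7, 1.30, 13.5, 0.06))))
  # oracle: RT*(ln(40.7/1.30) - ln(13.5/0.06)) = -1.1561...
  oracle <- RT_KCAL * (log(40.7 / 1.30) - log(13.5 / 0.06))
  expect_equal(cyc$ddG_int, oracle, tolerance = 1e-12)
  expect_equal(abs(cyc$ddG_int), 1.16, tolerance = 0.005)
})

test_that("swapping the edge-labelling convention flips only the sign", {
  dat <- corner_data(c(40.7, 1.30, 13.5, 0.06))
  a <- coupling_energy(cycle_spec(dat))
  # relabel with the sulfonate column as the reference side: the coupling
  # energy changes sign but not magnitude
  b <- coupling_energy(cycle_spec(
    dat, roles = c(reference = "AMS", lengthened = "taurine",
                   swapped = "glycine", both = "beta-alanine")
  ))
  expect_equal(b$ddG_int, -a$ddG_int, tolerance = 1e-12)
  # relabelling which modification counts as "1" vs "2" leaves the coupling
  # unchanged (closure identity)
  c_ <- coupling_energy(cycle_spec(
    dat, roles = c(reference = "glycine", lengthened = "AMS",
                   swapped = "beta-alanine", both = "taurine")
  ))
  expect_equal(c_$ddG_int, a$ddG_int, tolerance = 1e-12)
})

test_that("cycle closure is an algebraic identity over random corners", {
  set.seed(123)
  for (i in 1:200) {
    e <- exp(runif(4, -6, 6))
    cyc <- coupling_energy(cycle_spec(corner_data(e)))
    expect_lt(abs(cyc$closure_residual), 1e-12)
  }
})

test_that("coupling is invariant to a common scale factor on all corners", {
  e <- c(30, 2, 11, 0.08)
  a <- coupling_energy(cycle_spec(corner_data(e)))
  b <- coupling_energy(cycle_spec(corner_data(e * 37.5)))
  expect_equal(a$ddG_int, b$ddG_int, tolerance = 1e-12)
})

test_that("saturated and silent clusters follow the stated popen policy", {
  dat <- tibble::tibble(
    agonist = rep(c("glycine", "beta-alanine", "AMS", "taurine"), each = 3),
    popen = c(0.9, 0.95, 1.0,  0.5, 0.6, 0.55,  0.9, 0.85, 0.8,  0.1, 0.0, 0.15),
    open_time_ms = c(90, 95, 100, 50, 60, 55, 90, 85, 80, 10, 0, 15),
    duration_ms = rep(100, 12)
  )
  sp <- cycle_spec(dat)
  expect_identical(unname(sp$n_excluded), c(1L, 0L, 0L, 1L))
  expect_identical(lengths(sp$eeff), c(reference = 2L, lengthened = 3L,
                                       swapped = 3L, both = 2L))
  # continuity correction keeps every cluster with finite E_eff
  sp2 <- cycle_spec(dat, p_policy = "continuity", eps = 0.5)
  expect_identical(lengths(sp2$eeff),
                   c(reference = 3L, lengthened = 3L, swapped = 3L, both = 3L))
  expect_true(all(is.finite(unlist(sp2$eeff))))
  # a corner emptied by the policy is an error naming the corner
  dat2 <- dat
  dat2$popen[dat2$agonist == "taurine"] <- c(0, 0, 1)
  expect_error(cycle_spec(dat2), "both", class = "popencycle_data_error")
})

test_that("bootstrap SDs vanish for constant corners and are seed-stable", {
  dat <- corner_data(c(10, 1, 100, 10))
  dat <- dat[rep(1:4, each = 5), ]
  cyc <- suppressWarnings(bootstrap_cycle(cycle_spec(dat), n_boot = 500, seed = 1))
  expect_equal(cyc$sd_ddG, 0)
  expect_true(all(cyc$sd_dG == 0))
  # determinism
  sets <- make_agonist_dataset(
    c(glycine = 0.9, `beta-alanine` = 0.5, AMS = 0.8, taurine = 0.2),
    kinetics = gating_params(alpha = 200, n_clusters = 20), seed = 3
  )
  c1 <- bootstrap_cycle(cycle_spec(sets), n_boot = 300, seed = 11)
  c2 <- bootstrap_cycle(cycle_spec(sets), n_boot = 300, seed = 11)
  expect_identical(c1$boot, c2$boot)
  c3 <- bootstrap_cycle(cycle_spec(sets), n_boot = 300, seed = 12)
  expect_false(identical(c1$boot, c2$boot) && identical(c1$boot, c3$boot) &&
               identical(c2$boot, c3$boot))
})

test_that("bootstrap edge SDs match the delta-method approximation", {
  set.seed(77)
  n_ref <- 80; n_mod <- 120
  e_ref <- exp(rnorm(n_ref, log(20), 0.3))
  e_mod <- exp(rnorm(n_mod, log(2), 0.4))
  dat <- tibble::tibble(
    agonist = c(rep("glycine", n_ref), rep("beta-alanine", n_mod),
                rep("AMS", n_ref), rep("taurine", n_mod)),
    popen = eeff_to_popen(c(e_ref, e_mod, e_ref, e_mod))
  )
  cyc <- bootstrap_cycle(cycle_spec(dat), n_boot = 4000, seed = 5)
  # delta method on dG1 = -RT ln(mean(Em)/mean(Eref)):
  # SD ~ RT * sqrt(cv_ref^2/n_ref + cv_mod^2/n_mod)
  cv <- function(x) sd(x) / mean(x)
  pred <- RT_KCAL * sqrt(cv(e_ref)^2 / n_ref + cv(e_mod)^2 / n_mod)
  expect_lt(abs(cyc$sd_dG[["dG1"]] - pred) / pred, 0.15)
})

test_that("tidy and glance expose the cycle quantities", {
  dat <- corner_data(c(40.7, 1.30, 13.5, 0.06))
  dat <- dat[rep(1:4, each = 4), ]
  cyc <- bootstrap_cycle(cycle_spec(dat), n_boot = 100, seed = 2)
  td <- tidy(cyc)
  expect_identical(td$term, c("dG1", "dG1p", "dG2", "dG2p", "ddG_int"))
  expect_equal(unname(td$estimate[1] + td$estimate[4]),
               unname(td$estimate[3] + td$estimate[2]), tolerance = 1e-12)
  gl <- glance(cyc)
  expect_equal(gl$abs_ddG_int, abs(cyc$ddG_int))
  expect_identical(gl$n_boot, 100L)
})
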