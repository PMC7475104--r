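test_that("external scatter bases resample losslessly onto the grid", {
  grid <- energy_grid()
  tab <- data.frame(energy_kev = grid, value = dnorm(grid, 150, 40))
  s <- load_scatter_basis(tab, "Th227")
  expect_equal(s$value, tab$value)

  # 2 keV spacing: midpoint bins are neighbor averages
  coarse <- data.frame(energy_kev = seq(20.5, 599.5, by = 2),
                       value = exp(-seq(20.5, 599.5, by = 2) / 100))
  s2 <- load_scatter_basis(coarse, "Ra223")
  at <- function(e) s2$value[s2$energy_kev == e]
  expect_equal(at(21.5), (at(20.5) + at(22.5)) / 2)

  # integral preserved vs trapezoid of the raw table
  raw_int <- pracma::trapz(coarse$energy_kev, coarse$value)
  res_int <- pracma::trapz(s2$energy_kev, s2$value)
  expect_lt(abs(res_int - raw_int) / raw_int, 5e-3)

  # outside the tabulated range the basis is zero
  short <- data.frame(energy_kev = c(100, 200), value = c(1, 1))
  s3 <- load_scatter_basis(short, "Th227")
  expect_true(all(s3$value[s3$energy_kev < 99 | s3$energy_kev > 201] == 0))

  expect_error(load_scatter_basis(data.frame(energy_kev = c(2, 1),
                                             value = c(1, 1)), "Th227"),
               "ascending")
  expect_error(load_scatter_basis(data.frame(energy_kev = c(1, 2),
                                             value = c(-1, 1)), "Th227"),
               "non-negative")
})

test_that("the parametric single-scatter continuum respects kinematics", {
  det <- detector_spec()
  s <- parametric_scatter(fake_lines(364.5, 1), 20, det)
  expect_equal(sum(s$value), 1, tolerance = 1e-3)
  # nothing (beyond Gaussian tail dregs) above the line energy plus 3 FWHM
  hi <- 364.5 + 3 * energy_resolution(det, 364.5)
  expect_true(all(s$value[s$energy_kev > hi] < 1e-6 * max(s$value)))
  expect_true(all(s$value >= 0))

  # backscatter limit of the pre-blur continuum: E0 / (1 + 2 E0 / 511)
  cont <- thoraquant:::kn_continuum(236)
  grid <- energy_grid()
  e_min_obs <- min(grid[cont > 0])
  e_min <- 236 / (1 + 2 * 236 / 511)
  expect_lt(abs(e_min_obs - e_min), 1)

  # continuity after blurring: no bin-to-bin step exceeding 20% of the
  # spectrum maximum (relative jumps are large only on the smooth
  # exponential rise through near-zero values)
  full <- parametric_scatter(emission_lines("Ra223chain"), 20, det)
  expect_lt(max(abs(diff(full$value))), 0.2 * max(full$value))
  expect_true(all(full$value[full$energy_kev >
                               445 + 3 * energy_resolution(det, 445)] <
                    1e-6 * max(full$value)))
})

test_that("nu coefficients scale scatter window integrals locally", {
  cmp <- test_components(20)
  s <- cmp$spectra$s_ra
  nu1 <- default_scatter_coefficients()
  plain <- scatter_window_integrals(s, nu1)
  expect_equal(plain, window_integral(s))

  nu2 <- nu1
  nu2$nu[nu2$isotope == "Ra223" & nu2$window == "135-165"] <- 2
  scaled <- scatter_window_integrals(s, nu2)
  expect_equal(unname(scaled[2] / plain[2]), 2)
  expect_equal(scaled[-2], plain[-2])

  # brute-force bin sum oracle
  wins <- default_windows()
  brute <- sum(s$value[s$energy_kev >= 215 & s$energy_kev < 260])
  expect_equal(unname(plain[3]), brute, tolerance = 1e-12)

  expect_error(scatter_window_integrals(s, nu1[nu1$isotope == "Th227", ]),
               "missing nu")
})

make_calibration_meas <- function(cmp, nu_true, b = 1, noisy = FALSE,
                                  seed = 1) {
  # day 0: Th-dominant fill; day 14: substantial Ra ingrowth
  cmp_true <- set_scatter_coefficients(cmp, nu_true)
  a0 <- bateman_activities(0.54, 0.014, 0)
  a14 <- bateman_activities(0.54, 0.014, 14)
  mk <- function(a, offset) {
    counts <- model_window_counts(cmp_true, a$a_th227, a$a_ra223, b, 1200)
    if (noisy) {
      set.seed(seed + offset)
      counts <- rpois(4, counts)
    }
    list(gm_counts = counts, duration_s = 1200,
         a_th = a$a_th227, a_ra = a$a_ra223)
  }
  list(th = mk(a0, 0), ra = mk(a14, 1))
}

test_that("nu calibration recovers the generating coefficients", {
  cmp <- test_components(20)
  # self-consistency at nu = 1
  m <- make_calibration_meas(cmp, default_scatter_coefficients())
  nu_hat <- calibrate_nu(m$th, m$ra, cmp)
  expect_equal(nu_hat$nu, rep(1, 8), tolerance = 1e-6)

  # injected mismatch: nu_Ra(75-100) = 1.4
  nu_true <- default_scatter_coefficients()
  nu_true$nu[nu_true$isotope == "Ra223" & nu_true$window == "75-100"] <- 1.4
  m2 <- make_calibration_meas(cmp, nu_true)
  nu_hat2 <- calibrate_nu(m2$th, m2$ra, cmp)
  expect_equal(nu_hat2$nu[nu_hat2$isotope == "Ra223" &
                            nu_hat2$window == "75-100"], 1.4,
               tolerance = 1e-3)
  expect_equal(nu_hat2$nu[!(nu_hat2$isotope == "Ra223" &
                              nu_hat2$window == "75-100")],
               rep(1, 7), tolerance = 1e-3)

  # re-application reproduces the calibration counts
  cmp_hat <- set_scatter_coefficients(cmp, nu_hat2)
  refit <- model_window_counts(cmp_hat, m2$th$a_th, m2$th$a_ra, 1, 1200)
  expect_equal(unname(refit), unname(m2$th$gm_counts), tolerance = 1e-3)
})

test_that("nu calibration is robust to Poisson noise at phantom counts", {
  cmp <- test_components(20)
  nu_true <- default_scatter_coefficients()
  nu_true$nu[nu_true$isotope == "Th227" & nu_true$window == "215-260"] <- 1.3
  rec <- replicate(100, NA_real_)
  for (i in seq_len(100)) {
    m <- make_calibration_meas(cmp, nu_true, noisy = TRUE, seed = 1000 + i)
    suppressWarnings(nu_hat <- calibrate_nu(m$th, m$ra, cmp))
    rec[i] <- nu_hat$nu[nu_hat$isotope == "Th227" &
                          nu_hat$window == "215-260"]
  }
  expect_lt(abs(median(rec) - 1.3) / 1.3, 0.10)
})

test_that("scatter basis scale is absorbed by B (shape invariance)", {
  cmp <- test_components(20)
  scaled_basis <- list(th = cmp$spectra$s_th, ra = cmp$spectra$s_ra)
  scaled_basis$th$value <- scaled_basis$th$value * 7.3
  scaled_basis$ra$value <- scaled_basis$ra$value * 7.3
  cmp2 <- prepare_components(20, scatter_basis = scaled_basis)
  counts <- model_window_counts(cmp, 0.4, 0.2, 1.5, 1200)
  e1 <- solve_activities(counts, 1200, cmp)
  e2 <- solve_activities(counts, 1200, cmp2)
  expect_equal(e2$a_th227, e1$a_th227, tolerance = 1e-6)
  expect_equal(e2$a_ra223, e1$a_ra223, tolerance = 1e-6)
})
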