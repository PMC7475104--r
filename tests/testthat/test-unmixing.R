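test_that("conjugate geometric mean has the Eq-2 algebra", {
  expect_equal(conjugate_geometric_mean(100, 100), 100)
  expect_equal(conjugate_geometric_mean(0, 500), 0)
  C <- 350
  expect_equal(conjugate_geometric_mean(C * exp(-0.3), C * exp(-0.9)),
               C * exp(-0.6), tolerance = 1e-12)
  expect_error(conjugate_geometric_mean(-1, 5), "non-negative")
})

test_that("modelled window counts are linear and separable", {
  cmp <- test_components(20)
  expect_equal(unname(model_window_counts(cmp, 0, 0, 1, 1200)), rep(0, 4))
  # B = 0 reduces to the pure primary prediction
  b0 <- model_window_counts(cmp, 0.5, 0.1, 0, 1200)
  expect_equal(unname(b0), unname(1200 * (0.5 * cmp$p_th + 0.1 * cmp$p_ra)))
  # degree-1 homogeneity in the activities at fixed B
  m1 <- model_window_counts(cmp, 0.5, 0.1, 1.2, 1200)
  m2 <- model_window_counts(cmp, 1.0, 0.2, 1.2, 1200)
  expect_equal(m2, 2 * m1, tolerance = 1e-12)
})

test_that("the solver inverts noise-free modelled counts", {
  cmp <- test_components(20)
  counts <- model_window_counts(cmp, 0.5, 0.1, 1.2, 1200)
  est <- solve_activities(counts, 1200, cmp)
  expect_equal(est$a_th227, 0.5, tolerance = 1e-3)
  expect_equal(est$a_ra223, 0.1, tolerance = 1e-3)
  expect_equal(est$b, 1.2, tolerance = 1e-3)
  expect_true(est$converged)
  # objective at the solution cannot exceed the objective at truth (= 0,
  # up to floating-point noise on counts of order 10^3)
  expect_lt(est$residual, 1e-12 * sum(counts^2))
})

test_that("Ra-only counts put the Th estimate exactly on the boundary", {
  cmp <- test_components(20)
  counts <- model_window_counts(cmp, 0, 0.15, 1, 1200)
  est <- solve_activities(counts, 1200, cmp)
  expect_identical(est$a_th227, 0)
  expect_equal(est$a_ra223, 0.15, tolerance = 1e-3)
})

test_that("all-zero measurements give zero activities and residual", {
  cmp <- test_components(20)
  est <- solve_activities(rep(0, 4), 1200, cmp)
  expect_identical(est$a_th227, 0)
  expect_identical(est$a_ra223, 0)
  expect_equal(est$residual, 0)
})

test_that("the solver matches an exhaustive grid-search oracle", {
  cmp <- test_components(20)
  set.seed(7)
  counts <- rpois(4, model_window_counts(cmp, 0.5, 0.1, 1.2, 1200))
  est <- solve_activities(counts, 1200, cmp)
  obj <- function(a_th, a_ra, b) {
    sum((counts - model_window_counts(cmp, a_th, a_ra, b, 1200))^2)
  }
  # 200^3 grid bracketing the truth, chunked over B
  a_th_grid <- seq(0, 1.0, length.out = 200)
  a_ra_grid <- seq(0, 0.4, length.out = 200)
  b_grid <- seq(0, 4, length.out = 200)
  best <- Inf
  pred_th <- outer(a_th_grid, rep(1, 200))
  pred_ra <- outer(rep(1, 200), a_ra_grid)
  for (b in b_grid) {
    tot <- 0
    for (j in 1:4) {
      mod <- 1200 * (pred_th * (cmp$p_th[j] + b * cmp$nu_th[j] * cmp$s_th[j]) +
                     pred_ra * (cmp$p_ra[j] + b * cmp$nu_ra[j] * cmp$s_ra[j]))
      tot <- tot + (counts[j] - mod)^2
    }
    best <- min(best, min(tot))
  }
  expect_lte(est$residual, best + 1e-9)
})

test_that("estimates are invariant to a consistent count/duration rescale", {
  cmp <- test_components(20)
  counts <- model_window_counts(cmp, 0.3, 0.2, 0.8, 1200)
  e1 <- solve_activities(counts, 1200, cmp)
  e2 <- solve_activities(counts * 3, 3600, cmp)
  expect_equal(e2$a_th227, e1$a_th227, tolerance = 1e-6)
  expect_equal(e2$a_ra223, e1$a_ra223, tolerance = 1e-6)
})

test_that("tidy and glance summarise an estimate", {
  cmp <- test_components(20)
  est <- solve_activities(model_window_counts(cmp, 0.5, 0.1, 1, 1200),
                          1200, cmp)
  td <- tidy(est)
  expect_equal(td$term, c("a_th227", "a_ra223", "b"))
  expect_equal(td$estimate[1], 0.5, tolerance = 1e-3)
  gl <- glance(est)
  expect_true(gl$converged)
  expect_equal(gl$n_windows, 4L)
})

test_that("Poisson-weighted fitting is available and sane", {
  cmp <- test_components(20)
  counts <- model_window_counts(cmp, 0.5, 0.1, 1.2, 1200)
  est <- solve_activities(counts, 1200, cmp, weights = "poisson")
  expect_equal(est$a_th227, 0.5, tolerance = 1e-3)
  expect_equal(est$a_ra223, 0.1, tolerance = 1e-3)
})

test_that("parameter recovery under Poisson noise stays within 10% bias", {
  cmp <- test_components(20)
  truth <- model_window_counts(cmp, 0.5, 0.07, 1, 1200)
  errs_th <- errs_ra <- numeric(100)
  for (i in seq_len(100)) {
    set.seed(i)
    est <- solve_activities(rpois(4, truth), 1200, cmp)
    errs_th[i] <- est$a_th227 / 0.5 - 1
    errs_ra[i] <- est$a_ra223 / 0.07 - 1
  }
  expect_lt(abs(median(errs_th)), 0.10)
  expect_lt(abs(median(errs_ra)), 0.10)
})

test_that("pixelwise decomposition agrees with scalar solves", {
  cmp <- test_components(20)
  counts <- model_window_counts(cmp, 0.4, 0.1, 1, 600)
  mkimg <- function(j, view, value) {
    planar_image(matrix(value, 6, 6), unname(c(cmp$windows$lo_kev[j],
                                               cmp$windows$hi_kev[j])),
                 view, 600)
  }
  ant <- lapply(1:4, function(j) mkimg(j, "anterior", counts[j]))
  post <- lapply(1:4, function(j) mkimg(j, "posterior", counts[j]))
  dec <- pixelwise_decompose(ant, post, components = cmp)
  expect_true(all(dec$mask))
  expect_equal(dec$a_th227, matrix(0.4, 6, 6), tolerance = 1e-3)
  expect_equal(dec$a_ra223, matrix(0.1, 6, 6), tolerance = 1e-3)

  # aggregation consistency: pixel sums match the whole-field ROI estimate
  whole <- solve_activities(counts * 36, 600, cmp)
  expect_equal(sum(dec$a_th227), whole$a_th227, tolerance = 0.02)
  expect_equal(sum(dec$a_ra223), whole$a_ra223, tolerance = 0.02)
})

test_that("a Ra-only disc yields an identically zero Th image", {
  cmp <- test_components(20)
  counts <- model_window_counts(cmp, 0, 0.2, 1, 600)
  img <- matrix(0, 8, 8)
  disc <- (row(img) - 4.5)^2 + (col(img) - 4.5)^2 <= 4
  mk <- function(j, view) {
    m <- img
    m[disc] <- counts[j]
    planar_image(m, unname(c(cmp$windows$lo_kev[j], cmp$windows$hi_kev[j])),
                 view, 600)
  }
  ant <- lapply(1:4, function(j) mk(j, "anterior"))
  post <- lapply(1:4, function(j) mk(j, "posterior"))
  dec <- pixelwise_decompose(ant, post, components = cmp)
  expect_true(all(dec$a_th227 == 0))
  expect_true(all(dec$a_ra223[disc] > 0))
  expect_true(all(dec$a_ra223[!disc] == 0))
  expect_error(pixelwise_decompose(ant[1:4], list(post[[1]]), components = cmp))
})
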