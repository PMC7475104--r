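#' Conjugate-view geometric mean
#'
#' \eqn{\sqrt{C_{ant} C_{post}}}, elementwise. For a source at depth d in a
#' total thickness x, the product of the two views' attenuation factors is
#' \eqn{e^{-\mu x}} regardless of d, which is what makes the geometric mean
#' depth-independent.
#'
#' @param ant,post Non-negative counts (vectors or matrices of equal shape).
#' @return Geometric-mean counts.
#' @export
conjugate_geometric_mean <- function(ant, post) {
  if (any(ant < 0) || any(post < 0)) {
    abort("counts must be non-negative (clip background-corrected counts upstream)")
  }
  sqrt(ant * post)
}

#' Model the geometric-mean counts in the four windows
#'
#' Per window j the modelled counts are
#' \deqn{d \left[ A_{Th} P_{Th,j} + A_{Ra} P_{Ra,j}
#'  + B (A_{Th}\,\nu_{Th,j} S_{Th,j} + A_{Ra}\,\nu_{Ra,j} S_{Ra,j}) \right]}
#' with d the acquisition duration, P the primary window rates and S the
#' unit-normalised scatter window fractions. Scattered counts are taken
#' proportional to the activities, with the dimensionless global scale B.
#'
#' @param components A [prepare_components()] bundle.
#' @param a_th,a_ra Activities (MBq).
#' @param b Scatter scale (dimensionless, >= 0).
#' @param duration_s Acquisition duration (s).
#' @return Named numeric vector of modelled counts, one per window.
#' @export
model_window_counts <- function(components, a_th, a_ra, b, duration_s) {
  duration_s * (a_th * components$p_th + a_ra * components$p_ra +
    b * (a_th * components$nu_th * components$s_th +
         a_ra * components$nu_ra * components$s_ra))
}

# exact non-negative least squares in two variables (active-set by
# enumeration): minimise ||y - M %*% c||^2 over c >= 0
nnls2 <- function(M, y, w = NULL) {
  if (!is.null(w)) {
    M <- M * sqrt(w)
    y <- y * sqrt(w)
  }
  cand <- list()
  g <- crossprod(M)
  if (abs(det(g)) > 1e-300) {
    c_free <- drop(solve(g, crossprod(M, y)))
    if (all(c_free >= 0)) cand <- c(cand, list(c_free))
  }
  for (i in 1:2) {
    ci <- c(0, 0)
    mi <- M[, i]
    den <- sum(mi^2)
    ci[i] <- if (den > 0) max(0, sum(mi * y) / den) else 0
    cand <- c(cand, list(ci))
  }
  cand <- c(cand, list(c(0, 0)))
  res <- vapply(cand, function(ci) sum((y - drop(M %*% ci))^2), numeric(1))
  cand[[which.min(res)]]
}

#' Estimate Th-227 and Ra-223 activity from window counts
#'
#' Minimises the sum of squared differences between the background-corrected
#' geometric-mean counts in the four acquisition windows and the counts
#' modelled by [model_window_counts()], over the non-negative octant
#' (A_Th, A_Ra, B >= 0). The objective is unweighted across windows by
#' default (an optional Poisson-variance weighting is provided).
#'
#' For fixed B the model is linear in the activities, so the solver profiles
#' them out with an exact two-variable non-negative least squares, scans and
#' then optimises the one-dimensional profile over B, and finally polishes
#' all three parameters with box-constrained quasi-Newton steps seeded from
#' the profile solution and from fixed deterministic starts (primary-only
#' B = 0, B = 1, Ra-only). Ties are broken by lowest residual, then lowest
#' B. Boundary solutions are reported as exact zeros.
#'
#' @param gm_counts Background-corrected geometric-mean counts per window
#'   (numeric(4), window order of `components$windows`).
#' @param duration_s Acquisition duration (s).
#' @param components A [prepare_components()] bundle at the measurement's
#'   thickness.
#' @param weights `NULL` (unweighted, default) or `"poisson"` to weight each
#'   window by 1/max(counts, 1).
#' @return An object of class `"activity_estimate"`: a list with
#'   `a_th227`, `a_ra223` (MBq), `b`, `residual` (sum of squared count
#'   differences), `converged`, `gm_counts`, `fitted`, `windows`.
#' @export
solve_activities <- function(gm_counts, duration_s, components,
                             weights = NULL) {
  stopifnot(length(gm_counts) == nrow(components$windows), duration_s > 0)
  if (any(gm_counts < 0)) abort("gm_counts must be non-negative")
  w <- NULL
  if (identical(weights, "poisson")) w <- 1 / pmax(gm_counts, 1)
  ns_th <- components$nu_th * components$s_th
  ns_ra <- components$nu_ra * components$s_ra
  if (all(gm_counts == 0)) {
    est <- list(a_th227 = 0, a_ra223 = 0, b = 0, residual = 0,
                converged = TRUE)
    return(finish_estimate(est, gm_counts, duration_s, components))
  }

  design <- function(b) {
    duration_s * cbind(components$p_th + b * ns_th,
                       components$p_ra + b * ns_ra)
  }
  objective <- function(par) {
    mod <- duration_s * (par[1] * components$p_th + par[2] * components$p_ra +
      par[3] * (par[1] * ns_th + par[2] * ns_ra))
    r <- gm_counts - mod
    if (is.null(w)) sum(r^2) else sum(w * r^2)
  }
  profile <- function(b) {
    a <- nnls2(design(b), gm_counts, w)
    list(par = c(a, b), value = objective(c(a, b)))
  }

  b_grid <- c(0, 10^seq(-3, 6, length.out = 55))
  prof <- lapply(b_grid, profile)
  vals <- vapply(prof, `[[`, numeric(1), "value")
  i0 <- which.min(vals)
  lo <- b_grid[max(1, i0 - 1)]
  hi <- b_grid[min(length(b_grid), i0 + 1)]
  cand <- prof[i0]
  if (hi > lo) {
    ob <- optimize(function(b) profile(b)$value, c(lo, hi), tol = 1e-10)
    cand <- c(cand, list(profile(ob$minimum)))
  }

  # deterministic polish starts: profile solution plus fixed seeds
  seeds <- unique(c(cand[length(cand)], list(
    profile(0), profile(1),
    list(par = c(0, nnls2(design(0), gm_counts, w)[2], 1), value = NA)
  )))
  converged <- TRUE
  for (s in seeds) {
    fit <- tryCatch(
      optim(pmax(s$par, 0), objective, method = "L-BFGS-B",
            lower = c(0, 0, 0), control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence != 0 && is.na(fit$value)) next
    cand <- c(cand, list(list(par = fit$par, value = fit$value,
                              conv = fit$convergence == 0)))
  }
  vals <- vapply(cand, `[[`, numeric(1), "value")
  bs <- vapply(cand, function(ci) ci$par[3], numeric(1))
  best <- order(vals, bs)[1]
  # prefer an (effectively tied) lower-B solution over a microscopically
  # better polished one so that boundary zeros stay exact
  vtol <- max(vals[best], sum(gm_counts)) * 1e-12
  tied <- which(vals <= vals[best] + vtol)
  best <- tied[which.min(bs[tied])]
  par <- cand[[best]]$par
  par[par < 1e-12 * max(par, 1)] <- 0
  est <- list(a_th227 = par[1], a_ra223 = par[2], b = par[3],
              residual = objective(par), converged = converged)
  finish_estimate(est, gm_counts, duration_s, components)
}

finish_estimate <- function(est, gm_counts, duration_s, components) {
  est$gm_counts <- gm_counts
  est$fitted <- model_window_counts(components, est$a_th227, est$a_ra223,
                                    est$b, duration_s)
  est$duration_s <- duration_s
  est$windows <- components$windows
  structure(est, class = "activity_estimate")
}

#' @export
print.activity_estimate <- function(x, ...) {
  cat(sprintf("<activity_estimate> A_Th227 = %.4g MBq, A_Ra223 = %.4g MBq, B = %.4g\n",
              x$a_th227, x$a_ra223, x$b))
  cat(sprintf("  residual (sum sq counts) = %.4g, converged = %s\n",
              x$residual, x$converged))
  invisible(x)
}

#' Tidy an activity estimate
#'
#' @param x An `activity_estimate`.
#' @param ... Unused.
#' @return `tidy()`: one row per fitted parameter (`term`, `estimate`);
#'   `glance()`: a one-row summary (`residual`, `converged`).
#' @method tidy activity_estimate
#' @export
tidy.activity_estimate <- function(x, ...) {
  tibble(term = c("a_th227", "a_ra223", "b"),
         estimate = c(x$a_th227, x$a_ra223, x$b),
         unit = c("MBq", "MBq", ""))
}

#' @rdname tidy.activity_estimate
#' @method glance activity_estimate
#' @export
glance.activity_estimate <- function(x, ...) {
  tibble(residual = x$residual, converged = x$converged,
         n_windows = nrow(x$windows))
}
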