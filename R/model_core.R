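#' Density-dependent growth/quiescence switch
#'
#' Monotone switch gating the transition from net proliferation to
#' quiescence as the total cell density approaches the carrying capacity.
#' It is the Beta(3, 1) cumulative distribution function of the total
#' density, i.e. `min(u, 1)^3`, so that `delta(0) = 0` and `delta(1) = 1`:
#' sparse populations grow nearly exponentially, saturated ones only
#' transfer cells into the quiescent pool. Values above 1 (transient local
#' overshoot from diffusion influx) saturate at 1.
#'
#' @param u total cell density `p + q` (>= 0); vectorized.
#' @return switch value in `[0, 1]`.
#' @export
#' @examples
#' delta_switch(c(0, 0.5, 1)) # 0, 0.125, 1
delta_switch <- function(u) {
  if (any(u < 0)) stop("total density must be nonnegative", call. = FALSE)
  pmin(u, 1)^3
}

#' Build the spatial coefficient fields for one scenario
#'
#' The model coefficients are piecewise constant over the labeled domain
#' and the tumor segmentations:
#' * diffusivity `D = D_w` in white matter and in any segmented tumorous
#'   region (enhancing, edema or necrotic voxels override gray matter),
#'   `D_w / 2` in remaining gray matter, and exactly 0 in CSF and
#'   background (which yields no-flux interfaces there);
#' * growth rate `rho = log(2) / rhohat1` and quiescence rate
#'   `k = log(2) / khat1` on enhancing voxels;
#' * `rho = log(2) / rhohat0`, `k = log(2) / khat0` on all other brain
#'   tissue. The edema-region values are applied beyond the edema
#'   segmentation itself because cells diffusing into unsegmented tissue
#'   are presumed to be at low, edema-like densities.
#'
#' @param grid a [voxel_grid()].
#' @param study an [imaging_study()] on `grid` (supplies the segmentations).
#' @param params a [model_parameters()].
#' @return object of class `coefficient_fields`: list with per-voxel arrays
#'   `D` (mm^2/day), `rho`, `k` (1/day), plus `spacing` and `dims`.
#' @export
build_coefficients <- function(grid, study, params) {
  stopifnot(inherits(grid, "voxel_grid"),
            inherits(study, "imaging_study"),
            inherits(params, "model_parameters"))
  stopifnot_same_dims(study$grid$labels, grid$labels, "study vs grid")
  codes <- label_codes()
  labels <- grid$labels
  tumor <- study$enhancing | study$edema
  if (!is.null(study$necrotic)) tumor <- tumor | study$necrotic

  D <- array(0, dim = grid$dims)
  D[labels == codes[["WHITE"]]] <- params$D_w
  D[labels == codes[["GRAY"]]] <- params$D_w / 2
  D[tumor] <- params$D_w
  D[labels == codes[["CSF"]] | labels == codes[["BACKGROUND"]]] <- 0

  tissue <- tissue_mask(grid)
  rho <- array(0, dim = grid$dims)
  k <- array(0, dim = grid$dims)
  rho[tissue] <- rate_from_time(params$rhohat0)
  k[tissue] <- rate_from_time(params$khat0)
  enh <- study$enhancing & tissue
  rho[enh] <- rate_from_time(params$rhohat1)
  k[enh] <- rate_from_time(params$khat1)

  structure(
    list(D = D, rho = rho, k = k, spacing = grid$spacing, dims = grid$dims),
    class = "coefficient_fields"
  )
}

#' Impute the initial cell-density state from image intensities
#'
#' Initial tumor cell densities are ascribed from the segmentations using
#' an approximately linear intensity-density relationship: within the
#' enhancing mask, T1 post-contrast intensities are min-max normalized over
#' the mask to `s` in `[0, 1]` and the proliferating density is set to
#' `I_c[1] + s * (I_c[2] - I_c[1])` (density increases with T1C intensity);
#' within the edema mask, T2/FLAIR intensities are normalized likewise and
#' the density decreases with intensity: `I_e[2] - s * (I_e[2] - I_e[1])`.
#' A constant-intensity mask maps to the window midpoint. All imputed
#' density starts in the proliferating compartment; necrotic-core voxels
#' instead get `p = 0` and a dense quiescent population `q = q_core`
#' (necrosis is T1-hypointense, so the core must never re-classify as
#' enhancing: the default 0.9 exceeds every default scenario's `I_c` upper
#' bound). Everywhere else `p = q = 0`.
#'
#' @param study an [imaging_study()] with a nonempty enhancing mask.
#' @param params a [model_parameters()].
#' @param q_core quiescent density assigned to necrotic-core voxels.
#' @return object of class `state_fields`: list with arrays `p`, `q` and
#'   elapsed time `t = 0` (days).
#' @export
impute_initial_state <- function(study, params, q_core = 0.9) {
  stopifnot(inherits(study, "imaging_study"),
            inherits(params, "model_parameters"))
  if (sum(study$enhancing) == 0L)
    stop("empty enhancing mask: no tumor to simulate", call. = FALSE)
  dims <- study$grid$dims
  p <- array(0, dim = dims)
  q <- array(0, dim = dims)

  minmax <- function(v) {
    r <- range(v)
    if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else rep(0.5, length(v))
  }
  s_c <- minmax(study$t1c[study$enhancing])
  p[study$enhancing] <- params$I_c[1] + s_c * diff(params$I_c)
  if (sum(study$edema) > 0L) {
    s_e <- minmax(study$t2[study$edema])
    p[study$edema] <- params$I_e[2] - s_e * diff(params$I_e)
  }
  if (!is.null(study$necrotic) && sum(study$necrotic) > 0L) {
    p[study$necrotic] <- 0
    q[study$necrotic] <- q_core
  }
  structure(list(p = p, q = q, t = 0), class = "state_fields")
}

#' Divergence of the diffusive flux on the voxel grid
#'
#' Second-order finite-volume discretization of `div(D grad(field))` on the
#' anisotropic voxel grid. The diffusivity on each face between neighboring
#' voxels is the harmonic mean of the two voxel values (zero whenever
#' either is zero), which makes CSF/background interfaces no-flux without
#' explicit boundary bookkeeping; grid edges are no-flux. The scheme
#' conserves total mass exactly: every face flux enters the two adjacent
#' voxels with opposite signs.
#'
#' @param field numeric 3-D density array.
#' @param D per-voxel diffusivity array (mm^2/day), same dims.
#' @param spacing mm triple.
#' @return per-voxel rate array (density/day).
#' @export
diffusion_divergence <- function(field, D, spacing) {
  stopifnot_same_dims(field, D, "field vs D")
  dims <- dim(field)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  out <- array(0, dim = dims)
  harmonic <- function(a, b) {
    s <- a + b
    f <- 2 * a * b
    f[s > 0] <- f[s > 0] / s[s > 0]
    f
  }
  if (nx >= 2L) {
    h <- spacing[1]
    Df <- harmonic(D[-nx, , , drop = FALSE], D[-1, , , drop = FALSE])
    flux <- Df * (field[-1, , , drop = FALSE] -
                    field[-nx, , , drop = FALSE]) / h^2
    out[-nx, , ] <- out[-nx, , , drop = FALSE] + flux
    out[-1, , ] <- out[-1, , , drop = FALSE] - flux
  }
  if (ny >= 2L) {
    h <- spacing[2]
    Df <- harmonic(D[, -ny, , drop = FALSE], D[, -1, , drop = FALSE])
    flux <- Df * (field[, -1, , drop = FALSE] -
                    field[, -ny, , drop = FALSE]) / h^2
    out[, -ny, ] <- out[, -ny, , drop = FALSE] + flux
    out[, -1, ] <- out[, -1, , drop = FALSE] - flux
  }
  if (nz >= 2L) {
    h <- spacing[3]
    Df <- harmonic(D[, , -nz, drop = FALSE], D[, , -1, drop = FALSE])
    flux <- Df * (field[, , -1, drop = FALSE] -
                    field[, , -nz, drop = FALSE]) / h^2
    out[, , -nz] <- out[, , -nz, drop = FALSE] + flux
    out[, , -1] <- out[, , -1, drop = FALSE] - flux
  }
  out
}

#' Reaction terms of the two-compartment model
#'
#' Pointwise growth and quiescence kinetics: proliferating cells grow at
#' per-capita rate `rho * (1 - delta(p + q))` and become quiescent at rate
#' `k * delta(p + q)`, where `delta` is the density switch
#' ([delta_switch()]). Quiescent cells only accumulate. At low total
#' density growth is nearly exponential (`dp ~ rho * p`); at carrying
#' capacity the reaction is a pure transfer `p -> q` conserving the total.
#'
#' @param p,q nonnegative density arrays.
#' @param rho,k per-voxel maximum growth and quiescence rates (1/day).
#' @return list with `dp_react` and `dq_react` (density/day).
#' @export
reaction_rates <- function(p, q, rho, k) {
  if (any(p < 0) || any(q < 0))
    stop("densities must be nonnegative", call. = FALSE)
  dlt <- delta_switch(p + q)
  h <- k * p * dlt
  list(dp_react = rho * p * (1 - dlt) - h, dq_react = h)
}

#' Solver options
#'
#' Error-control settings for the adaptive explicit stabilized
#' (Runge-Kutta-Chebyshev) time integrator. Correctness is defined by
#' tolerance robustness (halving `rel_tol` changes virtual segmentation
#' counts by well under 0.5%), not by any particular internal step
#' sequence.
#'
#' @param rel_tol,abs_tol relative and absolute error tolerances.
#' @param max_step_days upper bound on the time step (days).
#' @param checkpoint_days optional increasing numeric vector of times
#'   (days) at which intermediate states are saved.
#' @return object of class `solver_options`.
#' @export
solver_options <- function(rel_tol = 1e-4, abs_tol = 1e-7,
                           max_step_days = 1, checkpoint_days = NULL) {
  if (rel_tol <= 0 || abs_tol <= 0 || max_step_days <= 0)
    stop("tolerances and max_step_days must be positive", call. = FALSE)
  if (!is.null(checkpoint_days)) {
    checkpoint_days <- sort(unique(as.numeric(checkpoint_days)))
    if (any(checkpoint_days <= 0))
      stop("checkpoint_days must be positive", call. = FALSE)
  }
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol,
                 max_step_days = max_step_days,
                 checkpoint_days = checkpoint_days),
            class = "solver_options")
}

# right-hand side of the PDE system; evaluates reactions on densities
# clamped to [0, Inf) so tiny explicit-scheme undershoots cannot feed back
rhs_fields <- function(p, q, coeffs) {
  pp <- pmax(p, 0)
  u <- pmax(p + q, 0)
  dlt <- pmin(u, 1)^3
  h <- coeffs$k * pp * dlt
  dp <- diffusion_divergence(p, coeffs$D, coeffs$spacing) +
    coeffs$rho * pp * (1 - dlt) - h
  list(dp = dp, dq = h)
}

# conservative upper bound on the spectral radius of the semi-discrete
# operator: Gershgorin bound for the diffusion stencil plus a bound on the
# reaction Jacobian (|d(dp)/dp| <= 4 (rho + k) since |delta'| <= 3)
spectral_radius_bound <- function(coeffs) {
  maxD <- max(coeffs$D)
  4 * maxD * sum(1 / coeffs$spacing^2) + 4 * max(coeffs$rho + coeffs$k)
}

# damped second-order Runge-Kutta-Chebyshev coefficients for s stages
rkc_coefficients <- function(s) {
  eps <- 2 / 13
  w0 <- 1 + eps / s^2
  jj <- 0:s
  Tj <- numeric(s + 1); dT <- numeric(s + 1); ddT <- numeric(s + 1)
  Tj[1] <- 1; Tj[2] <- w0
  dT[1] <- 0; dT[2] <- 1
  ddT[1] <- 0; ddT[2] <- 0
  for (j in 2:s) {
    Tj[j + 1] <- 2 * w0 * Tj[j] - Tj[j - 1]
    dT[j + 1] <- 2 * Tj[j] + 2 * w0 * dT[j] - dT[j - 1]
    ddT[j + 1] <- 4 * dT[j] + 2 * w0 * ddT[j] - ddT[j - 1]
  }
  w1 <- dT[s + 1] / ddT[s + 1]
  b <- numeric(s + 1)
  for (j in 2:s) b[j + 1] <- ddT[j + 1] / dT[j + 1]^2
  b[1] <- b[3]; b[2] <- b[3]
  a <- 1 - b * Tj
  list(w0 = w0, w1 = w1, b = b, a = a)
}

#' Integrate the growth model over an imaging interval
#'
#' Advances the proliferating/quiescent density fields by `days` using an
#' adaptive second-order Runge-Kutta-Chebyshev (RKC) scheme: an explicit
#' stabilized method whose extended real stability interval suits the
#' mildly stiff diffusion operator. The stage count per step is chosen from
#' a conservative spectral-radius bound; step size is controlled by the
#' standard embedded second-order error estimate against
#' `abs_tol + rel_tol * |state|`. The model has no stochastic components:
#' results are deterministic for fixed inputs and tolerances.
#'
#' Densities within the numerical positivity band `[-1e-9, 0)` are zeroed
#' at the end of each accepted step; any value below `-1e-9` aborts with an
#' error (reported, never silently clipped).
#'
#' @param state a `state_fields` (see [impute_initial_state()]).
#' @param coeffs a `coefficient_fields` (see [build_coefficients()]).
#' @param days simulation horizon in days (> 0).
#' @param opts a [solver_options()].
#' @return a `state_fields` at `t = state$t + days`; if
#'   `opts$checkpoint_days` is set, the attribute `"checkpoints"` holds a
#'   list of intermediate `state_fields`.
#' @export
simulate_growth <- function(state, coeffs, days, opts = solver_options()) {
  stopifnot(inherits(coeffs, "coefficient_fields"))
  if (!is.finite(days) || days <= 0)
    stop("days must be positive", call. = FALSE)
  p <- state$p; q <- state$q
  stopifnot_same_dims(p, coeffs$D, "state vs coefficients")

  sr <- spectral_radius_bound(coeffs)
  t_end <- days
  t <- 0
  # save times: checkpoints (relative to state$t) then the horizon
  cps <- opts$checkpoint_days
  cps <- cps[cps < t_end]
  stops <- sort(unique(c(cps, t_end)))
  checkpoints <- list()

  hmax <- min(opts$max_step_days, t_end)
  h <- min(hmax, max(1e-4, 0.1 / max(sr, 1e-12)))
  f <- rhs_fields(p, q, coeffs)
  uround <- .Machine$double.eps
  nfail_row <- 0L

  for (t_stop in stops) {
    while (t < t_stop - 1e-12 * t_end) {
      h <- min(h, t_stop - t)
      s <- max(2L, ceiling(sqrt(h * sr / 0.653) + 1e-12))
      cf <- rkc_coefficients(s)
      # stage recursion on both fields
      mu1t <- cf$b[2] * cf$w1
      Yp0 <- p; Yq0 <- q
      Yp1 <- p + mu1t * h * f$dp
      Yq1 <- q + mu1t * h * f$dq
      for (j in 2:s) {
        bj <- cf$b[j + 1]; bjm1 <- cf$b[j]; bjm2 <- cf$b[j - 1]
        mu <- 2 * bj * cf$w0 / bjm1
        nu <- -bj / bjm2
        mut <- 2 * bj * cf$w1 / bjm1
        gt <- -cf$a[j] * mut
        fj <- rhs_fields(Yp1, Yq1, coeffs)
        Yp2 <- (1 - mu - nu) * p + mu * Yp1 + nu * Yp0 +
          mut * h * fj$dp + gt * h * f$dp
        Yq2 <- (1 - mu - nu) * q + mu * Yq1 + nu * Yq0 +
          mut * h * fj$dq + gt * h * f$dq
        Yp0 <- Yp1; Yq0 <- Yq1
        Yp1 <- Yp2; Yq1 <- Yq2
      }
      f_new <- rhs_fields(Yp1, Yq1, coeffs)
      # embedded second-order error estimate
      est_p <- 0.8 * (p - Yp1) + 0.4 * h * (f$dp + f_new$dp)
      est_q <- 0.8 * (q - Yq1) + 0.4 * h * (f$dq + f_new$dq)
      sc_p <- opts$abs_tol + opts$rel_tol * pmax(abs(p), abs(Yp1))
      sc_q <- opts$abs_tol + opts$rel_tol * pmax(abs(q), abs(Yq1))
      err <- sqrt((sum((est_p / sc_p)^2) + sum((est_q / sc_q)^2)) /
                    (2 * length(p)))
      if (err <= 1 || h <= 16 * uround * max(t, 1)) {
        # accept
        t <- t + h
        mn <- min(min(Yp1), min(Yq1))
        if (mn < -1e-9)
          stop(sprintf(
            "positivity violation: density %.3e below tolerance -1e-9 at t = %.4g d",
            mn, state$t + t), call. = FALSE)
        Yp1[Yp1 < 0] <- 0
        Yq1[Yq1 < 0] <- 0
        p <- Yp1; q <- Yq1
        f <- rhs_fields(p, q, coeffs)
        fac <- 0.8 * err^(-1 / 3)
        h <- h * min(10, max(0.1, fac))
        h <- min(h, hmax)
        nfail_row <- 0L
      } else {
        nfail_row <- nfail_row + 1L
        if (nfail_row > 50L)
          stop("integrator failed to meet the error tolerance", call. = FALSE)
        h <- h * max(0.1, 0.8 * err^(-1 / 3))
      }
    }
    t <- t_stop
    if (t_stop < t_end) {
      checkpoints[[length(checkpoints) + 1L]] <-
        structure(list(p = p, q = q, t = state$t + t_stop),
                  class = "state_fields")
    }
  }

  out <- structure(list(p = p, q = q, t = state$t + days),
                   class = "state_fields")
  if (!is.null(opts$checkpoint_days)) {
    checkpoints[[length(checkpoints) + 1L]] <- out
    attr(out, "checkpoints") <- checkpoints
  }
  out
}

#' @export
print.state_fields <- function(x, ...) {
  cat(sprintf(
    "<state_fields> t = %g d, total p = %.4g, total q = %.4g, max p+q = %.4g\n",
    x$t, sum(x$p), sum(x$q), max(x$p + x$q)))
  invisible(x)
}
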