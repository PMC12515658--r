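# run code with a local RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Phantom specification
#'
#' Geometry and noise settings for the synthetic tumor studies. The tumor
#' is a set of concentric spherical shells (in physical mm, so anisotropic
#' voxels are handled correctly): an optional necrotic core, a
#' contrast-enhancing rim, and an edema halo, which must be strictly
#' nested. Defaults mirror clinical surveillance geometry: ~0.9 mm
#' in-plane resolution with 7 mm axial slices.
#'
#' @param dims integer triple of grid dimensions (each >= 8).
#' @param spacing mm triple (in-plane, in-plane, slice).
#' @param tumor_center voxel index triple, or `NULL` to place the tumor in
#'   white matter offset from the grid center.
#' @param rim_radius_mm outer radius of the enhancing rim.
#' @param edema_radius_mm outer radius of the edema halo.
#' @param necrotic_radius_mm radius of the necrotic core (0 = none).
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (intensities are clipped at 0; segmentation masks are noise-free).
#' @param seed integer RNG seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(48L, 48L, 10L),
                         spacing = c(0.9, 0.9, 7.0),
                         tumor_center = NULL,
                         rim_radius_mm = 6,
                         edema_radius_mm = 12,
                         necrotic_radius_mm = 2,
                         noise_sd = 0.02,
                         seed = 1L) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 8L))
    stop("dims must be three integers, each >= 8", call. = FALSE)
  if (!(necrotic_radius_mm < rim_radius_mm &&
        rim_radius_mm < edema_radius_mm))
    stop("tumor shells must be strictly nested: necrotic < rim < edema radius",
         call. = FALSE)
  if (necrotic_radius_mm < 0 || noise_sd < 0)
    stop("necrotic_radius_mm and noise_sd must be nonnegative", call. = FALSE)
  structure(
    list(dims = dims, spacing = as.numeric(spacing),
         tumor_center = tumor_center,
         rim_radius_mm = rim_radius_mm,
         edema_radius_mm = edema_radius_mm,
         necrotic_radius_mm = necrotic_radius_mm,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Generate a synthetic layered brain domain
#'
#' Builds a concentric-ellipsoid brain in index space: BACKGROUND outside
#' the outer shell, a GRAY cortical shell, a WHITE interior, and (when the
#' grid is large enough) two CSF ellipsoids emulating the lateral
#' ventricles inside the white matter.
#'
#' @param dims integer triple, each >= 8.
#' @param spacing mm triple.
#' @return a [voxel_grid()].
#' @export
make_brain_grid <- function(dims = c(48L, 48L, 10L),
                            spacing = c(0.9, 0.9, 7.0)) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 8L))
    stop("dims must be three integers, each >= 8 (too small to host all tissue layers)",
         call. = FALSE)
  codes <- label_codes()
  ctr <- (dims + 1) / 2
  semi <- dims / 2 - 0.5
  x <- (seq_len(dims[1]) - ctr[1]) / semi[1]
  y <- (seq_len(dims[2]) - ctr[2]) / semi[2]
  z <- (seq_len(dims[3]) - ctr[3]) / semi[3]
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  labels <- array(codes[["BACKGROUND"]], dim = dims)
  labels[r2 <= 1] <- codes[["GRAY"]]
  labels[r2 <= 0.82^2] <- codes[["WHITE"]]
  # paired ventricles: CSF ellipsoids inside the white matter, elongated
  # axially so they survive thick-slice grids
  vr <- c(0.13, 0.18, 0.45)
  for (sgn in c(-1, 1)) {
    vc <- c(sgn * 0.28, -0.08, 0)
    v2 <- outer(outer(((x - vc[1]) / vr[1])^2, ((y - vc[2]) / vr[2])^2, `+`),
                ((z - vc[3]) / vr[3])^2, `+`)
    vent <- v2 <= 1 & labels == codes[["WHITE"]]
    labels[vent] <- codes[["CSF"]]
  }
  voxel_grid(labels, spacing)
}

# physical distance (mm) of every voxel from a center voxel
radial_distance_mm <- function(dims, spacing, center) {
  dx2 <- ((seq_len(dims[1]) - center[1]) * spacing[1])^2
  dy2 <- ((seq_len(dims[2]) - center[2]) * spacing[2])^2
  dz2 <- ((seq_len(dims[3]) - center[3]) * spacing[3])^2
  sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
}

# default tumor placement: offset from the grid center, inside white matter
default_tumor_center <- function(grid) {
  codes <- label_codes()
  cand <- round(grid$dims * c(0.62, 0.60, 0.5))
  cand <- pmax(pmin(cand, grid$dims), 1L)
  if (grid$labels[cand[1], cand[2], cand[3]] == codes[["WHITE"]])
    return(cand)
  # fall back to the white-matter voxel closest to the candidate
  w <- which(grid$labels == codes[["WHITE"]], arr.ind = TRUE)
  d <- sweep(w, 2, cand)
  w[which.min(rowSums(d^2)), ]
}

#' Generate a synthetic baseline tumor study
#'
#' Builds a baseline [imaging_study()] on `grid` with a spherical tumor:
#' an optional necrotic core, a contrast-enhancing rim, and an edema halo
#' (segmentation masks are intersected with brain tissue and are disjoint
#' by construction). A ground-truth density field spanning `params$I_c`
#' (radially decreasing across the rim) and `params$I_e` (decreasing across
#' the halo) is chosen, and intensities are synthesized by the exact
#' inverse of the linear intensity-density maps used by
#' [impute_initial_state()]: with `noise_sd = 0`, imputation recovers the
#' ground-truth field exactly. The ground truth is attached as the study's
#' `truth` field.
#'
#' @param grid a [voxel_grid()] (e.g. from [make_brain_grid()]).
#' @param spec a [phantom_spec()].
#' @param params a [model_parameters()] supplying the density windows.
#' @return an [imaging_study()] at day 0 with `truth` attached.
#' @export
make_baseline_study <- function(grid, spec, params) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(spec, "phantom_spec"),
            inherits(params, "model_parameters"))
  codes <- label_codes()
  center <- spec$tumor_center
  if (is.null(center)) center <- default_tumor_center(grid)
  r <- radial_distance_mm(grid$dims, grid$spacing, center)
  tissue <- tissue_mask(grid)

  ball <- r <= spec$edema_radius_mm
  if (any(ball & grid$labels == codes[["BACKGROUND"]]))
    stop("tumor shells extend outside the brain: move the center or shrink the radii",
         call. = FALSE)

  necrotic <- NULL
  if (spec$necrotic_radius_mm > 0)
    necrotic <- r <= spec$necrotic_radius_mm & tissue
  enhancing <- r <= spec$rim_radius_mm & tissue
  if (!is.null(necrotic)) enhancing <- enhancing & !necrotic
  else enhancing <- enhancing
  edema <- r > spec$rim_radius_mm & r <= spec$edema_radius_mm & tissue
  if (sum(enhancing) == 0L)
    stop("phantom enhancing rim is empty on this grid", call. = FALSE)

  minmax <- function(v) {
    rg <- range(v)
    if (rg[2] > rg[1]) (v - rg[1]) / (rg[2] - rg[1]) else rep(0.5, length(v))
  }
  truth <- array(0, dim = grid$dims)
  # enhancing rim: density falls with distance from the core, spanning I_c
  s_c <- minmax(spec$rim_radius_mm - r[enhancing])
  truth[enhancing] <- params$I_c[1] + s_c * diff(params$I_c)
  # edema halo: density falls outward, spanning I_e
  s_e <- if (sum(edema) > 0) minmax(spec$edema_radius_mm - r[edema]) else numeric(0)
  truth[edema] <- params$I_e[1] + s_e * diff(params$I_e)

  t1c <- array(0, dim = grid$dims)
  t2 <- array(0, dim = grid$dims)
  t1c[tissue] <- 0.15
  t2[tissue] <- 0.15
  t1c[enhancing] <- 0.2 + 0.8 * s_c          # increases with density
  if (!is.null(necrotic)) t1c[necrotic] <- 0.05  # hypointense core
  t2[edema] <- 0.2 + 0.8 * (1 - s_e)          # decreases with density
  if (spec$noise_sd > 0) {
    with_local_seed(spec$seed, {
      t1c <- pmax(t1c + stats::rnorm(length(t1c), sd = spec$noise_sd), 0)
      t2 <- pmax(t2 + stats::rnorm(length(t2), sd = spec$noise_sd), 0)
    })
    dim(t1c) <- grid$dims
    dim(t2) <- grid$dims
  }

  imaging_study(grid, t1c = t1c, t2 = t2, enhancing = enhancing,
                edema = edema, necrotic = necrotic, day = 0L, truth = truth)
}

#' Generate a follow-up study by simulating forward
#'
#' Ground-truth pair generator: imputes the initial state from `baseline`,
#' integrates the growth model for `days`, virtually re-segments the final
#' density field with the same scenario's windows, and emits a follow-up
#' study whose masks are the simulated segmentations and whose intensities
#' re-encode the simulated density through the inverse linear
#' intensity-density maps. Voxels whose total density exceeds the `I_c`
#' upper bound are emitted as the necrotic mask (dense quiescent tissue is
#' T1-hypointense). The model has no stochastic components, so the output
#' is deterministic.
#'
#' @param baseline an [imaging_study()] (typically [make_baseline_study()]).
#' @param params the generating [model_parameters()].
#' @param days inter-scan interval in days (`0` returns the virtual
#'   re-segmentation of the imputed baseline state).
#' @param opts a [solver_options()].
#' @return an [imaging_study()] at day `baseline$day + days`, with the
#'   simulated total density attached as `truth`.
#' @export
make_followup_by_simulation <- function(baseline, params, days,
                                        opts = solver_options()) {
  stopifnot(inherits(baseline, "imaging_study"),
            inherits(params, "model_parameters"))
  grid <- baseline$grid
  state <- impute_initial_state(baseline, params)
  if (days > 0) {
    coeffs <- build_coefficients(grid, baseline, params)
    state <- simulate_growth(state, coeffs, days, opts)
  }
  masks <- classify_state(state, params)
  total <- state$p + state$q
  tissue <- tissue_mask(grid)
  necrotic <- total > params$I_c[2] & tissue
  if (sum(necrotic) == 0L) necrotic <- NULL

  t1c <- array(0, dim = grid$dims)
  t2 <- array(0, dim = grid$dims)
  t1c[tissue] <- 0.15
  t2[tissue] <- 0.15
  if (sum(masks$enhancing) > 0) {
    s_c <- (total[masks$enhancing] - params$I_c[1]) / diff(params$I_c)
    t1c[masks$enhancing] <- 0.2 + 0.8 * s_c
  }
  if (!is.null(necrotic)) t1c[necrotic] <- 0.05
  if (sum(masks$edema) > 0) {
    s_e <- (total[masks$edema] - params$I_e[1]) / diff(params$I_e)
    t2[masks$edema] <- 0.2 + 0.8 * (1 - s_e)
  }
  imaging_study(grid, t1c = t1c, t2 = t2, enhancing = masks$enhancing,
                edema = masks$edema, necrotic = necrotic,
                day = baseline$day + as.integer(round(days)), truth = total)
}
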