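# shared fixtures: everything is generated in code at test time

# tumor radii scaled so the shells fit inside the brain ellipsoid at the
# given grid size
phantom_fixture <- function(dims = c(32L, 32L, 8L), noise_sd = 0,
                            seed = 1L, necrotic = TRUE) {
  radii <- if (dims[1] >= 48) c(2, 6, 12) else c(1.5, 4, 8)
  grid <- make_brain_grid(dims)
  spec <- phantom_spec(
    dims = dims,
    necrotic_radius_mm = if (necrotic) radii[1] else 0,
    rim_radius_mm = radii[2], edema_radius_mm = radii[3],
    noise_sd = noise_sd, seed = seed
  )
  list(grid = grid, spec = spec)
}

# bare state constructor for hand-built fields
make_state <- function(p, q = array(0, dim = dim(p)), t = 0) {
  structure(list(p = p, q = q, t = t), class = "state_fields")
}

# all-white-matter grid: diffusion vanishes for uniform fields, so the PDE
# reduces voxelwise to the well-mixed two-compartment ODE
uniform_white_grid <- function(dims = c(6L, 6L, 3L),
                               spacing = c(0.9, 0.9, 7)) {
  voxel_grid(array(label_codes()[["WHITE"]], dim = dims), spacing)
}

# study whose every voxel is "enhancing": coefficients then take the
# enhancing-region rates everywhere
uniform_enhancing_study <- function(grid) {
  d <- grid$dims
  imaging_study(grid,
                t1c = array(0.5, d), t2 = array(0.5, d),
                enhancing = array(TRUE, d), edema = array(FALSE, d),
                day = 0L)
}

# independent well-mixed oracle: high-accuracy integration of the
# two-compartment kinetics with deSolve
oracle_well_mixed <- function(p0, q0, rho, k, days) {
  fn <- function(t, y, parms) {
    d <- min(max(y[1] + y[2], 0), 1)^3
    list(c(rho * y[1] * (1 - d) - k * y[1] * d, k * y[1] * d))
  }
  sol <- deSolve::ode(c(p = p0, q = q0), c(0, days), fn, NULL,
                      rtol = 1e-10, atol = 1e-12)
  c(p = unname(sol[2, "p"]), q = unname(sol[2, "q"]))
}
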