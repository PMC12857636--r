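# shared helpers: small deterministic inputs built in code

# a harmonic-well calculator handle for the adapter tests
harmonic_handle <- function(k = 3) {
  list(name = "harmonic",
       energy = function(s) 0.5 * k * sum(s$coords^2),
       forces = function(s) -k * s$coords)
}

# relaxed endpoint pair of a benchmark surface
surface_endpoints <- function(name) {
  sf <- benchmark_surface(name)
  ends <- rotapath:::benchmark_minima(name)
  list(surface = sf,
       a = point_structure(ends$a, "reactant"),
       b = point_structure(ends$b, "product"))
}

# quick converged CI-NEB on the Muller-Brown surface (shared by several
# tests; cached per session)
mb_converged_band <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ep <- surface_endpoints("muller_brown")
      band <- interpolate_linear(ep$a, ep$b, 21)
      cache <<- optimize_band(band, ep$surface$model,
                              neb_config(n_images = 21, max_steps = 2000,
                                         max_step = 0.1))
    }
    cache
  }
})

# dense-grid Muller-Brown oracle: energies on an nx x ny grid over the
# standard domain, plus the watershed (flooding) saddle energy between two
# basins found by bisection on the sub-level-set connectivity
mb_grid <- function(n = 2000) {
  gx <- seq(-1.8, 1.2, length.out = n)
  gy <- seq(-0.5, 2.2, length.out = n)
  list(gx = gx, gy = gy, E = outer(gx, gy, muller_brown_energy))
}

mb_flood_saddle <- function(grid, p_a, p_b, tol = 1e-8) {
  ia <- c(which.min(abs(grid$gx - p_a[1])), which.min(abs(grid$gy - p_a[2])))
  ib <- c(which.min(abs(grid$gx - p_b[1])), which.min(abs(grid$gy - p_b[2])))
  lo <- max(grid$E[ia[1], ia[2]], grid$E[ib[1], ib[2]])
  hi <- max(grid$E[grid$E < 1e6])
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    lab <- EBImage::bwlabel(EBImage::Image(grid$E <= mid))
    if (lab[ia[1], ia[2]] != 0 && lab[ia[1], ia[2]] == lab[ib[1], ib[2]]) {
      hi <- mid
    } else {
      lo <- mid
    }
  }
  hi
}

# analytic scalar field rho = exp(-2 r) (a.u.) on a small grid, with its
# exact gradient attached; used as an independent density fixture
exponential_density_field <- function(spacing = 0.08, extent = 2.5) {
  ab <- 1.8897261254578281
  g <- seq(-extent, extent, spacing)         # bohr
  f <- scalar_field(rep(-extent / ab, 3), spacing / ab, rep(length(g), 3),
                    numeric(length(g)^3), "density")
  pts <- grid_points(f) * ab
  r <- pmax(sqrt(rowSums(pts^2)), 1e-10)
  f$values <- exp(-2 * r)
  f$gradient <- -2 * exp(-2 * r) * pts / r
  f
}

# 3D gaussian blob density values at grid points (bohr), unit charge
gaussian_blob <- function(pts_bohr, center, sigma = 0.3) {
  r2 <- rowSums(sweep(pts_bohr, 2, center)^2)
  exp(-r2 / (2 * sigma^2)) / (sigma^3 * (2 * pi)^1.5)
}
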