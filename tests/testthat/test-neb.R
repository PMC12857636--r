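test_that("linear interpolation spaces images evenly and keeps endpoints", {
  a <- structure3d("X", matrix(c(0, 0, 0), 1, 3))
  b <- structure3d("X", matrix(c(1, 0, 0), 1, 3))
  band <- interpolate_linear(a, b, 3)
  expect_equal(vapply(band$images, function(s) s$coords[1, 1], numeric(1)),
               c(0, 0.25, 0.5, 0.75, 1))
  expect_identical(band$images[[1]]$coords, a$coords)
  expect_identical(band$images[[5]]$coords, b$coords)
  expect_length(interpolate_linear(a, b, 125)$images, 127)
  expect_error(interpolate_linear(a, a, 3), "degenerate-path")
  expect_error(
    interpolate_linear(a, structure3d("C", matrix(1, 1, 3)), 3),
    "composition"
  )
})

test_that("improved tangents follow the uphill neighbour and blend at extrema", {
  mk <- function(xs, es) {
    neb_band(lapply(xs, function(x) structure3d("X", matrix(c(x, 0, 0), 1, 3))),
             energies = es)
  }
  # monotone energies on a collinear band: tangents point along the step
  band <- mk(c(0, 1, 2, 3), c(0, 1, 2, 3))
  tau <- compute_tangents(band)
  for (t in tau) expect_equal(t, matrix(c(1, 0, 0), 1, 3))
  # energy maximum: energy-weighted blend of both neighbour vectors
  band2 <- mk(c(0, 1, 3), c(0, 5, 2))
  tau2 <- compute_tangents(band2)
  dmax <- max(abs(2 - 5), abs(0 - 5)); dmin <- min(abs(2 - 5), abs(0 - 5))
  # E[next] > E[prev] so the forward vector takes the large weight
  blend <- c(2, 0, 0) * dmax + c(1, 0, 0) * dmin
  expect_equal(tau2[[2]], matrix(blend / sqrt(sum(blend^2)), 1, 3))
  # unit norm on random bands
  set.seed(3)
  for (rep in 1:5) {
    xs <- cumsum(runif(6, 0.5, 1.5))
    band3 <- mk(xs, rnorm(6))
    for (t in compute_tangents(band3)) {
      expect_equal(sqrt(sum(t^2)), 1, tolerance = 1e-12)
    }
  }
  expect_error(compute_tangents(mk(c(0, 1, 2), NULL)), "energies")
})

test_that("chain forces vanish on a flat potential at equal spacing", {
  flat <- potential_model("flat", function(s) 0, function(s) 0 * s$coords)
  xs <- c(0, 1, 2, 3, 4)
  band <- neb_band(lapply(xs, function(x)
    structure3d("X", matrix(c(x, 0, 0), 1, 3))))
  band <- rotapath:::evaluate_band(band, flat)
  nf <- neb_forces(band, neb_config(n_images = 3), climbing_on = FALSE)
  for (f in nf$forces) expect_lt(max(abs(f)), 1e-14)
})

test_that("spring forces pull unequally spaced images toward equal spacing", {
  flat <- potential_model("flat", function(s) 0, function(s) 0 * s$coords)
  k <- 0.1
  band <- neb_band(lapply(c(0, 0.5, 3), function(x)
    structure3d("X", matrix(c(x, 0, 0), 1, 3))))
  band <- rotapath:::evaluate_band(band, flat)
  nf <- neb_forces(band, neb_config(n_images = 1, spring_k = k),
                   climbing_on = FALSE)
  # |d_next| = 2.5, |d_prev| = 0.5: force + along tangent (+x)
  expect_equal(nf$forces[[2]][1, 1], k * (2.5 - 0.5))
  expect_equal(nf$forces[[2]][1, 2:3], c(0, 0))
})

test_that("climbing-image force is zero at an exact saddle", {
  sf <- benchmark_surface("double_well_1d")
  xs <- c(-1, 0, 1)
  band <- neb_band(lapply(xs, function(x) point_structure(x)))
  band <- rotapath:::evaluate_band(band, sf$model)
  nf <- neb_forces(band, neb_config(n_images = 1), climbing_on = TRUE)
  expect_equal(nf$climbing_index, 2L)
  expect_lt(max(abs(nf$forces[[2]])), 1e-12)
})

test_that("string redistribution equalises arc lengths and fixes endpoints", {
  set.seed(5)
  X <- lapply(seq(0, 1, length.out = 9), function(t) {
    matrix(c(t, t^2, 0), 1, 3) + if (t %in% c(0, 1)) 0 else
      matrix(c(0, rnorm(1, sd = 0.05), 0), 1, 3)
  })
  Y <- rotapath:::reparameterize_equal_arc(X)
  expect_identical(Y[[1]], X[[1]])
  expect_identical(Y[[9]], X[[9]])
  seg <- vapply(2:9, function(i) sqrt(sum((Y[[i]] - Y[[i - 1]])^2)),
                numeric(1))
  expect_lt(max(abs(seg - mean(seg))) / mean(seg), 1e-8)
})

test_that("CI-NEB resolves the quartic double-well saddle", {
  sf <- benchmark_surface("double_well_1d")
  band <- interpolate_linear(point_structure(-1), point_structure(1), 11)
  out <- optimize_band(band, sf$model, neb_config(n_images = 11,
                                                  max_steps = 300))
  rep <- attr(out, "report")
  expect_true(rep$converged)
  expect_lt(abs(out$images[[out$climbing_index]]$coords[1, 1]), 1e-3)
  expect_lt(abs(band_barrier(out) - 1), 1e-3)
})

test_that("band optimization reports non-convergence instead of hiding it", {
  sf <- benchmark_surface("muller_brown")
  ep <- surface_endpoints("muller_brown")
  band <- interpolate_linear(ep$a, ep$b, 15)
  expect_warning(
    out <- optimize_band(band, sf$model,
                         neb_config(n_images = 15, max_steps = 3)),
    "not converged"
  )
  expect_false(attr(out, "report")$converged)
})

test_that("a floppy macrocycle against a huge terminus surfaces divergence", {
  cfg <- threading_config(terminal_radius = 6, ring_stiffness = 0,
                          angle_stiffness = 0)
  tm <- build_threading_model(cfg)
  band <- interpolate_linear(tm$endpoints$unthreaded, tm$endpoints$threaded,
                             11)
  err <- tryCatch(
    suppressWarnings(optimize_band(band, tm$model,
                                   neb_config(n_images = 11, max_steps = 400))),
    rotapath_divergence = function(e) e
  )
  expect_s3_class(err, "rotapath_divergence")
  expect_match(conditionMessage(err), "image \\d+")
})

test_that("structure relaxation reaches the requested force threshold", {
  pm <- external_adapter(harmonic_handle(k = 3))
  s <- optimize_structure(structure3d("C", matrix(c(1, 0, 0), 1, 3)), pm,
                          fmax = 1e-6)
  expect_lt(max(abs(s$coords)), 1e-6)
  # basin assignment on the double well
  sf <- benchmark_surface("double_well_1d")
  s2 <- optimize_structure(point_structure(0.4), sf$model, fmax = 1e-6)
  expect_equal(s2$coords[1, 1], 1, tolerance = 1e-5)
  # idempotence for an already-relaxed input
  s3 <- optimize_structure(s2, sf$model, fmax = 1e-6)
  expect_equal(attr(s3, "report")$steps, 0L)
  expect_identical(s3$coords, s2$coords)
})

test_that("frequency analysis classifies minima, saddles and free fragments", {
  k <- 3
  pm <- external_adapter(harmonic_handle(k))
  fc <- frequency_check(structure3d("C", matrix(0, 1, 3)), pm)
  expect_equal(fc$eigenvalues, rep(k / 12.011, 3), tolerance = 1e-6)
  expect_identical(fc$classification, "minimum")

  sf <- benchmark_surface("double_well_1d")
  fs <- frequency_check(point_structure(0), sf$model)
  expect_identical(fs$classification, "has_imaginary_modes")
  expect_equal(sum(fs$eigenvalues < -fs$zero_tol), 1)
  expect_equal(min(fs$eigenvalues), -4, tolerance = 1e-4)

  # two non-interacting fragments: soft relative modes flagged, still a minimum
  cfg <- threading_config()
  tm <- build_threading_model(cfg)
  far <- optimize_structure(threading_geometry(cfg, -50), tm$model,
                            fmax = 1e-4, max_steps = 5000)
  ff <- frequency_check(far, tm$model)
  expect_identical(ff$classification, "minimum")
  expect_gte(ff$n_near_zero, 6)

  expect_error(frequency_check(point_structure(0.35), sf$model),
               "precondition")
})

test_that("two-segment runs stitch with the shared image appearing once", {
  sf <- benchmark_surface("double_well_1d")
  a <- point_structure(-1); b <- point_structure(0); c <- point_structure(1)
  cfg <- neb_config(n_images = 3, max_steps = 200)
  out <- optimize_band(interpolate_linear(a, b, 3), sf$model, cfg)  # K = 5
  stitched <- suppressWarnings(run_two_segment(a, b, c, sf$model, cfg))
  expect_length(stitched$images, 9)   # 2K - 1
  expect_identical(stitched$images[[1]]$tag, "P_1")
  expect_identical(stitched$images[[9]]$tag, "P_9")
  rep <- attr(stitched, "report")
  expect_named(rep, c("segment1", "segment2"))
  expect_true(all(c(rep$segment1$wall_time_s, rep$segment2$wall_time_s) >= 0))
  # stitched NDC strictly increases across the junction
  ndc <- compute_ndc(stitched)$data$ndc
  expect_true(all(diff(ndc) > 0))
})

test_that("converged bands satisfy the path-optimality contracts", {
  out <- mb_converged_band()
  rep <- attr(out, "report")
  expect_true(rep$converged)
  cfg <- neb_config(n_images = 21)
  tau <- compute_tangents(out)
  for (i in 2:(length(out$images) - 1)) {
    f <- out$forces[[i]]
    fperp <- f - sum(f * tau[[i]]) * tau[[i]]
    expect_lt(sqrt(max(rowSums(fperp^2))), cfg$fmax_band)
  }
  ci <- out$climbing_index
  expect_lt(sqrt(max(rowSums(out$forces[[ci]]^2))), cfg$fmax_band)
  expect_gte(out$energies[ci], max(out$energies[1], out$energies[21 + 2]))
})

test_that("band energies approach the dense-path oracle as images grow", {
  ep <- surface_endpoints("muller_brown")
  grid <- mb_grid(400)
  level <- mb_flood_saddle(grid, ep$a$coords[1, 1:2], ep$b$coords[1, 1:2])
  # saddle point: the grid point at the flooding level bridging both basins
  cand <- which(abs(grid$E - level) < 0.5, arr.ind = TRUE)
  sp <- cand[which.min(grid$E[cand]), ]
  saddle <- c(grid$gx[sp[1]], grid$gy[sp[2]])
  # steepest-descent MEP oracle from the saddle, both directions
  sf <- benchmark_surface("muller_brown")
  descend <- function(p0) {
    path <- matrix(p0, 1, 2)
    for (i in 1:6000) {
      g <- sf$gradient_at(path[nrow(path), ])
      if (sqrt(sum(g^2)) < 1e-5) break
      step <- -1e-3 * g / max(sqrt(sum(g^2)), 1)
      path <- rbind(path, path[nrow(path), ] + step)
    }
    path
  }
  g0 <- sf$gradient_at(saddle)
  mep <- rbind(descend(saddle + c(0.02, 0)), descend(saddle - c(0.02, 0)))
  msd <- function(band) {
    mean(vapply(band$images, function(s) {
      min(colSums((t(mep) - s$coords[1, 1:2])^2))
    }, numeric(1)))
  }
  msds <- vapply(c(7, 15, 31), function(n) {
    band <- interpolate_linear(ep$a, ep$b, n)
    out <- suppressWarnings(
      optimize_band(band, sf$model,
                    neb_config(n_images = n, max_steps = 2000,
                               max_step = 0.1)))
    msd(out)
  }, numeric(1))
  expect_true(all(diff(msds) < 0))
})

test_that("identical inputs and seeds give bit-identical converged bands", {
  run <- function() {
    tm <- build_threading_model(threading_config(seed = 3))
    a <- optimize_structure(tm$endpoints$unthreaded, tm$model, fmax = 1e-4)
    c2 <- optimize_structure(tm$endpoints$threaded, tm$model, fmax = 1e-4,
                             max_steps = 5000)
    optimize_band(interpolate_linear(a, c2, 15), tm$model,
                  neb_config(n_images = 15, max_steps = 1500, max_step = 0.05,
                             seed = 3))
  }
  b1 <- run(); b2 <- run()
  expect_identical(lapply(b1$images, `[[`, "coords"),
                   lapply(b2$images, `[[`, "coords"))
  expect_identical(b1$energies, b2$energies)
})
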