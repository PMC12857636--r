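mk_band_1d <- function(xs, es = seq_along(xs)) {
  neb_band(lapply(xs, function(x) structure3d("X", matrix(c(x, 0, 0), 1, 3))),
           energies = es)
}

mk_profile <- function(e) {
  p <- list(data = tibble::tibble(image = seq_along(e),
                                  tag = sprintf("P_%d", seq_along(e)),
                                  ndc = seq(0, 1, length.out = length(e)),
                                  energy_rel = e))
  class(p) <- "ndc_profile"
  p
}

test_that("the normalized displacement coordinate is cumulative distance", {
  p <- compute_ndc(mk_band_1d(c(0, 1, 3)))
  expect_equal(p$data$ndc, c(0, 1 / 3, 1))
  expect_equal(p$data$energy_rel[1], 0)
  # random band vs an independent cumulative-pairwise-norm re-summation
  set.seed(9)
  images <- lapply(1:10, function(i) {
    structure3d(c("C", "O"), matrix(rnorm(6), 2, 3))
  })
  band <- neb_band(images, energies = rnorm(10))
  p2 <- compute_ndc(band)
  oracle <- cumsum(c(0, vapply(2:10, function(i) {
    sqrt(sum((images[[i]]$coords - images[[i - 1]]$coords)^2))
  }, numeric(1))))
  expect_equal(p2$data$ndc, oracle / oracle[10], tolerance = 1e-12)
  expect_identical(p2$data$ndc[1], 0)
  expect_identical(p2$data$ndc[10], 1)
  expect_true(all(diff(p2$data$ndc) >= 0))
})

test_that("aligned NDC is invariant under rigid motion of whole frames", {
  set.seed(21)
  images <- lapply(1:6, function(i) structure3d(c("C", "N", "O"),
                                                matrix(rnorm(9), 3, 3)))
  band <- neb_band(images, energies = rnorm(6))
  p0 <- compute_ndc(band, align = TRUE)
  rotated <- band
  for (i in seq_along(images)) {
    R <- rotapath:::rotation_from_uniforms(runif(3))
    rotated$images[[i]] <- transform_structure(images[[i]], R, runif(3, -4, 4))
  }
  p1 <- compute_ndc(rotated, align = TRUE)
  expect_equal(p1$data$ndc, p0$data$ndc, tolerance = 1e-8)
})

test_that("degenerate paths are rejected", {
  expect_error(compute_ndc(mk_band_1d(c(2, 2, 2))), "degenerate-path")
})

test_that("Kabsch superposition recovers rigid motions, rejects mirrors", {
  set.seed(4)
  ref <- structure3d(c("C", "N", "O", "H"), matrix(rnorm(12), 4, 3))
  R <- rotapath:::rotation_from_uniforms(c(0.8, 0.3, 0.55))
  moved <- transform_structure(ref, R, c(2, -1, 3))
  fit <- kabsch_superpose(moved, ref)
  expect_lt(fit$rmsd, 1e-10)
  # idempotence
  fit2 <- kabsch_superpose(fit$structure, ref)
  expect_lt(abs(fit2$rmsd - fit$rmsd), 1e-12)
  # mirror image: proper-rotation constraint keeps RMSD positive, and a
  # brute-force scan over many proper rotations cannot beat it
  mirror <- ref
  mirror$coords[, 1] <- -mirror$coords[, 1]
  fitm <- kabsch_superpose(mirror, ref)
  expect_gt(fitm$rmsd, 0.1)
  rmsd_of <- function(u) {
    Rr <- rotapath:::rotation_from_uniforms(u)
    P <- sweep(mirror$coords, 2, colMeans(mirror$coords)) %*% t(Rr)
    Q <- sweep(ref$coords, 2, colMeans(ref$coords))
    sqrt(mean(rowSums((P - Q)^2)))
  }
  brute <- min(vapply(1:500, function(i) rmsd_of(runif(3)), numeric(1)))
  expect_lte(fitm$rmsd, brute + 1e-9)
})

test_that("interaction energy equals the nonbonded host-guest terms", {
  cfg <- threading_config(charge_state = 1)
  tm <- build_threading_model(cfg)
  s <- tm$endpoints$threaded
  e_int <- interaction_energy(s, tm$model)
  # term-level bookkeeping oracle: complex minus isolated fragments equals
  # the LJ + Coulomb cross terms, recomputed directly from the geometry
  sig <- rotapath:::bead_sigmas(cfg)
  q <- cfg$bead_charges
  host <- s$groups$host; guest <- s$groups$guest
  e_nb <- 0
  for (i in host) for (j in guest) {
    r <- sqrt(sum((s$coords[i, ] - s$coords[j, ])^2))
    sp <- (sig[i] + sig[j]) / 2
    if (r < 12) {
      e_nb <- e_nb + 4 * cfg$lj_epsilon *
        (((sp / r)^12 - (sp / r)^6) - ((sp / 12)^12 - (sp / 12)^6))
    }
    e_nb <- e_nb + 14.399645 * q[i] * q[j] / r
  }
  expect_equal(e_int, e_nb * 96.4853, tolerance = 1e-9)
})

test_that("two beads at the pair-potential minimum bind by the well depth", {
  eps <- 0.05; sig <- 1.3
  lj_pair <- potential_model(
    "lj_pair",
    energy_of = function(s) {
      if (is.null(s$groups$host) || is.null(s$groups$guest)) return(0)
      r <- sqrt(sum((s$coords[1, ] - s$coords[2, ])^2))
      4 * eps * ((sig / r)^12 - (sig / r)^6)
    },
    forces_of = function(s) 0 * s$coords,
    supports_subsystems = TRUE
  )
  pair <- structure3d(c("C", "C"),
                      rbind(c(0, 0, 0), c(2^(1 / 6) * sig, 0, 0)),
                      groups = list(host = 1L, guest = 2L))
  expect_equal(interaction_energy(pair, lj_pair), -eps * 96.4853,
               tolerance = 1e-9)
  expect_error(interaction_energy(structure3d("C", matrix(0, 1, 3)), lj_pair),
               "host")
})

test_that("stage segmentation recovers a constructed four-stage profile", {
  e <- c(rep(0, 20),
         seq(-3, -25, length.out = 10),
         seq(-18, 30, length.out = 9), 34.2,
         seq(25, -60, length.out = 8),
         seq(-55, -50, length.out = 7))
  seg <- segment_stages(mk_profile(e))
  expect_equal(seg$initialization, c(1L, 20L))
  expect_equal(seg$preparation, c(21L, 30L))
  expect_equal(seg$activation, c(31L, 47L))
  expect_equal(seg$stabilization, c(48L, 55L))
  expect_identical(extract_barrier(mk_profile(e), seg), 59.2)
  # brute-force scan oracle over the stated ranges
  expect_equal(extract_barrier(mk_profile(e), seg),
               max(e[31:47]) - min(e[21:30]))
})

test_that("profiles without a barrier are rejected", {
  expect_error(segment_stages(mk_profile(seq(10, -10, length.out = 12))),
               "no-barrier")
  e <- c(rep(0, 5), -2, -4, 3, -1, -6)
  expect_error(segment_stages(mk_profile(e), eps_flat = 100), "no-barrier")
})

test_that("macrocycle-opening descriptor averages per-oxygen maxima", {
  sq <- structure3d(rep("O", 4),
                    rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                    groups = list(ring_oxygens = 1:4))
  expect_equal(descriptor_dmax_oo(sq), sqrt(2))
  coincident <- structure3d(rep("O", 3), matrix(1, 3, 3),
                            groups = list(ring_oxygens = 1:3))
  expect_equal(descriptor_dmax_oo(coincident), 0)
  # 8 oxygens on a circle vs a brute-force pairwise oracle
  th <- 2 * pi * (0:7) / 8
  circ <- structure3d(rep("O", 8), cbind(3 * cos(th), 3 * sin(th), 0),
                      groups = list(ring_oxygens = 1:8))
  D <- as.matrix(dist(circ$coords))
  expect_equal(descriptor_dmax_oo(circ), mean(apply(D, 1, max)),
               tolerance = 1e-12)
  expect_equal(descriptor_dmax_oo(circ), 6, tolerance = 1e-12)
})

test_that("hydrogen-bond descriptor takes the minimum donor-acceptor distance", {
  s <- structure3d(c("N", "O", "O", "O"),
                   rbind(c(0, 0, 0), c(2.8, 0, 0), c(0, 3.4, 0), c(0, 0, 5)),
                   groups = list(donor_N = 1L, ring_oxygens = 2:4))
  expect_equal(descriptor_hbond(s), 2.8)
  s1 <- structure3d(c("N", "O"), rbind(c(0, 0, 0), c(0, 0, 3.1)),
                    groups = list(donor_N = 1L, ring_oxygens = 2L))
  expect_equal(descriptor_hbond(s1), 3.1)
  set.seed(12)
  cloud <- structure3d(c("N", rep("O", 9)), matrix(rnorm(30, sd = 3), 10, 3),
                       groups = list(donor_N = 1L, ring_oxygens = 2:10))
  oracle <- min(vapply(2:10, function(i) {
    sqrt(sum((cloud$coords[1, ] - cloud$coords[i, ])^2))
  }, numeric(1)))
  expect_equal(descriptor_hbond(cloud), oracle, tolerance = 1e-12)
})

test_that("ring centre-of-mass descriptor is mass-weighted", {
  ringA <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0))
  s <- structure3d(c("C", "C", "C", "C", "C", "C"),
                   rbind(ringA, sweep(ringA, 2, c(4, 0, 0), "+")),
                   groups = list(phenyl_A = 1:3, phenyl_B = 4:6))
  expect_equal(descriptor_ring_cm(s), 4)
  same <- structure3d(c("C", "C", "C"), ringA,
                      groups = list(phenyl_A = 1:3, phenyl_B = 1:3))
  expect_equal(descriptor_ring_cm(same), 0)
  # heteroatomic groups against a hand-computed weighted centroid
  s2 <- structure3d(c("C", "O", "N", "H"),
                    rbind(c(0, 0, 0), c(2, 0, 0), c(5, 1, 0), c(6, -1, 2)),
                    groups = list(phenyl_A = 1:2, phenyl_B = 3:4))
  m <- c(12.011, 15.999, 14.007, 1.008)
  cA <- colSums(s2$coords[1:2, ] * m[1:2]) / sum(m[1:2])
  cB <- colSums(s2$coords[3:4, ] * m[3:4]) / sum(m[3:4])
  expect_equal(descriptor_ring_cm(s2), sqrt(sum((cA - cB)^2)),
               tolerance = 1e-12)
})

test_that("the assembled threading profile carries stages and descriptors", {
  cfg <- threading_config(terminal_radius = 2.0)
  tm <- build_threading_model(cfg)
  a <- optimize_structure(tm$endpoints$unthreaded, tm$model, fmax = 1e-4)
  b <- optimize_structure(tm$endpoints$midpoint, tm$model, fmax = 1e-4,
                          max_steps = 5000)
  c2 <- optimize_structure(tm$endpoints$threaded, tm$model, fmax = 1e-4,
                           max_steps = 5000)
  band <- suppressWarnings(run_two_segment(a, b, c2, tm$model,
    neb_config(n_images = 15, max_steps = 1500, max_step = 0.05)))
  p <- build_profile(band)
  expect_equal(nrow(p$data), length(band$images))
  expect_true(all(c("d_max_oo", "d_no", "stage") %in% names(p$data)))
  stages_seen <- unique(p$data$stage)
  expect_identical(stages_seen, c("initialization", "preparation",
                                  "activation", "stabilization"))
  expect_gt(p$barrier, 0)
  # bit-stable on identical inputs
  expect_identical(build_profile(band)$data, p$data)
  # flat band of identical energies has no barrier
  flatband <- neb_band(band$images[1:5], energies = rep(1, 5))
  expect_error(build_profile(flatband), "no-barrier")
})
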