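#' Configuration for the coarse-grained threading model
#'
#' Defines a bead-spring macrocycle (the host ring) and a dumbbell axle (the
#' guest) whose assembly emulates the threading of a crown-ether torus over a
#' bulky, optionally charged axle terminus. The ring is a regular polygon of
#' `n_ring_beads` beads joined by harmonic bonds and angles; every third bead
#' is an "oxygen" bead carrying a negative partial charge (annotated in the
#' `ring_oxygens` group so descriptor operations run unchanged). The axle is
#' a linear bead chain whose first bead is the bulky terminus (LJ sigma
#' `terminal_radius`) and whose second bead is the charge-bearing donor
#' nitrogen. Host and guest interact through Lennard-Jones (12 A cutoff,
#' energy-shifted) plus Coulomb terms; bonded terms are intramolecular only.
#'
#' @param n_ring_beads ring bead count (multiple of 3, >= 6).
#' @param ring_bond_length equilibrium bond length, Angstrom (ring and axle).
#' @param ring_stiffness harmonic bond stiffness, eV/A^2.
#' @param angle_stiffness harmonic angle stiffness, eV/rad^2.
#' @param axle_bead_count axle bead count (>= 3).
#' @param terminal_radius LJ sigma of the bulky terminal bead, Angstrom.
#' @param lj_epsilon LJ well depth, eV.
#' @param charge_state declared total charge (0, +1 or +2), carried by the
#'   guest donor bead; ring partial charges are net-neutral (O -0.2 e,
#'   C +0.1 e).
#' @param bead_charges optional per-bead charges (e), host beads first; must
#'   sum to `charge_state`. Default derived from `charge_state`.
#' @param dielectric relative dielectric constant.
#' @param seed integer seed for the deterministic symmetry-breaking jitter of
#'   the generated endpoint geometries.
#' @return An object of class `threading_config`.
#' @export
threading_config <- function(n_ring_beads = 6, ring_bond_length = 1.2,
                             ring_stiffness = 10, angle_stiffness = 2,
                             axle_bead_count = 7, terminal_radius = 1.5,
                             lj_epsilon = 0.02, charge_state = 0,
                             bead_charges = NULL, dielectric = 1.0,
                             seed = 1L) {
  if (n_ring_beads < 6 || n_ring_beads %% 3 != 0) {
    stop("configuration error: n_ring_beads must be a multiple of 3, >= 6")
  }
  if (axle_bead_count < 3) stop("configuration error: axle_bead_count >= 3")
  if (ring_stiffness < 0 || angle_stiffness < 0) {
    stop("configuration error: stiffnesses must be >= 0")
  }
  if (terminal_radius <= 0) stop("configuration error: terminal_radius > 0")
  if (lj_epsilon < 0) stop("configuration error: lj_epsilon must be >= 0")
  if (dielectric <= 0) stop("configuration error: dielectric must be > 0")
  n <- as.integer(n_ring_beads); m <- as.integer(axle_bead_count)
  if (is.null(bead_charges)) {
    ring_q <- rep(c(0.1, 0.1, -0.2), length.out = n)   # O every third bead
    axle_q <- numeric(m)
    axle_q[2] <- charge_state                          # donor bead
    bead_charges <- c(ring_q, axle_q)
  }
  if (length(bead_charges) != n + m) {
    stop("configuration error: bead_charges must have one entry per bead")
  }
  if (abs(sum(bead_charges) - charge_state) > 1e-9) {
    stop("configuration error: total bead charge (", sum(bead_charges),
         ") does not equal the declared charge state (", charge_state, ")")
  }
  cfg <- list(n_ring_beads = n, ring_bond_length = ring_bond_length,
              ring_stiffness = ring_stiffness,
              angle_stiffness = angle_stiffness, axle_bead_count = m,
              terminal_radius = terminal_radius, lj_epsilon = lj_epsilon,
              charge_state = charge_state, bead_charges = bead_charges,
              dielectric = dielectric, seed = as.integer(seed))
  class(cfg) <- "threading_config"
  cfg
}

LJ_CUTOFF <- 12.0  # Angstrom, energy-shifted

# per-bead LJ sigma: the bulky terminal bead carries terminal_radius; ring
# beads are wide (1.4 A) so that crossing the terminus is repulsive for
# every passage mode (a slim ring can tilt its beads past a small terminus
# one at a time and erase the threading barrier); interior axle beads are
# slim (1.0 A) so the threaded complex stays bound
bead_sigmas <- function(cfg) {
  c(rep(1.4, cfg$n_ring_beads),
    c(cfg$terminal_radius, rep(1.0, cfg$axle_bead_count - 1)))
}

#' Build the coarse-grained threading model
#'
#' Returns the [potential_model()] together with deterministic endpoint
#' geometries for the two-segment path protocol: `unthreaded` (ring on the
#' axle axis, 8 A before the bulky terminus), `midpoint` (ring just past the
#' terminus) and `threaded` (ring around the axle interior, near the donor
#' bead). A small seeded jitter (0.01 A) breaks the exact cylindrical
#' symmetry so relaxations can find symmetry-broken (claw-like) minima.
#'
#' The model energy is: ring bonded terms (harmonic bonds and angles) +
#' axle bonded terms + host-guest Lennard-Jones (12 A shifted cutoff) +
#' host-guest Coulomb `q_i q_j / (4 pi eps0 dielectric r)`. Host and guest
#' fragments can be evaluated alone (`supports_subsystems = TRUE`), so
#' interaction energies are available by subtraction.
#'
#' @param cfg a [threading_config()].
#' @return List with `model` (a `potential_model`), `endpoints` (list of
#'   three `structure3d`: unthreaded, midpoint, threaded) and `config`.
#' @export
build_threading_model <- function(cfg) {
  stopifnot(inherits(cfg, "threading_config"))
  model <- threading_potential(cfg)
  L <- cfg$ring_bond_length
  # unthreaded: far approach; midpoint: the pre-barrier contact complex
  # (the first segment then covers only the approach, like a threading
  # protocol's quick first leg); threaded: one corrugation pocket past the
  # first post-barrier minimum, so the descent shows a stabilization stage
  endpoints <- list(
    unthreaded = threading_geometry(cfg, ring_center_x = -8),
    midpoint   = threading_geometry(cfg, ring_center_x = -2),
    threaded   = threading_geometry(cfg, ring_center_x = 3 * L)
  )
  endpoints$unthreaded$tag <- "unthreaded"
  endpoints$midpoint$tag <- "midpoint"
  endpoints$threaded$tag <- "threaded"
  list(model = model, endpoints = endpoints, config = cfg)
}

#' Generate a ring + axle geometry at a given ring position
#'
#' The axle lies along +x with the bulky terminus at the origin; the ring is
#' a regular polygon in the plane perpendicular to x centred at
#' `(ring_center_x, 0, 0)`.
#'
#' @param cfg a [threading_config()].
#' @param ring_center_x x position of the ring centroid (Angstrom).
#' @param jitter apply the seeded 0.01 A symmetry-breaking jitter?
#' @export
threading_geometry <- function(cfg, ring_center_x, jitter = TRUE) {
  n <- cfg$n_ring_beads; m <- cfg$axle_bead_count; L <- cfg$ring_bond_length
  R <- L / (2 * sin(pi / n))
  th <- 2 * pi * (seq_len(n) - 1) / n
  ring <- cbind(rep(ring_center_x, n), R * cos(th), R * sin(th))
  axle <- cbind(L * (seq_len(m) - 1), numeric(m), numeric(m))
  coords <- rbind(ring, axle)
  if (jitter) {
    coords <- coords + with_seed_local(cfg$seed, {
      matrix(stats::rnorm(3 * (n + m), sd = 0.01), n + m, 3)
    })
  }
  sym_ring <- rep(c("C", "C", "O"), length.out = n)
  sym_axle <- c("C", "N", rep("C", m - 2))
  structure3d(
    c(sym_ring, sym_axle), coords,
    groups = list(host = 1:n, guest = n + 1:m,
                  ring_oxygens = which(sym_ring == "O"),
                  donor_N = n + 2L),
    tag = sprintf("cg_rotaxane_x%.2f", ring_center_x)
  )
}

# evaluate expr with a locally-seeded RNG, restoring the caller's RNG state
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

threading_potential <- function(cfg) {
  sig <- bead_sigmas(cfg)
  q <- cfg$bead_charges
  n <- cfg$n_ring_beads; m <- cfg$axle_bead_count
  kc <- COULOMB_EV_ANGSTROM / cfg$dielectric
  cache <- new.env(parent = emptyenv())

  eval_s <- function(s) {
    if (!is.null(cache$coords) && identical(cache$coords, s$coords) &&
        identical(cache$groups, s$groups)) {
      return(cache$result)
    }
    host <- s$groups$host; guest <- s$groups$guest
    if (is.null(host) && is.null(guest)) {
      stop("threading model requires 'host' and/or 'guest' group annotations")
    }
    if (!is.null(host) && length(host) != n) {
      stop("threading model: host fragment must contain all ", n, " ring beads")
    }
    if (!is.null(guest) && length(guest) != m) {
      stop("threading model: guest fragment must contain all ", m, " axle beads")
    }
    e <- 0
    f <- matrix(0, n_atoms(s), 3)
    X <- s$coords
    if (!is.null(host)) {
      ring_theta0 <- pi - 2 * pi / n
      b <- bonded_terms(X, host, cyclic = TRUE, r0 = cfg$ring_bond_length,
                        kb = cfg$ring_stiffness, theta0 = ring_theta0,
                        ka = cfg$angle_stiffness)
      e <- e + b$e; f <- f + b$f
    }
    if (!is.null(guest)) {
      b <- bonded_terms(X, guest, cyclic = FALSE, r0 = cfg$ring_bond_length,
                        kb = cfg$ring_stiffness, theta0 = pi,
                        ka = cfg$angle_stiffness)
      e <- e + b$e; f <- f + b$f
    }
    if (!is.null(host) && !is.null(guest)) {
      nb <- nonbonded_terms(X, host, guest, sig_h = sig[seq_len(n)],
                            sig_g = sig[n + seq_len(m)],
                            q_h = q[seq_len(n)], q_g = q[n + seq_len(m)],
                            eps = cfg$lj_epsilon, kc = kc)
      e <- e + nb$e; f <- f + nb$f
    }
    res <- list(e = e, f = f)
    cache$coords <- s$coords; cache$groups <- s$groups; cache$result <- res
    res
  }

  potential_model(
    name = sprintf("cg_threading(rt=%.2f,q=%+d)", cfg$terminal_radius,
                   as.integer(cfg$charge_state)),
    energy_of = function(s) eval_s(s)$e,
    forces_of = function(s) eval_s(s)$f,
    supports_subsystems = TRUE,
    check_topology = function(s) {
      lim <- 3 * cfg$ring_bond_length
      for (grp in c("host", "guest")) {
        ix <- s$groups[[grp]]
        if (is.null(ix)) next
        pairs <- cbind(ix, c(ix[-1], ix[1]))
        if (grp == "guest") pairs <- pairs[-nrow(pairs), , drop = FALSE]
        d <- sqrt(rowSums((s$coords[pairs[, 1], , drop = FALSE] -
                           s$coords[pairs[, 2], , drop = FALSE])^2))
        if (any(d > lim)) {
          return(if (grp == "host") "MB" else "axle breaking")
        }
      }
      NULL
    }
  )
}

# harmonic bonds + angles along an ordered bead chain (cyclic for the ring)
bonded_terms <- function(X, ix, cyclic, r0, kb, theta0, ka) {
  k <- length(ix)
  e <- 0
  f <- matrix(0, nrow(X), 3)
  bonds <- if (cyclic) cbind(ix, ix[c(2:k, 1)]) else cbind(ix[-k], ix[-1])
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    d <- X[j, ] - X[i, ]
    r <- sqrt(sum(d * d))
    e <- e + 0.5 * kb * (r - r0)^2
    fij <- kb * (r - r0) * d / r
    f[i, ] <- f[i, ] + fij
    f[j, ] <- f[j, ] - fij
  }
  angles <- if (cyclic) {
    cbind(ix[c(k, 1:(k - 1))], ix, ix[c(2:k, 1)])
  } else if (k >= 3) {
    cbind(ix[1:(k - 2)], ix[2:(k - 1)], ix[3:k])
  } else NULL
  if (!is.null(angles)) {
    for (a in seq_len(nrow(angles))) {
      i <- angles[a, 1]; j <- angles[a, 2]; l <- angles[a, 3]
      u <- X[i, ] - X[j, ]; v <- X[l, ] - X[j, ]
      nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
      ct <- sum(u * v) / (nu * nv)
      ct <- min(1, max(-1, ct))
      th <- acos(ct)
      st <- sqrt(max(1 - ct^2, 1e-12))
      e <- e + 0.5 * ka * (th - theta0)^2
      dEdth <- ka * (th - theta0)
      dthdi <- (ct * u / nu - v / nv) / (nu * st)
      dthdl <- (ct * v / nv - u / nu) / (nv * st)
      f[i, ] <- f[i, ] - dEdth * dthdi
      f[l, ] <- f[l, ] - dEdth * dthdl
      f[j, ] <- f[j, ] + dEdth * (dthdi + dthdl)
    }
  }
  list(e = e, f = f)
}

# host-guest LJ (shifted 12 A cutoff) + Coulomb (no cutoff), vectorised
nonbonded_terms <- function(X, host, guest, sig_h, sig_g, q_h, q_g, eps, kc) {
  H <- X[host, , drop = FALSE]; G <- X[guest, , drop = FALSE]
  nh <- length(host); ng <- length(guest)
  dx <- outer(H[, 1], G[, 1], "-")
  dy <- outer(H[, 2], G[, 2], "-")
  dz <- outer(H[, 3], G[, 3], "-")
  r2 <- dx^2 + dy^2 + dz^2
  r <- sqrt(r2)
  sp <- outer(sig_h, sig_g, function(a, b) (a + b) / 2)
  qq <- outer(q_h, q_g)
  # LJ inside cutoff, energy-shifted to zero at the cutoff
  in_cut <- r < LJ_CUTOFF
  s6 <- (sp / r)^6
  s6c <- (sp / LJ_CUTOFF)^6
  e_lj <- 4 * eps * ((s6^2 - s6) - (s6c^2 - s6c))
  e_lj[!in_cut] <- 0
  # dE/dr for LJ
  dlj <- 4 * eps * (-12 * s6^2 + 6 * s6) / r
  dlj[!in_cut] <- 0
  e_c <- kc * qq / r
  dc <- -kc * qq / r2
  e <- sum(e_lj) + sum(e_c)
  dEdr <- dlj + dc
  # force on host atom i from pair (i,j): -dE/dr * (H_i - G_j)/r
  w <- dEdr / r
  fHx <- -rowSums(w * dx); fHy <- -rowSums(w * dy); fHz <- -rowSums(w * dz)
  fGx <- colSums(w * dx); fGy <- colSums(w * dy); fGz <- colSums(w * dz)
  f <- matrix(0, nrow(X), 3)
  f[host, ] <- f[host, ] + cbind(fHx, fHy, fHz)
  f[guest, ] <- f[guest, ] + cbind(fGx, fGy, fGz)
  list(e = e, f = f)
}
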