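#' Band of images for chain-of-states path search
#'
#' An ordered chain of composition-identical structures discretizing a path
#' between two endpoints, with optional per-image energies and forces.
#'
#' @param images list of [structure3d()] with identical symbols/ordering.
#' @param energies optional numeric vector of per-image energies (eV).
#' @param forces optional list of per-image n x 3 force matrices (eV/A).
#' @param fixed_ends are the endpoints frozen during optimization?
#' @param climbing_index optional index of the climbing image.
#' @export
neb_band <- function(images, energies = NULL, forces = NULL,
                     fixed_ends = TRUE, climbing_index = NULL) {
  if (length(images) < 3) stop("a band needs at least 3 images")
  ref <- images[[1]]
  for (im in images) {
    if (!same_composition(ref, im)) {
      stop("input error: all images must share symbols and atom order")
    }
  }
  if (!is.null(energies) && length(energies) != length(images)) {
    stop("energies length must match image count")
  }
  if (!is.null(forces) && length(forces) != length(images)) {
    stop("forces length must match image count")
  }
  b <- list(images = images, energies = energies, forces = forces,
            fixed_ends = isTRUE(fixed_ends), climbing_index = climbing_index)
  class(b) <- "neb_band"
  b
}

#' @export
print.neb_band <- function(x, ...) {
  cat(sprintf("<neb_band> %d images x %d atoms%s\n", length(x$images),
              n_atoms(x$images[[1]]),
              if (!is.null(x$climbing_index))
                sprintf(" (climbing image %d)", x$climbing_index) else ""))
  if (!is.null(x$energies)) {
    cat(sprintf("  energy range: [%.6g, %.6g] eV\n", min(x$energies),
                max(x$energies)))
  }
  invisible(x)
}

#' Chain-optimizer configuration
#'
#' Defaults follow the two-segment threading protocol: 125 interior images
#' with linear interpolation, climbing image and string-method
#' redistribution on, band convergence at max|F| 0.1 eV/A and endpoint
#' relaxation at 1e-4 eV/A under L-BFGS.
#'
#' @param n_images interior image count (>= 1; endpoints are added).
#' @param spring_k spring constant, eV/A^2.
#' @param climbing activate the climbing image (after the first 10 steps)?
#' @param string_method redistribute images to equal arc length each step?
#' @param fmax_band band convergence threshold on max per-atom force, eV/A.
#' @param fmax_endpoint endpoint-relaxation threshold, eV/A.
#' @param max_steps optimizer step budget.
#' @param history_size L-BFGS memory.
#' @param max_step largest per-atom displacement per step, Angstrom.
#' @param seed integer seed recorded in reports.
#' @export
neb_config <- function(n_images = 125, spring_k = 0.1, climbing = TRUE,
                       string_method = TRUE, fmax_band = 0.1,
                       fmax_endpoint = 1e-4, max_steps = 500,
                       history_size = 25, max_step = 0.2, seed = 1L) {
  if (n_images < 1) stop("n_images must be >= 1 interior image")
  if (fmax_band <= 0 || fmax_endpoint <= 0) stop("fmax values must be > 0")
  if (spring_k < 0) stop("spring_k must be >= 0")
  cfg <- list(n_images = as.integer(n_images), spring_k = spring_k,
              climbing = isTRUE(climbing), string_method = isTRUE(string_method),
              fmax_band = fmax_band, fmax_endpoint = fmax_endpoint,
              max_steps = as.integer(max_steps),
              history_size = as.integer(history_size), max_step = max_step,
              seed = as.integer(seed))
  class(cfg) <- "neb_config"
  cfg
}

#' Linear interpolation between two endpoint structures
#'
#' Image i of the K = `n_interior` + 2 images has coordinates
#' `reactant + (i - 1)/(K - 1) * (product - reactant)`; the endpoints are
#' bit-identical to the inputs.
#'
#' @param reactant,product composition-identical [structure3d()].
#' @param n_interior number of interior images.
#' @export
interpolate_linear <- function(reactant, product, n_interior) {
  if (!same_composition(reactant, product)) {
    stop("input error: reactant and product composition differ")
  }
  if (n_interior < 1) stop("n_interior must be >= 1")
  delta <- product$coords - reactant$coords
  if (sqrt(sum(delta^2)) < 1e-12) {
    stop("degenerate-path error: reactant and product coincide")
  }
  K <- n_interior + 2
  images <- vector("list", K)
  images[[1]] <- reactant
  images[[K]] <- product
  for (i in 2:(K - 1)) {
    im <- reactant
    im$coords <- reactant$coords + ((i - 1) / (K - 1)) * delta
    im$tag <- sprintf("interp_%d", i)
    images[[i]] <- im
  }
  neb_band(images)
}

#' Improved-tangent estimate for every image
#'
#' Interior images take the uphill-neighbour difference vector; at energy
#' extrema the two neighbour vectors are blended with energy-difference
#' weights. All tangents are unit-norm. Endpoint tangents point along the
#' adjacent chord.
#'
#' @param band a [neb_band()] with populated energies.
#' @return list of per-image unit tangent matrices (n x 3).
#' @export
compute_tangents <- function(band) {
  if (is.null(band$energies)) stop("state error: band energies not populated")
  K <- length(band$images)
  E <- band$energies
  X <- lapply(band$images, `[[`, "coords")
  tau <- vector("list", K)
  unit <- function(v) {
    nv <- sqrt(sum(v^2))
    if (nv < 1e-300) stop("degenerate-path error: coincident images")
    v / nv
  }
  tau[[1]] <- unit(X[[2]] - X[[1]])
  tau[[K]] <- unit(X[[K]] - X[[K - 1]])
  for (i in 2:(K - 1)) {
    tp <- X[[i + 1]] - X[[i]]
    tm <- X[[i]] - X[[i - 1]]
    if (E[i + 1] > E[i] && E[i] > E[i - 1]) {
      t <- tp
    } else if (E[i + 1] < E[i] && E[i] < E[i - 1]) {
      t <- tm
    } else {
      dmax <- max(abs(E[i + 1] - E[i]), abs(E[i - 1] - E[i]))
      dmin <- min(abs(E[i + 1] - E[i]), abs(E[i - 1] - E[i]))
      t <- if (E[i + 1] > E[i - 1]) tp * dmax + tm * dmin
           else tp * dmin + tm * dmax
      if (sqrt(sum(t^2)) < 1e-300) t <- tp + tm   # flat triple: average
    }
    tau[[i]] <- unit(t)
  }
  tau
}

#' Effective chain forces (nudging, springs, climbing)
#'
#' Regular interior images feel the true force perpendicular to the tangent
#' plus a spring term `spring_k (|d_next| - |d_prev|)` along the tangent.
#' The climbing image (highest-energy interior image when climbing is
#' enabled) feels the true force with its parallel component inverted and no
#' spring. Frozen endpoints get zero force.
#'
#' @param band a [neb_band()] with energies and forces populated.
#' @param cfg a [neb_config()].
#' @param climbing_on is the climbing image active this step?
#' @return list of per-image effective force matrices plus the climbing index.
#' @export
neb_forces <- function(band, cfg, climbing_on = cfg$climbing) {
  K <- length(band$images)
  tau <- compute_tangents(band)
  X <- lapply(band$images, `[[`, "coords")
  Fts <- band$forces
  ci <- NA_integer_
  if (climbing_on && K > 2) {
    ci <- which.max(band$energies[2:(K - 1)]) + 1L
  }
  out <- vector("list", K)
  for (i in seq_len(K)) {
    if ((i == 1 || i == K) && band$fixed_ends) {
      out[[i]] <- matrix(0, nrow(X[[1]]), 3)
      next
    }
    Ft <- Fts[[i]]
    t <- tau[[i]]
    fpar <- sum(Ft * t)
    if (!is.na(ci) && i == ci) {
      out[[i]] <- Ft - 2 * fpar * t
    } else {
      dn <- sqrt(sum((X[[min(i + 1, K)]] - X[[i]])^2))
      dp <- sqrt(sum((X[[i]] - X[[max(i - 1, 1)]])^2))
      out[[i]] <- (Ft - fpar * t) + cfg$spring_k * (dn - dp) * t
    }
  }
  list(forces = out, climbing_index = ci, tangents = tau)
}

# redistribute images to equal arc length by per-coordinate natural cubic
# splines over cumulative arc length, iterated to a fixed point so chord
# lengths equalise to tight relative tolerance; endpoints untouched
reparameterize_equal_arc <- function(X, tol = 1e-9, max_iter = 60) {
  K <- length(X)
  n3 <- length(X[[1]])
  for (it in seq_len(max_iter)) {
    M <- t(vapply(X, as.vector, numeric(n3)))   # K x 3n
    seg <- sqrt(rowSums((M[-1, , drop = FALSE] - M[-K, , drop = FALSE])^2))
    if (any(seg < 1e-300)) stop("degenerate-path error: coincident images")
    dev <- max(abs(seg - mean(seg))) / mean(seg)
    if (dev < tol) break
    s <- c(0, cumsum(seg))
    targets <- seq(0, s[K], length.out = K)
    Mnew <- M
    for (j in seq_len(n3)) {
      Mnew[2:(K - 1), j] <- stats::spline(s, M[, j], xout = targets[2:(K - 1)],
                                          method = "natural")$y
    }
    for (i in 2:(K - 1)) X[[i]] <- matrix(Mnew[i, ], ncol = 3)
  }
  X
}

evaluate_band <- function(band, potential) {
  band$energies <- vapply(seq_along(band$images), function(i) {
    tryCatch(model_energy(potential, band$images[[i]]),
             rotapath_divergence = function(e) {
               stop_divergence(sprintf("image %d: %s", i, conditionMessage(e)))
             })
  }, numeric(1))
  band$forces <- lapply(seq_along(band$images), function(i) {
    tryCatch(model_forces(potential, band$images[[i]]),
             rotapath_divergence = function(e) {
               stop_divergence(sprintf("image %d: %s", i, conditionMessage(e)))
             })
  })
  band
}

#' Optimize a band to the minimum-energy path
#'
#' Iterates: (optional) string-method redistribution to equal arc length,
#' energy/force evaluation, effective chain forces (climbing activated after
#' the first 10 steps), and a damped L-BFGS update with per-atom step clip.
#' Converged when the max per-atom effective-force norm over movable images
#' is at most `fmax_band`; hitting `max_steps` is reported, not silently
#' accepted. Non-finite energies or forces, any |force| above 1000 eV/A, or
#' a broken bonded topology raise a divergence error naming the image (and a
#' "MB"-style label where the model provides one).
#'
#' @param band a [neb_band()] (energies/forces need not be populated).
#' @param potential a [potential_model()].
#' @param cfg a [neb_config()].
#' @return The converged band, with a `report` attribute (list: `converged`,
#'   `steps`, `fmax`, `barrier_ev`, per-step `log` tibble, `wall_time_s`).
#' @export
optimize_band <- function(band, potential, cfg = neb_config()) {
  t0 <- proc.time()[["elapsed"]]
  K <- length(band$images)
  climb_delay <- 10L
  st <- lbfgs_state(cfg$history_size, h0 = 1 / 70, max_step = cfg$max_step)
  log_steps <- integer(0); log_fmax <- numeric(0); log_emax <- numeric(0)
  converged <- FALSE
  fmax_now <- NA_real_
  ftrue_first <- Inf
  # string redistribution equilibrates image spacing during the early
  # (pre-climbing) phase; it is then frozen so the projected forces can
  # relax all the way to fmax_band without the reparameterization and the
  # climbing image fighting over image positions
  for (step in seq_len(cfg$max_steps)) {
    if (cfg$climbing && step == climb_delay + 1L) lbfgs_reset(st)
    string_on <- cfg$string_method && step <= climb_delay
    if (string_on) {
      X <- reparameterize_equal_arc(lapply(band$images, `[[`, "coords"))
      for (i in seq_len(K)) band$images[[i]]$coords <- X[[i]]
    }
    band <- evaluate_band(band, potential)
    ftrue_now <- max(vapply(band$forces, function(f) max(abs(f)), numeric(1)))
    if (step == 1L) ftrue_first <- ftrue_now
    check_band_health(band, potential, ftrue_first)
    nf <- neb_forces(band, cfg, climbing_on = cfg$climbing && step > climb_delay)
    band$climbing_index <- if (is.na(nf$climbing_index)) NULL else nf$climbing_index
    movable <- if (band$fixed_ends) 2:(K - 1) else seq_len(K)
    fmax_now <- max(vapply(movable, function(i) {
      sqrt(max(rowSums(nf$forces[[i]]^2)))
    }, numeric(1)))
    log_steps <- c(log_steps, step)
    log_fmax <- c(log_fmax, fmax_now)
    log_emax <- c(log_emax, max(band$energies))
    if (fmax_now <= cfg$fmax_band &&
        (!cfg$climbing || step > climb_delay + 1L)) {
      converged <- TRUE
      break
    }
    x <- unlist(lapply(movable, function(i) as.vector(band$images[[i]]$coords)))
    g <- -unlist(lapply(movable, function(i) as.vector(nf$forces[[i]])))
    # deep inside a repulsive wall (huge forces) the step cap is tightened
    # so the quasi-Newton update cannot overshoot through the wall; the
    # floor keeps wall escape from stalling
    st$max_step <- if (fmax_now > 10) {
      max(cfg$max_step * sqrt(10 / fmax_now), 0.2 * cfg$max_step)
    } else cfg$max_step
    dx <- lbfgs_step(st, x, g)
    off <- 0L
    n3 <- 3L * n_atoms(band$images[[1]])
    for (i in movable) {
      band$images[[i]]$coords <- band$images[[i]]$coords +
        matrix(dx[off + seq_len(n3)], ncol = 3)
      off <- off + n3
    }
  }
  if (!converged) band <- evaluate_band(band, potential)
  report <- list(
    converged = converged, steps = length(log_steps), fmax = fmax_now,
    fmax_target = cfg$fmax_band,
    climbing_index = band$climbing_index,
    barrier_ev = if (!is.null(band$climbing_index)) {
      band$energies[band$climbing_index] - band$energies[1]
    } else max(band$energies) - band$energies[1],
    seed = cfg$seed,
    log = tibble::tibble(step = log_steps, fmax = log_fmax,
                         max_energy = log_emax),
    wall_time_s = proc.time()[["elapsed"]] - t0
  )
  attr(band, "report") <- report
  if (!converged) {
    warning(sprintf("band not converged in %d steps (max|F| = %.3g eV/A)",
                    cfg$max_steps, fmax_now))
  }
  band
}

# divergence means the chain broke, not that the guess was stiff: transient
# wall forces of 1e3-1e4 eV/A occur while a tight macrocycle squeezes past a
# terminus and relax out, so the force bound is only an overflow guard; the
# scientific failure mode is the bonded-topology check (the "MB"-style
# macrocycle-breaking label)
check_band_health <- function(band, potential, ftrue_first = Inf) {
  for (i in seq_along(band$images)) {
    fmax_i <- max(abs(band$forces[[i]]))
    if (fmax_i > 1e6) {
      stop_divergence(sprintf("image %d: forces blowing up (%.3g eV/A)",
                              i, fmax_i))
    }
    if (!is.null(potential$check_topology)) {
      label <- potential$check_topology(band$images[[i]])
      if (!is.null(label)) {
        stop_divergence(sprintf("image %d: bonded topology broken", i),
                        label = label)
      }
    }
  }
  invisible(TRUE)
}

#' Relax a structure to a force threshold
#'
#' Damped L-BFGS descent on the true forces until the max per-atom force
#' norm is at most `fmax`. Deterministic given identical inputs.
#'
#' @param s a [structure3d()].
#' @param potential a [potential_model()].
#' @param fmax convergence threshold, eV/A.
#' @param max_steps step budget.
#' @param max_step largest per-atom displacement per step, Angstrom.
#' @return The relaxed structure with a `report` attribute.
#' @export
optimize_structure <- function(s, potential, fmax = 1e-4, max_steps = 2000,
                               max_step = 0.2) {
  st <- lbfgs_state(25, h0 = 1 / 70, max_step = max_step)
  converged <- FALSE
  fm <- NA_real_
  steps <- 0L
  f_first <- Inf
  for (step in seq_len(max_steps)) {
    f <- model_forces(potential, s)
    fm <- sqrt(max(rowSums(f^2)))
    if (step == 1L) f_first <- fm
    if (fm > 1e6) {
      stop_divergence(sprintf("relaxation diverged (max|F| = %.3g eV/A)", fm))
    }
    steps <- step - 1L
    if (fm <= fmax) { converged <- TRUE; break }
    st$max_step <- if (fm > 10) {
      max(max_step * sqrt(10 / fm), 0.2 * max_step)
    } else max_step
    dx <- lbfgs_step(st, as.vector(s$coords), as.vector(-f))
    s$coords <- s$coords + matrix(dx, ncol = 3)
  }
  if (!converged) {
    f <- model_forces(potential, s)
    fm <- sqrt(max(rowSums(f^2)))
    if (fm > fmax) {
      warning(sprintf("relaxation not converged in %d steps (max|F| = %.3g)",
                      max_steps, fm))
    } else converged <- TRUE
  }
  attr(s, "report") <- list(converged = converged, steps = steps, fmax = fm)
  s
}

#' Two-segment path protocol
#'
#' Runs two chain optimizations over three relaxed structures (a -> b and
#' b -> c), the middle structure serving as product of the first segment and
#' reactant of the second, then stitches the two converged bands dropping
#' the duplicated shared image. With K images per segment the stitched band
#' has 2K - 1 images, tagged `P_1` ... `P_(2K-1)`.
#'
#' @param a,b,c composition-identical [structure3d()].
#' @param potential a [potential_model()].
#' @param cfg a [neb_config()] applied to both segments.
#' @return Stitched [neb_band()]; `report` attribute holds per-segment
#'   reports (`segment1`, `segment2`) with step counts and wall times.
#' @export
run_two_segment <- function(a, b, c, potential, cfg = neb_config()) {
  if (!same_composition(a, b) || !same_composition(b, c)) {
    stop("input error: the three structures must be composition-identical")
  }
  seg <- function(r, p, label) {
    band <- interpolate_linear(r, p, cfg$n_images)
    tryCatch(optimize_band(band, potential, cfg),
             rotapath_divergence = function(e) {
               stop_divergence(sprintf("%s diverged: %s", label,
                                       conditionMessage(e)))
             })
  }
  b1 <- seg(a, b, "segment 1 (NEB1)")
  b2 <- seg(b, c, "segment 2 (NEB2)")
  images <- c(b1$images, b2$images[-1])
  energies <- c(b1$energies, b2$energies[-1])
  forces <- c(b1$forces, b2$forces[-1])
  for (i in seq_along(images)) images[[i]]$tag <- sprintf("P_%d", i)
  stitched <- neb_band(images, energies, forces, fixed_ends = TRUE)
  attr(stitched, "report") <- list(segment1 = attr(b1, "report"),
                                   segment2 = attr(b2, "report"))
  stitched
}

#' Barrier of a converged band relative to its first image
#' @param band a [neb_band()] with energies.
#' @param units `"ev"` or `"kjmol"`.
#' @export
band_barrier <- function(band, units = c("ev", "kjmol")) {
  units <- match.arg(units)
  i <- band$climbing_index %||% which.max(band$energies)
  de <- band$energies[i] - band$energies[1]
  if (units == "kjmol") de * EV_TO_KJMOL else de
}
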