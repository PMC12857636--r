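#' Potential model contract
#'
#' A `potential_model` supplies the energy (eV) and forces (eV/Angstrom,
#' negative gradient) of a [structure3d()]. The nudged-elastic-band engine,
#' the relaxation and frequency routines, and the profile analyses all work
#' against this contract, so analytic benchmark surfaces, the coarse-grained
#' threading force field and external calculators are interchangeable.
#'
#' @param name model name.
#' @param energy_of function(structure) -> scalar energy in eV.
#' @param forces_of function(structure) -> n x 3 matrix of forces in eV/A.
#' @param supports_subsystems can host/guest fragments be evaluated alone?
#' @param check_topology optional function(structure) returning `NULL` when
#'   the bonded topology is intact or a character label (e.g. `"MB"`) naming
#'   the failure; used by the optimizer for divergence detection.
#' @return An object of class `potential_model`.
#' @export
potential_model <- function(name, energy_of, forces_of,
                            supports_subsystems = FALSE,
                            check_topology = NULL) {
  stopifnot(is.function(energy_of), is.function(forces_of))
  m <- list(name = as.character(name)[1], energy_of = energy_of,
            forces_of = forces_of,
            supports_subsystems = isTRUE(supports_subsystems),
            check_topology = check_topology)
  class(m) <- "potential_model"
  m
}

#' @export
print.potential_model <- function(x, ...) {
  cat(sprintf("<potential_model> %s (subsystems: %s)\n", x$name,
              x$supports_subsystems))
  invisible(x)
}

#' Evaluate a model's energy
#' @param model a `potential_model`. @param s a `structure3d`.
#' @export
model_energy <- function(model, s) {
  e <- model$energy_of(s)
  if (!is.finite(e)) {
    stop_divergence(sprintf("non-finite energy from model '%s'", model$name))
  }
  e
}

#' Evaluate a model's forces
#' @param model a `potential_model`. @param s a `structure3d`.
#' @export
model_forces <- function(model, s) {
  f <- model$forces_of(s)
  f <- as.matrix(f)
  if (!all(is.finite(f))) {
    stop_divergence(sprintf("non-finite force from model '%s'", model$name))
  }
  f
}

stop_divergence <- function(msg, label = NULL) {
  stop(errorCondition(paste0(msg, if (!is.null(label)) paste0(" [", label, "]")),
                      class = c("rotapath_divergence", "error"),
                      label = label))
}

# ---------------------------------------------------------------------------
# analytic benchmark surfaces
# ---------------------------------------------------------------------------

#' Analytic benchmark surfaces for the path-search engine
#'
#' Three low-dimensional analytic surfaces with exact gradients, each wrapped
#' as a [potential_model()] acting on fictitious atoms so the full chain
#' machinery can be validated against closed-form or dense-grid results:
#'
#' * `double_well_1d`: E(x) = (x^2 - 1)^2 — minima at x = +/-1 (E = 0),
#'   saddle at x = 0 (E = 1). One atom; only its x coordinate matters.
#' * `muller_brown`: the standard four-Gaussian two-dimensional surface
#'   (literature parameterization) on the (x, y) plane of one atom.
#' * `leps_like`: a collinear triatomic LEPS-type surface in the two bond
#'   lengths (rAB, rBC), standard parameterization.
#'
#' These surfaces are functions of absolute coordinates in a fixed frame, so
#' (unlike molecular models) they are deliberately not invariant under rigid
#' motion.
#'
#' @param name one of `"muller_brown"`, `"double_well_1d"`, `"leps_like"`.
#' @return A list with `name`, `n_dim`, `energy_at(point)`,
#'   `gradient_at(point)` and `model` (the wrapped `potential_model`).
#' @export
benchmark_surface <- function(name) {
  surfaces <- list(
    double_well_1d = list(n_dim = 1, fn = dw1d_eg),
    muller_brown   = list(n_dim = 2, fn = mb_eg),
    leps_like      = list(n_dim = 2, fn = leps_eg)
  )
  if (!name %in% names(surfaces)) {
    stop("unknown benchmark surface: '", name, "' (available: ",
         paste(names(surfaces), collapse = ", "), ")")
  }
  def <- surfaces[[name]]
  fn <- def$fn
  nd <- def$n_dim
  energy_at <- function(point) {
    stopifnot(length(point) == nd)
    fn(point)$e
  }
  gradient_at <- function(point) {
    stopifnot(length(point) == nd)
    fn(point)$g
  }
  model <- potential_model(
    name = name,
    energy_of = function(s) fn(s$coords[1, seq_len(nd)])$e,
    forces_of = function(s) {
      f <- matrix(0, n_atoms(s), 3)
      f[1, seq_len(nd)] <- -fn(s$coords[1, seq_len(nd)])$g
      f
    }
  )
  list(name = name, n_dim = nd, energy_at = energy_at,
       gradient_at = gradient_at, model = model)
}

#' Wrap a low-dimensional point as a one-atom structure
#' @param point numeric vector of up to 3 surface coordinates.
#' @param tag optional tag.
#' @export
point_structure <- function(point, tag = "") {
  xyz <- c(point, rep(0, 3 - length(point)))
  structure3d("X", matrix(xyz, 1, 3), tag = tag)
}

dw1d_eg <- function(p) {
  x <- p[1]
  list(e = (x^2 - 1)^2, g = 4 * x * (x^2 - 1))
}

# Muller-Brown, standard constants
MB_A  <- c(-200, -100, -170, 15)
MB_a  <- c(-1, -1, -6.5, 0.7)
MB_b  <- c(0, 0, 11, 0.6)
MB_c  <- c(-10, -10, -6.5, 0.7)
MB_x0 <- c(1, 0, -0.5, -1)
MB_y0 <- c(0, 0.5, 1.5, 1)

mb_eg <- function(p) {
  dx <- p[1] - MB_x0
  dy <- p[2] - MB_y0
  t <- MB_A * exp(MB_a * dx^2 + MB_b * dx * dy + MB_c * dy^2)
  list(e = sum(t),
       g = c(sum(t * (2 * MB_a * dx + MB_b * dy)),
             sum(t * (MB_b * dx + 2 * MB_c * dy))))
}

#' Vectorised Muller-Brown energies (for dense-grid oracles)
#' @param x,y coordinate vectors (recycled outer-style: same length).
#' @export
muller_brown_energy <- function(x, y) {
  e <- 0
  for (k in 1:4) {
    e <- e + MB_A[k] * exp(MB_a[k] * (x - MB_x0[k])^2 +
                           MB_b[k] * (x - MB_x0[k]) * (y - MB_y0[k]) +
                           MB_c[k] * (y - MB_y0[k])^2)
  }
  e
}

# LEPS-type surface coupled to a harmonic degree of freedom: atom B moves
# on the A--C line (A, C fixed at separation l) with coordinate x = rAB,
# and a harmonic oscillator y couples to it. The standard chain-method
# benchmark: two minima in the entrance/exit channels, one saddle between.
leps_eg <- function(p) {
  a <- 0.05; b <- 0.80; cc <- 0.05
  d <- c(4.746, 4.746, 3.445); r0 <- 0.742; al <- 1.942
  l <- 3.742; kc <- 0.2025; cw <- 1.154
  x <- p[1]; y <- p[2]
  r <- c(x, l - x, l)
  ex1 <- exp(-al * (r - r0)); ex2 <- ex1^2
  Q <- d / 2 * (1.5 * ex2 - ex1)
  J <- d / 4 * (ex2 - 6 * ex1)
  dQ <- d / 2 * (-3 * al * ex2 + al * ex1)
  dJ <- d / 4 * (-2 * al * ex2 + 6 * al * ex1)
  s <- 1 + c(a, b, cc)
  qs <- sum(Q / s)
  j1 <- J[1] / s[1]; j2 <- J[2] / s[2]; j3 <- J[3] / s[3]
  rad2 <- j1^2 + j2^2 + j3^2 - j1 * j2 - j2 * j3 - j1 * j3
  rad <- sqrt(max(rad2, 1e-300))
  dj <- c(2 * j1 - j2 - j3, 2 * j2 - j1 - j3, 2 * j3 - j1 - j2)
  dEdr <- dQ / s - dj * (dJ / s) / (2 * rad)
  h <- x - l / 2 + y / cw
  e <- qs - rad + 2 * kc * h^2
  list(e = e,
       g = c(dEdr[1] - dEdr[2] + 4 * kc * h,
             4 * kc * h / cw))
}

# ---------------------------------------------------------------------------
# external calculator adapter
# ---------------------------------------------------------------------------

#' Wrap an external calculator behind the potential contract
#'
#' `handle` is any object (typically a list of closures) exposing
#' `energy(structure)` in eV and `forces(structure)` in eV/Angstrom, for
#' example a bridge to a neural-network potential. The adapter validates the
#' capabilities and returns a [potential_model()], so external engines plug
#' into the chain optimizer unchanged.
#'
#' @param handle object with `$energy` and `$forces` functions.
#' @param name model name; defaults to `handle$name` or `"external"`.
#' @param supports_subsystems whether fragments may be evaluated alone.
#' @export
external_adapter <- function(handle, name = NULL, supports_subsystems = FALSE) {
  if (!is.function(handle$energy) || !is.function(handle$forces)) {
    stop("adapter error: handle must expose energy() and forces() functions")
  }
  potential_model(
    name = name %||% (handle$name %||% "external"),
    energy_of = function(s) handle$energy(s),
    forces_of = function(s) handle$forces(s),
    supports_subsystems = supports_subsystems
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Forces by central finite differences (validation oracle)
#'
#' Differentiates `model_energy()` numerically; used to verify that a
#' model's analytic forces are the negative energy gradient.
#'
#' @param model a `potential_model`. @param s a `structure3d`.
#' @param step finite-difference step in Angstrom.
#' @export
fd_forces <- function(model, s, step = 1e-4) {
  n <- n_atoms(s)
  f <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    for (d in 1:3) {
      sp <- s; sp$coords[i, d] <- sp$coords[i, d] + step
      sm <- s; sm$coords[i, d] <- sm$coords[i, d] - step
      f[i, d] <- -(model_energy(model, sp) - model_energy(model, sm)) / (2 * step)
    }
  }
  f
}
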