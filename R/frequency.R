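#' Finite-difference frequency verification of a stationary point
#'
#' Builds the Hessian by central finite differences of the model forces,
#' mass-weights it, and classifies the structure from the eigenvalue
#' spectrum. Up to six near-zero modes (|lambda| below `zero_tol`) are
#' expected as the free translations/rotations of a connected system; weakly
#' bound supramolecular fragments may show additional soft relative-motion
#' modes, which are counted and reported but do not change the
#' classification. Any negative eigenvalue beyond the threshold marks a
#' genuine imaginary mode.
#'
#' @param s a relaxed [structure3d()].
#' @param potential a [potential_model()].
#' @param fd_step finite-difference displacement, Angstrom.
#' @param fmax_endpoint the relaxation threshold the structure is expected
#'   to satisfy; a precondition error is raised if max|F| exceeds ten times
#'   this value.
#' @param zero_tol near-zero eigenvalue threshold (mass-weighted model
#'   units, eV/(A^2 amu)).
#' @return List with `eigenvalues` (ascending, mass-weighted),
#'   `classification` (`"minimum"` or `"has_imaginary_modes"`),
#'   `n_near_zero`, `n_negative` and the thresholds used.
#' @export
frequency_check <- function(s, potential, fd_step = 0.01,
                            fmax_endpoint = 1e-4, zero_tol = 1e-4) {
  f0 <- model_forces(potential, s)
  fm <- sqrt(max(rowSums(f0^2)))
  if (fm > 10 * fmax_endpoint) {
    stop(sprintf(
      "precondition error: structure not relaxed (max|F| = %.3g > 10 x %.1g)",
      fm, fmax_endpoint))
  }
  n <- n_atoms(s)
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    for (d in 1:3) {
      col <- 3 * (i - 1) + d
      sp <- s; sp$coords[i, d] <- sp$coords[i, d] + fd_step
      sm <- s; sm$coords[i, d] <- sm$coords[i, d] - fd_step
      dF <- (model_forces(potential, sp) - model_forces(potential, sm)) /
        (2 * fd_step)
      # H[a, col] = -dF_a/dx_col, rows in atom-major (x,y,z) order
      H[, col] <- -as.vector(t(dF))
    }
  }
  H <- (H + t(H)) / 2
  m <- rep(atomic_mass(s$symbols), each = 3)
  W <- 1 / sqrt(m)
  Hm <- H * outer(W, W)
  ev <- sort(eigen(Hm, symmetric = TRUE, only.values = TRUE)$values)
  near_zero <- abs(ev) < zero_tol
  negative <- ev < -zero_tol
  classification <- if (any(negative)) "has_imaginary_modes" else "minimum"
  list(eigenvalues = ev, classification = classification,
       n_near_zero = sum(near_zero), n_negative = sum(negative),
       zero_tol = zero_tol, fd_step = fd_step)
}
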