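#' Uniform 3D scalar field
#'
#' Grid geometry (origin, per-axis spacing, shape) is stored in Angstrom;
#' values of density-derived quantities are in atomic units, following NCI
#' and cube-file conventions. Optional per-point `gradient` (M x 3, a.u.)
#' and `hessian` (M x 6, packed xx, yy, zz, xy, xz, yz) arrays ride along.
#' Point ordering is z-fastest (cube-file order).
#'
#' @param origin grid origin, Angstrom (length 3).
#' @param spacing per-axis spacing, Angstrom (length 3 or scalar).
#' @param shape per-axis point counts (length 3).
#' @param values numeric vector, one value per grid point (z-fastest).
#' @param quantity one of `"density"`, `"rdg"`, `"signed_density"`.
#' @param gradient,hessian optional derivative arrays (see above).
#' @export
scalar_field <- function(origin, spacing, shape, values,
                         quantity = c("density", "rdg", "signed_density"),
                         gradient = NULL, hessian = NULL) {
  quantity <- match.arg(quantity)
  spacing <- rep(as.numeric(spacing), length.out = 3)
  shape <- as.integer(shape)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  if (length(values) != prod(shape)) stop("values length must match shape")
  if (!all(is.finite(values[!is.na(values)]))) stop("values must be finite")
  if (quantity == "density" && any(values < 0, na.rm = TRUE)) {
    stop("density fields must be >= 0")
  }
  f <- list(origin = as.numeric(origin), spacing = spacing, shape = shape,
            values = values, quantity = quantity, gradient = gradient,
            hessian = hessian)
  class(f) <- "scalar_field"
  f
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field> %s, %d x %d x %d @ %.3g A\n", x$quantity,
              x$shape[1], x$shape[2], x$shape[3], x$spacing[1]))
  invisible(x)
}

#' Grid-point coordinates of a field (Angstrom, z-fastest order)
#' @param field a [scalar_field()].
#' @export
grid_points <- function(field) {
  gx <- field$origin[1] + field$spacing[1] * (seq_len(field$shape[1]) - 1)
  gy <- field$origin[2] + field$spacing[2] * (seq_len(field$shape[2]) - 1)
  gz <- field$origin[3] + field$spacing[3] * (seq_len(field$shape[3]) - 1)
  cbind(rep(gx, each = field$shape[2] * field$shape[3]),
        rep(rep(gy, each = field$shape[3]), times = field$shape[1]),
        rep(gz, times = field$shape[1] * field$shape[2]))
}

# ---------------------------------------------------------------------------
# promolecular atomic densities
# ---------------------------------------------------------------------------

# Spherical free-atom densities as sums of exponential shells,
# rho_A(r) = sum_k c_k exp(-r / zeta_k) (atomic units; r in bohr).
# Core-shell decay lengths follow Slater-rule effective exponents
# (zeta = 1/(2 Zeff/n)); valence decay lengths are scaled by 1.3 to emulate
# the flatter interstitial tails of densities fitted to free atoms, which
# is what makes weak-interaction (low reduced-gradient) regions resolvable
# on standard 0.1 A grids. Coefficients are normalised shell-by-shell,
# c_k = N_k / (8 pi zeta_k^3), so each atom integrates exactly to its
# neutral electron count. The hydrogen entry is the exact ground-state
# hydrogenic density e^(-2r)/pi.
PROMOLECULAR_SHELLS <- list(
  H = list(n_el = 1,     zeta = 1 / 2),
  C = list(n_el = c(2, 4), zeta = c(1 / 11.4, 1.3 / 3.25)),
  N = list(n_el = c(2, 5), zeta = c(1 / 13.4, 1.3 / 3.90)),
  O = list(n_el = c(2, 6), zeta = c(1 / 15.4, 1.3 / 4.55))
)

promolecular_coefficients <- function(element) {
  sh <- PROMOLECULAR_SHELLS[[element]]
  if (is.null(sh)) {
    stop("unsupported-element error: no promolecular table for '", element, "'")
  }
  list(c = sh$n_el / (8 * pi * sh$zeta^3), zeta = sh$zeta)
}

#' Evaluate the promolecular density at arbitrary points
#'
#' Superposition of spherical exponential free-atom densities with analytic
#' gradient and Hessian. Coordinates in Angstrom; values in atomic units.
#'
#' @param s a [structure3d()] (elements must be tabulated: H, C, N, O).
#' @param points M x 3 matrix of evaluation points, Angstrom.
#' @param derivatives `"none"`, `"gradient"` or `"hessian"`.
#' @return List with `rho` (length M) and, when requested, `gradient`
#'   (M x 3) and `hessian` (M x 6 packed xx, yy, zz, xy, xz, yz), all a.u.
#' @export
promolecular_at <- function(s, points, derivatives = c("hessian", "gradient",
                                                       "none")) {
  derivatives <- match.arg(derivatives)
  P <- as.matrix(points) * ANGSTROM_TO_BOHR
  M <- nrow(P)
  rho <- numeric(M)
  want_g <- derivatives %in% c("gradient", "hessian")
  want_h <- derivatives == "hessian"
  G <- if (want_g) matrix(0, M, 3)
  Hk <- if (want_h) matrix(0, M, 6)
  for (a in seq_len(n_atoms(s))) {
    cf <- promolecular_coefficients(s$symbols[a])
    Ra <- s$coords[a, ] * ANGSTROM_TO_BOHR
    dx <- P[, 1] - Ra[1]; dy <- P[, 2] - Ra[2]; dz <- P[, 3] - Ra[3]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    r <- pmax(r, 1e-8)
    for (k in seq_along(cf$c)) {
      f <- cf$c[k] * exp(-r / cf$zeta[k])
      rho <- rho + f
      if (want_g || want_h) {
        fp <- -f / cf$zeta[k]                 # df/dr
        if (want_g) {
          G[, 1] <- G[, 1] + fp * dx / r
          G[, 2] <- G[, 2] + fp * dy / r
          G[, 3] <- G[, 3] + fp * dz / r
        }
        if (want_h) {
          fpp <- f / cf$zeta[k]^2             # d2f/dr2
          w2 <- (fpp - fp / r) / r^2          # coefficient of d_i d_j
          w1 <- fp / r                        # coefficient of delta_ij
          Hk[, 1] <- Hk[, 1] + w2 * dx * dx + w1
          Hk[, 2] <- Hk[, 2] + w2 * dy * dy + w1
          Hk[, 3] <- Hk[, 3] + w2 * dz * dz + w1
          Hk[, 4] <- Hk[, 4] + w2 * dx * dy
          Hk[, 5] <- Hk[, 5] + w2 * dx * dz
          Hk[, 6] <- Hk[, 6] + w2 * dy * dz
        }
      }
    }
  }
  out <- list(rho = rho)
  if (want_g) out$gradient <- G
  if (want_h) out$hessian <- Hk
  out
}

#' Promolecular density on a uniform grid
#'
#' @param s a [structure3d()].
#' @param box optional list with `origin` and `lengths` (Angstrom); default
#'   is the structure extent plus `padding` on every side.
#' @param spacing grid spacing, Angstrom.
#' @param padding default box padding, Angstrom.
#' @param derivatives which analytic derivative fields to attach.
#' @return A [scalar_field()] of quantity `"density"`.
#' @export
promolecular_density <- function(s, box = NULL, spacing = 0.1, padding = 3,
                                 derivatives = c("hessian", "gradient",
                                                 "none")) {
  derivatives <- match.arg(derivatives)
  if (is.null(box)) {
    lo <- apply(s$coords, 2, min) - padding
    hi <- apply(s$coords, 2, max) + padding
  } else {
    lo <- box$origin
    hi <- box$origin + box$lengths
  }
  spacing <- rep(spacing, length.out = 3)
  shape <- pmax(2L, as.integer(floor((hi - lo) / spacing)) + 1L)
  field <- scalar_field(lo, spacing, shape, numeric(prod(shape)), "density")
  ev <- promolecular_at(s, grid_points(field), derivatives)
  field$values <- ev$rho
  field$gradient <- ev$gradient
  field$hessian <- ev$hessian
  field
}

#' Reduced density gradient field
#'
#' `s = |grad rho| / (2 (3 pi^2)^(1/3) rho^(4/3))`, the NCI detector for
#' weak-interaction regions. Points with density below `rho_floor` are
#' masked (NA).
#'
#' @param density a density [scalar_field()] with gradient attached.
#' @param rho_floor density floor below which points are masked, a.u.
#' @export
reduced_density_gradient <- function(density, rho_floor = 1e-10) {
  stopifnot(density$quantity == "density")
  if (is.null(density$gradient)) stop("density field lacks gradients")
  gnorm <- sqrt(rowSums(density$gradient^2))
  rho <- density$values
  s <- gnorm / (2 * (3 * pi^2)^(1 / 3) * rho^(4 / 3))
  s[rho < rho_floor] <- NA_real_
  scalar_field(density$origin, density$spacing, density$shape, s, "rdg")
}

# middle eigenvalue of symmetric 3x3 matrices, vectorised (trigonometric
# closed form); Hs is M x 6 packed xx, yy, zz, xy, xz, yz
lambda2_of_hessian <- function(Hs) {
  a11 <- Hs[, 1]; a22 <- Hs[, 2]; a33 <- Hs[, 3]
  a12 <- Hs[, 4]; a13 <- Hs[, 5]; a23 <- Hs[, 6]
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
  detB <- b11 * (b22 * b33 - a23^2) - a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(1, pmax(-1, r))
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)                 # largest
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)    # smallest
  3 * q - l1 - l3
}

#' Density signed by the middle Hessian eigenvalue
#'
#' `sign(lambda_2) * rho`: negative in attractive (hydrogen-bond-like)
#' regions, positive in repulsive (steric-clash) regions. Eigenvalues of
#' the density Hessian are sorted ascending; lambda_2 is the second.
#'
#' @param density a density [scalar_field()] with Hessian attached.
#' @export
sign_lambda2_density <- function(density) {
  stopifnot(density$quantity == "density")
  if (is.null(density$hessian)) stop("density field lacks Hessian")
  l2 <- lambda2_of_hessian(density$hessian)
  scalar_field(density$origin, density$spacing, density$shape,
               sign(l2) * density$values, "signed_density")
}

#' Noncovalent-interaction basin summary
#'
#' Quantitative reading of an NCI isosurface picture: connected grid regions
#' (6-neighbour) where the reduced density gradient falls below `iso_s`
#' inside the density window, each labelled intra- or intermolecular from
#' the host/guest partition and scored by its minimum signed density.
#'
#' @param s a [structure3d()]; `host`/`guest` groups, when present, drive
#'   the inter/intra labelling (without them every basin is intramolecular).
#' @param iso_s reduced-density-gradient isovalue.
#' @param rho_window density window (a.u.) selecting weak-interaction points.
#' @param spacing grid spacing, Angstrom.
#' @param padding box padding, Angstrom.
#' @return A tibble, one row per basin, sorted by volume (then by minimum
#'   signed density): `basin`, `n_voxels`, `volume_a3`, `min_signed_rho`,
#'   `label`, `x`, `y`, `z` (centroid, Angstrom). Empty window gives an
#'   empty tibble.
#' @export
nci_summary <- function(s, iso_s = 0.3, rho_window = c(1e-3, 0.05),
                        spacing = 0.1, padding = 3) {
  density <- promolecular_density(s, spacing = spacing, padding = padding,
                                  derivatives = "gradient")
  rdg <- reduced_density_gradient(density)
  keep <- which(!is.na(rdg$values) & rdg$values < iso_s &
                density$values >= rho_window[1] &
                density$values <= rho_window[2])
  empty <- tibble::tibble(basin = integer(0), n_voxels = integer(0),
                          volume_a3 = numeric(0), min_signed_rho = numeric(0),
                          label = character(0), x = numeric(0), y = numeric(0),
                          z = numeric(0))
  if (length(keep) == 0) return(empty)
  comp <- grid_components(keep, density$shape)
  pts <- grid_points(density)
  # signed density only where needed
  hes <- promolecular_at(s, pts[keep, , drop = FALSE], "hessian")
  signed <- sign(lambda2_of_hessian(hes$hessian)) * hes$rho
  vvol <- prod(density$spacing)
  host <- s$groups$host; guest <- s$groups$guest
  rows <- lapply(split(seq_along(keep), comp), function(ii) {
    vox <- keep[ii]
    sd_min_i <- ii[which.min(signed[ii])]
    crit <- pts[keep[sd_min_i], ]
    label <- "intramolecular"
    if (!is.null(host) && !is.null(guest)) {
      dall <- sqrt(colSums((t(s$coords) - crit)^2))
      near2 <- order(dall)[1:2]
      if (any(near2 %in% host) && any(near2 %in% guest)) {
        label <- "intermolecular"
      }
    }
    cen <- colMeans(pts[vox, , drop = FALSE])
    tibble::tibble(n_voxels = length(vox), volume_a3 = length(vox) * vvol,
                   min_signed_rho = min(signed[ii]), label = label,
                   x = cen[1], y = cen[2], z = cen[3])
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, dplyr::desc(.data$volume_a3),
                        .data$min_signed_rho)
  dplyr::bind_cols(tibble::tibble(basin = seq_len(nrow(out))), out)
}

# connected components (6-neighbour) of a voxel index subset; returns a
# component id per element of `keep` (deterministic labelling)
grid_components <- function(keep, shape) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  # z-fastest linear index -> (ix, iy, iz)
  iz <- (keep - 1) %% nz
  iy <- ((keep - 1) %/% nz) %% ny
  ix <- (keep - 1) %/% (nz * ny)
  pos <- integer(nx * ny * nz)
  pos[keep] <- seq_along(keep)
  edges <- integer(0)
  add_dir <- function(dx, dy, dz) {
    ok <- ix + dx < nx & iy + dy < ny & iz + dz < nz
    nb <- keep[ok] + dz + dy * nz + dx * nz * ny
    has <- pos[nb] > 0
    rbind(pos[keep[ok]][has], pos[nb][has])
  }
  e <- cbind(add_dir(1, 0, 0), add_dir(0, 1, 0), add_dir(0, 0, 1))
  if (length(e) == 0) return(seq_along(keep))
  g <- igraph::graph_from_edgelist(t(e), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(keep) - igraph::vcount(g)))
  igraph::components(g)$membership[seq_along(keep)]
}
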