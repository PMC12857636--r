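#' Normalized displacement coordinate of a band
#'
#' The reaction coordinate of a converged chain: the cumulative Euclidean
#' distance between consecutive images over all 3N coordinates, normalized
#' by the total path length (`s_i / s_N`, with `s_1 = 0`). Energies are
#' reported relative to the first image, in kJ/mol. With `align = TRUE`
#' every image is first rigid-body superposed onto its predecessor (see
#' [kabsch_superpose()]) before distances are accumulated.
#'
#' @param band a [neb_band()] with >= 2 images and energies.
#' @param align superpose each image onto its predecessor first?
#' @return An `ndc_profile` object; its `data` element is a tibble with one
#'   row per image (`image`, `tag`, `ndc`, `energy_rel`).
#' @export
compute_ndc <- function(band, align = FALSE) {
  if (length(band$images) < 2) stop("need at least 2 images")
  if (is.null(band$energies)) stop("state error: band energies not populated")
  images <- band$images
  if (align) {
    for (i in 2:length(images)) {
      images[[i]] <- kabsch_superpose(images[[i]], images[[i - 1]])$structure
    }
  }
  seg <- vapply(2:length(images), function(i) {
    sqrt(sum((images[[i]]$coords - images[[i - 1]]$coords)^2))
  }, numeric(1))
  s <- c(0, cumsum(seg))
  if (s[length(s)] <= 0) stop("degenerate-path error: total path length is 0")
  ndc <- s / s[length(s)]
  tags <- vapply(band$images, `[[`, character(1), "tag")
  p <- list(
    data = tibble::tibble(
      image = seq_along(band$images),
      tag = ifelse(nzchar(tags), tags, sprintf("P_%d", seq_along(tags))),
      ndc = ndc,
      energy_rel = (band$energies - band$energies[1]) * EV_TO_KJMOL
    ),
    align = align,
    stages = NULL, barrier = NULL
  )
  class(p) <- "ndc_profile"
  p
}

#' @export
print.ndc_profile <- function(x, ...) {
  cat(sprintf("<ndc_profile> %d images, energy span %.2f kJ/mol%s\n",
              nrow(x$data), diff(range(x$data$energy_rel)),
              if (!is.null(x$barrier))
                sprintf(", barrier %.2f kJ/mol", x$barrier) else ""))
  invisible(x)
}

#' Least-squares rigid-body superposition
#'
#' Rotates and translates `mobile` onto `reference` minimizing the RMSD,
#' with the proper-rotation constraint (determinant +1), so mirror images
#' are never matched by an improper operation.
#'
#' @param mobile,reference composition-identical [structure3d()].
#' @return List with `structure` (superposed mobile) and `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(mobile, reference) {
  if (!same_composition(mobile, reference)) {
    stop("input error: structures must be composition-identical")
  }
  P <- mobile$coords
  Q <- reference$coords
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- t(P0) %*% Q0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Pnew <- P0 %*% t(R)
  Pnew <- sweep(Pnew, 2, cq, "+")
  out <- mobile
  out$coords <- Pnew
  list(structure = out, rmsd = sqrt(mean(rowSums((Pnew - Q)^2))))
}

#' Host-guest interaction energy
#'
#' `E_int = E(complex) - E(host alone) - E(guest alone)`, in kJ/mol. At the
#' start of a well-prepared threading path the fragments are effectively
#' non-interacting and this quantity is zero.
#'
#' @param complex_s a [structure3d()] with a `host`/`guest` partition.
#' @param potential a [potential_model()] with `supports_subsystems`.
#' @export
interaction_energy <- function(complex_s, potential) {
  if (is.null(complex_s$groups$host) || is.null(complex_s$groups$guest)) {
    stop("input error: structure needs 'host' and 'guest' groups")
  }
  if (!potential$supports_subsystems) {
    stop("potential does not support subsystem evaluation")
  }
  e_all <- model_energy(potential, complex_s)
  e_h <- model_energy(potential, subset_atoms(complex_s, complex_s$groups$host))
  e_g <- model_energy(potential, subset_atoms(complex_s, complex_s$groups$guest))
  (e_all - e_h - e_g) * EV_TO_KJMOL
}

# interior local minima of a series; a flat plateau flanked by ascents on
# both sides counts once, at its lower index
local_minima <- function(e) {
  n <- length(e)
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && e[j + 1L] == e[i]) j <- j + 1L
    if (e[i - 1L] > e[i] && j < n && e[j + 1L] > e[i]) out <- c(out, i)
    i <- j + 1L
  }
  out
}

#' Four-stage segmentation of an energy profile
#'
#' Partitions the images into the four stages of a threading profile based
#' on the energy behaviour: *initialization* is the maximal leading run
#' whose relative energy stays within `eps_flat` of zero; *activation* is
#' the contiguous ascent-to-descent window around the global maximum,
#' bounded (exclusively) by the last local minimum before it and the first
#' local minimum after it, so the pre-barrier dip closes *preparation* and
#' the post-barrier minimum opens *stabilization*; *preparation* lies
#' between initialization and activation; *stabilization* is the remainder.
#' Extrema are located on the raw profile; plateau ties
#' break toward the lower index. The rule parameters are echoed in the
#' result.
#'
#' @param profile an `ndc_profile`.
#' @param eps_flat flatness threshold for stage 1, kJ/mol.
#' @return A `stage_segmentation` object (list of four index ranges plus
#'   `rule_parameters`).
#' @export
segment_stages <- function(profile, eps_flat = 1.0) {
  e <- profile$data$energy_rel
  n <- length(e)
  m <- which.max(e)
  if (m == 1 || m == n) {
    stop("no-barrier error: global maximum sits at an endpoint")
  }
  flat <- abs(e) <= eps_flat
  i1 <- if (flat[1]) { r <- rle(flat); r$lengths[1] } else 0L
  if (i1 >= m) {
    stop("no-barrier error: flat initialization swallows the energy maximum")
  }
  mins <- local_minima(e)
  # the ascent-to-descent window around the global maximum runs between the
  # flanking local minima, exclusive: the pre-barrier dip belongs to
  # preparation (it is the reference of the barrier) and the post-barrier
  # minimum opens the stabilization stage
  pre <- mins[mins > i1 & mins < m]
  p_lo <- if (length(pre)) max(pre) else i1
  post <- mins[mins > m]
  q_hi <- if (length(post)) min(post) else n + 1L
  seg <- list(
    initialization = if (i1 >= 1) c(1L, i1) else integer(0),
    preparation = if (p_lo > i1) c(i1 + 1L, p_lo) else integer(0),
    activation = c(p_lo + 1L, q_hi - 1L),
    stabilization = if (q_hi <= n) c(q_hi, n) else integer(0),
    rule_parameters = list(eps_flat = eps_flat,
                           rule = "leading-flat / between-flanking-minima window")
  )
  class(seg) <- "stage_segmentation"
  seg
}

#' @export
print.stage_segmentation <- function(x, ...) {
  for (nm in c("initialization", "preparation", "activation", "stabilization")) {
    r <- x[[nm]]
    cat(sprintf("  %-14s %s\n", nm,
                if (length(r)) sprintf("images %d..%d", r[1], r[2]) else "(empty)"))
  }
  invisible(x)
}

stage_labels <- function(seg, n) {
  lab <- rep(NA_character_, n)
  for (nm in c("initialization", "preparation", "activation", "stabilization")) {
    r <- seg[[nm]]
    if (length(r)) lab[r[1]:r[2]] <- nm
  }
  lab
}

#' Barrier height from a segmented profile
#'
#' The activation barrier of the threading process: the energy difference
#' between the maximum in the activation stage and the minimum in the
#' preparation stage (kJ/mol); always non-negative.
#'
#' @param profile an `ndc_profile`.
#' @param seg a `stage_segmentation` for the same profile.
#' @export
extract_barrier <- function(profile, seg) {
  e <- profile$data$energy_rel
  if (!length(seg$activation)) stop("no-barrier error: empty activation stage")
  act <- e[seg$activation[1]:seg$activation[2]]
  prep <- if (length(seg$preparation)) {
    e[seg$preparation[1]:seg$preparation[2]]
  } else {
    # no distinct preparation window: reference the initialization plateau
    e[seg$initialization[1]:seg$initialization[2]]
  }
  max(act) - min(prep)
}

# ---------------------------------------------------------------------------
# geometric descriptors
# ---------------------------------------------------------------------------

#' Macrocycle-opening descriptor D^max_OO
#'
#' For each ring oxygen, the maximum distance to any other ring oxygen; the
#' descriptor is the mean of these per-atom maxima (Angstrom). Tracks the
#' expansion of the macrocycle cavity along the path.
#'
#' @param s a [structure3d()] with a `ring_oxygens` group of >= 2 atoms.
#' @export
descriptor_dmax_oo <- function(s) {
  ix <- s$groups$ring_oxygens
  if (is.null(ix) || length(ix) < 2) {
    stop("input error: need a 'ring_oxygens' group with >= 2 atoms")
  }
  X <- s$coords[ix, , drop = FALSE]
  D <- as.matrix(stats::dist(X))
  mean(apply(D, 1, max))
}

#' Hydrogen-bond donor-acceptor distance D_N...O
#'
#' Minimum distance between the donor nitrogen and any ring oxygen
#' (Angstrom).
#'
#' @param s a [structure3d()] with `donor_N` (one atom) and `ring_oxygens`.
#' @export
descriptor_hbond <- function(s) {
  dn <- s$groups$donor_N
  ox <- s$groups$ring_oxygens
  if (is.null(dn) || length(dn) != 1 || is.null(ox) || length(ox) < 1) {
    stop("input error: need 'donor_N' (1 atom) and 'ring_oxygens' groups")
  }
  min(sqrt(colSums((t(s$coords[ox, , drop = FALSE]) - s$coords[dn, ])^2)))
}

#' Distance between phenyl-ring centres of mass D_CM
#'
#' Distance between the mass-weighted centroids of the `phenyl_A` and
#' `phenyl_B` groups (standard atomic masses), in Angstrom.
#'
#' @param s a [structure3d()] with `phenyl_A` and `phenyl_B` groups.
#' @export
descriptor_ring_cm <- function(s) {
  a <- s$groups$phenyl_A; b <- s$groups$phenyl_B
  if (is.null(a) || is.null(b)) {
    stop("input error: need 'phenyl_A' and 'phenyl_B' groups")
  }
  com <- function(ix) {
    m <- atomic_mass(s$symbols[ix])
    colSums(s$coords[ix, , drop = FALSE] * m) / sum(m)
  }
  sqrt(sum((com(a) - com(b))^2))
}

#' Assemble the full profile of a converged band
#'
#' Computes the normalized displacement coordinate and relative energies,
#' evaluates every geometric descriptor whose atom groups are annotated on
#' the images, segments the profile into the four stages and extracts the
#' barrier. The per-image table (tibble) carries one row per image with
#' `image`, `tag`, `ndc`, `energy_rel`, descriptor columns and `stage`.
#'
#' @param band a converged [neb_band()].
#' @param align align images before accumulating path length?
#' @param eps_flat flatness threshold for stage detection, kJ/mol.
#' @return An `ndc_profile` with `stages`, `barrier` and descriptor columns
#'   populated.
#' @export
build_profile <- function(band, align = FALSE, eps_flat = 1.0) {
  p <- compute_ndc(band, align = align)
  desc <- list(
    d_max_oo = function(s) descriptor_dmax_oo(s),
    d_no = function(s) descriptor_hbond(s),
    d_cm = function(s) descriptor_ring_cm(s)
  )
  available <- c(
    d_max_oo = !is.null(band$images[[1]]$groups$ring_oxygens) &&
      length(band$images[[1]]$groups$ring_oxygens) >= 2,
    d_no = !is.null(band$images[[1]]$groups$donor_N) &&
      !is.null(band$images[[1]]$groups$ring_oxygens),
    d_cm = !is.null(band$images[[1]]$groups$phenyl_A) &&
      !is.null(band$images[[1]]$groups$phenyl_B)
  )
  for (nm in names(desc)[available]) {
    p$data[[nm]] <- vapply(band$images, desc[[nm]], numeric(1))
  }
  p$stages <- segment_stages(p, eps_flat = eps_flat)
  p$data$stage <- stage_labels(p$stages, nrow(p$data))
  p$barrier <- extract_barrier(p, p$stages)
  p
}

#' Write a profile as a delimited table
#' @param profile an `ndc_profile`. @param path output path (TSV).
#' @export
write_profile <- function(profile, path) {
  write_atomic(path, function(tmp) {
    utils::write.table(profile$data, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  invisible(path)
}
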