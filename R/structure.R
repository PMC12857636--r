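#' Molecular structure container
#'
#' A `structure3d` is the universal geometry record: element symbols,
#' Cartesian coordinates in Angstrom, optional named atom groups (disjoint
#' index sets such as `ring_oxygens`, `donor_N`, `host`, `guest`) and a
#' free-text tag. When both `host` and `guest` groups are present they must
#' partition the atom set.
#'
#' @param symbols character vector of element labels.
#' @param coords numeric n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param groups named list of integer index vectors.
#' @param tag free-text label (e.g. `"P_162"`).
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(symbols, coords, groups = list(), tag = "") {
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3) {
    stop("coords must be an n x 3 matrix")
  }
  storage.mode(coords) <- "double"
  if (length(symbols) != nrow(coords)) {
    stop("symbols and coords must have the same length")
  }
  if (!all(is.finite(coords))) stop("coords must be finite")
  dimnames(coords) <- NULL
  s <- list(symbols = as.character(symbols), coords = coords,
            groups = validate_groups(groups, nrow(coords)),
            tag = as.character(tag)[1])
  class(s) <- "structure3d"
  s
}

validate_groups <- function(groups, n_atoms) {
  if (length(groups) == 0) return(list())
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be a named list")
  }
  groups <- lapply(groups, function(ix) {
    ix <- as.integer(ix)
    if (any(ix < 1L | ix > n_atoms)) stop("group index out of range")
    if (anyDuplicated(ix)) stop("group indices must be unique within a group")
    ix
  })
  hg <- intersect(c("host", "guest"), names(groups))
  if (length(hg) == 2) {
    both <- c(groups$host, groups$guest)
    if (anyDuplicated(both) || length(both) != n_atoms) {
      stop("'host' and 'guest' must partition the atom set")
    }
  }
  groups
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("<structure3d> %d atoms%s\n", n_atoms(x),
              if (nzchar(x$tag)) paste0(" [", x$tag, "]") else ""))
  if (length(x$groups)) {
    cat("  groups:", paste(sprintf("%s(%d)", names(x$groups),
                                   lengths(x$groups)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `structure3d`.
#' @export
n_atoms <- function(s) nrow(s$coords)

#' Extract a subset of atoms as a new structure
#'
#' Groups are remapped to the new indexing; groups with no surviving atoms
#' are dropped.
#'
#' @param s a `structure3d`.
#' @param idx integer vector of atom indices to keep.
#' @param tag tag for the subset; defaults to the parent tag.
#' @export
subset_atoms <- function(s, idx, tag = s$tag) {
  idx <- as.integer(idx)
  map <- integer(n_atoms(s))
  map[idx] <- seq_along(idx)
  groups <- lapply(s$groups, function(g) map[g[g %in% idx]])
  groups <- groups[lengths(groups) > 0]
  structure3d(s$symbols[idx], s$coords[idx, , drop = FALSE], groups, tag)
}

#' Test whether two structures have identical composition and atom order
#' @param a,b `structure3d` objects.
#' @export
same_composition <- function(a, b) {
  n_atoms(a) == n_atoms(b) && all(a$symbols == b$symbols)
}

#' @export
as.data.frame.structure3d <- function(x, ...) {
  data.frame(symbol = x$symbols, x = x$coords[, 1], y = x$coords[, 2],
             z = x$coords[, 3])
}

#' Apply a rigid-body motion to a structure
#' @param s a `structure3d`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 shift vector (Angstrom).
#' @export
transform_structure <- function(s, rotation = diag(3), translation = c(0, 0, 0)) {
  s$coords <- s$coords %*% t(rotation) +
    matrix(translation, n_atoms(s), 3, byrow = TRUE)
  s
}

# deterministic random rotation matrix from 3 uniforms (used by tests/fixtures)
rotation_from_uniforms <- function(u) {
  ang <- c(2 * pi * u[1], acos(2 * u[2] - 1), 2 * pi * u[3])
  rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  ry <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
                           3, 3, byrow = TRUE)
  rz(ang[1]) %*% ry(ang[2]) %*% rz(ang[3])
}
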