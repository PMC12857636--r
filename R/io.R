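#' @section Extended XYZ dialect:
#' Structures travel as plain XYZ with a key=value comment line:
#' `energy=<eV> tag="..." groups=host:1-6;guest:7-13;ring_oxygens:3,6`.
#' Index lists use 1-based ranges (`a-b`) and commas; groups are separated
#' by semicolons. Plain XYZ without annotations reads back as a structure
#' with empty groups. Coordinates are written with 17 significant digits so
#' write/read round-trips are bit-identical.
#' @name rotapath-io
#' @keywords internal
NULL

encode_indices <- function(ix) {
  ix <- sort(as.integer(ix))
  if (!length(ix)) return("")
  breaks <- c(0, which(diff(ix) != 1), length(ix))
  parts <- vapply(seq_len(length(breaks) - 1), function(k) {
    a <- ix[breaks[k] + 1]; b <- ix[breaks[k + 1]]
    if (a == b) as.character(a) else paste0(a, "-", b)
  }, character(1))
  paste(parts, collapse = ",")
}

decode_indices <- function(txt) {
  if (!nzchar(txt)) return(integer(0))
  unlist(lapply(strsplit(txt, ",", fixed = TRUE)[[1]], function(p) {
    if (grepl("-", p, fixed = TRUE)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      ab[1]:ab[2]
    } else as.integer(p)
  }))
}

encode_comment <- function(s, energy = NULL) {
  parts <- character(0)
  if (!is.null(energy)) parts <- c(parts, sprintf("energy=%.17g", energy))
  if (nzchar(s$tag)) parts <- c(parts, sprintf('tag="%s"', s$tag))
  if (length(s$groups)) {
    g <- paste(vapply(names(s$groups), function(nm) {
      paste0(nm, ":", encode_indices(s$groups[[nm]]))
    }, character(1)), collapse = ";")
    parts <- c(parts, paste0("groups=", g))
  }
  paste(parts, collapse = " ")
}

decode_comment <- function(line) {
  out <- list(energy = NULL, tag = "", groups = list())
  pat <- '([A-Za-z_][A-Za-z0-9_]*)=("[^"]*"|[^ ]*)'
  m <- gregexpr(pat, line)[[1]]
  if (m[1] == -1) return(out)
  for (tok in regmatches(line, gregexpr(pat, line))[[1]]) {
    eq <- regexpr("=", tok, fixed = TRUE)
    key <- substr(tok, 1, eq - 1)
    val <- substr(tok, eq + 1, nchar(tok))
    val <- gsub('^"|"$', "", val)
    if (key == "energy") out$energy <- as.numeric(val)
    if (key == "tag") out$tag <- val
    if (key == "groups" && nzchar(val)) {
      for (grp in strsplit(val, ";", fixed = TRUE)[[1]]) {
        cc <- regexpr(":", grp, fixed = TRUE)
        out$groups[[substr(grp, 1, cc - 1)]] <-
          decode_indices(substr(grp, cc + 1, nchar(grp)))
      }
    }
  }
  out
}

#' Write structures or bands as (extended) XYZ
#'
#' Multi-frame for bands, with per-frame energies in the comment line.
#' Writing is atomic (temp file + rename), so interrupted runs never leave
#' truncated output.
#'
#' @param x a [structure3d()] or [neb_band()].
#' @param path output path.
#' @export
write_xyz <- function(x, path) {
  frames <- if (inherits(x, "neb_band")) x$images else list(x)
  energies <- if (inherits(x, "neb_band")) x$energies
  lines <- character(0)
  for (i in seq_along(frames)) {
    s <- frames[[i]]
    lines <- c(lines, as.character(n_atoms(s)),
               encode_comment(s, energies[i]),
               sprintf("%s %.17g %.17g %.17g", s$symbols, s$coords[, 1],
                       s$coords[, 2], s$coords[, 3]))
  }
  write_atomic(path, function(tmp) writeLines(lines, tmp))
  invisible(path)
}

#' Read (extended) XYZ
#'
#' @param path input path.
#' @return A [structure3d()] for single-frame files, a [neb_band()]
#'   otherwise (with energies when every frame carries one).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  frames <- list(); energies <- numeric(0); have_e <- TRUE
  ln <- 1L
  while (ln <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(nat) || nat < 1) {
      stop(sprintf("parse error at line %d: expected atom count", ln))
    }
    if (ln + 1L + nat > length(lines)) {
      stop(sprintf("parse error at line %d: frame truncated (%d atoms declared)",
                   ln, nat))
    }
    meta <- decode_comment(lines[ln + 1L])
    body <- lines[ln + 1L + seq_len(nat)]
    toks <- strsplit(trimws(body), "[ \t]+")
    bad <- which(lengths(toks) < 4)
    if (length(bad)) {
      stop(sprintf("parse error at line %d: need 'symbol x y z'",
                   ln + 1L + bad[1]))
    }
    sym <- vapply(toks, `[[`, character(1), 1)
    xyz <- t(vapply(toks, function(t) {
      suppressWarnings(as.numeric(t[2:4]))
    }, numeric(3)))
    if (any(is.na(xyz))) {
      stop(sprintf("parse error near line %d: non-numeric coordinate", ln + 2L))
    }
    frames <- c(frames, list(structure3d(sym, xyz, meta$groups, meta$tag)))
    if (is.null(meta$energy)) have_e <- FALSE else {
      energies <- c(energies, meta$energy)
    }
    ln <- ln + 2L + nat
  }
  if (length(frames) == 1) return(frames[[1]])
  neb_band(frames, energies = if (have_e) energies)
}

# ---------------------------------------------------------------------------
# Gaussian cube files
# ---------------------------------------------------------------------------

#' Write a scalar field as a Gaussian cube file
#'
#' Standard cube layout: bohr units, nuclear charges, values in z-fastest
#' order, six per line. High-precision values (12 digits) so round-trips
#' through [read_cube()] are exact to 1e-12.
#'
#' @param field a [scalar_field()].
#' @param s the [structure3d()] sharing the field's frame.
#' @param path output path.
#' @export
write_cube <- function(field, s, path) {
  b <- ANGSTROM_TO_BOHR
  z <- ATOMIC_NUMBERS[s$symbols]
  if (anyNA(z)) stop("no nuclear charge tabulated for some element")
  head <- c(
    "rotapath scalar field",
    field$quantity,
    sprintf("%5d %21.13E %21.13E %21.13E", n_atoms(s), field$origin[1] * b,
            field$origin[2] * b, field$origin[3] * b),
    sprintf("%5d %21.13E %21.13E %21.13E", field$shape[1],
            field$spacing[1] * b, 0, 0),
    sprintf("%5d %21.13E %21.13E %21.13E", field$shape[2], 0,
            field$spacing[2] * b, 0),
    sprintf("%5d %21.13E %21.13E %21.13E", field$shape[3], 0, 0,
            field$spacing[3] * b),
    sprintf("%5d %11.6f %21.13E %21.13E %21.13E", z, as.numeric(z),
            s$coords[, 1] * b, s$coords[, 2] * b, s$coords[, 3] * b)
  )
  vals <- field$values
  vals[is.na(vals)] <- 0
  n6 <- ceiling(length(vals) / 6) * 6
  vals6 <- c(sprintf("%20.12E", vals), rep("", n6 - length(vals)))
  body <- apply(matrix(vals6, ncol = 6, byrow = TRUE), 1, paste,
                collapse = " ")
  write_atomic(path, function(tmp) writeLines(c(head, body), tmp))
  invisible(path)
}

#' Read a Gaussian cube file
#' @param path input path.
#' @return List with `field` (a [scalar_field()]) and `structure`.
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  quantity <- trimws(lines[2])
  if (!quantity %in% c("density", "rdg", "signed_density")) quantity <- "density"
  num <- function(l) as.numeric(strsplit(trimws(l), "[ \t]+")[[1]])
  h3 <- num(lines[3]); nat <- as.integer(h3[1])
  ax <- lapply(4:6, function(i) num(lines[i]))
  shape <- vapply(ax, function(a) as.integer(a[1]), integer(1))
  spacing <- c(ax[[1]][2], ax[[2]][3], ax[[3]][4]) / ANGSTROM_TO_BOHR
  origin <- h3[2:4] / ANGSTROM_TO_BOHR
  at <- t(vapply(6 + seq_len(nat), function(i) num(lines[i]), numeric(5)))
  zsym <- names(ATOMIC_NUMBERS)[match(as.integer(at[, 1]), ATOMIC_NUMBERS)]
  s <- structure3d(zsym, at[, 3:5, drop = FALSE] / ANGSTROM_TO_BOHR)
  vals <- as.numeric(unlist(strsplit(trimws(lines[(7 + nat):length(lines)]),
                                     "[ \t]+")))
  vals <- vals[!is.na(vals)][seq_len(prod(shape))]
  list(field = scalar_field(origin, spacing, shape, vals, quantity),
       structure = s)
}

# atomic write contract: write to a temp file in the target directory, then
# rename into place
write_atomic <- function(path, writer) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("atomic write failed for ", path)
  invisible(path)
}
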