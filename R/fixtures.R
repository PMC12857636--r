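#' Built-in fixture generator
#'
#' Every test input the package needs is generated deterministically in
#' code — no downloads. Available fixtures:
#'
#' * `"cg_rotaxane"`: a coarse-grained ring + axle system (see
#'   [build_threading_model()]) with the unthreaded/midpoint/threaded
#'   triplet of endpoint geometries for the two-segment path protocol.
#'   `params` are forwarded to [threading_config()].
#' * `"water_dimer"`: the classic hydrogen-bonded water dimer (6 atoms,
#'   donor H pointing at the acceptor oxygen, O...H about 1.95 A), with
#'   `host`/`guest` groups marking the two molecules.
#' * `"separated_waters"`: the same two molecules displaced to 10 A
#'   oxygen-oxygen separation (no density overlap).
#' * `"benchmark_band"`: a linearly interpolated band between the two
#'   minima of an analytic benchmark surface (`params$surface`, default
#'   `"double_well_1d"`; `params$n_interior`, default 11).
#'
#' @param name fixture name.
#' @param params fixture-specific parameter list.
#' @param seed integer seed (recorded in output; drives the deterministic
#'   jitter of `cg_rotaxane`).
#' @param dir optional output directory; when given, geometries are written
#'   as extended XYZ (plus a config YAML for `cg_rotaxane`).
#' @return The fixture object (list or band; see above).
#' @export
generate_fixture <- function(name = c("cg_rotaxane", "water_dimer",
                                      "separated_waters", "benchmark_band"),
                             params = list(), seed = 1L, dir = NULL) {
  name <- match.arg(name)
  fx <- switch(name,
    cg_rotaxane = {
      cfg <- do.call(threading_config, c(params, list(seed = as.integer(seed))))
      build_threading_model(cfg)
    },
    water_dimer = water_dimer_structure(0),
    separated_waters = water_dimer_structure(10 - 2.91),
    benchmark_band = {
      surface <- params$surface %||% "double_well_1d"
      n_interior <- params$n_interior %||% 11L
      ends <- benchmark_minima(surface)
      interpolate_linear(point_structure(ends$a, "reactant"),
                         point_structure(ends$b, "product"), n_interior)
    }
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (name == "cg_rotaxane") {
      for (nm in names(fx$endpoints)) {
        write_xyz(fx$endpoints[[nm]], file.path(dir, paste0(nm, ".xyz")))
      }
      write_atomic(file.path(dir, "threading_config.yaml"), function(tmp) {
        yaml::write_yaml(unclass(fx$config), tmp)
      })
    } else if (name == "benchmark_band") {
      write_xyz(fx, file.path(dir, "benchmark_band.xyz"))
    } else {
      write_xyz(fx, file.path(dir, paste0(name, ".xyz")))
    }
  }
  fx
}

# rigid water monomer (gas-phase geometry: r_OH 0.9572 A, angle 104.52 deg)
water_monomer <- function() {
  r <- 0.9572; a <- 104.52 * pi / 180
  rbind(c(0, 0, 0),
        c(r, 0, 0),
        c(r * cos(a), r * sin(a), 0))
}

# donor water hydrogen-bonded to an acceptor water along +x; `extra_sep`
# stretches the O-O distance beyond the equilibrium-like 2.91 A
water_dimer_structure <- function(extra_sep = 0) {
  don <- water_monomer()            # O1 at origin, H2 along +x (the donor H)
  r <- 0.9572; half <- 104.52 / 2 * pi / 180
  d <- 2.91 + extra_sep
  # acceptor O on +x; its HOH bisector points along +x, away from the donor
  acc <- rbind(c(d, 0, 0),
               c(d + r * cos(half), r * sin(half), 0),
               c(d + r * cos(half), -r * sin(half), 0))
  # generic (non-axis-aligned) orientation: thin interaction regions must
  # not sit exactly on a grid plane of an axis-aligned analysis box
  rot <- rotation_from_uniforms(c(0.17, 0.43, 0.71))
  structure3d(
    c("O", "H", "H", "O", "H", "H"), rbind(don, acc) %*% t(rot),
    groups = list(host = 1:3, guest = 4:6),
    tag = if (extra_sep > 0) "separated_waters" else "water_dimer"
  )
}

# the two minima of a benchmark surface (relaxed on the analytic model)
benchmark_minima <- function(surface) {
  if (surface == "double_well_1d") return(list(a = -1, b = 1))
  if (surface == "muller_brown") {
    sf <- benchmark_surface("muller_brown")
    relax <- function(p0) {
      s <- optimize_structure(point_structure(p0), sf$model, fmax = 1e-8)
      s$coords[1, 1:2]
    }
    return(list(a = relax(c(-0.55, 1.45)), b = relax(c(0.6, 0.03))))
  }
  if (surface == "leps_like") {
    sf <- benchmark_surface("leps_like")
    relax <- function(p0) {
      s <- optimize_structure(point_structure(p0), sf$model, fmax = 1e-8)
      s$coords[1, 1:2]
    }
    return(list(a = relax(c(0.74, 1.0)), b = relax(c(3.0, -1.9))))
  }
  stop("unknown benchmark surface: ", surface)
}
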