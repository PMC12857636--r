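#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a band into a per-image tibble
#' @param x a [neb_band()]. @param ... unused.
#' @export
tidy.neb_band <- function(x, ...) {
  tibble::tibble(
    image = seq_along(x$images),
    tag = vapply(x$images, `[[`, character(1), "tag"),
    energy_ev = if (is.null(x$energies)) NA_real_ else x$energies,
    fmax = if (is.null(x$forces)) NA_real_ else {
      vapply(x$forces, function(f) sqrt(max(rowSums(f^2))), numeric(1))
    },
    climbing = seq_along(x$images) == (x$climbing_index %||% 0L)
  )
}

#' One-row summary of a band optimization
#' @param x a [neb_band()] with a `report` attribute. @param ... unused.
#' @export
glance.neb_band <- function(x, ...) {
  rep <- attr(x, "report")
  seg <- !is.null(rep$segment1)
  tibble::tibble(
    n_images = length(x$images),
    converged = if (seg) rep$segment1$converged && rep$segment2$converged
                else rep$converged %||% NA,
    steps = if (seg) rep$segment1$steps + rep$segment2$steps
            else rep$steps %||% NA_integer_,
    fmax = if (seg) max(rep$segment1$fmax, rep$segment2$fmax)
           else rep$fmax %||% NA_real_,
    barrier_kjmol = band_barrier(x, "kjmol"),
    wall_time_s = if (seg) rep$segment1$wall_time_s + rep$segment2$wall_time_s
                  else rep$wall_time_s %||% NA_real_
  )
}

#' Tidy a profile into its per-image table
#' @param x an `ndc_profile`. @param ... unused.
#' @export
tidy.ndc_profile <- function(x, ...) x$data

#' One-row summary of a profile
#' @param x an `ndc_profile`. @param ... unused.
#' @export
glance.ndc_profile <- function(x, ...) {
  stg <- x$stages
  tibble::tibble(
    n_images = nrow(x$data),
    barrier_kjmol = x$barrier %||% NA_real_,
    prep_min_kjmol = if (!is.null(stg) && length(stg$preparation)) {
      min(x$data$energy_rel[stg$preparation[1]:stg$preparation[2]])
    } else NA_real_,
    activation_start = if (!is.null(stg)) stg$activation[1] else NA_integer_,
    activation_end = if (!is.null(stg)) stg$activation[2] else NA_integer_,
    aligned = x$align
  )
}

#' Energy profile plot along the normalized displacement coordinate
#'
#' Relative energy against the NDC, coloured by stage when the profile is
#' segmented; descriptor series are drawn as free-scale facets when
#' `descriptors = TRUE` and present.
#'
#' @param object an `ndc_profile`.
#' @param descriptors facet the geometric descriptor series too?
#' @param ... unused.
#' @export
autoplot.ndc_profile <- function(object, descriptors = FALSE, ...) {
  d <- object$data
  if (descriptors) {
    keep <- intersect(c("energy_rel", "d_max_oo", "d_no", "d_cm"), names(d))
    long <- tidyr_pivot(d, keep)
    return(
      ggplot2::ggplot(long, ggplot2::aes(x = .data$ndc, y = .data$value)) +
        ggplot2::geom_line() +
        ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
        ggplot2::labs(x = "normalized displacement coordinate", y = NULL)
    )
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$ndc, y = .data$energy_rel))
  if ("stage" %in% names(d)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(group = 1)) +
      ggplot2::geom_point(ggplot2::aes(colour = .data$stage), size = 1.4)
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "normalized displacement coordinate",
                    y = "relative energy (kJ/mol)")
}

# minimal long-format pivot (avoids a tidyr dependency for one reshape)
tidyr_pivot <- function(d, cols) {
  dplyr::bind_rows(lapply(cols, function(cn) {
    tibble::tibble(ndc = d$ndc, series = cn, value = d[[cn]])
  }))
}

#' Convergence-history plot of a band optimization
#' @param object a [neb_band()] with a `report` attribute.
#' @param ... unused.
#' @export
autoplot.neb_band <- function(object, ...) {
  rep <- attr(object, "report")
  logs <- if (!is.null(rep$segment1)) {
    dplyr::bind_rows(
      dplyr::mutate(rep$segment1$log, segment = "NEB1"),
      dplyr::mutate(rep$segment2$log, segment = "NEB2")
    )
  } else dplyr::mutate(rep$log, segment = "NEB")
  ggplot2::ggplot(logs, ggplot2::aes(x = .data$step, y = .data$fmax,
                                     colour = .data$segment)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "optimizer step", y = "max |F| (eV/Å)")
}

#' Bar plot of decomposition deltas against the reference image
#' @param object an `eda_table` from [eda_relative()].
#' @param ... unused.
#' @export
autoplot.eda_table <- function(object, ...) {
  long <- dplyr::bind_rows(lapply(c("dE_s", "dE_e", "dE_q", "dE_t"),
    function(cn) tibble::tibble(tag = object$tag, term = cn,
                                value = object[[cn]])))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tag, y = .data$value,
                                     fill = .data$term)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL,
                  y = sprintf("delta vs reference (%s)",
                              attr(object, "units") %||% "kJ/mol"))
}

#' Plain-text convergence table for a stitched or single band
#'
#' One row per segment with step counts, final max|F|, wall time and the
#' extracted barrier — the shape of a run-report table, with divergence
#' surfaced as failure labels upstream.
#'
#' @param band a [neb_band()] with a `report` attribute.
#' @export
convergence_table <- function(band) {
  rep <- attr(band, "report")
  rows <- if (!is.null(rep$segment1)) {
    list(NEB1 = rep$segment1, NEB2 = rep$segment2)
  } else list(NEB = rep)
  dplyr::bind_rows(lapply(names(rows), function(nm) {
    r <- rows[[nm]]
    tibble::tibble(segment = nm, converged = r$converged, steps = r$steps,
                   fmax = r$fmax, wall_time_s = r$wall_time_s)
  }))
}
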