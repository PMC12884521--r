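# broom-style tidiers and ggplot2 autoplot methods for the package's
# result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Boltzmann population result
#'
#' @param x A `boltzmann_pop` object from [boltzmann_populations()].
#' @param ... Unused.
#' @return A tibble with one row per conformer (`id`, `delta_g`,
#'   `population`, `percent`).
#' @export
tidy.boltzmann_pop <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("id", "delta_g", "population", "percent")])
}

#' @rdname tidy.boltzmann_pop
#' @return `glance()` returns a one-row summary: conformer count,
#'   temperature, top population and the Shannon entropy of the
#'   distribution (nats).
#' @export
glance.boltzmann_pop <- function(x, ...) {
  p <- x$population
  tibble::tibble(
    n_conformers = nrow(x),
    temperature = attr(x, "temperature"),
    top_percent = max(x$percent),
    entropy = -sum(ifelse(p > 0, p * log(p), 0))
  )
}

#' @rdname tidy.boltzmann_pop
#' @param object A `boltzmann_pop` object.
#' @export
autoplot.boltzmann_pop <- function(object, ...) {
  df <- tidy(object)
  df$id <- factor(df$id, levels = df$id[order(-df$percent)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id, y = .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "conformer", y = "population (%)",
                  title = sprintf("Boltzmann populations at %g K",
                                  attr(object, "temperature"))) +
    ggplot2::theme_minimal()
}

#' Tidy a two-layer energy combination
#'
#' @param x An `oniom2` object.
#' @param ... Unused.
#' @return Long tibble of the three components and the extrapolated total.
#' @export
tidy.oniom2 <- function(x, ...) {
  tibble::tibble(
    term = c("e_high_model", "e_low_real", "e_low_model", "e_oniom2"),
    energy = c(x$e_high_model, x$e_low_real, x$e_low_model, x$e_oniom2)
  )
}

#' @rdname tidy.oniom2
#' @export
glance.oniom2 <- function(x, ...) {
  tibble::tibble(e_high_model = x$e_high_model, e_low_real = x$e_low_real,
                 e_low_model = x$e_low_model, e_oniom2 = x$e_oniom2)
}

#' Tidy a binding-energy decomposition
#'
#' @param x A `binding_result` object.
#' @param ... Unused.
#' @return Long tibble of component energies and the binding energy.
#' @export
tidy.binding_result <- function(x, ...) {
  tibble::tibble(
    term = c("e_complex", "e_active_site", "e_ligand", "binding_energy"),
    energy = c(x$e_complex, x$e_active_site, x$e_ligand, x$binding_energy)
  )
}

#' @rdname tidy.binding_result
#' @export
glance.binding_result <- function(x, ...) {
  tibble::tibble(e_complex = x$e_complex, e_active_site = x$e_active_site,
                 e_ligand = x$e_ligand, binding_energy = x$binding_energy)
}

#' Tidy an NCI grid into a point table
#'
#' @param x An `nci_grid` object.
#' @param ... Unused.
#' @param masked_only Keep only scatter-eligible points? Default `TRUE`.
#' @return Tibble with `signed_rho`, `s` and the interaction `class`.
#' @export
tidy.nci_grid <- function(x, ..., masked_only = TRUE) {
  keep <- if (masked_only) as.vector(x$mask) else
    rep(TRUE, length(x$mask))
  sr <- as.vector(x$signed_rho)[keep]
  tibble::tibble(signed_rho = sr, s = as.vector(x$rdg)[keep],
                 class = classify_points(sr))
}

#' @rdname tidy.nci_grid
#' @param object An `nci_grid` object.
#' @export
autoplot.nci_grid <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$signed_rho, y = .data$s,
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::scale_colour_manual(values = c(
      attractive = "#2166ac", van_der_waals = "#1a9850",
      repulsive = "#b2182b"), drop = FALSE) +
    ggplot2::coord_cartesian(xlim = c(-0.06, 0.06)) +
    ggplot2::labs(x = expression(sign(lambda[2]) * rho ~ "(au)"),
                  y = "reduced density gradient s") +
    ggplot2::theme_minimal()
}

#' Plot a UV-vis spectrum
#'
#' @param object A `uv_spectrum` tibble from [broaden()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uv_spectrum <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$wavelength, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)",
                  y = if (isTRUE(attr(object, "normalized")))
                    "normalised intensity" else "intensity (arb. units)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
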