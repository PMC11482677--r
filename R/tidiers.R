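#' Tidy a quasibinomial recovery fit
#'
#' @param x a `pp_glm` from [recovery_regression()].
#' @param ... unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`.
#' @method tidy pp_glm
#' @export
tidy.pp_glm <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$std_error),
    statistic = unname(x$coefficients / x$std_error)
  )
}

#' One-row summary of a quasibinomial recovery fit
#'
#' @param x a `pp_glm`.
#' @param ... unused.
#' @return A tibble with `dispersion`, `nobs`, `converged`, `degenerate`.
#' @method glance pp_glm
#' @export
glance.pp_glm <- function(x, ...) {
  tibble(
    dispersion = x$dispersion, nobs = x$n,
    converged = x$converged, degenerate = x$degenerate
  )
}

#' Plot a community trajectory
#'
#' Species density (and optionally mean trait) paths over time; forced
#' species, if any, are highlighted.
#'
#' @param object a `pp_trajectory` from [simulate_community()].
#' @param what `"N"` (densities) or `"u"` (mean traits).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot pp_trajectory
#' @export
autoplot.pp_trajectory <- function(object, what = c("N", "u"), ...) {
  what <- match.arg(what)
  forcing <- attr(object, "forcing")
  df <- as_tibble(object)
  forced_labels <- character()
  if (!is.null(forcing)) {
    labels <- unique(df$species)
    forced_labels <- labels[forcing$species]
  }
  df$forced <- df$species %in% forced_labels
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time, y = .data[[what]], group = .data$species,
    colour = .data$guild, linewidth = .data$forced
  )) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::scale_linewidth_manual(values = c(`FALSE` = 0.3, `TRUE` = 1),
                                    guide = "none") +
    ggplot2::labs(
      x = "time",
      y = if (what == "N") "density" else "mean trait",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  if (!is.null(forcing)) {
    p <- p + ggplot2::geom_vline(xintercept = forcing$duration,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a collapse or hysteresis sweep
#'
#' @param object a `pp_sweep`.
#' @param y column to plot against `gamma0` (default `"richness"`).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot pp_sweep
#' @export
autoplot.pp_sweep <- function(object, y = "richness", ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$gamma0, y = .data[[y]])) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(
      x = expression(gamma[0]), y = y,
      title = paste(attr(object, "direction"), "sweep")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a recovery phase diagram
#'
#' @param object a `pp_phase` from [phase_diagram()].
#' @param ... unused.
#' @return A ggplot tile map of recovery richness.
#' @method autoplot pp_phase
#' @export
autoplot.pp_phase <- function(object, ...) {
  axis <- attr(object, "axis")
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(
    x = .data$gamma0, y = .data[[axis]], fill = .data$recovery_richness
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = expression(gamma[0]), y = axis,
                  fill = "recovery\nrichness") +
    ggplot2::theme_minimal()
}
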