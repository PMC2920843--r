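#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an MM-PBSA result into its component table
#' @param x An `mmpbsa_result`.
#' @param ... Unused.
#' @return Tibble of `term`, `value`, `sem`.
#' @export
tidy.mmpbsa_result <- function(x, ...) x$table

#' One-row summary of an MM-PBSA result
#' @param x An `mmpbsa_result`.
#' @param ... Unused.
#' @export
glance.mmpbsa_result <- function(x, ...) {
  v <- setNames(x$table$value, x$table$term)
  tibble(dH = v[["dH"]],
         vdw = v[["vdw"]], elec = v[["elec"]],
         deformation = v[["deformation"]],
         n_snapshots = x$n_snapshots)
}

#' Tidy quasiharmonic modes
#' @param x A `quasiharmonic` object.
#' @param ... Unused.
#' @return Tibble of `mode`, `frequency` (cm^-1).
#' @export
tidy.quasiharmonic <- function(x, ...) {
  tibble(mode = seq_along(x$frequencies), frequency = x$frequencies)
}

#' One-row summary of a quasiharmonic analysis
#' @param x A `quasiharmonic` object.
#' @param ... Unused.
#' @export
glance.quasiharmonic <- function(x, ...) {
  tibble(TS = x$TS, n_modes = x$n_modes, temperature = x$temperature)
}

#' Per-frame energy time series plot
#'
#' @param object An `mmpbsa_result`.
#' @param ... Unused.
#' @return A ggplot object (requires ggplot2).
#' @exportS3Method ggplot2::autoplot
autoplot.mmpbsa_result <- function(object, ...) {
  require_ggplot()
  long <- tidyr::pivot_longer(object$per_frame,
                              cols = -c("frame", "time"),
                              names_to = "term", values_to = "energy")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$energy,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = "energy (kcal/mol)",
                  colour = NULL)
}

#' Hydration-site free-energy bar chart
#'
#' @param sites A characterized site tibble (rows from
#'   [characterize_site()]).
#' @param weighted Plot the occupancy-weighted values.
#' @return A ggplot object (requires ggplot2).
#' @export
plot_sites <- function(sites, weighted = TRUE) {
  require_ggplot()
  cols <- if (weighted) c("weighted_dH", "weighted_mTdS") else
    c("dH", "mTdS")
  df <- sites
  df$site <- factor(seq_len(nrow(df)))
  long <- tidyr::pivot_longer(df[, c("site", cols)], cols = -"site",
                              names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$site, y = .data$value,
                                     fill = .data$term)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "hydration site",
                  y = "excess free energy vs bulk (kcal/mol)", fill = NULL)
}

require_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting")
  }
}
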