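# Quick-look ggplot2 figures for the main result types.

#' Plot the tunnel radius profile with its constriction sites
#'
#' @param profile a `tunnel_profile`.
#' @param constrictions optional table from [find_constrictions()].
#' @return a ggplot.
#' @export
plot_tunnel_profile <- function(profile, constrictions = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$z, y = .data$r_eff)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from PTC (Å)",
                  y = "effective radius (Å)")
  if (!is.null(constrictions) && nrow(constrictions)) {
    p <- p +
      ggplot2::geom_vline(xintercept = constrictions$z, linetype = 2) +
      ggplot2::annotate("text", x = constrictions$z,
                        y = max(profile$r_eff), label = constrictions$rank,
                        vjust = -0.2, size = 3)
  }
  p
}

#' Plot PTC-to-termini distances over time
#'
#' @param traj a `cg_trajectory`.
#' @return a ggplot.
#' @export
plot_termini_distance <- function(traj) {
  td <- termini_distance(traj)
  long <- tidyr::pivot_longer(td, c("d_N", "d_C"), names_to = "terminus",
                              values_to = "distance")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$distance,
                                     colour = .data$terminus)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(d_N = "red", d_C = "blue"),
                                 labels = c(d_N = "N-terminus",
                                            d_C = "C-terminus")) +
    ggplot2::labs(x = "time (τ)", y = "distance from PTC (Å)")
}

#' Plot the outcome histogram in constriction-site binning
#'
#' @param histogram table from [outcome_histogram()].
#' @return a ggplot.
#' @export
plot_outcome_histogram <- function(histogram) {
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = (.data$lo + .data$hi) / 2,
                               y = .data$count,
                               width = .data$hi - .data$lo)) +
    ggplot2::geom_col(colour = "black", fill = "grey70") +
    ggplot2::labs(x = "final N-terminus distance from PTC (Å)",
                  y = "trajectories")
}

#' Plot a native contact map
#'
#' @param native a `native_model`.
#' @return a ggplot.
#' @export
plot_contact_map <- function(native) {
  con <- native$contacts
  ggplot2::ggplot(con, ggplot2::aes(x = .data$i, y = .data$j)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "residue i", y = "residue j")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.tunnel_profile <- function(object, ...) {
  cons <- tryCatch(find_constrictions(object), error = function(e) NULL)
  plot_tunnel_profile(object, cons)
}

#' @export
autoplot.cg_trajectory <- function(object, ...) plot_termini_distance(object)

#' @export
autoplot.native_model <- function(object, ...) plot_contact_map(object)

#' @importFrom rlang .data
NULL
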