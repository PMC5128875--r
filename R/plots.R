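# ggplot2 visualisations for result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_point
#'   labs scale_fill_viridis_c facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot a population heat map
#'
#' @param object A `population_heatmap`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.population_heatmap <- function(object, ...) {
  rmid <- (head(object$r_breaks, -1) + tail(object$r_breaks, -1)) / 2
  emid <- (head(object$e_breaks, -1) + tail(object$e_breaks, -1)) / 2
  df <- expand.grid(r = rmid, energy = emid)
  df$density <- as.vector(object$density)
  ggplot(df[df$density > 0, ], aes(x = .data$r, y = .data$energy,
                                   fill = .data$density)) +
    geom_tile() +
    scale_fill_viridis_c(option = "inferno") +
    labs(x = "similarity r", y = "total interaction energy (eps_HB)",
         fill = "population") +
    theme_minimal()
}

#' Plot the observable series of a run
#'
#' Kinetic temperature, total interaction energy, hydrogen-bond count and
#' largest cluster size versus collisions.
#'
#' @param object A `dmd_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dmd_run <- function(object, ...) {
  o <- object$observables
  df <- tidyr::pivot_longer(
    o[, c("collisions", "t_avg", "pe", "n_hb", "largest_cluster")],
    cols = -"collisions", names_to = "observable")
  ggplot(df, aes(x = .data$collisions, y = .data$value)) +
    geom_line() +
    facet_wrap(~observable, scales = "free_y") +
    labs(x = "collisions", y = NULL) +
    theme_minimal()
}

#' Plot a distance profile
#'
#' @param object A `distance_profile`.
#' @param ... Unused.
#' @return A ggplot of the mean CA-CA distance map.
#' @export
autoplot.distance_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$i, y = .data$j, fill = .data$dist)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = "residue i", y = "residue j", fill = "distance (A)") +
    theme_minimal()
}
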