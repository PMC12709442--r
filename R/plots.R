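#' Plot an unfolding trace
#'
#' Radius of gyration against the number of transposed monomers.
#'
#' @param object An `insertion_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.insertion_run <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$n_tr, y = .data$rg)) +
    ggplot2::geom_line(colour = "grey55") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression(N[tr]),
                  y = expression(R[g] ~ "(" * sigma * ")"),
                  title = paste0(object$model, " insertion run")) +
    ggplot2::theme_minimal()
}

#' Plot a Hill fit over its trace
#'
#' @param object A `hill_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hill_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(n_tr = seq(min(d$n_tr), max(d$n_tr), length.out = 200))
  grid$rg <- object$r0 + (object$r_inf - object$r0) *
    ifelse(grid$n_tr > 0, grid$n_tr^object$n /
             (object$k^object$n + grid$n_tr^object$n), 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_tr, y = .data$rg)) +
    ggplot2::geom_point(size = 1, alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = expression(N[tr]), y = expression(R[g]),
                  subtitle = sprintf("Hill n = %.2f, K = %.1f",
                                     object$n, object$k)) +
    ggplot2::theme_minimal()
}

#' Heatmaps of scan-grid aggregates
#'
#' @param object A `scan_grid` from [aggregate_scan()].
#' @param metric Cell statistic to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scan_grid <- function(object,
                               metric = c("alpha_mle_mean", "hill_n_mean",
                                          "hill_k_mean",
                                          "mean_insert_dist_mean"), ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$k_t),
                                       y = factor(.data$s_t),
                                       fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = expression(k[T]), y = expression(s[T]), fill = metric) +
    ggplot2::theme_minimal()
}

#' Pairwise-distance histogram against the uniform expectation
#'
#' Log-log plot of a [log_binned_histogram()] with the closed-form
#' density for uniform placement, `2 (L - x) / L^2`, overlaid when `L` is
#' given. Excess density at short distances relative to the curve is the
#' clustering signature.
#'
#' @param hist A [log_binned_histogram()] tibble.
#' @param L Genomic range for the uniform overlay (optional).
#' @return A ggplot.
#' @export
plot_distance_histogram <- function(hist, L = NULL) {
  p <- ggplot2::ggplot(hist, ggplot2::aes(x = .data$mid, y = .data$density)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "pairwise distance (nt)", y = "density") +
    ggplot2::theme_minimal()
  if (!is.null(L)) {
    ref <- tibble::tibble(mid = hist$mid,
                          density = uniform_density(pmin(hist$mid, L), L))
    p <- p + ggplot2::geom_line(data = ref, colour = "grey40",
                                linetype = "dashed")
  }
  p
}

#' Plot radial distance distributions by particle group
#'
#' @param rd A [radial_distributions()] tibble.
#' @return A ggplot.
#' @export
plot_radial_distributions <- function(rd) {
  ggplot2::ggplot(rd, ggplot2::aes(x = .data$mid, y = .data$density,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from chromatin center (sigma)",
                  y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}
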