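#' Heatmap of a joint SFS
#'
#' Cell brightness is log10(count + 1); masked cells are blank.
#'
#' @param object a [joint_sfs()].
#' @param ... unused.
#' @method autoplot joint_sfs
#' @export
autoplot.joint_sfs <- function(object, ...) {
  d <- dim(object$counts)
  df <- tidyr::expand_grid(j = 0:(d[2] - 1), i = 0:(d[1] - 1)) |>
    dplyr::mutate(count = as.vector(object$counts),
                  masked = as.vector(object$mask)) |>
    dplyr::filter(!.data$masked)
  if (length(object$sizes) == 1) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$count)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = paste0("derived copies (", object$pops[1], ")"),
                    y = "sites") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                     fill = log10(.data$count + 1))) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c(name = "log10(sites+1)") +
      ggplot2::labs(x = paste0("derived copies (", object$pops[2], ")"),
                    y = paste0("derived copies (", object$pops[1], ")")) +
      ggplot2::theme_minimal()
  }
}

#' AIC cloud of optimization runs
#'
#' Scatter of two fitted parameters across all runs, coloured by
#' log10(AIC) and shaped by pass — the standard view of where the
#' sequential optimizer settled.
#'
#' @param object an `expansion_fit`.
#' @param x,y parameter names to plot (defaults: the first two).
#' @param ... unused.
#' @method autoplot expansion_fit
#' @export
autoplot.expansion_fit <- function(object, x = NULL, y = NULL, ...) {
  td <- tidy(object) |> dplyr::filter(!.data$timeout)
  pn <- object$model$params$name
  if (is.null(x)) x <- pn[1]
  if (is.null(y)) y <- pn[2]
  ggplot2::ggplot(td, ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                   colour = log10(.data$aic),
                                   shape = factor(.data$pass))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_viridis_c(name = "log10(AIC)") +
    ggplot2::labs(shape = "pass", title = object$model$name) +
    ggplot2::theme_minimal()
}

#' Isolation-by-distance scatter
#'
#' Genetic against geographic pairwise distances with a linear trend.
#'
#' @param genetic,geographic `dist_matrix` objects on the same labels.
#' @export
plot_ibd <- function(genetic, geographic) {
  geo <- geographic[rownames(genetic), rownames(genetic)]
  lower <- lower.tri(genetic)
  df <- tibble(genetic = genetic[lower], geographic_km = geo[lower])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$geographic_km,
                                   y = .data$genetic)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "geographic distance (km)",
                  y = paste0("genetic distance (", attr(genetic, "kind"), ")")) +
    ggplot2::theme_minimal()
}
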