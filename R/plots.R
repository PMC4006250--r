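# ggplot2 graphics for the result types.

#' @export
autoplot.delay_distribution <- function(object, t_max = NULL, n = 400, ...) {
  if (is.null(t_max)) t_max <- distribution_quantile(object, 0.999)
  tt <- seq(0, t_max, length.out = n)
  df <- tibble::tibble(time = tt, cdf = distribution_cdf(object, tt))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$cdf)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "delay", y = "CDF",
                  title = if (is.null(object$label)) "delay distribution"
                          else object$label) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.trajectory <- function(object, species = NULL, ...) {
  df <- tidyr::pivot_longer(object, -"time", names_to = "species",
                            values_to = "count")
  if (!is.null(species)) df <- df[df$species %in% species, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$count,
                                   colour = .data$species)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time", y = "molecules") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ensemble <- function(object, species = NULL, ...) {
  df <- tidy(object)
  if (!is.null(species)) df <- df[df$species %in% species, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mean,
                                   colour = .data$species,
                                   fill = .data$species)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - 2 * .data$se,
                                      ymax = .data$mean + 2 * .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "mean molecules") +
    ggplot2::theme_minimal()
}

#' Overlay the mean curves of two ensembles (full-model SSA vs abridged DSSA)
#'
#' @param ensA,ensB `ensemble` objects sharing a grid.
#' @param species species to show.
#' @export
plot_ensemble_overlay <- function(ensA, ensB, species = NULL) {
  da <- tidy(ensA); da$model <- ensA$model_id
  db <- tidy(ensB); db$model <- ensB$model_id
  df <- dplyr::bind_rows(da, db)
  if (!is.null(species)) df <- df[df$species %in% species, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mean,
                                   colour = .data$species,
                                   linetype = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "mean molecules") +
    ggplot2::theme_minimal()
}
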