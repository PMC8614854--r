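#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-update history of a particle-filter run
#'
#' One row per filter update: the measurement, the one-step-ahead
#' prediction made before the update, the posterior parameter means and
#' sds, the mean inferred observation-noise sd and the three state-noise
#' sds.
#'
#' @param x A `growth_pf`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.growth_pf <- function(x, ...) x$history

#' @rdname tidy.growth_pf
#' @export
glance.growth_pf <- function(x, ...) {
  s <- pf_summary(x$state)
  roll <- rolling_mse(x)
  dplyr::bind_cols(
    tibble::tibble(n_updates = nrow(x$history),
                   n_particles = x$state$config$n_particles,
                   family = x$family,
                   final_rolling_mse = roll$mse[nrow(roll)]),
    s)
}

#' Tidy a static growth-model fit
#'
#' @param x A `growth_sm`.
#' @param ensemble Return the full particle ensemble (columns `k`, `b`,
#'   `c`, `weight`) instead of the parameter summary; this is the form
#'   [pf_init()] accepts as a seed.
#' @param ... Unused.
#' @return A tibble: per-parameter `term`, `estimate`, `std.error` by
#'   default, or the ensemble when `ensemble = TRUE`.
#' @export
tidy.growth_sm <- function(x, ensemble = FALSE, ...) {
  if (ensemble) {
    out <- tibble::as_tibble(as.data.frame(x$state$particles))
    out$weight <- x$state$weights
    return(out)
  }
  s <- pf_summary(x$state)
  tibble::tibble(term = c("k", "b", "c"),
                 estimate = c(s$k, s$b, s$c),
                 std.error = c(s$k_sd, s$b_sd, s$c_sd))
}

#' @rdname tidy.growth_sm
#' @export
glance.growth_sm <- function(x, ...) {
  s <- pf_summary(x$state)
  tibble::tibble(n_sweeps = x$n_sweeps, converged = x$converged,
                 n_particles = x$state$config$n_particles,
                 family = x$family, sigma = s$obs_sd)
}

#' Diagnostic plot of a particle-filter run
#'
#' Three synchronized panels over culture time: the transformed signal
#' with its one-step-ahead predictions, the rolling one-step-ahead mean
#' squared error, and the state-noise standard deviations of the three
#' growth parameters (log scale) — the view that shows the filter
#' switching between stationary precision and tracking.
#'
#' @param object A `growth_pf`.
#' @param window Rolling-mse window (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.growth_pf <- function(object, window = 15, ...) {
  h <- object$history
  roll <- rolling_mse(object, window = window)
  panels <- dplyr::bind_rows(
    tibble::tibble(time_h = h$time_h, value = h$value,
                   panel = "signal", series = "measured"),
    tibble::tibble(time_h = h$time_h, value = h$onestep_pred,
                   panel = "signal", series = "one-step prediction"),
    tibble::tibble(time_h = roll$time_h, value = roll$mse,
                   panel = "rolling mse", series = "mse"),
    tidyr::pivot_longer(
      dplyr::select(h, "time_h", k = "noise_sd_k", b = "noise_sd_b",
                    c = "noise_sd_c"),
      -"time_h", names_to = "series", values_to = "value") |>
      dplyr::mutate(panel = "state-noise sd"))
  ggplot2::ggplot(panels,
                  ggplot2::aes(x = .data$time_h, y = .data$value,
                               colour = .data$series)) +
    ggplot2::geom_line(data = ~dplyr::filter(.x, .data$panel != "signal")) +
    ggplot2::geom_point(data = ~dplyr::filter(.x, .data$panel == "signal"),
                        size = 0.6) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [h]", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Fit plot of a static growth model
#'
#' Training data overlaid with the frozen ensemble-mean curve and its
#' central credible band.
#'
#' @param object A `growth_sm`.
#' @param level Credible-band mass (default 0.9).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.growth_sm <- function(object, level = 0.9, ...) {
  d <- object$data
  grid <- seq(min(d$time_h), max(d$time_h), length.out = 200)
  fc <- predict(object, grid, level = level)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_ribbon(data = fc,
                         ggplot2::aes(x = .data$time_h, ymin = .data$.lower,
                                      ymax = .data$.upper),
                         inherit.aes = FALSE, alpha = 0.2) +
    ggplot2::geom_line(data = fc,
                       ggplot2::aes(x = .data$time_h, y = .data$.pred),
                       inherit.aes = FALSE, colour = "steelblue") +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::labs(x = "time [h]", y = "transformed signal") +
    ggplot2::theme_minimal()
}

#' Plot a protocol report
#'
#' Natural-log mean squared prediction errors of the particle filter and
#' the static model across split fractions; filled points mark splits with
#' a significant PF improvement (FDR < 0.05).
#'
#' @param report Output of [run_protocol()].
#' @return A ggplot object.
#' @export
plot_protocol <- function(report) {
  long <- tidyr::pivot_longer(
    dplyr::select(report, "split", "significant",
                  PF = "log_mse_pf", SM = "log_mse_sm"),
    c("PF", "SM"), names_to = "model", values_to = "log_mse")
  ggplot2::ggplot(long, ggplot2::aes(x = 100 * .data$split,
                                     y = .data$log_mse,
                                     colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$significant), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16)) +
    ggplot2::labs(x = "time used for inference [%]", y = "log(mse)",
                  shape = "FDR < 0.05") +
    ggplot2::theme_minimal()
}
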