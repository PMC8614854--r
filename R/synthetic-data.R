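#' Simulate a shake-flask-like culture signal with known ground truth
#'
#' Generates a transformed-scale (log) sensor series from a Gompertz or
#' Logistic backbone with additive Gaussian noise, irregular sampling, and
#' the two non-stationary phenomena seen in real shake-flask cultures:
#' regime switches (the parameter triple changes at given times, emulating
#' growth slowdowns) and step events (sudden additive offsets in level,
#' emulating a jump in the optical sensor response).
#'
#' Regime switches do not enforce value continuity by default (a genuine
#' discontinuity is a valid phenomenon); with `continuous = TRUE` the
#' offset `b` of each later regime is re-solved at its switch time so the
#' backbone stays continuous, which is the natural way to emulate a
#' slowdown.
#'
#' @param regimes Tibble/data frame with columns `start_time`, `k`, `b`,
#'   `c`; start times strictly increasing, first at 0.
#' @param family `"gompertz"` or `"logistic"`.
#' @param step_events Optional tibble with columns `time` and `offset`
#'   (additive, log-units); offsets accumulate.
#' @param noise_sd Gaussian observation-noise sd on the transformed scale.
#' @param duration Total duration (hours).
#' @param mean_interval Mean sampling interval (hours).
#' @param jitter Sampling jitter as a fraction of the interval: each
#'   interval is `mean_interval * (1 + U(-jitter, jitter))`.
#' @param continuous Re-solve `b` at each regime switch for a continuous
#'   backbone.
#' @param seed Optional integer seed; fixed seed gives an identical series.
#' @return Tibble with `time_h`, `value` (noisy), `mu` (noiseless backbone
#'   including steps), and the active ground-truth parameters `k`, `b`,
#'   `c` per sample.
#' @export
simulate_culture <- function(regimes, family = "gompertz",
                             step_events = NULL, noise_sd = 0.05,
                             duration = 12, mean_interval = 0.1,
                             jitter = 0.15, continuous = FALSE,
                             seed = NULL) {
  family <- match_family(family)
  regimes <- tibble::as_tibble(regimes)
  stopifnot(all(c("start_time", "k", "b", "c") %in% names(regimes)))
  if (regimes$start_time[1] != 0 ||
      (nrow(regimes) > 1 && any(diff(regimes$start_time) <= 0))) {
    stop("regime start times must be strictly increasing, the first at 0",
         call. = FALSE)
  }
  if (noise_sd < 0 || duration <= 0 || mean_interval <= 0 ||
      jitter < 0 || jitter >= 1) {
    stop("invalid simulation specification", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  # sampling grid: irregular, strictly increasing, spanning [0, duration]
  n_max <- ceiling(duration / mean_interval) + 10
  steps <- mean_interval * (1 + stats::runif(n_max, -jitter, jitter))
  times <- cumsum(c(0, steps))
  times <- times[times <= duration]

  if (continuous && nrow(regimes) > 1) {
    for (j in 2:nrow(regimes)) {
      ts <- regimes$start_time[j]
      y_prev <- growth_value(family, ts, regimes$k[j - 1], regimes$b[j - 1],
                             regimes$c[j - 1])
      regimes$b[j] <- solve_offset(family, y_prev, regimes$k[j],
                                   regimes$c[j], ts)
    }
  }

  reg_idx <- findInterval(times, regimes$start_time)
  mu <- growth_value(family, times, regimes$k[reg_idx], regimes$b[reg_idx],
                     regimes$c[reg_idx])
  if (!is.null(step_events) && nrow(step_events)) {
    step_events <- dplyr::arrange(tibble::as_tibble(step_events), .data$time)
    cum <- cumsum(step_events$offset)
    pos <- findInterval(times, step_events$time)
    mu <- mu + c(0, cum)[pos + 1L]
  }
  value <- mu + stats::rnorm(length(times), 0, noise_sd)
  tibble::tibble(time_h = times, value = value, mu = mu,
                 k = regimes$k[reg_idx], b = regimes$b[reg_idx],
                 c = regimes$c[reg_idx])
}

# offset b such that the curve passes through (ts, y) given k and c
solve_offset <- function(family, y, k, c, ts) {
  frac <- y / k
  if (!is.finite(frac) || frac <= 0 || frac >= 1) {
    stop("cannot continue regime: previous level outside (0, k)",
         call. = FALSE)
  }
  if (family == "gompertz") c * ts + log(-log(frac)) else
    c * ts + log(1 / frac - 1)
}

#' Simulate a declining dissolved-oxygen-like profile
#'
#' Uses the monotone-decreasing sign convention (`b < 0`, `c < 0`) of the
#' growth laws, with an optional floor emulating the near-zero oxygen tail
#' at the end of a culture.
#'
#' @inheritParams simulate_culture
#' @param floor Optional minimum level applied to the backbone before
#'   noise is added.
#' @return Same columns as [simulate_culture()].
#' @export
simulate_do_profile <- function(regimes, family = "gompertz",
                                noise_sd = 0, duration = 12,
                                mean_interval = 0.1, jitter = 0,
                                floor = NULL, seed = NULL) {
  regimes <- tibble::as_tibble(regimes)
  if (any(regimes$b >= 0) || any(regimes$c >= 0)) {
    warning("declining profiles use the b < 0, c < 0 convention",
            call. = FALSE)
  }
  out <- simulate_culture(regimes, family = family, noise_sd = 0,
                          duration = duration,
                          mean_interval = mean_interval, jitter = jitter,
                          seed = seed)
  if (!is.null(floor)) out$mu <- pmax(out$mu, floor)
  out$value <- out$mu + stats::rnorm(nrow(out), 0, noise_sd)
  out
}

#' Write a simulated culture plus its ground truth
#'
#' Writes the standard `time_h,value` CSV next to a sidecar JSON holding
#' the noiseless backbone and per-sample ground-truth parameters.
#'
#' @param data Output of [simulate_culture()].
#' @param path CSV path; the sidecar is `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_synthetic_culture <- function(data, path) {
  write_culture(data, path)
  truth <- dplyr::select(data, "time_h", "mu", "k", "b", "c")
  jsonlite::write_json(truth, paste0(path, ".truth.json"), digits = NA)
  invisible(path)
}
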