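#' Specify a monitored culture event
#'
#' Two operational events are predefined: the optimal harvest time (biomass
#' reaches 95% of its maximal value) and the critically low oxygen time
#' (dissolved oxygen falls to 20% of its initial level). For an ensemble
#' forecast the biomass reference is each particle's own asymptote `k`
#' (forward-looking), while the post hoc estimate uses the maximum of the
#' smoothed observed signal; for dissolved oxygen the reference defaults to
#' the initial level, which for a declining curve essentially equals its
#' maximum.
#'
#' @param channel `"BM"` or `"DO"`.
#' @param fraction Fraction of the reference level defining the event;
#'   default 0.95 for `"BM"`, 0.20 for `"DO"`.
#' @param reference `"max_of_signal"` (default for BM) or `"initial_value"`
#'   (default for DO).
#' @return A list of class `event_spec`.
#' @export
event_spec <- function(channel = c("BM", "DO"), fraction = NULL,
                       reference = NULL) {
  channel <- match.arg(channel)
  fraction <- fraction %||% if (channel == "BM") 0.95 else 0.20
  reference <- reference %||%
    if (channel == "BM") "max_of_signal" else "initial_value"
  reference <- match.arg(reference, c("max_of_signal", "initial_value"))
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie in (0, 1)", call. = FALSE)
  }
  structure(list(channel = channel, fraction = fraction,
                 reference = reference), class = "event_spec")
}

#' Predict an event time from a model ensemble
#'
#' Per particle, the closed-form [crossing_time()] at `fraction` of the
#' particle's reference level is computed: the particle's own asymptote `k`
#' for `reference = "max_of_signal"`, or its curve value at `t0` for
#' `reference = "initial_value"`. The prediction is the weighted mean of
#' the finite crossing times; the fraction of particles whose curve never
#' attains the target (non-crossing) is reported, and no number is
#' fabricated when every particle is non-crossing.
#'
#' @param object A `growth_pf`, `growth_sm`, `pf_state`, or a data frame
#'   ensemble with columns `k`, `b`, `c` (optionally `weight`).
#' @param spec An [event_spec()].
#' @param family Required when `object` is a plain ensemble data frame.
#' @param t0 Reference time for `reference = "initial_value"`; defaults to
#'   the first observed time when `object` carries its data.
#' @param snapshot For `growth_pf`: use a snapshotted state.
#' @return One-row tibble: `tpred`, `tpred_sd`, `noncrossing` (fraction),
#'   `channel`, `fraction`, `reference`.
#' @export
predict_event <- function(object, spec, family = NULL, t0 = NULL,
                          snapshot = NULL) {
  stopifnot(inherits(spec, "event_spec"))
  if (inherits(object, "growth_pf")) {
    st <- if (is.null(snapshot)) object$state else
      object$snapshots[[as.character(snapshot)]]
    t0 <- t0 %||% object$data$time_h[1]
    return(predict_event(st, spec, t0 = t0))
  }
  if (inherits(object, "growth_sm")) {
    t0 <- t0 %||% object$data$time_h[1]
    return(predict_event(object$state, spec, t0 = t0))
  }
  if (inherits(object, "pf_state")) {
    ens <- tibble::as_tibble(as.data.frame(object$particles))
    ens$weight <- object$weights
    family <- object$family
    if (is.null(t0) && length(object$window$time)) t0 <- object$window$time[1]
    return(predict_event(ens, spec, family = family, t0 = t0))
  }
  stopifnot(is.data.frame(object), !is.null(family))
  w <- if ("weight" %in% names(object)) object$weight else
    rep(1 / nrow(object), nrow(object))
  w <- w / sum(w)
  frac <- rep(spec$fraction, nrow(object))
  if (spec$reference == "initial_value") {
    if (is.null(t0)) stop("`t0` required for an initial-value reference",
                          call. = FALSE)
    y0 <- growth_value(family, t0, object$k, object$b, object$c)
    frac <- spec$fraction * y0 / object$k
  }
  ok <- is.finite(frac) & frac > 0 & frac < 1 & object$c != 0
  tc <- rep(NA_real_, nrow(object))
  if (any(ok)) {
    tc[ok] <- crossing_time(family, frac[ok], object$k[ok], object$b[ok],
                            object$c[ok])
  }
  ok <- ok & is.finite(tc)
  noncross <- 1 - sum(w[ok])
  if (!any(ok)) {
    return(tibble::tibble(tpred = NA_real_, tpred_sd = NA_real_,
                          noncrossing = 1, channel = spec$channel,
                          fraction = spec$fraction,
                          reference = spec$reference))
  }
  wk <- w[ok] / sum(w[ok])
  tpred <- sum(wk * tc[ok])
  tsd <- sqrt(max(sum(wk * tc[ok]^2) - tpred^2, 0))
  tibble::tibble(tpred = tpred, tpred_sd = tsd, noncrossing = noncross,
                 channel = spec$channel, fraction = spec$fraction,
                 reference = spec$reference)
}

#' Post hoc event time from a completed signal
#'
#' Smooths the series with the Savitzky-Golay filter ([sg_smooth()],
#' defaults: order 6, window 21, mirror ends), computes the reference level
#' (maximum of the smoothed signal, or its first value), and returns the
#' sample time at which the smoothed signal is closest to
#' `fraction * reference`. Argmin ties break toward the earliest time. If
#' the smoothed signal never reaches the target level the boundary sample
#' time is returned with `noncrossing = TRUE`.
#'
#' @param data Tibble with `time_h` and `value`.
#' @param spec An [event_spec()].
#' @inheritParams sg_smooth
#' @return One-row tibble: `topt`, `reference`, `target`, `noncrossing`.
#' @export
posthoc_event_time <- function(data, spec, polyorder = 6, window = 21) {
  stopifnot(inherits(spec, "event_spec"))
  sm <- sg_smooth(data, polyorder = polyorder, window = window)$smooth
  ref <- if (spec$reference == "max_of_signal") max(sm) else sm[1]
  target <- spec$fraction * ref
  i <- which.min(abs(sm - target))
  noncross <- all(sm > target) || all(sm < target)
  tibble::tibble(topt = data$time_h[i], reference = ref, target = target,
                 noncrossing = noncross)
}

#' Signed event-time error
#'
#' `td = tpred - topt` in hours; positive means the prediction is late.
#'
#' @param tpred Predicted event time (hours).
#' @param topt Post hoc optimal event time (hours).
#' @return `tpred - topt`; `NA` propagates.
#' @export
event_error <- function(tpred, topt) tpred - topt

#' Relative signal loss from missing the optimal event time
#'
#' The signed relative difference, in percent, between the smoothed signal
#' at the predicted and at the optimal event time:
#' `(y[tpred] - y[topt]) / y[topt] * 100`. Signal values are looked up at
#' the sample nearest each time after Savitzky-Golay smoothing.
#'
#' @inheritParams posthoc_event_time
#' @param tpred,topt Event times (hours), both within the observed span.
#' @return Percent loss (scalar); `NA` with a warning when the smoothed
#'   signal at `topt` is zero.
#' @export
event_loss <- function(data, tpred, topt, spec = NULL, polyorder = 6,
                       window = 21) {
  if (!is.finite(tpred) || !is.finite(topt)) return(NA_real_)
  rng <- range(data$time_h)
  if (tpred < rng[1] || tpred > rng[2] || topt < rng[1] || topt > rng[2]) {
    stop("event times must lie within the observed time span", call. = FALSE)
  }
  sm <- sg_smooth(data, polyorder = polyorder, window = window)$smooth
  y_pred <- sm[which.min(abs(data$time_h - tpred))]
  y_opt <- sm[which.min(abs(data$time_h - topt))]
  if (y_opt == 0) {
    warning("smoothed signal is zero at `topt`: loss undefined",
            call. = FALSE)
    return(NA_real_)
  }
  (y_pred - y_opt) / y_opt * 100
}
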