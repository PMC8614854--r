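#' Three-parameter sigmoidal growth laws
#'
#' The package models transformed (rescaled, log) biomass and dissolved-oxygen
#' signals with either the Gompertz function
#' \deqn{y(t) = k \exp(-\exp(b - c t))}
#' or the Logistic function
#' \deqn{y(t) = k / (1 + \exp(b - c t)),}
#' where `k` is the asymptote on the transformed signal scale, and `b`
#' (dimensionless offset) and `c` (rate, per hour) parameterize the
#' transition dynamics. With `b > 0` and `c > 0` both curves increase
#' monotonically from 0 (Gompertz) or towards `k`; flipping the signs of
#' both `b` and `c` mirrors the curve in time about `t = b/c`, which gives
#' the monotone-decreasing convention used for dissolved oxygen.
#'
#' `k` is deliberately unconstrained: on the log scale the asymptote of a
#' rescaled signal may be zero or negative. [growth_direction()] flags
#' mixed-sign `(b, c)` combinations instead of rejecting them.
#'
#' @param family `"gompertz"` or `"logistic"`.
#' @param t Time in hours; any finite numeric vector.
#' @param k,b,c Curve parameters (vectors are recycled against `t`).
#' @return `growth_value()`: the curve value(s), same length as the longest
#'   input.
#' @examples
#' growth_value("gompertz", t = 3, k = 2, b = 3, c = 1)  # 2 * exp(-1)
#' growth_value("logistic", t = 2, k = 4, b = 2, c = 1)  # midpoint k/2
#' @export
growth_value <- function(family, t, k, b, c) {
  family <- match_family(family)
  if (!all(is.finite(t))) stop("`t` must be finite", call. = FALSE)
  if (!all(is.finite(k), is.finite(b), is.finite(c))) {
    stop("growth parameters must be finite", call. = FALSE)
  }
  z <- b - c * t
  if (family == "gompertz") k * exp(-exp(z)) else k / (1 + exp(z))
}

#' Threshold-crossing time of a growth curve
#'
#' Inverts [growth_value()] at a fraction of the asymptote: returns the time
#' `t` at which the curve equals `fraction * k`. Closed forms:
#' Gompertz `t = (b - log(-log(fraction)))/c`; Logistic
#' `t = (b - log(1/fraction - 1))/c`. Used for harvest-time (95% of `k`)
#' and critical-oxygen (20% of a reference level) predictions.
#'
#' @inheritParams growth_value
#' @param fraction Fraction of the asymptote in (0, 1); vectorized.
#' @return Crossing time(s) in hours.
#' @examples
#' crossing_time("gompertz", exp(-1), k = 2, b = 3, c = 1)  # b/c = 3
#' crossing_time("logistic", 0.5, k = 4, b = 2, c = 1)      # b/c = 2
#' @export
crossing_time <- function(family, fraction, k, b, c) {
  family <- match_family(family)
  if (!all(is.finite(fraction)) || any(fraction <= 0) || any(fraction >= 1)) {
    stop("`fraction` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(c == 0)) stop("`c` must be nonzero to invert the curve", call. = FALSE)
  if (family == "gompertz") {
    (b - log(-log(fraction))) / c
  } else {
    (b - log(1 / fraction - 1)) / c
  }
}

#' Monotonicity direction of a parameter triple
#'
#' @inheritParams growth_value
#' @return `"increasing"` (`c > 0`), `"decreasing"` (`c < 0`) or
#'   `"invalid"` (`c = 0`, a constant curve). A warning is raised when the
#'   signs of `b` and `c` disagree: the curve is still well defined but
#'   falls outside the monotone-increasing / monotone-decreasing sign
#'   conventions.
#' @export
growth_direction <- function(family, k, b, c) {
  match_family(family)
  if (!all(is.finite(k), is.finite(b), is.finite(c))) {
    stop("growth parameters must be finite", call. = FALSE)
  }
  dir <- dplyr::case_when(c > 0 ~ "increasing", c < 0 ~ "decreasing",
                          .default = "invalid")
  if (any(dir != "invalid" & sign(b) != sign(c))) {
    warning("mixed signs of b and c: curve violates the usual sign convention",
            call. = FALSE)
  }
  dir
}

match_family <- function(family) {
  match.arg(family, c("gompertz", "logistic"))
}
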