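#' Fit a static growth model by reshuffled-profile MCMC
#'
#' Fits a time-invariant Gompertz or Logistic model to a complete culture
#' by running the particle-filter update kernel over randomly reshuffled
#' `(time, value)` pairs: because the sliding window then always spans the
#' dynamics of the whole profile, the particle ensemble converges to a
#' posterior over a single static parameter set. Each sweep re-permutes the
#' profile; sweeps stop early once the relative change of every posterior
#' mean falls below `tol`.
#'
#' The resulting ensemble doubles as a particle-filter initializer for a
#' different culture (pass `tidy(fit)` or `fit$state$particles` to
#' [pf_init()]).
#'
#' @param data Tibble with `time_h` and `value` (transformed scale).
#' @param family `"gompertz"` or `"logistic"`.
#' @param init Prior spec or seed ensemble for [pf_init()]; by default a
#'   cold-start uniform prior bracketing the observed signal range and
#'   time span (direction inferred from the ends of the profile).
#' @param n_sweeps Maximum number of reshuffled passes (default 50).
#' @param tol Early-stop threshold on the relative change of the posterior
#'   means between sweeps (default 1e-3).
#' @param seed Optional integer seed.
#' @param ... Passed to [pf_init()] (particle count, windows, hyperpriors).
#' @return An object of class `growth_sm` with elements `state`, `family`,
#'   `n_sweeps`, `converged`, `history` (per-sweep posterior means).
#'   Supports [tidy()], [glance()], [predict()] and [ggplot2::autoplot()].
#' @export
fit_static <- function(data, family, init = NULL, n_sweeps = 50,
                       tol = 1e-3, seed = NULL, ...) {
  validate_series(data)
  family <- match_family(family)
  if (n_sweeps < 1) stop("`n_sweeps` must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  state <- pf_init(family, init %||% default_prior(data), ...)
  n <- nrow(data)
  if (n < state$config$window) {
    stop("series length (", n, ") shorter than the sample window (",
         state$config$window, ")", call. = FALSE)
  }
  prev <- rep(NA_real_, 3)
  sweep_rows <- vector("list", n_sweeps)
  converged <- FALSE
  sweeps_run <- 0L
  for (s in seq_len(n_sweeps)) {
    perm <- sample.int(n)
    for (i in perm) {
      state <- pf_update(state, data$time_h[i], data$value[i],
                         check_time = FALSE)
    }
    sm <- pf_summary(state)
    cur <- c(sm$k, sm$b, sm$c)
    sweep_rows[[s]] <- dplyr::bind_cols(tibble::tibble(sweep = s), sm)
    sweeps_run <- s
    if (!anyNA(prev)) {
      rel <- abs(cur - prev) / pmax(abs(prev), 1e-8)
      if (all(rel < tol)) {
        converged <- TRUE
        break
      }
    }
    prev <- cur
  }
  structure(list(state = state, family = family, n_sweeps = sweeps_run,
                 converged = converged,
                 history = dplyr::bind_rows(sweep_rows[seq_len(sweeps_run)]),
                 data = tibble::as_tibble(data)),
            class = "growth_sm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cold-start prior bracketing the observed signal range and time span.
# The transition rate is drawn so the sigmoid transition spans between the
# whole profile and a twentieth of it; the offset b is coupled to a
# transition midpoint drawn around the observed half-level time.
default_prior <- function(data) {
  v <- data$value
  t <- data$time_h
  span_v <- max(diff(range(v)), 0.1)
  span_t <- max(diff(range(t)), 1e-6)
  increasing <- v[length(v)] >= v[1]
  t50 <- t[which.min(abs(v - (max(v) + min(v)) / 2))]
  k_range <- c(max(v) - 0.1 * span_v, max(v) + 0.5 * span_v)
  c_mag <- c(4 / span_t, 80 / span_t)
  tmid <- c(max(t50 - 0.25 * span_t, min(t)), t50 + 0.25 * span_t)
  if (increasing) {
    list(k = k_range, c = c_mag, tmid = tmid)
  } else {
    list(k = k_range, c = -rev(c_mag), tmid = tmid)
  }
}

#' @export
print.growth_sm <- function(x, ...) {
  s <- pf_summary(x$state)
  cat("Static growth model (", x$family, "), reshuffled-profile MCMC\n",
      sep = "")
  cat("  sweeps:", x$n_sweeps,
      if (x$converged) "(converged)" else "(max sweeps reached)", "\n")
  cat(sprintf("  k = %.4g (sd %.3g), b = %.4g (sd %.3g), c = %.4g (sd %.3g)\n",
              s$k, s$k_sd, s$b, s$b_sd, s$c, s$c_sd))
  invisible(x)
}

#' Forecast from a fitted model
#'
#' For a static fit the parameters are frozen: the forecast is the weighted
#' ensemble mean curve with weighted-quantile intervals. For a filter the
#' final (or a snapshotted) state is used.
#'
#' @param object A `growth_sm` or `growth_pf`.
#' @param times Times (hours) at which to predict.
#' @param level Central interval mass (default 0.9).
#' @param snapshot For `growth_pf`: name/index of a stored snapshot
#'   (default: final state).
#' @param ... Unused.
#' @return Tibble with `time_h`, `.pred`, `.lower`, `.upper`.
#' @export
predict.growth_sm <- function(object, times, level = 0.9, ...) {
  st <- object$state
  st$window <- list(time = numeric(0), value = numeric(0)) # frozen model
  pf_predict(st, times, level = level)
}

#' @rdname predict.growth_sm
#' @export
predict.growth_pf <- function(object, times, level = 0.9, snapshot = NULL,
                              ...) {
  st <- if (is.null(snapshot)) object$state else
    object$snapshots[[as.character(snapshot)]]
  if (is.null(st)) stop("no such snapshot: ", snapshot, call. = FALSE)
  pf_predict(st, times, level = level)
}
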