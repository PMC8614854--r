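#' Initialize a growth-model particle filter
#'
#' Builds the filter state: `n_particles` parameter triples `(k, b, c)`,
#' uniform weights, the observation-noise precision state at its Gamma
#' prior, an empty observation window, and state-noise precisions set so
#' the initial random-walk sd is a tenth of the ensemble spread of each
#' parameter (override via `state_noise`).
#'
#' @param family `"gompertz"` or `"logistic"`.
#' @param init Either a data frame ensemble with columns `k`, `b`, `c`
#'   (optionally `weight`), e.g. the [tidy()] ensemble of a static fit of
#'   another culture, or a prior specification: a list with entries
#'   `k = c(lo, hi)`, `c = c(lo, hi)` and `tmid = c(lo, hi)` from which
#'   particles are drawn uniformly with `b = c * tmid` (this couples the
#'   offset to the transition midpoint so that cold-start curves bracket
#'   the observed time span).
#' @param n_particles Ensemble size (default 1000).
#' @param window Sliding sample window size `W` (default 20): the number of
#'   most recent measurements entering each likelihood evaluation.
#' @param noise_window State-noise window size `S` (default 10): the number
#'   of most recent update steps whose particle increments drive the
#'   state-noise precisions.
#' @param hyper_lambda,hyper_nu,hyper_gamma Gamma `(shape, rate)`
#'   hyperpriors for the state-noise precisions of `k`, `b` and `c`;
#'   defaults `(0.1, 1)`, non-informative.
#' @param hyper_obs Gamma `(shape, rate)` hyperprior for the shared
#'   observation-noise precision; default `(0.1, 1)`.
#' @param mh_delta Metropolis-Hastings proposal width `delta` in (0, 1) for
#'   the precision of `c` (default 0.9): proposals are `gamma * u` with
#'   `u ~ U(delta, 1/delta)`.
#' @param resampling `"systematic"` (default) or `"multinomial"`.
#' @param adapt_state_noise If `FALSE` the state-noise precisions stay at
#'   their initial values (useful to emulate a nearly static model).
#' @param state_noise Optional named vector `c(k=, b=, c=)` of initial
#'   state-noise precisions; defaults to the Gamma-prior means.
#' @param seed Optional integer seed for the particle draw.
#' @return An object of class `pf_state`.
#' @export
pf_init <- function(family, init, n_particles = 1000, window = 20,
                    noise_window = 10,
                    hyper_lambda = c(0.1, 1), hyper_nu = c(0.1, 1),
                    hyper_gamma = c(0.1, 1), hyper_obs = c(0.1, 1),
                    mh_delta = 0.9,
                    resampling = c("systematic", "multinomial"),
                    adapt_state_noise = TRUE, state_noise = NULL,
                    seed = NULL) {
  family <- match_family(family)
  resampling <- match.arg(resampling)
  if (n_particles < 2) stop("need at least 2 particles", call. = FALSE)
  if (window < 2 || noise_window < 2) {
    stop("`window` and `noise_window` must be at least 2", call. = FALSE)
  }
  if (mh_delta <= 0 || mh_delta >= 1) {
    stop("`mh_delta` must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  if (is.data.frame(init)) {
    stopifnot(all(c("k", "b", "c") %in% names(init)))
    idx <- if (nrow(init) == n_particles) seq_len(n_particles) else {
      w0 <- if ("weight" %in% names(init)) init$weight else NULL
      sample.int(nrow(init), n_particles, replace = TRUE, prob = w0)
    }
    particles <- cbind(k = init$k[idx], b = init$b[idx], c = init$c[idx])
  } else {
    stopifnot(is.list(init), all(c("k", "c", "tmid") %in% names(init)))
    kk <- stats::runif(n_particles, init$k[1], init$k[2])
    cc <- stats::runif(n_particles, init$c[1], init$c[2])
    tm <- stats::runif(n_particles, init$tmid[1], init$tmid[2])
    particles <- cbind(k = kk, b = cc * tm, c = cc)
  }

  prec <- if (is.null(state_noise)) {
    # start the random-walk sd at a tenth of the ensemble spread: small
    # enough not to destroy an informative seed ensemble, large enough for
    # the hierarchical update to take over within a few steps
    spread <- pmax(apply(particles, 2, stats::sd), 1e-3)
    stats::setNames(1 / (0.1 * spread)^2, c("k", "b", "c"))
  } else {
    stopifnot(all(c("k", "b", "c") %in% names(state_noise)),
              all(state_noise > 0))
    state_noise[c("k", "b", "c")]
  }

  structure(list(
    family = family,
    particles = particles,
    weights = rep(1 / n_particles, n_particles),
    tau_shape = hyper_obs[1],
    tau_rate = hyper_obs[2],
    noise_prec = prec,
    noise_buffer = list(),
    window = list(time = numeric(0), value = numeric(0)),
    config = list(n_particles = n_particles, window = window,
                  noise_window = noise_window,
                  hyper_lambda = hyper_lambda, hyper_nu = hyper_nu,
                  hyper_gamma = hyper_gamma, hyper_obs = hyper_obs,
                  mh_delta = mh_delta, resampling = resampling,
                  adapt_state_noise = adapt_state_noise)
  ), class = "pf_state")
}

#' Curve values of every particle at given times
#' @noRd
curve_matrix <- function(family, particles, times) {
  z <- outer(particles[, "b"], rep(1, length(times))) -
    particles[, "c"] %o% times
  if (family == "gompertz") {
    particles[, "k"] * exp(-exp(z))
  } else {
    particles[, "k"] / (1 + exp(z))
  }
}

#' One particle-filter update step
#'
#' Appends a measurement to the sliding window, updates the shared
#' observation-noise precision state with the one-step-ahead innovation,
#' propagates every particle by Gaussian random-walk increments with
#' per-parameter variances given by the current state-noise precisions,
#' reweights by the Gaussian likelihood of all windowed values (computed in
#' log space with max-shift, so weight degeneracy never produces silent
#' `NaN`), resamples, and finally re-estimates the state-noise precisions
#' from the coherent ensemble motion (see [update_state_noise()]).
#'
#' @param state A `pf_state`.
#' @param time_h,value The new measurement.
#' @param check_time Require `time_h` to exceed the last window time
#'   (disabled by the reshuffled-profile static fit).
#' @return The updated `pf_state`.
#' @export
pf_update <- function(state, time_h, value, check_time = TRUE) {
  stopifnot(inherits(state, "pf_state"))
  if (!is.finite(time_h) || !is.finite(value)) {
    stop("measurement must be finite", call. = FALSE)
  }
  w <- state$window
  if (check_time && length(w$time) && time_h <= w$time[length(w$time)]) {
    stop("`time_h` must exceed the last window time", call. = FALSE)
  }
  w$time <- c(w$time, time_h)
  w$value <- c(w$value, value)
  W <- state$config$window
  if (length(w$time) > W) {
    keep <- seq.int(length(w$time) - W + 1L, length(w$time))
    w$time <- w$time[keep]
    w$value <- w$value[keep]
  }
  state$window <- w

  n <- state$config$n_particles
  w_prev <- state$weights / sum(state$weights)
  mean_prev <- drop(crossprod(state$particles, w_prev))

  # discounted conjugate update of the shared obs-noise precision with the
  # one-step-ahead ensemble innovation (computed before propagation, so the
  # point never explains itself); forgetting over one sample window lets
  # the inferred noise level track the current innovation scale: the
  # likelihood is sharp while tracking is good and flattens during
  # adaptation, instead of being dominated by the vague prior and the
  # initial misfit phase
  innov <- value -
    sum(w_prev * drop(curve_matrix(state$family, state$particles, time_h)))
  rho <- 1 - 1 / W
  state$tau_shape <- rho * state$tau_shape + 0.5
  state$tau_rate <- rho * state$tau_rate + 0.5 * innov^2
  tau <- state$tau_shape / state$tau_rate

  sds <- 1 / sqrt(state$noise_prec)
  eps <- cbind(k = stats::rnorm(n, 0, sds["k"]),
               b = stats::rnorm(n, 0, sds["b"]),
               c = stats::rnorm(n, 0, sds["c"]))
  state$particles <- state$particles + eps

  fit <- curve_matrix(state$family, state$particles, w$time)
  resid <- fit - matrix(w$value, nrow = n, ncol = length(w$time), byrow = TRUE)
  ssr <- rowSums(resid^2)
  loglik <- 0.5 * length(w$time) * log(tau) - 0.5 * tau * ssr
  logw <- log(state$weights) + loglik
  logw[!is.finite(logw)] <- -Inf
  if (all(logw == -Inf)) logw[] <- 0 # total underflow: fall back to uniform
  wgt <- exp(logw - max(logw))
  wgt <- wgt / sum(wgt)

  idx <- resample_indices(wgt, state$config$resampling)
  state$particles <- state$particles[idx, , drop = FALSE]
  state$weights <- rep(1 / n, n)

  # the coherent per-step motion of the ensemble mean — the systematic
  # drift each of the N particles underwent — feeds the state-noise window;
  # idiosyncratic Monte-Carlo diffusion is excluded so the precisions
  # respond to demanded parameter motion, not to self-injected noise
  mean_new <- colMeans(state$particles)
  d_bar <- mean_new - mean_prev
  entry <- list(n = n, ss = n * d_bar^2)
  state$noise_buffer <- c(state$noise_buffer, list(entry))
  S <- state$config$noise_window
  if (length(state$noise_buffer) > S) {
    state$noise_buffer <-
      state$noise_buffer[seq.int(length(state$noise_buffer) - S + 1L,
                                 length(state$noise_buffer))]
  }
  if (state$config$adapt_state_noise) state <- update_state_noise(state)
  state
}

#' Re-estimate the state-noise precisions
#'
#' The precisions of the random-walk increments of `k` and `b` are set to
#' the mean of their conjugate Gamma posterior given the coherent
#' ensemble-mean increments collected over the state-noise window, each
#' counted once per particle (posterior shape = prior shape + half the
#' increment count, posterior rate = prior rate + half the sum of squared
#' increments). The precision of `c` is updated by
#' one Metropolis-Hastings step with a multiplicative uniform proposal
#' against the same Gamma posterior density (see [mh_gamma_step()]).
#'
#' With an empty history buffer the state is returned unchanged.
#'
#' @param state A `pf_state`.
#' @return The state with updated `noise_prec`.
#' @export
update_state_noise <- function(state) {
  buf <- state$noise_buffer
  if (!length(buf)) return(state)
  n_tot <- sum(vapply(buf, `[[`, numeric(1), "n"))
  ss <- Reduce(`+`, lapply(buf, `[[`, "ss"))
  cfg <- state$config
  post_k <- gamma_posterior(cfg$hyper_lambda[1], cfg$hyper_lambda[2],
                            n_tot, ss[["k"]])
  post_b <- gamma_posterior(cfg$hyper_nu[1], cfg$hyper_nu[2],
                            n_tot, ss[["b"]])
  post_c <- gamma_posterior(cfg$hyper_gamma[1], cfg$hyper_gamma[2],
                            n_tot, ss[["c"]])
  state$noise_prec[["k"]] <- max(post_k$mean, 1e-12)
  state$noise_prec[["b"]] <- max(post_b$mean, 1e-12)
  state$noise_prec[["c"]] <- max(
    mh_gamma_step(state$noise_prec[["c"]], post_c$shape, post_c$rate,
                  cfg$mh_delta), 1e-12)
  state
}

#' Conjugate Gamma posterior for a precision
#'
#' For `n` Gaussian increments with known zero mean and sum of squares
#' `ss`, the Gamma(shape, rate) prior on the precision yields the posterior
#' Gamma(shape + n/2, rate + ss/2).
#'
#' @param shape,rate Prior parameters.
#' @param n Number of increments.
#' @param ss Sum of squared increments.
#' @return List with `shape`, `rate` and the posterior `mean`.
#' @export
gamma_posterior <- function(shape, rate, n, ss) {
  s <- shape + n / 2
  r <- rate + ss / 2
  list(shape = s, rate = r, mean = s / r)
}

#' One Metropolis-Hastings step targeting a Gamma density
#'
#' Multiplicative uniform proposal: `x' = x * u` with
#' `u ~ Uniform(delta, 1/delta)`. The proposal density is
#' `1/(x (1/delta - delta))` on `(x delta, x/delta)`, so the Hastings
#' correction is `x/x'`; the acceptance probability is
#' `min(1, [p(x') x] / [p(x) x'])` with `p` the Gamma(shape, rate) target.
#'
#' @param x Current (positive) value.
#' @param shape,rate Target Gamma parameters.
#' @param delta Proposal width in (0, 1).
#' @return The next chain value.
#' @export
mh_gamma_step <- function(x, shape, rate, delta = 0.9) {
  u <- stats::runif(1, delta, 1 / delta)
  xp <- x * u
  log_acc <- (shape - 1) * (log(xp) - log(x)) - rate * (xp - x) +
    (log(x) - log(xp))
  if (log(stats::runif(1)) < log_acc) xp else x
}

#' Resample a weighted ensemble
#'
#' Draws `N` particle indices with probability proportional to the weights
#' and resets the weights to `1/N`. The systematic scheme places one
#' stratified point per `1/N` interval (low variance, copy counts within
#' one of `N * weight`); the multinomial scheme draws independently.
#'
#' @param ensemble A `pf_state` or a data frame with a `weight` column.
#' @param scheme `"systematic"` or `"multinomial"`.
#' @return Same type as the input, resampled.
#' @export
pf_resample <- function(ensemble, scheme = c("systematic", "multinomial")) {
  scheme <- match.arg(scheme)
  if (inherits(ensemble, "pf_state")) {
    idx <- resample_indices(ensemble$weights, scheme)
    ensemble$particles <- ensemble$particles[idx, , drop = FALSE]
    ensemble$weights <- rep(1 / length(idx), length(idx))
    return(ensemble)
  }
  stopifnot(is.data.frame(ensemble), "weight" %in% names(ensemble))
  idx <- resample_indices(ensemble$weight, scheme)
  out <- tibble::as_tibble(ensemble)[idx, ]
  out$weight <- 1 / length(idx)
  out
}

resample_indices <- function(weights, scheme) {
  if (any(weights < 0)) stop("negative weight", call. = FALSE)
  n <- length(weights)
  w <- weights / sum(weights)
  if (scheme == "multinomial") {
    return(sample.int(n, n, replace = TRUE, prob = w))
  }
  u <- (stats::runif(1) + seq_len(n) - 1) / n
  findInterval(u, cumsum(w), left.open = TRUE) + 1L
}

#' Forecast future signal values from a particle ensemble
#'
#' Point forecasts are the weighted ensemble mean of each particle's curve;
#' the interval is formed from weighted ensemble quantiles.
#'
#' @param state A `pf_state`.
#' @param times Future times (hours); must not precede the last windowed
#'   observation.
#' @param level Central credible-interval mass (default 0.9, i.e. 5-95%).
#' @return A tibble with `time_h`, `.pred`, `.lower`, `.upper`.
#' @export
pf_predict <- function(state, times, level = 0.9) {
  stopifnot(inherits(state, "pf_state"))
  if (!length(times)) {
    return(tibble::tibble(time_h = numeric(0), .pred = numeric(0),
                          .lower = numeric(0), .upper = numeric(0)))
  }
  last_t <- if (length(state$window$time)) max(state$window$time) else -Inf
  if (any(times < last_t)) {
    stop("forecast times must not precede the last observation", call. = FALSE)
  }
  fit <- curve_matrix(state$family, state$particles, times)
  w <- state$weights / sum(state$weights)
  pred <- drop(crossprod(fit, w))
  a <- (1 - level) / 2
  qs <- apply(fit, 2, weighted_quantile, w = w, probs = c(a, 1 - a))
  tibble::tibble(time_h = times, .pred = pred,
                 .lower = qs[1, ], .upper = qs[2, ])
}

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[ord][which(cw >= p - 1e-12)[1]], numeric(1))
}

#' Weighted ensemble summary of a filter state
#' @param state A `pf_state`.
#' @return One-row tibble of weighted means and sds of `k`, `b`, `c`, the
#'   mean inferred observation-noise sd, and the state-noise sds.
#' @export
pf_summary <- function(state) {
  stopifnot(inherits(state, "pf_state"))
  w <- state$weights / sum(state$weights)
  m <- drop(crossprod(state$particles, w))
  v <- drop(crossprod(state$particles^2, w)) - m^2
  tau <- state$tau_shape / state$tau_rate
  tibble::tibble(
    k = m[["k"]], b = m[["b"]], c = m[["c"]],
    k_sd = sqrt(max(v[["k"]], 0)), b_sd = sqrt(max(v[["b"]], 0)),
    c_sd = sqrt(max(v[["c"]], 0)),
    obs_sd = 1 / sqrt(tau),
    noise_sd_k = 1 / sqrt(state$noise_prec[["k"]]),
    noise_sd_b = 1 / sqrt(state$noise_prec[["b"]]),
    noise_sd_c = 1 / sqrt(state$noise_prec[["c"]])
  )
}

#' Run the particle filter over a culture time series
#'
#' Applies [pf_update()] to every row of `data` in time order, recording a
#' one-step-ahead prediction (made *before* each update, so the point never
#' predicts itself) and the post-update ensemble summary. Full filter
#' states can be snapshotted at chosen update indices for later split-wise
#' evaluation.
#'
#' @param data Tibble with `time_h` and `value` (transformed scale),
#'   strictly increasing times.
#' @param family `"gompertz"` or `"logistic"`.
#' @param init Initial ensemble or prior spec (see [pf_init()]); ignored
#'   when `state` is given.
#' @param state Optionally an already-initialized `pf_state` to continue.
#' @param snapshots Integer update indices at which to store a copy of the
#'   full filter state.
#' @param seed Optional integer seed; fixing it makes the whole run
#'   (particle trajectories included) reproducible.
#' @param ... Passed to [pf_init()].
#' @return An object of class `growth_pf` with elements `state` (final),
#'   `history` (one row per update), `snapshots` (named list of
#'   `pf_state`), `family` and `data`. Supports [tidy()], [glance()],
#'   [predict()] and [ggplot2::autoplot()].
#' @export
pf_filter <- function(data, family, init = NULL, state = NULL,
                      snapshots = integer(0), seed = NULL, ...) {
  validate_series(data)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state)) {
    if (is.null(init)) stop("supply `init` or `state`", call. = FALSE)
    state <- pf_init(family, init, ...)
  }
  family <- state$family
  n <- nrow(data)
  snaps <- list()
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    t_i <- data$time_h[i]
    y_i <- data$value[i]
    pred <- drop(crossprod(
      drop(curve_matrix(family, state$particles, t_i)),
      state$weights / sum(state$weights)))
    state <- pf_update(state, t_i, y_i)
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(step = i, time_h = t_i, value = y_i,
                     onestep_pred = pred, onestep_err = y_i - pred),
      pf_summary(state))
    if (i %in% snapshots) snaps[[as.character(i)]] <- state
  }
  structure(list(state = state, history = dplyr::bind_rows(rows),
                 snapshots = snaps, family = family,
                 data = tibble::as_tibble(data)),
            class = "growth_pf")
}

#' @export
print.growth_pf <- function(x, ...) {
  s <- pf_summary(x$state)
  cat("Particle-filter growth model (", x$family, ")\n", sep = "")
  cat("  updates:", nrow(x$history),
      " particles:", x$state$config$n_particles, "\n")
  cat(sprintf("  k = %.4g (sd %.3g), b = %.4g (sd %.3g), c = %.4g (sd %.3g)\n",
              s$k, s$k_sd, s$b, s$b_sd, s$c, s$c_sd))
  cat(sprintf("  obs noise sd = %.3g; state-noise sd (k, b, c) = %.3g, %.3g, %.3g\n",
              s$obs_sd, s$noise_sd_k, s$noise_sd_b, s$noise_sd_c))
  invisible(x)
}

#' Save / load a filter state as JSON
#'
#' Checkpoint format: particles, weights, observation-noise states,
#' state-noise precisions and buffer, window and configuration.
#'
#' @param state A `pf_state`.
#' @param path JSON file path.
#' @return `pf_save_state()` the path, invisibly; `pf_load_state()` the
#'   restored `pf_state`.
#' @export
pf_save_state <- function(state, path) {
  stopifnot(inherits(state, "pf_state"))
  obj <- list(
    family = state$family,
    particles = as.data.frame(state$particles),
    weights = state$weights,
    tau_shape = state$tau_shape, tau_rate = state$tau_rate,
    noise_prec = as.list(state$noise_prec),
    buffer_n = vapply(state$noise_buffer, `[[`, numeric(1), "n"),
    buffer_ss = lapply(state$noise_buffer,
                       function(e) as.list(e$ss[c("k", "b", "c")])),
    window = state$window,
    config = state$config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pf_save_state
#' @export
pf_load_state <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  buf <- lapply(seq_along(obj$buffer_n), function(i) {
    ss <- unlist(obj$buffer_ss[i, c("k", "b", "c")])
    list(n = obj$buffer_n[i], ss = ss)
  })
  particles <- as.matrix(obj$particles)
  dimnames(particles) <- list(NULL, colnames(particles))
  structure(list(
    family = obj$family,
    particles = particles,
    weights = obj$weights,
    tau_shape = obj$tau_shape, tau_rate = obj$tau_rate,
    noise_prec = unlist(obj$noise_prec),
    noise_buffer = buf,
    window = list(time = as.numeric(obj$window$time),
                  value = as.numeric(obj$window$value)),
    config = cfg), class = "pf_state")
}
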