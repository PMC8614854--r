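test_that("initialization seeds particles and uniform weights as requested", {
  seed_ens <- tibble::tibble(k = rep(1.4, 50), b = rep(2.8, 50),
                             c = rep(0.9, 50))
  st <- pf_init("gompertz", seed_ens, n_particles = 50)
  expect_equal(unname(st$particles[, "k"]), rep(1.4, 50))
  expect_equal(st$weights, rep(1 / 50, 50))
  expect_length(st$window$time, 0)
  # prior-spec seeding is deterministic under a fixed seed
  pr <- list(k = c(1, 2), c = c(0.5, 2), tmid = c(1, 4))
  a <- pf_init("gompertz", pr, n_particles = 100, seed = 3)
  b <- pf_init("gompertz", pr, n_particles = 100, seed = 3)
  expect_identical(a$particles, b$particles)
  expect_error(pf_init("gompertz", pr, n_particles = 1), "2 particles")
})

test_that("whole filter runs are bit-identical under a fixed seed", {
  cult <- series_of(ref_culture())[1:40, ]
  pr <- list(k = c(1, 2), c = c(0.5, 2), tmid = c(1, 4))
  a <- pf_filter(cult, "gompertz", init = pr, n_particles = 100, seed = 8)
  b <- pf_filter(cult, "gompertz", init = pr, n_particles = 100, seed = 8)
  expect_identical(a$state$particles, b$state$particles)
  expect_identical(a$history, b$history)
})

test_that("weights stay normalized and times must increase", {
  cult <- series_of(ref_culture())[1:30, ]
  st <- pf_init("gompertz", ref_seed_ensemble(200), n_particles = 200,
                seed = 1)
  for (i in seq_len(nrow(cult))) {
    st <- pf_update(st, cult$time_h[i], cult$value[i])
    expect_lt(abs(sum(st$weights) - 1), 1e-12)
    expect_true(all(st$noise_prec > 0))
  }
  expect_error(pf_update(st, cult$time_h[30] - 1, 0), "exceed")
  expect_length(st$window$time, st$config$window)
})

test_that("an ensemble of identical particles keeps uniform weights", {
  seed_ens <- tibble::tibble(k = rep(1.5, 64), b = rep(3, 64), c = rep(1, 64))
  st <- pf_init("gompertz", seed_ens, n_particles = 64,
                state_noise = c(k = 1e12, b = 1e12, c = 1e12), seed = 2)
  st <- pf_update(st, 1, growth_value("gompertz", 1, 1.5, 3, 1))
  expect_equal(st$weights, rep(1 / 64, 64))
  expect_lt(max(abs(st$particles[, "k"] - 1.5)), 1e-4)
})

test_that("conjugate Gamma posterior matches the closed form and integration", {
  post <- gamma_posterior(0.1, 1, n = 10, ss = 2)
  expect_equal(post$shape, 5.1)
  expect_equal(post$rate, 2)
  expect_equal(post$mean, 2.55)
  # numerical integration oracle for the posterior mean
  dens <- function(x) x * dgamma(x, shape = 5.1, rate = 2)
  expect_equal(integrate(dens, 0, Inf)$value, 2.55, tolerance = 1e-6)
  # zero increments: rate equals the prior rate, precision grows
  post0 <- gamma_posterior(0.1, 1, n = 10, ss = 0)
  expect_equal(post0$rate, 1)
  expect_equal(post0$mean, 5.1)
  expect_gt(post0$mean, 0.1)
})

test_that("the Metropolis-Hastings kernel targets its Gamma distribution", {
  set.seed(42)
  x <- 1
  draws <- numeric(1e5)
  for (i in seq_along(draws)) {
    # a wider proposal than the filter default mixes fast enough for a
    # tight long-run comparison with the analytic Gamma(3, 2) moments
    x <- mh_gamma_step(x, shape = 3, rate = 2, delta = 0.5)
    draws[i] <- x
  }
  expect_equal(mean(draws[-(1:1000)]), 1.5, tolerance = 0.02)
  expect_equal(var(draws[-(1:1000)]), 0.75, tolerance = 0.05)
})

test_that("resampling handles degenerate weights and preserves means", {
  ens <- tibble::tibble(k = c(1, 2), b = c(1, 1), c = c(1, 1),
                        weight = c(1, 0))
  set.seed(1)
  out <- pf_resample(ens, "systematic")
  expect_equal(out$k, rep(1, 2))
  expect_equal(out$weight, rep(0.5, 2))
  # uniform weights: a permutation-with-repetition, unbiased mean
  set.seed(2)
  u <- tibble::tibble(k = rnorm(400), b = 0, c = 0, weight = 1 / 400)
  means <- replicate(50, mean(pf_resample(u, "multinomial")$k))
  expect_lt(abs(mean(means) - mean(u$k)), 3 * sd(u$k) / sqrt(400 * 50 / 2))
  expect_error(pf_resample(tibble::tibble(k = 1, b = 1, c = 1, weight = -1)),
               "negative")
})

test_that("systematic resampling copy counts are within one of expectation", {
  # the stratified grid places one point per 1/N interval, so a particle
  # with weight 0.7 receives floor(0.7 N) or ceil(0.7 N) copies
  n <- 1e5
  big <- tibble::tibble(k = rep(c(0, 1), c(0.7 * n, 0.3 * n)), b = 0, c = 0,
                        weight = rep(c(0.7, 0.3) / c(0.7 * n, 0.3 * n),
                                     c(0.7 * n, 0.3 * n)))
  set.seed(9)
  for (rep in 1:3) {
    out <- pf_resample(big, "systematic")
    expect_lte(abs(sum(out$k == 0) - 0.7 * n), 1)
  }
})

test_that("forecasts reduce to curve evaluation for degenerate ensembles", {
  seed_ens <- tibble::tibble(k = rep(1.5, 10), b = rep(3, 10), c = rep(1, 10))
  st <- pf_init("gompertz", seed_ens, n_particles = 10)
  fc <- pf_predict(st, c(2, 4, 6))
  expect_equal(fc$.pred, growth_value("gompertz", c(2, 4, 6), 1.5, 3, 1))
  expect_equal(fc$.lower, fc$.upper)
  # two equally weighted particles average their curves
  st2 <- pf_init("gompertz", tibble::tibble(k = c(1, 2), b = c(2, 3),
                                            c = c(1, 1)), n_particles = 2)
  fc2 <- pf_predict(st2, 5)
  expect_equal(fc2$.pred,
               mean(growth_value("gompertz", 5, c(1, 2), c(2, 3), c(1, 1))))
  expect_equal(nrow(pf_predict(st2, numeric(0))), 0)
})

test_that("filter forecasts beat last-value-carried-forward on held-out data", {
  cult <- ref_culture(seed = 19)
  n <- nrow(cult)
  cut <- floor(0.6 * n)
  pf <- pf_filter(series_of(cult)[1:cut, ], "gompertz",
                  init = ref_seed_ensemble(400), n_particles = 400, seed = 4)
  future <- cult[(cut + 1):n, ]
  pred <- pf_predict(pf$state, future$time_h)$.pred
  lvcf <- rep(cult$value[cut], nrow(future))
  expect_lt(mse(future$value, pred), mse(future$value, lvcf))
})

test_that("pinned high state-noise precisions track stationary noiseless data", {
  t <- seq(0.05, 6, length.out = 60)
  dat <- tibble::tibble(time_h = t,
                        value = growth_value("gompertz", t, 1.5, 3, 1))
  set.seed(6)
  seed_ens <- tibble::tibble(k = 1.5 * runif(500, 0.98, 1.02),
                             b = 3 * runif(500, 0.98, 1.02),
                             c = 1 * runif(500, 0.98, 1.02))
  pf <- pf_filter(dat, "gompertz", init = seed_ens, n_particles = 500,
                  state_noise = c(k = 1e8, b = 1e8, c = 1e8),
                  adapt_state_noise = FALSE, seed = 13)
  g <- glance(pf)
  expect_lt(abs(g$k - 1.5) / 1.5, 0.01)
  expect_lt(abs(g$b - 3) / 3, 0.01)
  expect_lt(abs(g$c - 1) / 1, 0.01)
})

test_that("filter state survives a JSON checkpoint round trip", {
  cult <- series_of(ref_culture())[1:25, ]
  pf <- pf_filter(cult, "gompertz", init = ref_seed_ensemble(100),
                  n_particles = 100, seed = 21)
  path <- withr::local_tempfile(fileext = ".json")
  pf_save_state(pf$state, path)
  back <- pf_load_state(path)
  expect_equal(back$particles, pf$state$particles, tolerance = 1e-12)
  expect_equal(back$noise_prec, pf$state$noise_prec, tolerance = 1e-12)
  expect_equal(back$window$value, pf$state$window$value, tolerance = 1e-12)
  # the restored state keeps filtering
  st <- pf_update(back, max(cult$time_h) + 0.1, 1.2)
  expect_s3_class(st, "pf_state")
})
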