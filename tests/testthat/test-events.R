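test_that("event specs carry the operational defaults", {
  bm <- event_spec("BM")
  expect_equal(bm$fraction, 0.95)
  expect_identical(bm$reference, "max_of_signal")
  do <- event_spec("DO")
  expect_equal(do$fraction, 0.20)
  expect_identical(do$reference, "initial_value")
  expect_error(event_spec("BM", fraction = 1.2), "fraction")
})

test_that("degenerate ensembles reproduce the closed-form crossing exactly", {
  ens_g <- tibble::tibble(k = 1.5, b = 3, c = 1)
  ev <- predict_event(ens_g, event_spec("BM", fraction = exp(-1)),
                      family = "gompertz")
  expect_equal(ev$tpred, 3)  # fraction e^-1 lands on t = b/c
  ens_l <- tibble::tibble(k = 2, b = 4, c = 2)
  ev2 <- predict_event(ens_l, event_spec("BM", fraction = 0.5),
                       family = "logistic")
  expect_equal(ev2$tpred, 2)
})

test_that("two-particle predictions match a dense-grid threshold oracle", {
  ens <- tibble::tibble(k = c(1.4, 1.8), b = c(2.5, 3.2), c = c(0.9, 1.1),
                        weight = c(0.25, 0.75))
  spec <- event_spec("BM")
  ev <- predict_event(ens, spec, family = "gompertz")
  grid <- seq(0, 30, by = 1e-5)
  cross_oracle <- vapply(1:2, function(i) {
    y <- growth_value("gompertz", grid, ens$k[i], ens$b[i], ens$c[i])
    grid[which.min(abs(y - 0.95 * ens$k[i]))]
  }, numeric(1))
  expect_equal(ev$tpred, sum(ens$weight * cross_oracle), tolerance = 1e-4)
  expect_equal(ev$noncrossing, 0)
})

test_that("a fully non-crossing ensemble yields no fabricated time", {
  ens <- tibble::tibble(k = c(1, 1), b = c(2, 2), c = c(0, 0))
  ev <- predict_event(ens, event_spec("BM"), family = "gompertz")
  expect_true(is.na(ev$tpred))
  expect_equal(ev$noncrossing, 1)
})

test_that("post hoc event times converge to the closed-form crossing", {
  cult <- simulate_culture(tibble::tibble(start_time = 0, k = 1.5, b = 3,
                                          c = 1),
                           noise_sd = 0, duration = 12, mean_interval = 0.1,
                           jitter = 0, seed = 1)
  ph <- posthoc_event_time(series_of(cult), event_spec("BM"))
  closed <- crossing_time("gompertz", 0.95, 1.5, 3, 1)
  expect_lt(abs(ph$topt - closed), 0.1)  # one sampling interval
  expect_false(ph$noncrossing)
  # declining DO-like curve, 20%-of-initial rule
  do <- simulate_do_profile(tibble::tibble(start_time = 0, k = 2, b = -3,
                                           c = -1),
                            duration = 12, mean_interval = 0.1)
  ph_do <- posthoc_event_time(series_of(do), event_spec("DO"))
  # reference is the first sample of the smoothed (monotone) signal
  y0 <- do$value[1]
  closed_do <- crossing_time("gompertz", 0.2 * y0 / 2, 2, -3, -1)
  expect_lt(abs(ph_do$topt - closed_do), 0.1)
})

test_that("a series that never reaches the target is flagged at the boundary", {
  # declining oxygen observed only early: never reaches 20% of the start
  t <- seq(0, 3, length.out = 40)
  cult <- tibble::tibble(time_h = t,
                         value = growth_value("gompertz", t, 2, -5, -1))
  ph <- posthoc_event_time(cult, event_spec("DO"))
  expect_true(ph$noncrossing)
  expect_equal(ph$topt, 3)  # argmin lands on the boundary sample
})

test_that("event-time error and loss follow their definitions", {
  expect_equal(event_error(5.5, 5.0), 0.5)
  expect_equal(event_error(4, 4), 0)
  cult <- simulate_culture(tibble::tibble(start_time = 0, k = 1.5, b = 3,
                                          c = 1),
                           noise_sd = 0, duration = 12, mean_interval = 0.1,
                           jitter = 0, seed = 2)
  ser <- series_of(cult)
  topt <- posthoc_event_time(ser, event_spec("BM"))$topt
  expect_equal(event_loss(ser, topt, topt), 0)
  # harvesting 30 min early: loss equals the direct smoothed-curve lookup
  sm <- sg_smooth(ser)
  y_at <- function(tt) sm$smooth[which.min(abs(sm$time_h - tt))]
  expect_equal(event_loss(ser, topt - 0.5, topt),
               (y_at(topt - 0.5) - y_at(topt)) / y_at(topt) * 100)
  expect_error(event_loss(ser, -5, topt), "span")
})

test_that("filter and static-fit objects plug into event prediction", {
  cult <- ref_culture(seed = 41)
  fit <- fit_static(series_of(cult), "gompertz", seed = 3,
                    n_particles = 300)
  ev <- predict_event(fit, event_spec("BM"))
  expect_true(is.finite(ev$tpred))
  pf <- pf_filter(series_of(cult), "gompertz",
                  init = tidy(fit, ensemble = TRUE), n_particles = 300,
                  seed = 12)
  ev2 <- predict_event(pf, event_spec("BM"))
  expect_true(is.finite(ev2$tpred))
})
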