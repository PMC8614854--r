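# shared fixtures, built in code

# reference single-regime gompertz culture on the transformed scale:
# growth phase plus early plateau, as a monitored shake-flask run
ref_params <- list(k = 1.5, b = 3, c = 1)

ref_culture <- function(noise_sd = 0.05, duration = 8, seed = 11,
                        jitter = 0.15, mean_interval = 0.0667, ...) {
  simulate_culture(tibble::tibble(start_time = 0, k = ref_params$k,
                                  b = ref_params$b, c = ref_params$c),
                   noise_sd = noise_sd, duration = duration,
                   mean_interval = mean_interval, jitter = jitter,
                   seed = seed, ...)
}

series_of <- function(data) data[, c("time_h", "value")]

# replicate-condition culture (same parameters, independent noise/grid)
# whose static fit seeds the filter, as in routine deployment
ref_seed_ensemble <- function(n_particles = 1000) {
  repl <- ref_culture(seed = 77)
  fit <- fit_static(series_of(repl), "gompertz", seed = 5,
                    n_particles = n_particles)
  tidy(fit, ensemble = TRUE)
}

# independent local least-squares polynomial smoother (oracle for sg_smooth)
local_poly_oracle <- function(x, polyorder, window) {
  n <- length(x)
  half <- (window - 1L) / 2L
  padded <- c(x[(half + 1L):2L], x, x[(n - 1L):(n - half)])
  vapply(seq_len(n), function(i) {
    seg <- padded[i:(i + window - 1L)]
    j <- seq(-half, half)
    unname(stats::lm(seg ~ stats::poly(j, polyorder, raw = TRUE))$fitted[half + 1L])
  }, numeric(1))
}

# brute-force step-up FDR (oracle for bh_fdr)
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  cummin_rev <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  q[ord] <- pmin(cummin_rev, 1)
  q
}
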