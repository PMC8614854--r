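#' Run the unbiased split-wise evaluation protocol
#'
#' Compares particle-filter (PF) predictive monitoring against a static
#' model (SM) the way a laboratory would, without information leakage:
#' the SM is fitted to a *different* replicate culture; the PF is
#' initialized on further independent cultures and then filtered through
#' the test culture; at each split fraction both models predict all
#' strictly-future measurements of the test culture, and only those enter
#' the error metrics (a sample used for updating is never evaluated).
#'
#' Per split the report holds the PF and SM mean squared errors, the
#' one-sided paired sign-flip permutation p-value for PF superiority,
#' Benjamini-Hochberg FDR across the splits, and the event-time metrics
#' (signed error `td` and percent loss) for the channel's event.
#'
#' @param cultures Named list of culture tibbles (`time_h`, `value`,
#'   transformed scale).
#' @param sm_training Name of the culture used to fit the SM (must differ
#'   from `test`).
#' @param pf_initialization Character vector of culture names whose static
#'   fits seed the PF ensemble (must not include `test`).
#' @param test Name of the culture that is monitored.
#' @param family `"gompertz"` or `"logistic"`.
#' @param channel `"BM"` (default; splits 30-80%) or `"DO"` (splits capped
#'   at 60%, since late dissolved-oxygen tails are flat).
#' @param splits Split fractions; defaults depend on `channel`.
#' @param K Permutations for the significance test (default 1e5).
#' @param seed Optional integer seed covering the whole protocol run.
#' @param ... Passed to [pf_init()] via the fits (e.g. `n_particles`).
#' @return A tibble, one row per split: `split`, `n_train`, `n_future`,
#'   `mse_pf`, `mse_sm`, `log_mse_pf`, `log_mse_sm` (natural log),
#'   `p_value`, `fdr`, `significant`, `tpred_pf`, `tpred_sm`, `topt`,
#'   `td_pf`, `td_sm`, `loss_pf`, `loss_sm`.
#' @export
run_protocol <- function(cultures, sm_training, pf_initialization, test,
                         family, channel = c("BM", "DO"), splits = NULL,
                         K = 1e5, seed = NULL, ...) {
  channel <- match.arg(channel)
  family <- match_family(family)
  for (id in c(sm_training, pf_initialization, test)) {
    if (!id %in% names(cultures)) {
      stop("culture not found: ", id, call. = FALSE)
    }
  }
  if (sm_training == test || test %in% pf_initialization) {
    stop("the test culture must differ from training/initialization",
         call. = FALSE)
  }
  splits <- splits %||%
    if (channel == "BM") seq(0.3, 0.8, by = 0.1) else seq(0.3, 0.6, by = 0.1)
  if (!is.null(seed)) set.seed(seed)

  sm <- fit_static(cultures[[sm_training]], family, ...)

  seed_particles <- dplyr::bind_rows(lapply(pf_initialization, function(id) {
    fit <- fit_static(cultures[[id]], family, ...)
    tibble::as_tibble(as.data.frame(fit$state$particles))
  }))

  test_data <- cultures[[test]]
  validate_series(test_data)
  n <- nrow(test_data)
  split_idx <- pmax(pmin(floor(splits * n), n - 1L), 1L)
  pf <- pf_filter(test_data, family, init = seed_particles,
                  snapshots = unique(split_idx), ...)

  spec <- event_spec(channel)
  topt_row <- posthoc_event_time(test_data, spec)
  t0 <- test_data$time_h[1]

  rows <- purrr::map2(splits, split_idx, function(frac, i) {
    future <- test_data[(i + 1):n, ]
    pred_pf <- predict(pf, future$time_h, snapshot = i)$.pred
    pred_sm <- predict(sm, future$time_h)$.pred
    eps_pf <- (future$value - pred_pf)^2
    eps_sm <- (future$value - pred_sm)^2
    pt <- paired_permutation_test(eps_pf, eps_sm, K = K)
    ev_pf <- predict_event(pf, spec, snapshot = i, t0 = t0)
    ev_sm <- predict_event(sm, spec, t0 = t0)
    loss_of <- function(tpred) {
      tryCatch(event_loss(test_data, tpred, topt_row$topt),
               error = function(e) NA_real_)
    }
    tibble::tibble(
      split = frac, n_train = i, n_future = n - i,
      mse_pf = mse(future$value, pred_pf),
      mse_sm = mse(future$value, pred_sm),
      p_value = pt$p_value,
      tpred_pf = ev_pf$tpred, tpred_sm = ev_sm$tpred,
      topt = topt_row$topt,
      td_pf = event_error(ev_pf$tpred, topt_row$topt),
      td_sm = event_error(ev_sm$tpred, topt_row$topt),
      loss_pf = loss_of(ev_pf$tpred), loss_sm = loss_of(ev_sm$tpred),
      noncrossing_pf = ev_pf$noncrossing, noncrossing_sm = ev_sm$noncrossing)
  })
  out <- dplyr::bind_rows(rows)
  out$log_mse_pf <- log(out$mse_pf)
  out$log_mse_sm <- log(out$mse_sm)
  out$fdr <- bh_fdr(out$p_value)
  out$significant <- out$fdr < 0.05
  dplyr::relocate(out, "split", "n_train", "n_future", "mse_pf", "mse_sm",
                  "log_mse_pf", "log_mse_sm", "p_value", "fdr",
                  "significant")
}

#' Tables-style report of a protocol run
#'
#' Reshapes a [run_protocol()] result into the compact column layout used
#' for reporting (time percentage, natural-log MSEs, significance,
#' event-time errors and losses).
#'
#' @param report Output of [run_protocol()].
#' @return Tibble with columns `time_pct`, `log_mse_pf`, `log_mse_sm`,
#'   `significant`, `td_pf`, `td_sm`, `loss_pf`, `loss_sm`.
#' @export
protocol_table <- function(report) {
  tibble::tibble(
    time_pct = report$split * 100,
    log_mse_pf = report$log_mse_pf,
    log_mse_sm = report$log_mse_sm,
    significant = report$significant,
    td_pf = report$td_pf, td_sm = report$td_sm,
    loss_pf = report$loss_pf, loss_sm = report$loss_sm)
}
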