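#' Prediction-error metrics
#'
#' `ssd()` is the sum of squared deviations between observed and predicted
#' values over the evaluation (future) time points; `mse()` divides by the
#' number of future points, which keeps values comparable while the filter
#' progresses through a culture.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return A scalar.
#' @examples
#' ssd(c(1, 3), c(0, 0))  # 10
#' mse(c(1, 3), c(0, 0))  # 5
#' @export
ssd <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal length", call. = FALSE)
  }
  if (!length(observed)) stop("need at least one value", call. = FALSE)
  sum((observed - predicted)^2)
}

#' @rdname ssd
#' @export
mse <- function(observed, predicted) {
  if (!length(observed)) {
    stop("no future points: mean squared error undefined", call. = FALSE)
  }
  ssd(observed, predicted) / length(observed)
}

#' Paired sign-flip permutation test for improved predictive accuracy
#'
#' Tests whether particle-filter squared residuals are systematically
#' smaller than the paired static-model squared residuals at the same
#' future time points. The per-sample statistic is
#' `s = eps_pf - eps_sm`; under the null the pairing is exchangeable, so
#' `K` sign-flip replicates of `s` are drawn and the one-sided p-value is
#' the fraction of replicates whose mean is *strictly* below the observed
#' mean (alternative: the expectation of `s` is negative). Ties are not
#' counted; with continuous residuals they have probability zero. For
#' `exhaustive = TRUE` (n <= 20) all `2^n` sign assignments are enumerated
#' instead.
#'
#' @param eps_pf,eps_sm Paired squared residuals (equal length).
#' @param K Number of permutations (default 1e5).
#' @param exhaustive Enumerate all sign flips instead of sampling.
#' @param seed Optional integer seed.
#' @return One-row tibble: `statistic` (observed mean of `s`), `p_value`,
#'   `K`, `exhaustive`. A sampled p-value of exactly zero should be read
#'   as "< 1/K" (see `format_p()`).
#' @export
paired_permutation_test <- function(eps_pf, eps_sm, K = 1e5,
                                    exhaustive = FALSE, seed = NULL) {
  n <- length(eps_pf)
  if (n == 0 || length(eps_sm) != n) {
    stop("paired residual vectors must be non-empty and of equal length",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  s <- eps_pf - eps_sm
  obs <- mean(s)
  if (exhaustive) {
    if (n > 20) stop("exhaustive enumeration limited to n <= 20",
                     call. = FALSE)
    K_eff <- 2^n
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    means <- drop(signs %*% s) / n
    kappa <- sum(means < obs)
    return(tibble::tibble(statistic = obs, p_value = kappa / K_eff,
                          K = K_eff, exhaustive = TRUE))
  }
  K <- as.integer(K)
  kappa <- 0L
  chunk <- max(1L, min(K, as.integer(2e6 / n)))
  done <- 0L
  while (done < K) {
    m <- min(chunk, K - done)
    signs <- matrix(sample(c(-1, 1), m * n, replace = TRUE), nrow = m)
    means <- drop(signs %*% s) / n
    kappa <- kappa + sum(means < obs)
    done <- done + m
  }
  tibble::tibble(statistic = obs, p_value = kappa / K, K = K,
                 exhaustive = FALSE)
}

#' Human-readable p-value respecting permutation resolution
#' @param p P-value from [paired_permutation_test()].
#' @param K Number of permutations used.
#' @return Character: `"< 1/K"` when `p` is exactly zero.
#' @export
format_p <- function(p, K) {
  ifelse(p == 0, paste0("< ", format(1 / K, scientific = TRUE)),
         format(p, digits = 3))
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjusted q-values; improvements are declared significant at
#' `fdr < 0.05`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of FDR q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Rolling one-step-ahead mean squared error
#'
#' The tracking diagnostic: squared one-step-ahead prediction errors
#' averaged over a trailing window (default 15 samples). Positions with
#' fewer than `window` preceding samples are computed over the partial
#' window and flagged.
#'
#' @param x A `growth_pf` object (uses its recorded one-step-ahead errors)
#'   or a numeric vector of one-step-ahead prediction errors (residuals).
#' @param window Trailing window length (default 15).
#' @return Tibble with `time_h` (or `step`), `mse`, `partial`.
#' @export
rolling_mse <- function(x, window = 15) {
  if (inherits(x, "growth_pf")) {
    err <- x$history$onestep_err
    time <- x$history$time_h
  } else {
    err <- as.numeric(x)
    time <- seq_along(err)
  }
  m <- zoo::rollapplyr(err^2, window, mean, partial = TRUE)
  tibble::tibble(time_h = time, mse = m,
                 partial = seq_along(err) < window)
}
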