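#' Rescale raw sensor signals to the modelling scale
#'
#' Biomass back-scatter (channel `"BM"`, Attenuation Units) is divided by
#' 1000 and dissolved oxygen (channel `"DO"`, percent of maximum) by 10 to
#' avoid large magnitudes during model fitting; both are then log
#' transformed, since Gompertz/Logistic models represent these signals best
#' on a log scale.
#'
#' @param data A data frame with a `value` column (raw sensor units) or a
#'   bare numeric vector.
#' @param channel `"BM"` or `"DO"`; selects the rescaling constant.
#' @return Input with `value` replaced by the transformed signal (a tibble
#'   when a data frame came in, a numeric vector otherwise).
#' @examples
#' transform_signal(c(1000, 1000 * exp(1)), channel = "BM")  # 0, 1
#' @export
transform_signal <- function(data, channel = c("BM", "DO")) {
  channel <- match.arg(channel)
  if (is.data.frame(data)) {
    data <- tibble::as_tibble(data)
    data$value <- transform_signal(data$value, channel)
    return(data)
  }
  bad <- which(!is.finite(data) | data <= 0)
  if (length(bad)) {
    stop("non-positive raw value at index ", bad[1],
         ": log transform undefined", call. = FALSE)
  }
  log(data / signal_divisor(channel))
}

#' @rdname transform_signal
#' @export
inverse_transform_signal <- function(data, channel = c("BM", "DO")) {
  channel <- match.arg(channel)
  if (is.data.frame(data)) {
    data <- tibble::as_tibble(data)
    data$value <- inverse_transform_signal(data$value, channel)
    return(data)
  }
  exp(data) * signal_divisor(channel)
}

signal_divisor <- function(channel) if (channel == "BM") 1000 else 10

#' Savitzky-Golay smoothing with mirror padding
#'
#' Local least-squares polynomial smoothing used for post hoc event-time
#' estimation. Defaults follow the event-assessment parameterization:
#' polynomial order 6, window length 21, and mirror treatment of the two
#' signal ends (the series is extended by its own reflection about each end
#' point, excluding the end point itself, before the central filter
#' coefficients are applied). Exactly reproduces any polynomial of degree
#' up to `polyorder`.
#'
#' The filter assumes approximately uniform sampling and is applied
#' index-wise; a warning is emitted when the coefficient of variation of
#' the time steps exceeds 10%.
#'
#' @param data Tibble with `time_h` and `value` columns.
#' @param polyorder Polynomial order (default 6).
#' @param window Odd window length (default 21), must exceed `polyorder`.
#' @return The input tibble with an added `smooth` column.
#' @export
sg_smooth <- function(data, polyorder = 6, window = 21) {
  stopifnot(is.data.frame(data), all(c("time_h", "value") %in% names(data)))
  n <- nrow(data)
  if (window %% 2 != 1) stop("`window` must be odd", call. = FALSE)
  if (window <= polyorder) stop("`window` must exceed `polyorder`", call. = FALSE)
  if (n < window) {
    stop("series length (", n, ") shorter than the smoothing window (",
         window, ")", call. = FALSE)
  }
  dt <- diff(data$time_h)
  if (length(dt) > 1 && stats::sd(dt) / mean(dt) > 0.10) {
    warning("time steps vary by more than 10%: index-wise smoothing assumes ",
            "near-uniform sampling", call. = FALSE)
  }
  half <- (window - 1L) / 2L
  coefs <- signal::sgolay(p = polyorder, n = window)[half + 1L, ]
  x <- data$value
  padded <- c(x[(half + 1L):2L], x, x[(n - 1L):(n - half)])
  sm <- vapply(seq_len(n), function(i) {
    sum(coefs * padded[i:(i + window - 1L)])
  }, numeric(1))
  out <- tibble::as_tibble(data)
  out$smooth <- sm
  out
}

#' Read and write single-channel culture time series
#'
#' The on-disk format is delimited text with header `time_h,value`, one row
#' per measurement and one channel per file; lines starting with `#` are
#' comments. Values are expected on the transformed (log) scale unless you
#' transform after reading.
#'
#' @param path File path. `read_culture()` auto-detects comma or tab
#'   delimiters; `write_culture()` writes CSV.
#' @param data Tibble with `time_h` and `value` columns.
#' @return `read_culture()`: a tibble with `time_h` and `value`, checked
#'   for strictly increasing finite times.
#' @export
read_culture <- function(path) {
  data <- readr::read_delim(path, comment = "#", show_col_types = FALSE,
                            trim_ws = TRUE)
  if (!all(c("time_h", "value") %in% names(data))) {
    stop("expected columns `time_h` and `value` in ", path, call. = FALSE)
  }
  data <- dplyr::select(data, "time_h", "value")
  validate_series(data)
  data
}

#' @rdname read_culture
#' @export
write_culture <- function(data, path) {
  validate_series(data)
  readr::write_csv(dplyr::select(data, "time_h", "value"), path)
  invisible(path)
}

validate_series <- function(data) {
  if (!all(is.finite(data$time_h)) || !all(is.finite(data$value))) {
    stop("times and values must be finite", call. = FALSE)
  }
  if (nrow(data) > 1 && any(diff(data$time_h) <= 0)) {
    stop("`time_h` must be strictly increasing", call. = FALSE)
  }
  invisible(data)
}
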