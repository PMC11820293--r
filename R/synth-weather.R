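#' Build a daily weather series
#'
#' Packages daily rainfall and air temperature into the weather table the
#' pipeline consumes; the CSV round-trips losslessly through
#' [read_weather()].
#'
#' @param rainfall_mm Daily rainfall, millimetres, all `>= 0`.
#' @param temp_c Daily mean air temperature, degrees Celsius; same length
#'   as `rainfall_mm`.
#' @param day Optional day indices (default `1:n`).
#' @return Data frame `day`, `rain_mm`, `temp_c`.
#' @export
make_weather <- function(rainfall_mm, temp_c, day = seq_along(rainfall_mm)) {
  if (length(rainfall_mm) != length(temp_c)) {
    stop("rainfall and temperature series differ in length", call. = FALSE)
  }
  if (any(rainfall_mm < 0)) stop("rainfall must be >= 0", call. = FALSE)
  data.frame(day = as.numeric(day), rain_mm = as.numeric(rainfall_mm),
             temp_c = as.numeric(temp_c))
}

#' Demo rainy filling-period weather series
#'
#' A deterministic 46-day daily weather fixture for a wet filling
#' season: one 13-day stretch of continuous rain totalling 339.3 mm
#' inside a period totalling 539 mm (so the window carries 63% of the
#' period's rainfall), with a mild cool-down during the rain.  Used by
#' the worked examples and the pipeline demo.
#'
#' @param window_days Day indices of the continuous-rain window.
#' @return List with `weather` (data frame from [make_weather()]) and
#'   `window` (the `c(first, last)` day pair).
#' @export
demo_rainfall <- function(window_days = 17:29) {
  n <- 46
  rain <- rep(0, n)
  # 13 rainy days summing to 339.3 mm, heaviest mid-window
  w <- length(window_days)
  shape <- stats::dnorm(seq(-2, 2, length.out = w))
  rain[window_days] <- round(339.3 * shape / sum(shape), 4)
  rain[window_days[1]] <- rain[window_days[1]] + (339.3 - sum(rain))
  # the rest of the period carries the remaining 199.7 mm in scattered
  # showers on fixed days
  other <- c(3, 6, 7, 12, 34, 38, 43)
  share <- c(2, 3, 1, 4, 5, 3, 2)
  rain[other] <- 199.7 * share / sum(share)
  temp <- 22 + 4 * sin(seq(0, pi, length.out = n))
  temp[window_days] <- temp[window_days] - 3   # rain cools the air
  list(weather = make_weather(rain, temp),
       window = range(window_days))
}

#' Read / write the weather CSV
#'
#' @param x Weather data frame from [make_weather()].
#' @param path CSV path.
#' @return `read_weather` returns the weather data frame.
#' @export
write_weather <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weather
#' @export
read_weather <- function(path) {
  w <- utils::read.csv(path)
  make_weather(w$rain_mm, w$temp_c, day = w$day)
}
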