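# internal helpers: date windows, rounding, matrix utilities

#' Parse a time window
#'
#' Accepts a length-2 `Date` vector, or a length-2 character vector in
#' `"YYYY-MM"` or `"YYYY-MM-DD"` form. A `"YYYY-MM"` end month is expanded to
#' its last day so windows written as month ranges are inclusive.
#'
#' @param window Length-2 vector `c(start, end)`.
#' @return Length-2 `Date` vector with `start <= end`.
#' @keywords internal
#' @noRd
parseWindow <- function(window) {
  stopifnot(length(window) == 2L)
  if (inherits(window, "Date")) {
    out <- window
  } else {
    window <- as.character(window)
    expand <- function(x, end = FALSE) {
      if (grepl("^\\d{4}-\\d{2}$", x)) {
        d <- as.Date(paste0(x, "-01"))
        if (end) d <- lastDayOfMonth(d)
        d
      } else {
        as.Date(x)
      }
    }
    out <- c(expand(window[1]), expand(window[2], end = TRUE))
  }
  if (is.na(out[1]) || is.na(out[2]) || out[1] > out[2])
    stop("invalid window: ", paste(window, collapse = " .. "))
  out
}

lastDayOfMonth <- function(d) {
  first <- as.Date(format(d, "%Y-%m-01"))
  nxt <- seq(first, by = "1 month", length.out = 2L)[2L]
  nxt - 1L
}

#' Indices of series dates falling inside a window (inclusive)
#' @keywords internal
#' @noRd
windowIndices <- function(dates, window) {
  w <- parseWindow(window)
  which(dates >= w[1] & dates <= w[2])
}

#' Round half away from zero (the convention used for integer percentages)
#' @keywords internal
#' @noRd
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Monthly date axis (first of month) between two year-months, inclusive
#' @keywords internal
#' @noRd
monthlyDates <- function(from = "1998-01", to = "2016-12") {
  seq(as.Date(paste0(from, "-01")), as.Date(paste0(to, "-01")), by = "1 month")
}

# stopifnot with a readable message
assertThat <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# per-pixel median over the 3rd dimension of an array, NA-skipping,
# plus the count of non-NA observations
stackMedian <- function(arr) {
  d <- dim(arr)
  m <- matrix(arr, nrow = d[1] * d[2], ncol = d[3])
  cnt <- rowSums(!is.na(m))
  med <- apply(m, 1L, median, na.rm = TRUE)
  med[cnt == 0L] <- NA_real_
  list(
    median = matrix(med, d[1], d[2]),
    count = matrix(as.integer(cnt), d[1], d[2])
  )
}
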