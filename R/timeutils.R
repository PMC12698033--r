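#' @title Timestamp utilities
#' @description Internal helpers for ISO-8601 timestamps and calendar window
#'   arithmetic. All timestamps in a record are UTC; date-only timestamps are
#'   treated as midnight so comparisons are deterministic.
#' @name timeutils
#' @keywords internal
NULL

#' Parse ISO-8601 timestamps
#'
#' Accepts `YYYY-MM-DD`, `YYYY-MM-DDTHH:MM:SS` (also with a space separator)
#' and an optional trailing `Z`. Date-only values are interpreted as midnight.
#'
#' @param x character vector of timestamps.
#' @return `POSIXct` vector in UTC.
#' @export
parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- as.character(x)
  bad <- is.na(x) | !nzchar(x)
  if (any(bad)) stop("unparseable timestamp: empty or NA value", call. = FALSE)
  y <- sub("Z$", "", x)
  y <- sub("T", " ", y, fixed = TRUE)
  date_only <- grepl("^\\d{4}-\\d{2}-\\d{2}$", y)
  y[date_only] <- paste(y[date_only], "00:00:00")
  out <- as.POSIXct(y, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  if (anyNA(out)) {
    stop("unparseable timestamp: ", paste(x[is.na(out)], collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Format a timestamp as ISO-8601 UTC
#' @param t `POSIXct` vector.
#' @return character vector `YYYY-MM-DDTHH:MM:SSZ`.
#' @export
format_timestamp <- function(t) {
  format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

days_in_month <- function(year, month) {
  # month is 1..12
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- base[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
  d[month == 2 & leap] <- 29L
  d
}

#' Shift a time point by a calendar amount
#'
#' Days are exact 86400-second shifts. Months and years use calendar
#' arithmetic: the same day-of-month `n` months/years away, clamped to the
#' last day of the target month (e.g. Mar 31 minus 1 month is Feb 28/29).
#'
#' @param t `POSIXct` scalar (UTC).
#' @param n signed integer amount.
#' @param unit one of `"DAYS"`, `"MONTHS"`, `"YEARS"`.
#' @return shifted `POSIXct`.
#' @export
shift_time <- function(t, n, unit) {
  unit <- match.arg(unit, c("DAYS", "MONTHS", "YEARS"))
  if (unit == "DAYS") return(t + n * 86400)
  lt <- as.POSIXlt(t, tz = "UTC")
  if (unit == "YEARS") {
    lt$year <- lt$year + n
  } else {
    m <- lt$mon + n
    lt$year <- lt$year + m %/% 12L
    lt$mon <- m %% 12L
  }
  lt$mday <- pmin(lt$mday, days_in_month(lt$year + 1900L, lt$mon + 1L))
  as.POSIXct(lt, tz = "UTC")
}

#' Resolve a temporal window to a half-open interval
#'
#' `BEFORE_INDEX` windows resolve to `[index - amount, index)`: an event at
#' exactly `index - amount` is inside, an event at `index` is outside.
#' `AFTER_INDEX` resolves to `[index, index + amount)`.
#'
#' @param window a [temporal_window()] or `NULL` (unbounded).
#' @param index_time `POSIXct` index time.
#' @return list with `start` and `end` (`POSIXct`), or `NULL` if `window` is.
#' @export
resolve_window <- function(window, index_time) {
  if (is.null(window)) return(NULL)
  stopifnot(inherits(window, "temporal_window"))
  if (window$direction == "BEFORE_INDEX") {
    list(start = shift_time(index_time, -window$amount, window$unit),
         end = index_time)
  } else {
    list(start = index_time,
         end = shift_time(index_time, window$amount, window$unit))
  }
}

#' Test timestamps against a resolved window
#' @param ts `POSIXct` vector.
#' @param window `temporal_window` or `NULL` (everything passes).
#' @param index_time `POSIXct` index time.
#' @return logical vector.
#' @export
in_window <- function(ts, window, index_time) {
  if (is.null(window)) return(rep(TRUE, length(ts)))
  iv <- resolve_window(window, index_time)
  ts >= iv$start & ts < iv$end
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
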