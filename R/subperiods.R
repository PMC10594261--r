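#' Calendar subperiods of the pandemic observation window
#'
#' The observation window (April 2020 -- July 2021) is divided into three
#' calendar subperiods that track the national infection waves and lockdown
#' phases: subperiod 1 = April--August 2020, subperiod 2 =
#' September--November 2020, subperiod 3 = December 2020--July 2021.
#' All intervals are closed.
#'
#' @param dates a vector coercible with [as.Date()].
#' @return integer vector of subperiod indices in `{1, 2, 3}`.
#' @examples
#' assign_subperiod(as.Date(c("2020-05-15", "2020-11-30", "2021-07-31")))
#' @export
assign_subperiod <- function(dates) {
  dates <- as.Date(dates)
  if (anyNA(dates)) {
    stop("assign_subperiod: dates contain NA or unparseable values")
  }
  win <- subperiod_window()
  if (any(dates < win[1] | dates > win[2])) {
    bad <- format(dates[dates < win[1] | dates > win[2]][1])
    stop(sprintf(
      "assign_subperiod: date %s outside the observation window %s..%s",
      bad, format(win[1]), format(win[2])
    ))
  }
  sp <- rep.int(3L, length(dates))
  sp[dates <= as.Date("2020-11-30")] <- 2L
  sp[dates <= as.Date("2020-08-31")] <- 1L
  sp
}

#' @describeIn assign_subperiod first and last admissible dates of the window.
#' @export
subperiod_window <- function() {
  c(start = as.Date("2020-04-01"), end = as.Date("2021-07-31"))
}
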