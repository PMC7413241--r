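#' Treatment schedule
#'
#' An ordered list of administered fractions: injected activity (MBq) and
#' administration time (hours from the first injection).  Activities must be
#' positive and times non-decreasing.  A fractionated arm such as
#' "18.5 + 9.25 MBq, 10 days apart" is `schedule(c(18.5, 9.25), c(0, 240))`.
#'
#' @param activity_mbq Injected activity per fraction, MBq.
#' @param time_h Administration times, hours; defaults to `0` for a single
#'   fraction and must be non-decreasing.
#' @return Object of class `schedule` (a data frame).
#' @export
schedule <- function(activity_mbq, time_h = rep(0, length(activity_mbq))) {
  activity_mbq <- as.numeric(activity_mbq)
  time_h <- as.numeric(time_h)
  stopifnot(length(activity_mbq) == length(time_h))
  if (any(!is.finite(activity_mbq)) || any(activity_mbq <= 0))
    stop("fraction activities must be positive", call. = FALSE)
  if (is.unsorted(time_h))
    stop("fraction times must be non-decreasing", call. = FALSE)
  structure(data.frame(activity_mbq = activity_mbq, time_h = time_h),
            class = c("schedule", "data.frame"))
}

#' Total absorbed dose for a treatment schedule
#'
#' Doses add linearly across fractions: each fraction contributes
#' `coefficient (Gy/MBq) * fraction activity (MBq)`, and the schedule total
#' is their plain sum.  No dose-rate, repair or radiobiological (BED/EQD2)
#' modelling is applied — administration times do not change the total, only
#' document the arm.  Per-fraction doses are conventionally quoted at 0.1 Gy
#' precision.
#'
#' @param report A [absorbed_dose()] report, or a single numeric dose
#'   coefficient in Gy/MBq (for desk calculations from published values).
#' @param sched A [schedule()]; an empty schedule gives 0 Gy.
#' @param target Target organ when `report` is a dose report.
#' @return List of class `schedule_dose`: per-fraction doses (`fraction_gy`)
#'   and their sum (`total_gy`), both in Gy.
#' @examples
#' schedule_dose(1.68, schedule(c(9.25, 9.25), c(0, 240)))$total_gy
#' @export
schedule_dose <- function(report, sched, target = "tumor") {
  coef <- if (inherits(report, "dose_report"))
    dose_coefficient(report, target) else as.numeric(report)
  stopifnot(length(coef) == 1L, is.finite(coef), coef >= 0)
  if (is.null(sched) || nrow(sched) == 0L) {
    fr <- numeric(0)
  } else {
    stopifnot(inherits(sched, "schedule"))
    fr <- coef * sched$activity_mbq
  }
  structure(list(fraction_gy = fr, total_gy = sum(fr),
                 coefficient_gy_per_mbq = coef),
            class = "schedule_dose")
}

#' @export
print.schedule_dose <- function(x, ...) {
  cat(sprintf("<schedule_dose> coefficient %.2f Gy/MBq\n",
              x$coefficient_gy_per_mbq))
  if (length(x$fraction_gy))
    cat("  fractions:", paste(sprintf("%.1f", x$fraction_gy), collapse = " + "),
        "Gy\n")
  cat(sprintf("  total: %.1f Gy\n", x$total_gy))
  invisible(x)
}
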