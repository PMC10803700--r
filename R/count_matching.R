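#' Expected counts from an exponentially decaying source
#'
#' Integral of `exp(-lambda t)` over the acquisition window, in units of
#' initial activity A0 = 1:
#' `(exp(-lambda start) - exp(-lambda (start + duration))) / lambda`.
#'
#' @param start_min acquisition start, minutes after the reference time.
#' @param duration_min acquisition duration, minutes (> 0).
#' @param lambda_per_min decay constant, 1/min (> 0); default F-18.
#' @return relative expected counts.
#' @export
expected_counts <- function(start_min, duration_min,
                            lambda_per_min = log(2) / F18_HALF_LIFE_MIN) {
  if (lambda_per_min <= 0) stop("lambda must be > 0", call. = FALSE)
  if (duration_min <= 0) stop("duration must be > 0", call. = FALSE)
  (exp(-lambda_per_min * start_min) -
     exp(-lambda_per_min * (start_min + duration_min))) / lambda_per_min
}

#' Solve the second acquisition's duration for count matching
#'
#' Finds the duration t2 such that an acquisition starting `delay_min`
#' after the first collects the same expected counts as the first
#' acquisition of duration `t1_min`, compensating the radioactive decay
#' over the inter-exam delay. Closed form:
#' `t2 = -log(1 - exp(lambda delay) (1 - exp(-lambda t1))) / lambda`.
#'
#' @param t1_min duration of the first acquisition, minutes.
#' @param delay_min delay between the start of the two acquisitions,
#'   minutes (>= 0).
#' @param lambda_per_min decay constant, 1/min; default F-18.
#' @return duration t2 in minutes.
#' @export
solve_duration <- function(t1_min, delay_min,
                           lambda_per_min = log(2) / F18_HALF_LIFE_MIN) {
  if (lambda_per_min <= 0) stop("lambda must be > 0", call. = FALSE)
  if (t1_min <= 0) stop("t1 must be > 0", call. = FALSE)
  if (delay_min < 0) stop("delay must be >= 0", call. = FALSE)
  target <- exp(lambda_per_min * delay_min) * (1 - exp(-lambda_per_min * t1_min))
  if (target >= 1) {
    max_frac <- 1 / (exp(lambda_per_min * delay_min) *
                       (1 - exp(-lambda_per_min * t1_min)))
    stop(sprintf(paste0("count matching infeasible: decay too deep; at most ",
                        "%.1f%% of the first exam's counts are attainable"),
                 100 * max_frac), call. = FALSE)
  }
  -log(1 - target) / lambda_per_min
}

#' Acquisition plan for a count-matched scan-rescan pair
#'
#' @param t1_min duration of exam 1, minutes.
#' @param delay_min inter-exam delay, minutes.
#' @param half_life_min isotope half-life, minutes; default F-18.
#' @return an `acquisition_plan` with the solved exam-2 duration.
#' @export
acquisition_plan <- function(t1_min, delay_min,
                             half_life_min = F18_HALF_LIFE_MIN) {
  lam <- log(2) / half_life_min
  t2 <- solve_duration(t1_min, delay_min, lam)
  structure(list(t1_min = t1_min, delay_min = delay_min,
                 lambda_per_min = lam, t2_min = t2),
            class = "acquisition_plan")
}

#' @export
print.acquisition_plan <- function(x, ...) {
  cat(sprintf("<acquisition_plan> t1 = %.4g min, delay = %.4g min -> t2 = %.4f min\n",
              x$t1_min, x$delay_min, x$t2_min))
  invisible(x)
}
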