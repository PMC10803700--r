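#' F-18 half-life in minutes
#' @export
F18_HALF_LIFE_MIN <- 109.77

#' Scan acquisition metadata
#'
#' Injection and acquisition parameters for one PET exam; drives
#' radioactive-decay factors, count levels and SUV normalization.
#' The uptake time is stored as minutes between injection and scan start.
#'
#' @param injected_activity_MBq injected activity at injection time, MBq.
#' @param uptake_min minutes between injection and scan start (>= 0).
#' @param duration_min acquisition duration per bed position, minutes.
#' @param weight_kg patient (or phantom) weight, kg.
#' @param half_life_min isotope half-life in minutes; default F-18.
#' @return an object of class `scan_meta`.
#' @export
scan_meta <- function(injected_activity_MBq, uptake_min = 60,
                      duration_min = 2, weight_kg = 70,
                      half_life_min = F18_HALF_LIFE_MIN) {
  if (injected_activity_MBq <= 0) stop("injected activity must be > 0", call. = FALSE)
  if (uptake_min < 0) stop("scan start cannot precede injection", call. = FALSE)
  if (duration_min <= 0) stop("duration must be > 0", call. = FALSE)
  if (weight_kg <= 0) stop("weight must be > 0", call. = FALSE)
  if (half_life_min <= 0) stop("half-life must be > 0", call. = FALSE)
  structure(list(injected_activity_MBq = injected_activity_MBq,
                 uptake_min = uptake_min, duration_min = duration_min,
                 weight_kg = weight_kg, half_life_min = half_life_min),
            class = "scan_meta")
}

#' @export
print.scan_meta <- function(x, ...) {
  cat(sprintf("<scan_meta> %.1f MBq, uptake %.1f min, %.2f min/bed, %.1f kg, T1/2 %.2f min\n",
              x$injected_activity_MBq, x$uptake_min, x$duration_min,
              x$weight_kg, x$half_life_min))
  invisible(x)
}

#' Radioactive decay factor after a given time
#' @param t_min elapsed time in minutes.
#' @param half_life_min isotope half-life, minutes.
#' @return `2^(-t/half_life)`.
#' @export
decay_factor <- function(t_min, half_life_min = F18_HALF_LIFE_MIN) {
  if (half_life_min <= 0) stop("half-life must be > 0", call. = FALSE)
  2^(-t_min / half_life_min)
}

#' Injected activity decay-corrected to scan start
#' @param meta a `scan_meta`.
#' @return activity remaining at scan start, MBq.
#' @export
activity_at_scan_MBq <- function(meta) {
  meta$injected_activity_MBq * decay_factor(meta$uptake_min, meta$half_life_min)
}
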