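#' PET system imaging model
#'
#' Abstract imaging contract for one PET system: reconstructed voxel grid,
#' effective point-spread function, time-of-flight capability and relative
#' count sensitivity. Two constructors mirror the study configuration: a
#' BGO, non-TOF system reconstructing on a 2.34 x 2.34 x 3.26 mm grid and a
#' LYSO, TOF-capable digital system on a 2.34 x 2.34 x 2.8 mm grid. The
#' TOF signal-to-noise advantage is encoded as a sensitivity multiplier
#' (default 2x), a free parameter of the simulator, not a measured value.
#'
#' @param name system label.
#' @param voxel_mm length-3 reconstructed voxel dimensions, mm.
#' @param psf_fwhm_mm scalar or length-3 effective PSF FWHM, mm.
#' @param tof logical, time-of-flight capable.
#' @param sensitivity relative count sensitivity (counts per kBq-second per
#'   mL scale factor); drives the Poisson noise level.
#' @return an object of class `system_model`.
#' @export
system_model <- function(name, voxel_mm, psf_fwhm_mm, tof = FALSE,
                         sensitivity = 3e-4) {
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) != 3L || any(voxel_mm <= 0))
    stop("voxel_mm must be 3 positive values", call. = FALSE)
  psf_fwhm_mm <- as.numeric(psf_fwhm_mm)
  if (any(psf_fwhm_mm <= 0)) stop("psf_fwhm_mm must be > 0", call. = FALSE)
  if (sensitivity <= 0) stop("sensitivity must be > 0", call. = FALSE)
  structure(list(name = as.character(name), voxel_mm = voxel_mm,
                 psf_fwhm_mm = psf_fwhm_mm, tof = isTRUE(tof),
                 sensitivity = sensitivity),
            class = "system_model")
}

#' @rdname system_model
#' @export
diq_like <- function(psf_fwhm_mm = 5.0, sensitivity = 3e-4)
  system_model("DIQ-like", c(2.34, 2.34, 3.26), psf_fwhm_mm,
               tof = FALSE, sensitivity = sensitivity)

#' @rdname system_model
#' @param tof_gain sensitivity multiplier standing in for the TOF
#'   signal-to-noise advantage.
#' @export
dmi_like <- function(psf_fwhm_mm = 4.0, sensitivity = 3e-4, tof_gain = 2.0)
  system_model("DMI-like", c(2.34, 2.34, 2.8), psf_fwhm_mm,
               tof = TRUE, sensitivity = sensitivity * tof_gain)

#' @export
print.system_model <- function(x, ...) {
  cat(sprintf("<system_model> %s: voxel %.2f x %.2f x %.2f mm, PSF %s mm, %s, sens %.4g\n",
              x$name, x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3],
              paste(format(x$psf_fwhm_mm), collapse = " x "),
              if (x$tof) "TOF" else "non-TOF", x$sensitivity))
  invisible(x)
}
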