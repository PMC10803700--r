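#' Convert an activity-concentration volume to SUV
#'
#' Body-weight SUV: `SUV = AC (kBq/mL) x weight (kg) / injected activity
#' decay-corrected to scan start (MBq)`. The map is linear and voxelwise.
#'
#' @param vol a `volume3d` of AC in kBq/mL.
#' @param meta a `scan_meta` with injected activity, uptake time, weight.
#' @return a `volume3d` whose voxels are dimensionless SUV (g/mL).
#' @export
ac_to_suv <- function(vol, meta) {
  if (!inherits(meta, "scan_meta")) stop("meta must be a scan_meta", call. = FALSE)
  act <- activity_at_scan_MBq(meta)
  if (act <= 0) stop("decayed injected activity must be > 0", call. = FALSE)
  out <- vol
  out$data <- vol$data * meta$weight_kg / act
  out
}

#' Extract SUVmax, SUVmean and SUVpeak for one lesion
#'
#' All three metrics are measured in a spherical search region of diameter
#' `diameter + 2 x margin_mm` centred on the lesion:
#' \itemize{
#'   \item SUVmax: maximum voxel value in the search region;
#'   \item SUVmean: mean over voxels at or above 50\% of SUVmax (a standard
#'     isocontour VOI) within the region;
#'   \item SUVpeak: the largest mean over a 1 cm^3 sphere (radius
#'     6.2035 mm, voxel-centre inclusion) positioned at any voxel centre of
#'     the search region.
#' }
#'
#' @param vol a `volume3d` in SUV (or AC; the metrics are unit-agnostic).
#' @param spec a `lesion_spec` giving centre and diameter.
#' @param margin_mm search margin added around the lesion radius; default
#'   8 mm (about twice a clinical PSF FWHM).
#' @param isocontour fraction of SUVmax defining the SUVmean VOI.
#' @param peak_volume_cm3 volume of the peak sphere; default 1 cm^3.
#' @return list with `suv_max`, `suv_mean`, `suv_peak`.
#' @export
extract_suv <- function(vol, spec, margin_mm = 8, isocontour = 0.5,
                        peak_volume_cm3 = 1.0) {
  search_r <- spec$diameter_mm / 2 + margin_mm
  idx <- sphere_voxel_indices(vol, spec$centre_mm, search_r)
  if (is.null(idx))
    stop("lesion search region extends outside the volume", call. = FALSE)
  if (!length(idx))
    stop("lesion search region contains no voxels", call. = FALSE)
  vals <- vol$data[idx]
  suv_max <- max(vals)
  iso <- vals[vals >= isocontour * suv_max]
  if (!length(iso)) stop("empty isocontour: degenerate lesion", call. = FALSE)
  suv_mean <- mean(iso)

  # SUVpeak: mean over a fixed sphere, maximized over candidate centres
  peak_r <- voi_radius_mm(peak_volume_cm3)
  d <- dim(vol$data)
  co <- axis_coords(vol)
  # voxel offsets (in index steps) whose centres fall within the peak sphere
  noff <- ceiling(peak_r / vol$spacing)
  og <- expand.grid(i = -noff[1]:noff[1], j = -noff[2]:noff[2],
                    k = -noff[3]:noff[3])
  keep <- (og$i * vol$spacing[1])^2 + (og$j * vol$spacing[2])^2 +
    (og$k * vol$spacing[3])^2 <= peak_r^2
  og <- og[keep, , drop = FALSE]
  # candidate centres: voxel centres within the search region
  kk <- (idx - 1L) %/% (d[1] * d[2])
  rem <- (idx - 1L) %% (d[1] * d[2])
  jj <- rem %/% d[1]
  ii <- rem %% d[1]
  suv_peak <- -Inf
  for (m in seq_along(idx)) {
    ci <- ii[m] + 1L + og$i; cj <- jj[m] + 1L + og$j; ck <- kk[m] + 1L + og$k
    ok <- ci >= 1L & ci <= d[1] & cj >= 1L & cj <= d[2] & ck >= 1L & ck <= d[3]
    lin <- (ck[ok] - 1L) * d[1] * d[2] + (cj[ok] - 1L) * d[1] + ci[ok]
    v <- mean(vol$data[lin])
    if (v > suv_peak) suv_peak <- v
  }
  list(suv_max = suv_max, suv_mean = suv_mean, suv_peak = suv_peak)
}

#' Signed relative difference between two systems' SUV values (percent)
#'
#' `RD = (SUV_dmi - SUV_diq) / SUV_diq x 100`, referenced to the first
#' (DIQ-like) system. Note the asymmetry: RD(a, b) != -RD(b, a).
#'
#' @param suv_diq SUV on the reference system (> 0).
#' @param suv_dmi SUV on the comparison system.
#' @return signed percentage.
#' @export
relative_difference <- function(suv_diq, suv_dmi) {
  if (any(suv_diq == 0))
    stop("reference SUV is zero: relative difference undefined", call. = FALSE)
  (suv_dmi - suv_diq) / suv_diq * 100
}

#' Summarize a relative-difference distribution
#'
#' Mean, sample SD (n - 1 denominator), median, min and max of the RD
#' values for lesions quantified on both systems. With a single lesion the
#' SD is reported as 0 and flagged degenerate.
#'
#' @param suv_diq,suv_dmi numeric vectors of paired SUV values (same
#'   length, one entry per lesion detected on both systems).
#' @return an `rd_summary` list: n, mean, sd, median, min, max, rd
#'   (the per-lesion values), degenerate flag.
#' @export
summarize_rd <- function(suv_diq, suv_dmi) {
  if (length(suv_diq) != length(suv_dmi))
    stop("paired SUV vectors must have equal length", call. = FALSE)
  if (!length(suv_diq)) stop("no lesions to summarize", call. = FALSE)
  rd <- relative_difference(suv_diq, suv_dmi)
  degenerate <- length(rd) < 2L
  structure(list(n = length(rd), mean = mean(rd),
                 sd = if (degenerate) 0 else stats::sd(rd),
                 median = stats::median(rd), min = min(rd), max = max(rd),
                 rd = rd, degenerate = degenerate),
            class = "rd_summary")
}

#' @export
print.rd_summary <- function(x, ...) {
  cat(sprintf("<rd_summary> n=%d: RD %.1f +/- %.1f %%, median %.1f [%.1f; %.1f]%s\n",
              x$n, x$mean, x$sd, x$median, x$min, x$max,
              if (x$degenerate) " (single lesion: SD degenerate)" else ""))
  invisible(x)
}
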