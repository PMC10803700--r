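#' Phantom specification
#'
#' A configurable compartment phantom standing in for patient exams: a
#' global background plus box/ellipsoid compartments at distinct activity
#' concentrations (torso, lungs, liver, mediastinum), with optional
#' embedded "natural" lesions. Compartment ACs default to values placing
#' lesion ACs (at the study's contrast range) across the few-to-tens
#' kBq/mL range typical of FDG exams.
#'
#' @param shape length-3 integer grid shape in voxels.
#' @param spacing_mm length-3 voxel spacing, mm.
#' @param compartments list of compartments, each a list with fields
#'   `label`, `type` ("box" or "ellipsoid"), `centre_mm`, `half_size_mm`
#'   (half extents / semi-axes, mm), `ac` (kBq/mL, >= 0).
#' @param lesions list of `lesion_spec` embedded as natural lesions.
#' @param background_ac global background AC outside all compartments.
#' @param seed RNG seed recorded with the spec.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 40L),
                         spacing_mm = c(2.34, 2.34, 3.26),
                         compartments = list(), lesions = list(),
                         background_ac = 0.2, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L))
    stop("shape must be 3 integers >= 4", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing must be positive on every axis", call. = FALSE)
  if (background_ac < 0) stop("AC values must be >= 0", call. = FALSE)
  extent <- (shape - 1) * spacing_mm
  lo <- -extent / 2; hi <- extent / 2
  for (cp in compartments) {
    if (!all(c("label", "type", "centre_mm", "half_size_mm", "ac") %in% names(cp)))
      stop("compartment missing fields", call. = FALSE)
    if (cp$ac < 0) stop("AC values must be >= 0", call. = FALSE)
    if (any(cp$centre_mm - cp$half_size_mm < lo) ||
        any(cp$centre_mm + cp$half_size_mm > hi))
      stop(sprintf("compartment '%s' extends outside the grid", cp$label),
           call. = FALSE)
  }
  structure(list(shape = shape, spacing_mm = spacing_mm,
                 compartments = compartments, lesions = lesions,
                 background_ac = background_ac, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' A torso-like default phantom
#'
#' Torso ellipsoid at soft-tissue AC, two low-AC lung boxes, a high-AC
#' liver box and a mediastinal box, sized to fit the default grid.
#'
#' @param shape,spacing_mm grid geometry, as in [phantom_spec()].
#' @param seed RNG seed recorded with the spec.
#' @return a `phantom_spec`.
#' @export
default_phantom_spec <- function(shape = c(64L, 64L, 40L),
                                 spacing_mm = c(2.34, 2.34, 3.26),
                                 seed = 1L) {
  extent <- (shape - 1) * spacing_mm
  torso <- list(label = "torso", type = "ellipsoid", centre_mm = c(0, 0, 0),
                half_size_mm = extent / 2 * 0.92, ac = 1.5)
  lungL <- list(label = "lung_left", type = "ellipsoid",
                centre_mm = c(-extent[1] * 0.18, -extent[2] * 0.08, extent[3] * 0.12),
                half_size_mm = extent * c(0.12, 0.14, 0.18), ac = 0.4)
  lungR <- list(label = "lung_right", type = "ellipsoid",
                centre_mm = c(extent[1] * 0.18, -extent[2] * 0.08, extent[3] * 0.12),
                half_size_mm = extent * c(0.12, 0.14, 0.18), ac = 0.4)
  liver <- list(label = "liver", type = "box",
                centre_mm = c(extent[1] * 0.15, extent[2] * 0.10, -extent[3] * 0.15),
                half_size_mm = extent * c(0.20, 0.17, 0.16), ac = 4.0)
  medias <- list(label = "mediastinum", type = "box",
                 centre_mm = c(-extent[1] * 0.05, extent[2] * 0.14, extent[3] * 0.16),
                 half_size_mm = extent * c(0.13, 0.13, 0.16), ac = 2.0)
  phantom_spec(shape, spacing_mm,
               compartments = list(torso, lungL, lungR, liver, medias),
               lesions = list(), background_ac = 0.05, seed = seed)
}

# paint compartments over the background, last-wins
paint_compartments <- function(spec) {
  a <- array(spec$background_ac, dim = spec$shape)
  vol <- volume3d(a, spec$spacing_mm)
  co <- axis_coords(vol)
  for (cp in spec$compartments) {
    dx <- (co[[1]] - cp$centre_mm[1]) / cp$half_size_mm[1]
    dy <- (co[[2]] - cp$centre_mm[2]) / cp$half_size_mm[2]
    dz <- (co[[3]] - cp$centre_mm[3]) / cp$half_size_mm[3]
    if (cp$type == "box") {
      mask <- outer(outer(abs(dx) <= 1, abs(dy) <= 1, "&"), abs(dz) <= 1, "&")
    } else if (cp$type == "ellipsoid") {
      mask <- outer(outer(dx^2, dy^2, "+"), dz^2, "+") <= 1
    } else stop("unknown compartment type: ", cp$type, call. = FALSE)
    vol$data[mask] <- cp$ac
  }
  vol
}

#' Generate a noiseless phantom exam for one system
#'
#' Paints the compartment ACs, inserts the spec's embedded natural lesions
#' (unblurred deltas, backgrounds frozen on the painted volume), then
#' blurs the whole volume with the system PSF. Deterministic given the
#' spec.
#'
#' @param spec a `phantom_spec`.
#' @param system a `system_model`.
#' @param meta a `scan_meta` (carried for downstream noise/SUV steps).
#' @return a noiseless `volume3d` of AC in kBq/mL.
#' @export
generate_phantom <- function(spec, system, meta = NULL) {
  vol <- paint_compartments(spec)
  if (length(spec$lesions)) {
    bgs <- vapply(spec$lesions, function(l)
      measure_background_ac(vol, l$centre_mm), numeric(1))
    for (i in seq_along(spec$lesions)) {
      l <- spec$lesions[[i]]
      lesion_ac <- contrast_to_ac(bgs[i], l$contrast)
      ras <- rasterize_sphere(vol, l$centre_mm, l$diameter_mm)
      vol$data[ras$index] <- vol$data[ras$index] +
        (lesion_ac - bgs[i]) * ras$fraction
    }
  }
  psf_blur(vol, system$psf_fwhm_mm)
}

#' Add Poisson acquisition noise to a volume
#'
#' Converts AC to expected counts per voxel (AC x voxel volume x duration
#' x system sensitivity x decay factor at scan start), draws one Poisson
#' realization and converts back to AC. Reproducible under a fixed seed.
#'
#' @param vol a non-negative `volume3d`.
#' @param system a `system_model`.
#' @param meta a `scan_meta`.
#' @param seed integer RNG seed.
#' @return a noisy `volume3d` in kBq/mL.
#' @export
add_acquisition_noise <- function(vol, system, meta, seed = 1L) {
  if (any(!is.finite(vol$data)))
    stop("volume contains non-finite voxels", call. = FALSE)
  if (any(vol$data < 0))
    stop("volume must be non-negative", call. = FALSE)
  decay <- decay_factor(meta$uptake_min, meta$half_life_min)
  # counts per (kBq/mL) of AC: 1000 decays/s/mL x voxel mL x seconds x sens
  factor <- 1000 * (voxel_volume_mm3(vol) / 1000) *
    (meta$duration_min * 60) * system$sensitivity * decay
  mu <- vol$data * factor
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  counts <- stats::rpois(length(mu), lambda = as.numeric(mu))
  out <- vol
  out$data <- array(counts / factor, dim = dim(vol$data))
  out
}

#' Generate a count-matched scan-rescan phantom pair
#'
#' Exam 1 on `system1`, exam 2 on `system2` after `delay_min` of decay:
#' the second noiseless volume is the first phantom's AC decayed by
#' `2^(-delay/half-life)` and resampled to the second system's grid, its
#' duration extended by [solve_duration()] so expected counts match, and
#' independent Poisson noise added to both.
#'
#' @param spec a `phantom_spec`.
#' @param system1,system2 `system_model` for the first and second exam.
#' @param meta1 `scan_meta` for exam 1.
#' @param delay_min inter-exam delay in minutes (default 25).
#' @param seed integer root seed; exam noise uses seed and seed + 1.
#' @param noise add Poisson noise (default TRUE).
#' @return list with `vol1`, `vol2`, `meta2` (exam-2 metadata with updated
#'   uptake time and solved duration) and `plan` (the `acquisition_plan`).
#' @export
generate_paired_exams <- function(spec, system1, system2, meta1,
                                  delay_min = 25, seed = 1L, noise = TRUE) {
  if (delay_min < 0) stop("delay must be >= 0", call. = FALSE)
  lam <- log(2) / meta1$half_life_min
  plan <- acquisition_plan(meta1$duration_min, delay_min, meta1$half_life_min)
  clean1 <- generate_phantom(spec, system1, meta1)
  clean2_native <- generate_phantom(spec, system2, meta1)
  dec <- decay_factor(delay_min, meta1$half_life_min)
  clean2_native$data <- clean2_native$data * dec
  clean2 <- if (all(system2$voxel_mm == spec$spacing_mm)) clean2_native
            else resample_volume(clean2_native, system2$voxel_mm)
  meta2 <- scan_meta(meta1$injected_activity_MBq,
                     uptake_min = meta1$uptake_min + delay_min,
                     duration_min = plan$t2_min,
                     weight_kg = meta1$weight_kg,
                     half_life_min = meta1$half_life_min)
  if (noise) {
    # decay to scan start is already painted into the volumes (uptake decay
    # is shared; the inter-exam decay was applied above), so the count
    # conversion uses a common reference decay
    vol1 <- add_acquisition_noise(clean1, system1,
                                  meta_at_reference(meta1), seed = seed)
    vol2 <- add_acquisition_noise(clean2, system2,
                                  meta_at_reference(meta2), seed = seed + 1L)
  } else {
    vol1 <- clean1; vol2 <- clean2
  }
  list(vol1 = vol1, vol2 = vol2, meta1 = meta1, meta2 = meta2, plan = plan)
}

# meta with the uptake decay factor neutralized: the volume's AC already
# reflects activity at scan start, so counts must not be decayed twice
meta_at_reference <- function(meta) {
  m <- meta; m$uptake_min <- 0; m
}

#' Draw a random synthetic-lesion set for a phantom
#'
#' Diameters uniform in [5, 11] mm and contrasts uniform in [2, 14] (the
#' study's design ranges); centres placed inside a chosen compartment
#' with full VOI support. Candidate centres whose measurement
#' neighbourhood (lesion plus background shell) crosses a compartment
#' boundary are rejected and redrawn, so every lesion sits on a locally
#' homogeneous background, mimicking the study's placement "at relevant
#' anatomical locations" away from organ interfaces.
#'
#' @param spec a `phantom_spec`.
#' @param n number of lesions.
#' @param labels anatomical labels to cycle through; each maps to the
#'   compartment of the same name when present, else the torso.
#' @param seed integer RNG seed.
#' @param max_tries rejection-sampling attempts per lesion.
#' @return list of `lesion_spec`.
#' @export
sample_lesions <- function(spec, n, labels = c("liver", "mediastinum", "other"),
                           seed = 1L, max_tries = 60L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  painted <- paint_compartments(spec)
  comp_names <- vapply(spec$compartments, `[[`, "", "label")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- labels[(i - 1L) %% length(labels) + 1L]
    target <- if (lab %in% comp_names) lab else "torso"
    cp <- spec$compartments[[match(target, comp_names)]]
    # keep the lesion + VOI and the reader's background shell inside
    margin <- pmax(pmin(cp$half_size_mm * 0.7, cp$half_size_mm - 12), 0)
    centre <- cp$centre_mm
    for (try in seq_len(max_tries)) {
      cand <- cp$centre_mm + stats::runif(3, -1, 1) * margin
      nb <- sphere_voxel_indices_clipped(painted, cand, 17)
      if (length(nb) && diff(range(painted$data[nb])) == 0 &&
          painted$data[nb][1] == cp$ac) {
        centre <- cand
        break
      }
    }
    lbl <- if (lab %in% .lesion_labels) lab else "other"
    out[[i]] <- lesion_spec(sprintf("S%03d", i), centre,
                            diameter_mm = stats::runif(1, 5, 11),
                            contrast = stats::runif(1, 2, 14),
                            label = lbl, provenance = "synthetic")
  }
  out
}
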