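#' Write a volume to NIfTI-1 with a JSON metadata sidecar
#'
#' The affine encodes the axis-aligned RAS+ grid (spacing on the diagonal,
#' voxel (0,0,0) centre at the origin). Scan metadata, when supplied, is
#' written next to the image as `<stem>.json`.
#'
#' @param vol a `volume3d`.
#' @param path output path ending in `.nii` (uncompressed) or `.nii.gz`.
#' @param meta optional `scan_meta` written as a JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, meta = NULL) {
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  img <- RNifti::asNifti(vol$data)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  if (!is.null(meta)) {
    jsonlite::write_json(unclass(meta), sidecar_path(path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Read a NIfTI volume (and its sidecar) into a `volume3d`
#'
#' Requires an axis-aligned affine (diagonal direction matrix); voxel
#' values are taken as AC in kBq/mL. When the JSON sidecar is missing or
#' lacks the fields needed for SUV conversion, the volume is returned
#' with `meta = NULL` and a `degraded` flag instead of an error.
#'
#' @param path NIfTI file path.
#' @return list with `volume` (a `volume3d`), `meta` (`scan_meta` or
#'   NULL) and `degraded` (TRUE when SUV conversion is impossible).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-6)
    stop("non-axis-aligned affine: rotated grids are not supported",
         call. = FALSE)
  spacing <- abs(diag(rot))
  vol <- volume3d(array(as.numeric(img), dim = dim(img)),
                  spacing = spacing, origin = aff[1:3, 4])
  sc <- sidecar_path(path)
  meta <- NULL; degraded <- TRUE
  if (file.exists(sc)) {
    raw <- jsonlite::fromJSON(sc)
    need <- c("injected_activity_MBq", "uptake_min", "duration_min",
              "weight_kg")
    if (all(need %in% names(raw))) {
      hl <- if ("half_life_min" %in% names(raw)) raw$half_life_min
            else F18_HALF_LIFE_MIN
      meta <- scan_meta(raw$injected_activity_MBq, raw$uptake_min,
                        raw$duration_min, raw$weight_kg, hl)
      degraded <- FALSE
    }
  }
  list(volume = vol, meta = meta, degraded = degraded)
}

#' Read a phantom specification from YAML or JSON
#'
#' Top-level fields mirror [phantom_spec()]: shape, spacing_mm,
#' background_ac, seed, compartments (list with label/type/centre_mm/
#' half_size_mm/ac) and lesions (manifest-style records).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `phantom_spec`.
#' @export
read_phantom_spec <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lesions <- lapply(raw$lesions, function(l)
    lesion_spec(l$id, c(l$x_mm, l$y_mm, l$z_mm), l$diameter_mm, l$contrast,
                if (is.null(l$label)) "other" else l$label,
                if (is.null(l$provenance)) "natural" else l$provenance))
  comps <- lapply(raw$compartments, function(cp)
    list(label = cp$label, type = cp$type,
         centre_mm = as.numeric(cp$centre_mm),
         half_size_mm = as.numeric(cp$half_size_mm), ac = cp$ac))
  phantom_spec(shape = raw$shape, spacing_mm = raw$spacing_mm,
               compartments = comps, lesions = lesions,
               background_ac = if (is.null(raw$background_ac)) 0
               else raw$background_ac,
               seed = if (is.null(raw$seed)) 1L else raw$seed)
}

#' Write an evaluation report as JSON
#'
#' Serializes the output of [evaluate_reading()] (detection rates, RTPR
#' with CI and method, per-metric RD summaries) in the layout of the
#' study's results tables.
#'
#' @param eval result of [evaluate_reading()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(eval, path) {
  rd <- lapply(eval$rd, function(s) if (is.null(s)) NULL else
    list(n = s$n, mean = s$mean, sd = s$sd, median = s$median,
         min = s$min, max = s$max))
  out <- list(
    detection = list(
      reference = eval$rates$reference,
      comparison = eval$rates$comparison),
    rtpr = list(ratio = eval$rtpr$ratio, ci = eval$rtpr$ci,
                n = eval$rtpr$n, method = eval$rtpr$method),
    relative_differences = rd)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
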