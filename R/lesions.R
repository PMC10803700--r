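.lesion_labels <- c("lungs", "bone", "liver", "mediastinum",
                    "retroperitoneal", "lymph_node", "other")

#' Synthetic (or natural) lesion specification
#'
#' One spherical lesion defined in world coordinates: centre, diameter and
#' the contrast that sets its activity concentration relative to the local
#' background. Diameters outside [5, 11] mm or contrasts outside [2, 14]
#' (the ranges exercised in the study design) trigger a warning but are
#' accepted; contrast must exceed -1 so lesion AC stays non-negative.
#'
#' @param id lesion identifier (string).
#' @param centre_mm length-3 world coordinate of the sphere centre, mm.
#' @param diameter_mm sphere diameter, mm (> 0).
#' @param contrast dimensionless contrast, (AC_lesion - AC_bg)/AC_bg; > -1.
#' @param label anatomical label, one of lungs, bone, liver, mediastinum,
#'   retroperitoneal, lymph_node, other.
#' @param provenance "synthetic" or "natural".
#' @return an object of class `lesion_spec`.
#' @export
lesion_spec <- function(id, centre_mm, diameter_mm, contrast,
                        label = "other", provenance = "synthetic") {
  centre_mm <- as.numeric(centre_mm)
  if (length(centre_mm) != 3L || any(!is.finite(centre_mm)))
    stop("centre_mm must be 3 finite values", call. = FALSE)
  if (!is.finite(diameter_mm) || diameter_mm <= 0)
    stop("diameter must be > 0", call. = FALSE)
  if (!is.finite(contrast) || contrast <= -1)
    stop("contrast must be > -1 (lesion AC must be >= 0)", call. = FALSE)
  label <- match.arg(label, .lesion_labels)
  provenance <- match.arg(provenance, c("synthetic", "natural"))
  if (diameter_mm < 5 || diameter_mm > 11)
    warning(sprintf("lesion %s: diameter %.2f mm outside the recommended [5, 11] mm range",
                    id, diameter_mm), call. = FALSE)
  if (contrast < 2 || contrast > 14)
    warning(sprintf("lesion %s: contrast %.2f outside the recommended [2, 14] range",
                    id, contrast), call. = FALSE)
  structure(list(id = as.character(id), centre_mm = centre_mm,
                 diameter_mm = diameter_mm, contrast = contrast,
                 label = label, provenance = provenance),
            class = "lesion_spec")
}

#' @export
print.lesion_spec <- function(x, ...) {
  cat(sprintf("<lesion_spec> %s [%s/%s]: d=%.1f mm, contrast %.2f at (%.1f, %.1f, %.1f) mm\n",
              x$id, x$label, x$provenance, x$diameter_mm, x$contrast,
              x$centre_mm[1], x$centre_mm[2], x$centre_mm[3]))
  invisible(x)
}

#' Analytic sphere volume for a lesion diameter
#' @param diameter_mm sphere diameter, mm.
#' @return volume in mm^3, `(pi/6) d^3`.
#' @export
sphere_volume_mm3 <- function(diameter_mm) pi / 6 * diameter_mm^3

#' Read a lesion manifest (CSV or JSON)
#'
#' Columns/fields: id, x_mm, y_mm, z_mm, diameter_mm, contrast, label,
#' provenance. Range violations warn (never error) via [lesion_spec()].
#'
#' @param path file path ending in .csv or .json.
#' @return list of `lesion_spec`.
#' @export
read_lesion_manifest <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  needed <- c("id", "x_mm", "y_mm", "z_mm", "diameter_mm", "contrast")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("lesion manifest missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"label" %in% names(df)) df$label <- "other"
  if (!"provenance" %in% names(df)) df$provenance <- "synthetic"
  lapply(seq_len(nrow(df)), function(i)
    lesion_spec(df$id[i], c(df$x_mm[i], df$y_mm[i], df$z_mm[i]),
                df$diameter_mm[i], df$contrast[i], df$label[i],
                df$provenance[i]))
}

#' Write a lesion manifest to CSV
#' @param lesions list of `lesion_spec`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_lesion_manifest <- function(lesions, path) {
  df <- do.call(rbind, lapply(lesions, function(l)
    data.frame(id = l$id, x_mm = l$centre_mm[1], y_mm = l$centre_mm[2],
               z_mm = l$centre_mm[3], diameter_mm = l$diameter_mm,
               contrast = l$contrast, label = l$label,
               provenance = l$provenance)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
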