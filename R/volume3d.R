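#' 3-D activity-concentration volume
#'
#' A `volume3d` wraps a 3-D numeric array of activity concentrations
#' (kBq/mL) together with its physical geometry: voxel spacing in mm per
#' axis and the world-mm coordinate of the centre of the first voxel
#' (RAS+ convention, axis-aligned grid, no rotation).
#'
#' Voxel indices are 0-based in the world mapping, so that
#' `world = origin + index * spacing`; the R array itself is 1-based as
#' usual and the conversion helpers account for the offset.
#'
#' @param data 3-D numeric array of activity concentrations (kBq/mL).
#' @param spacing numeric length-3, voxel spacing in mm; all > 0.
#' @param origin numeric length-3, world-mm centre of voxel (1,1,1).
#'   Default places the grid centre at the world origin.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing, origin = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)", call. = FALSE)
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * spacing
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm; AC range [%.4g, %.4g] kBq/mL\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Voxel volume in mm^3
#' @param vol a `volume3d`.
#' @return scalar voxel volume (mm^3).
#' @export
voxel_volume_mm3 <- function(vol) prod(vol$spacing)

#' Convert world-mm coordinates to (continuous, 0-based) voxel indices
#' @param vol a `volume3d`.
#' @param xyz numeric length-3 world coordinate, or an n x 3 matrix.
#' @return continuous 0-based voxel indices, same shape as `xyz`.
#' @export
world_to_voxel <- function(vol, xyz) {
  if (is.matrix(xyz))
    sweep(sweep(xyz, 2, vol$origin, "-"), 2, vol$spacing, "/")
  else (as.numeric(xyz) - vol$origin) / vol$spacing
}

#' Convert (0-based) voxel indices to world-mm coordinates
#' @param vol a `volume3d`.
#' @param ijk numeric length-3 0-based voxel index, or an n x 3 matrix.
#' @return world coordinates in mm.
#' @export
voxel_to_world <- function(vol, ijk) {
  if (is.matrix(ijk))
    sweep(sweep(ijk, 2, vol$spacing, "*"), 2, vol$origin, "+")
  else vol$origin + as.numeric(ijk) * vol$spacing
}

#' World-mm coordinates of every voxel centre along each axis
#' @param vol a `volume3d`.
#' @return list of 3 numeric vectors (x, y, z voxel-centre coordinates, mm).
#' @export
axis_coords <- function(vol) {
  d <- dim(vol$data)
  lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1) * vol$spacing[a])
}

# 1-D convolution matrix for a normalized kernel with half-sample symmetric
# boundary (edge value repeated: ... x2 x1 | x1 x2 ...). For a symmetric
# kernel the column sums of this matrix are exactly 1, so convolution along
# each axis conserves the array total to machine precision.
conv_matrix_1d <- function(n, kernel) {
  k <- length(kernel)
  half <- (k - 1L) %/% 2L
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      src <- i + j - 1L - half
      # reflect including edge until in range (grid always wider than kernel)
      while (src < 1L || src > n) {
        if (src < 1L) src <- 1L - src
        if (src > n) src <- 2L * n + 1L - src
      }
      m[i, src] <- m[i, src] + kernel[j]
    }
  }
  m
}

gauss_kernel_1d <- function(fwhm_mm, spacing_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sigma / spacing_mm))
  x <- (-half:half) * spacing_mm
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Blur a volume with an isotropic or anisotropic Gaussian PSF
#'
#' Separable Gaussian convolution parameterized by full width at half
#' maximum per axis, with a symmetric (edge-repeating) boundary so that
#' total activity is conserved exactly.
#'
#' @param vol a `volume3d`.
#' @param fwhm_mm scalar or length-3 FWHM in mm; 0 disables blurring.
#' @return blurred `volume3d` on the same grid.
#' @export
psf_blur <- function(vol, fwhm_mm) {
  fwhm_mm <- as.numeric(fwhm_mm)
  if (length(fwhm_mm) == 1L) fwhm_mm <- rep(fwhm_mm, 3L)
  if (any(fwhm_mm < 0)) stop("FWHM must be >= 0", call. = FALSE)
  if (all(fwhm_mm == 0)) return(vol)
  a <- vol$data
  d <- dim(a)
  for (ax in 1:3) {
    if (fwhm_mm[ax] == 0) next
    kern <- gauss_kernel_1d(fwhm_mm[ax], vol$spacing[ax])
    if (length(kern) >= 2L * d[ax])
      stop("PSF kernel wider than grid along axis ", ax, call. = FALSE)
    cm <- conv_matrix_1d(d[ax], kern)
    a <- apply_along_axis(a, ax, cm)
  }
  volume3d(a, vol$spacing, vol$origin)
}

# multiply conv matrix along one axis of a 3-D array via permute + matrix product
apply_along_axis <- function(a, axis, cm) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- cm %*% matrix(ap, nrow = dp[1])
  dim(m) <- dp
  aperm(m, order(perm))
}

#' Resample a volume onto a new voxel grid by trilinear interpolation
#'
#' The target grid covers the same world-space bounding box (voxel-centre
#' extent) with the requested spacing; values outside the source
#' voxel-centre hull are clamped to the nearest face.
#'
#' @param vol a `volume3d`.
#' @param new_spacing numeric scalar or length-3, target spacing in mm.
#' @return a `volume3d` on the new grid.
#' @export
resample_volume <- function(vol, new_spacing) {
  new_spacing <- as.numeric(new_spacing)
  if (length(new_spacing) == 1L) new_spacing <- rep(new_spacing, 3L)
  if (any(new_spacing <= 0)) stop("spacing must be > 0", call. = FALSE)
  d <- dim(vol$data)
  extent <- (d - 1) * vol$spacing
  nd <- pmax(2L, as.integer(floor(extent / new_spacing)) + 1L)
  # centre the new grid on the old grid's world centre
  centre <- vol$origin + extent / 2
  new_origin <- centre - (nd - 1) / 2 * new_spacing
  out <- array(0, dim = nd)
  xs <- (new_origin[1] + (seq_len(nd[1]) - 1) * new_spacing[1] - vol$origin[1]) / vol$spacing[1]
  ys <- (new_origin[2] + (seq_len(nd[2]) - 1) * new_spacing[2] - vol$origin[2]) / vol$spacing[2]
  zs <- (new_origin[3] + (seq_len(nd[3]) - 1) * new_spacing[3] - vol$origin[3]) / vol$spacing[3]
  clamp <- function(v, hi) pmin(pmax(v, 0), hi)
  xs <- clamp(xs, d[1] - 1); ys <- clamp(ys, d[2] - 1); zs <- clamp(zs, d[3] - 1)
  x0 <- pmin(floor(xs), d[1] - 2); y0 <- pmin(floor(ys), d[2] - 2); z0 <- pmin(floor(zs), d[3] - 2)
  fx <- xs - x0; fy <- ys - y0; fz <- zs - z0
  a <- vol$data
  # expand index grids (1-based array access)
  ix <- as.integer(x0) + 1L; iy <- as.integer(y0) + 1L; iz <- as.integer(z0) + 1L
  for (kz in seq_len(nd[3])) {
    z1 <- iz[kz]; wz <- fz[kz]
    sl0 <- a[, , z1]; sl1 <- a[, , z1 + 1L]
    # bilinear in-plane on both slabs, then lerp in z
    gx0 <- sl0[ix, iy, drop = FALSE]; gx1 <- sl0[ix + 1L, iy, drop = FALSE]
    hx0 <- sl0[ix, iy + 1L, drop = FALSE]; hx1 <- sl0[ix + 1L, iy + 1L, drop = FALSE]
    p0 <- (1 - fx) * gx0 + fx * gx1
    p1 <- (1 - fx) * hx0 + fx * hx1
    b0 <- sweep(p0, 2, 1 - fy, "*") + sweep(p1, 2, fy, "*")
    gx0 <- sl1[ix, iy, drop = FALSE]; gx1 <- sl1[ix + 1L, iy, drop = FALSE]
    hx0 <- sl1[ix, iy + 1L, drop = FALSE]; hx1 <- sl1[ix + 1L, iy + 1L, drop = FALSE]
    p0 <- (1 - fx) * gx0 + fx * gx1
    p1 <- (1 - fx) * hx0 + fx * hx1
    b1 <- sweep(p0, 2, 1 - fy, "*") + sweep(p1, 2, fy, "*")
    out[, , kz] <- (1 - wz) * b0 + wz * b1
  }
  volume3d(out, new_spacing, new_origin)
}

#' Total activity in a volume (kBq)
#' @param vol a `volume3d`.
#' @return sum of AC times voxel volume, in kBq (voxel volume taken in mL).
#' @export
total_activity_kbq <- function(vol) sum(vol$data) * voxel_volume_mm3(vol) / 1000
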