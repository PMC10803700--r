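meta_std <- scan_meta(140, uptake_min = 60, duration_min = 2, weight_kg = 70)

test_that("a single uniform compartment stays uniform after the PSF", {
  spec <- phantom_spec(shape = c(24L, 24L, 20L), spacing_mm = c(2.34, 2.34, 3.26),
                       compartments = list(), background_ac = 5)
  v <- generate_phantom(spec, diq_like(), meta_std)
  expect_equal(range(v$data), c(5, 5), tolerance = 1e-12)
})

test_that("compartment interiors hold their nominal AC after blurring", {
  spec <- default_phantom_spec()
  sys <- diq_like()
  v <- generate_phantom(spec, sys, meta_std)
  co <- axis_coords(v)
  for (cp in spec$compartments[c(4, 5)]) {  # liver and mediastinum boxes
    # erode by 2 x FWHM so compartment-boundary blur does not leak in
    h <- cp$half_size_mm - 2 * max(sys$psf_fwhm_mm)
    vals <- c()
    for (i in which(abs(co[[1]] - cp$centre_mm[1]) <= h[1]))
      for (j in which(abs(co[[2]] - cp$centre_mm[2]) <= h[2]))
        vals <- c(vals, v$data[i, j, which(abs(co[[3]] - cp$centre_mm[3]) <= h[3])])
    expect_lt(abs(mean(vals) / cp$ac - 1), 0.01, label = cp$label)
  }
})

test_that("phantom generation is deterministic and validates geometry", {
  spec <- default_phantom_spec(seed = 4)
  v1 <- generate_phantom(spec, dmi_like(), meta_std)
  v2 <- generate_phantom(spec, dmi_like(), meta_std)
  expect_identical(v1$data, v2$data)
  expect_error(phantom_spec(compartments = list(list(
    label = "out", type = "box", centre_mm = c(200, 0, 0),
    half_size_mm = c(10, 10, 10), ac = 1))), "outside")
  expect_error(phantom_spec(background_ac = -1), ">= 0")
})

test_that("acquisition noise is Poisson-faithful, seeded, and vanishing at high counts", {
  u <- uniform_volume(2, n = c(50L, 50L, 40L), spacing = c(2.34, 2.34, 3.26))
  sys <- diq_like()
  n1 <- add_acquisition_noise(u, sys, meta_std, seed = 7)
  n2 <- add_acquisition_noise(u, sys, meta_std, seed = 7)
  expect_identical(n1$data, n2$data)

  # Fano factor 1 at 1e5 voxels: variance of counts ~ mean of counts
  factor <- 1000 * (voxel_volume_mm3(u) / 1000) * (meta_std$duration_min * 60) *
    sys$sensitivity * decay_factor(meta_std$uptake_min)
  counts <- n1$data * factor
  expect_equal(var(as.numeric(counts)) / mean(counts), 1, tolerance = 0.02)

  # very high sensitivity: output converges to input
  hi <- system_model("hi", sys$voxel_mm, sys$psf_fwhm_mm, sensitivity = 1e4)
  nh <- add_acquisition_noise(u, hi, meta_std, seed = 8)
  expect_lt(sqrt(mean((nh$data - u$data)^2)) / 2, 1e-3)

  bad <- u; bad$data[1] <- NaN
  expect_error(add_acquisition_noise(bad, sys, meta_std), "non-finite")
})

test_that("noise is mean-preserving across seeds per compartment", {
  spec <- default_phantom_spec()
  v <- generate_phantom(spec, diq_like(), meta_std)
  acc <- array(0, dim(v$data))
  nseed <- 100
  for (s in seq_len(nseed))
    acc <- acc + add_acquisition_noise(v, diq_like(), meta_std, seed = s)$data
  mean_vol <- acc / nseed
  co <- axis_coords(v)
  for (cp in spec$compartments[c(1, 4)]) {   # torso, liver
    h <- cp$half_size_mm - 12
    sel_i <- which(abs(co[[1]] - cp$centre_mm[1]) <= h[1])
    sel_j <- which(abs(co[[2]] - cp$centre_mm[2]) <= h[2])
    sel_k <- which(abs(co[[3]] - cp$centre_mm[3]) <= h[3])
    expect_lt(abs(mean(mean_vol[sel_i, sel_j, sel_k]) /
                    mean(v$data[sel_i, sel_j, sel_k]) - 1), 0.01,
              label = cp$label)
  }
})

test_that("the paired exam applies the closed-form decay factor", {
  spec <- default_phantom_spec()
  pair <- generate_paired_exams(spec, diq_like(), diq_like(), meta_std,
                                delay_min = 25, noise = FALSE)
  v1 <- generate_phantom(spec, diq_like(), meta_std)
  expect_equal(pair$vol2$data / pmax(v1$data, 1e-300),
               array(2^(-25 / 109.77), dim(v1$data)), tolerance = 1e-10)
  expect_equal(2^(-25 / 109.77), 0.854, tolerance = 1e-3)
  expect_equal(pair$meta2$uptake_min, 85)
  expect_equal(pair$meta2$duration_min, solve_duration(2, 25), tolerance = 1e-12)
})

test_that("a zero-delay pair on identical systems is degenerate", {
  spec <- default_phantom_spec()
  pair <- generate_paired_exams(spec, diq_like(), diq_like(), meta_std,
                                delay_min = 0, noise = FALSE)
  expect_equal(pair$vol1$data, pair$vol2$data, tolerance = 1e-12)
})

test_that("count matching holds the paired exam's total counts within 1%", {
  spec <- default_phantom_spec()
  counts_of <- function(vol, sys, meta) {
    sum(vol$data) * 1000 * (voxel_volume_mm3(vol) / 1000) *
      (meta$duration_min * 60) * sys$sensitivity
  }
  sys <- diq_like()
  diffs <- vapply(1:5, function(s) {
    pair <- generate_paired_exams(spec, sys, sys, meta_std, delay_min = 25,
                                  seed = s)
    c1 <- counts_of(pair$vol1, sys, pair$meta1)
    c2 <- counts_of(pair$vol2, sys, pair$meta2)
    abs(c2 - c1) / c1
  }, 0)
  expect_lt(median(diffs), 0.01)
})

test_that("total noiseless activity decreases monotonically with delay", {
  spec <- default_phantom_spec()
  tots <- vapply(c(0, 10, 25, 50), function(d) {
    pair <- generate_paired_exams(spec, diq_like(), diq_like(), meta_std,
                                  delay_min = d, noise = FALSE)
    total_activity_kbq(pair$vol2)
  }, 0)
  expect_true(all(diff(tots) < 0))
})

test_that("the second exam is resampled onto the second system's grid", {
  spec <- default_phantom_spec()
  pair <- generate_paired_exams(spec, diq_like(), dmi_like(), meta_std,
                                delay_min = 25, noise = FALSE)
  expect_equal(pair$vol1$spacing, c(2.34, 2.34, 3.26))
  expect_equal(pair$vol2$spacing, c(2.34, 2.34, 2.8))
})

test_that("sampled lesions respect the design ranges and sit on uniform background", {
  spec <- default_phantom_spec()
  lesions <- sample_lesions(spec, 9, seed = 3)
  painted <- petisl:::paint_compartments(spec)
  for (l in lesions) {
    expect_gte(l$diameter_mm, 5); expect_lte(l$diameter_mm, 11)
    expect_gte(l$contrast, 2); expect_lte(l$contrast, 14)
    expect_silent(measure_background_ac(painted, l$centre_mm))
  }
  # reproducible
  again <- sample_lesions(spec, 9, seed = 3)
  expect_identical(vapply(lesions, `[[`, numeric(3), "centre_mm"),
                   vapply(again, `[[`, numeric(3), "centre_mm"))
})
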