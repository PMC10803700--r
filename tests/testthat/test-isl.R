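test_that("the 2 cm^3 measurement VOI has radius 7.8159 mm", {
  expect_equal(voi_radius_mm(2), (3 * 2000 / (4 * pi))^(1 / 3), tolerance = 1e-12)
  expect_equal(voi_radius_mm(2), 7.8159, tolerance = 1e-4)
})

test_that("background VOI mean matches a brute-force voxel enumeration", {
  u <- uniform_volume(5)
  expect_equal(measure_background_ac(u, c(0, 0, 0)), 5, tolerance = 1e-12)
  expect_equal(measure_background_ac(u, c(6.3, -4.1, 2.2)), 5, tolerance = 1e-12)

  g <- gradient_volume()
  ctr <- c(3.1, -2.0, 4.5)
  got <- measure_background_ac(g, ctr)
  # independent brute-force oracle: enumerate every voxel centre directly
  r <- voi_radius_mm(2)
  co <- axis_coords(g)
  acc <- c()
  for (i in seq_along(co[[1]])) for (j in seq_along(co[[2]]))
    for (k in seq_along(co[[3]])) {
      if (sum((c(co[[1]][i], co[[2]][j], co[[3]][k]) - ctr)^2) <= r^2)
        acc <- c(acc, g$data[i, j, k])
    }
  expect_equal(got, mean(acc), tolerance = 1e-12)
})

test_that("VOI error conditions are reported", {
  u <- uniform_volume(5)
  edge <- u$origin + c(1, 1, 1)   # VOI sphere pokes outside
  expect_error(measure_background_ac(u, edge), "outside")
  tiny <- uniform_volume(5, n = c(32L, 32L, 24L), spacing = c(12, 12, 12))
  expect_error(measure_background_ac(tiny, c(0, 0, 0)), "fewer than 8")
})

test_that("contrast conversion implements the defining relation and round-trips", {
  expect_identical(contrast_to_ac(2.0, 0), 2.0)
  expect_identical(contrast_to_ac(1.0, 2), 3.0)
  # boundary values from the study's lesion table round-trip through both maps
  c0 <- ac_to_contrast(6.16, 2.34)
  expect_equal(c0, (6.16 - 2.34) / 2.34, tolerance = 1e-12)
  expect_equal(contrast_to_ac(2.34, c0), 6.16, tolerance = 1e-12)
  for (bg in c(0.5, 2.34, 12.55)) for (cc in c(-0.5, 0, 2, 14)) {
    expect_equal(ac_to_contrast(contrast_to_ac(bg, cc), bg), cc,
                 tolerance = 1e-12)
  }
  expect_error(contrast_to_ac(2, -1), "-1")
  expect_error(ac_to_contrast(5, 0), "zero")
})

test_that("sphere rasterization reaches 1% volume accuracy on both study grids", {
  set.seed(11)
  for (sp in table3_grids) {
    u <- volume3d(array(0, c(40, 40, 30)), sp)
    for (d in c(5, 6.5, 8, 9.4, 11)) {
      ctr <- runif(3, -3, 3)
      ras <- rasterize_sphere(u, ctr, d)
      expect_lt(abs(ras$volume_mm3 / sphere_volume_mm3(d) - 1), 0.01,
                label = sprintf("d=%g on grid %s", d, paste(sp, collapse = "x")))
      expect_true(all(ras$fraction >= 0 & ras$fraction <= 1))
    }
  }
})

test_that("a voxel deep inside the sphere has occupancy 1", {
  u <- volume3d(array(0, c(33, 33, 33)), c(2, 2, 2))
  ras <- rasterize_sphere(u, c(0, 0, 0), 10)
  centre_idx <- which(ras$index == (16 * 33 * 33 + 16 * 33 + 17))
  expect_equal(ras$fraction[centre_idx], 1.0, tolerance = 1e-12)
})

test_that("rasterization has converged at the default supersampling", {
  set.seed(13)
  for (sp in table3_grids) {
    u <- volume3d(array(0, c(40, 40, 30)), sp)
    for (d in c(5, 9.4)) {
      ctr <- runif(3, -2, 2)
      v3 <- rasterize_sphere(u, ctr, d, supersampling = 3)$volume_mm3
      v7 <- rasterize_sphere(u, ctr, d, supersampling = 7)$volume_mm3
      expect_lt(abs(v3 / v7 - 1), 0.005)
    }
  }
  u <- volume3d(array(0, c(20, 20, 20)), 2)
  expect_error(rasterize_sphere(u, c(500, 0, 0), 8), "outside")
})

test_that("insertion at zero contrast is the identity", {
  u <- uniform_volume(2, n = c(40L, 40L, 28L))
  spec <- suppressWarnings(lesion_spec("z", c(0, 0, 0), 10, 0))  # out-of-design contrast
  res <- insert_lesion(u, spec, diq_like())
  expect_equal(res$volume$data, u$data, tolerance = 1e-14)
})

test_that("inserted activity matches the closed form and survives the blur", {
  u <- uniform_volume(2, n = c(48L, 48L, 32L))
  spec <- lesion_spec("L1", c(0, 0, 0), 10, 4)
  res <- insert_lesion(u, spec, diq_like())
  # report identity: inserted kBq = (lesion - background) x rasterized volume
  expect_equal(res$report$inserted_activity_kbq,
               (res$report$lesion_ac - res$report$background_ac) *
                 res$report$rasterized_volume_mm3 / 1000, tolerance = 1e-9)
  # analytic: dAC 8 kBq/mL x (pi/6) 10^3 mm^3 = 4.18879 kBq (to raster accuracy)
  expect_equal(res$report$inserted_activity_kbq, 4.18879, tolerance = 0.01)
  # conservation through the blur: the added activity in the volume equals
  # the report's inserted activity to 1e-6 relative
  added <- (sum(res$volume$data) - sum(u$data)) * voxel_volume_mm3(u) / 1000
  expect_equal(added, res$report$inserted_activity_kbq, tolerance = 1e-6)
  # original untouched
  expect_equal(u$data[1, 1, 1], 2)
})

test_that("insertion is linear in contrast and local in space", {
  u <- uniform_volume(2, n = c(48L, 48L, 32L))
  sys <- diq_like()
  d1 <- insert_lesion(u, lesion_spec("a", c(0, 0, 0), 8, 3), sys)$volume$data - u$data
  d2 <- insert_lesion(u, lesion_spec("b", c(0, 0, 0), 8, 6), sys)$volume$data - u$data
  expect_equal(d2, 2 * d1, tolerance = 1e-9)
  # a VOI >= 5 FWHM away does not see the lesion
  res <- insert_lesion(u, lesion_spec("c", c(-30, -30, -20), 8, 6), sys)
  far <- c(30, 30, 20)
  expect_lt(abs(measure_background_ac(res$volume, far) -
                  measure_background_ac(u, far)), 1e-9)
})

test_that("pre-blur lesion mean recovers the requested contrast", {
  u <- uniform_volume(3, n = c(40L, 40L, 28L))
  spec <- lesion_spec("e", c(1, -2, 0.5), 9, 5)
  bg <- measure_background_ac(u, spec$centre_mm)
  ras <- rasterize_sphere(u, spec$centre_mm, spec$diameter_mm)
  delta_ac <- contrast_to_ac(bg, spec$contrast) - bg
  mean_ac <- bg + sum(delta_ac * ras$fraction) * voxel_volume_mm3(u) /
    ras$volume_mm3 / 1
  expect_equal(mean_ac / bg, 1 + spec$contrast, tolerance = 1e-6)
})

test_that("batch insertion is order-independent for disjoint lesions", {
  u <- uniform_volume(2, n = c(48L, 48L, 32L))
  sys <- diq_like()
  a <- lesion_spec("a", c(-20, -20, -15), 8, 4)
  b <- lesion_spec("b", c(20, 20, 15), 6, 7)
  v_ab <- insert_lesions(u, list(a, b), sys)$volume
  v_ba <- insert_lesions(u, list(b, a), sys)$volume
  expect_equal(v_ab$data, v_ba$data, tolerance = 1e-12)
})

test_that("matched insertion applies the same contrast to each exam", {
  u1 <- uniform_volume(2, n = c(48L, 48L, 32L))
  spec <- lesion_spec("m", c(0, 0, 0), 9, 3)
  same <- insert_matched(u1, u1, spec, diq_like(), diq_like())
  expect_equal(same$report$lesion_ac[1], same$report$lesion_ac[2])
  expect_equal(same$volumes[[1]]$data, same$volumes[[2]]$data)

  # decayed second exam: lesion AC scales with its background
  dec <- decay_factor(25)
  u2 <- u1; u2$data <- u2$data * dec
  res <- insert_matched(u1, u2, spec, diq_like(), dmi_like())
  expect_equal(res$report$lesion_ac[2] / res$report$lesion_ac[1], dec,
               tolerance = 1e-10)
  # Eq-1 round trip per entry
  for (i in 1:2)
    expect_equal(ac_to_contrast(res$report$lesion_ac[i],
                                res$report$background_ac[i]),
                 spec$contrast, tolerance = 1e-12)
})

test_that("lesion manifests round-trip through CSV with range warnings", {
  lesions <- list(lesion_spec("L1", c(1, 2, 3), 9.4, 2.5, "liver"),
                  lesion_spec("L2", c(-5, 0, 4), 7, 5, "lymph_node"))
  path <- tempfile(fileext = ".csv")
  write_lesion_manifest(lesions, path)
  back <- read_lesion_manifest(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$centre_mm, c(1, 2, 3))
  expect_equal(back[[2]]$contrast, 5)
  expect_warning(lesion_spec("w", c(0, 0, 0), 3, 5), "diameter")
  expect_warning(lesion_spec("w", c(0, 0, 0), 8, 20), "contrast")
  expect_error(lesion_spec("e", c(0, 0, 0), 8, -1.5), "-1")
})
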