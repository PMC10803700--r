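#' Deterministic threshold reader
#'
#' Surrogate for human lesion detection used by the end-to-end simulation
#' tests: a lesion is called detected when its contrast-to-local-noise
#' index exceeds a threshold. The signal is the mean over the lesion-core
#' sphere (the known insertion site), the local background level and
#' noise are the median and MAD of a concentric shell, and the index is
#' the core excess in units of the noise of the core mean,
#' `(mean(core) - median(shell)) / (MAD(shell) / sqrt(n_core))` --
#' a matched-region detectability index that rewards both contrast and
#' count statistics.
#'
#' @param vol a noisy `volume3d`.
#' @param lesions list of `lesion_spec` (known insertion sites).
#' @param theta detection threshold on the index (default 4).
#' @param shell_mm inner and outer offsets (mm) of the background shell,
#'   added to the lesion radius.
#' @return logical vector of detection flags, one per lesion.
#' @export
threshold_reader <- function(vol, lesions, theta = 4, shell_mm = c(4, 12)) {
  vapply(lesions, function(l) {
    r <- l$diameter_mm / 2
    core <- sphere_voxel_indices_clipped(vol, l$centre_mm, r)
    if (!length(core)) return(FALSE)
    inner <- sphere_voxel_indices_clipped(vol, l$centre_mm, r + shell_mm[1])
    outer <- sphere_voxel_indices_clipped(vol, l$centre_mm, r + shell_mm[2])
    shell <- setdiff(outer, inner)
    if (length(shell) < 16L) return(FALSE)
    bg_mu <- stats::median(vol$data[shell])
    bg_sd <- stats::mad(vol$data[shell])
    if (bg_sd <= 0) bg_sd <- stats::sd(vol$data[shell])
    if (bg_sd <= 0) return(mean(vol$data[core]) > bg_mu)
    (mean(vol$data[core]) - bg_mu) / (bg_sd / sqrt(length(core))) >= theta
  }, logical(1))
}

# like sphere_voxel_indices but tolerates spheres extending past the grid
sphere_voxel_indices_clipped <- function(vol, centre_mm, radius_mm) {
  d <- dim(vol$data)
  co <- axis_coords(vol)
  rng <- lapply(1:3, function(a) which(abs(co[[a]] - centre_mm[a]) <= radius_mm))
  if (any(lengths(rng) == 0L)) return(integer(0))
  g <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
  r2 <- (co[[1]][g$i] - centre_mm[1])^2 + (co[[2]][g$j] - centre_mm[2])^2 +
    (co[[3]][g$k] - centre_mm[3])^2
  g <- g[r2 <= radius_mm^2, , drop = FALSE]
  (g$k - 1L) * d[1] * d[2] + (g$j - 1L) * d[1] + g$i
}

#' Simulate a matched-lesion detection batch on two systems
#'
#' Generates `n_phantoms` scan-rescan phantom pairs, inserts
#' `lesions_per_phantom` matched synthetic lesions into each pair, adds
#' acquisition noise, applies the threshold reader to both exams and
#' returns the pooled detection table. Exam 1 runs on the reference
#' system and exam 2 (decayed, count-matched) on the comparison system.
#'
#' @param n_phantoms number of phantom pairs (default 20).
#' @param lesions_per_phantom matched lesions per pair (default 3).
#' @param system_ref,system_cmp `system_model`s; defaults [diq_like()] and
#'   [dmi_like()].
#' @param meta1 `scan_meta` for exam 1.
#' @param delay_min inter-exam delay (default 25).
#' @param theta reader CNR threshold.
#' @param seed integer root seed.
#' @return a `detection_table` with one row per lesion (reference flags in
#'   `det_1`, comparison in `det_2`).
#' @export
simulate_detection_batch <- function(n_phantoms = 20, lesions_per_phantom = 3,
                                     system_ref = diq_like(),
                                     system_cmp = dmi_like(),
                                     meta1 = scan_meta(140, uptake_min = 60,
                                                       duration_min = 2,
                                                       weight_kg = 70),
                                     delay_min = 25, theta = 4, seed = 1L) {
  rows <- vector("list", n_phantoms)
  for (p in seq_len(n_phantoms)) {
    sp <- default_phantom_spec(seed = seed + p)
    lesions <- sample_lesions(sp, lesions_per_phantom,
                              seed = seed * 1000L + p)
    clean_ref <- generate_phantom(sp, system_ref, meta1)
    clean_cmp <- generate_phantom(sp, system_cmp, meta1)
    ins_ref <- insert_lesions(clean_ref, lesions, system_ref)
    ins_cmp <- insert_lesions(clean_cmp, lesions, system_cmp)
    # exam 2 (comparison system): decay over the delay, count-matched duration
    dec <- decay_factor(delay_min, meta1$half_life_min)
    vol_cmp <- ins_cmp$volume
    vol_cmp$data <- vol_cmp$data * dec
    plan <- acquisition_plan(meta1$duration_min, delay_min,
                             meta1$half_life_min)
    meta2 <- scan_meta(meta1$injected_activity_MBq,
                       uptake_min = meta1$uptake_min + delay_min,
                       duration_min = plan$t2_min,
                       weight_kg = meta1$weight_kg,
                       half_life_min = meta1$half_life_min)
    noisy_ref <- add_acquisition_noise(ins_ref$volume, system_ref,
                                       meta_at_reference(meta1),
                                       seed = seed * 7919L + 2L * p)
    noisy_cmp <- add_acquisition_noise(vol_cmp, system_cmp,
                                       meta_at_reference(meta2),
                                       seed = seed * 7919L + 2L * p + 1L)
    det_ref <- threshold_reader(noisy_ref, lesions, theta = theta)
    det_cmp <- threshold_reader(noisy_cmp, lesions, theta = theta)
    rows[[p]] <- data.frame(
      lesion_id = sprintf("P%02d_%s", p,
                          vapply(lesions, `[[`, "", "id")),
      det_1 = det_ref, det_2 = det_cmp)
  }
  tab <- do.call(rbind, rows)
  attr(tab, "systems") <- c(system_ref$name, system_cmp$name)
  class(tab) <- c("detection_table", class(tab))
  tab
}
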