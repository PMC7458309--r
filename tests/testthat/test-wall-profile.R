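synth_profile <- function(intensity, px = 1.5, smoothing = 6) {
  structure(list(angle_deg = 0,
                 radii_um = (seq_along(intensity) - 1) * px,
                 intensity = intensity,
                 smoothing_window_um = smoothing,
                 pixel_size_um = px),
            class = "radial_profile")
}

# independent brute-force rupture scan for piecewise-constant profiles
oracle_steps <- function(y, r, frac) {
  rng <- max(y) - min(y)
  i <- which(abs(diff(y)) >= frac * rng)
  data.frame(r = (r[i] + r[i + 1]) / 2, up = diff(y)[i] > 0)
}

test_that("step-profile boundaries match the brute-force rupture scan", {
  r <- seq(0, 600, by = 1.5)
  y <- ifelse(r < 100, 500, ifelse(r < 250, 1200, 2000))
  prof <- synth_profile(y)
  bs <- detect_boundaries(prof, min_jump_fraction = 0.2)
  steps <- oracle_steps(y, r, 0.2)
  halfwin <- 3  # smoothing half-window, um
  expect_lt(abs(bs$lumen_edge_um - steps$r[steps$up][1]), halfwin)
  expect_lt(abs(bs$media_adventitia_um - steps$r[2]), halfwin)
  expect_true(is.na(bs$outer_edge_um))   # profile never falls back down

  # wall-shaped profile: all four boundaries against the oracle
  y2 <- ifelse(r < 90, 550, ifelse(r < 150, 950,
          ifelse(r < 240, 1600, ifelse(r < 300, 1150, 520))))
  y2[abs(r - 150) <= 4] <- 570   # IEL dip at the intima/media interface
  bs2 <- detect_boundaries(synth_profile(y2), min_jump_fraction = 0.15)
  steps2 <- oracle_steps(ifelse(r < 90, 550, ifelse(r < 150, 950,
    ifelse(r < 240, 1600, ifelse(r < 300, 1150, 520)))), r, 0.15)
  expect_lt(abs(bs2$lumen_edge_um - steps2$r[steps2$up][1]), halfwin)
  expect_lt(abs(bs2$iel_um - 150), halfwin + 4)
  expect_lt(abs(bs2$media_adventitia_um - 240), halfwin + 4)
  expect_lt(abs(bs2$outer_edge_um - steps2$r[!steps2$up][sum(!steps2$up)]),
            halfwin)
  # thickness additivity holds exactly for any complete boundary set
  expect_equal((bs2$iel_um - bs2$lumen_edge_um) +
                 (bs2$media_adventitia_um - bs2$iel_um) +
                 (bs2$outer_edge_um - bs2$media_adventitia_um),
               bs2$outer_edge_um - bs2$lumen_edge_um)
})

test_that("featureless profiles yield undetectable boundaries, not errors", {
  bs <- detect_boundaries(synth_profile(rep(1000, 80)))
  expect_true(all(is.na(c(bs$lumen_edge_um, bs$iel_um,
                          bs$media_adventitia_um, bs$outer_edge_um))))
  expect_true(all(bs$confidence == 0))
  expect_error(detect_boundaries(synth_profile(rep(1, 10))), "16 samples")
})

test_that("radial profiles interpolate, convert units and smooth as stated", {
  img <- matrix(500, 64, 64)
  sec <- section_2d(img, 1.5)
  prof <- radial_profile(sec, c(32, 32), 123, 6)
  expect_true(all(prof$intensity == 500))
  expect_equal(diff(prof$radii_um)[1], 1.5)

  # gradient image: the ray at 0 degrees reads off the column coordinate
  gimg <- matrix(seq_len(64), 64, 64, byrow = TRUE)
  gsec <- section_2d(gimg, 2)
  raw <- radial_profile(gsec, c(32, 10.5), 0, smoothing_window_um = 0)
  expect_equal(raw$intensity, 10.5 + raw$radii_um / 2)
  expect_error(radial_profile(gsec, c(-3, 10), 0), "outside")
})

test_that("noise-free phantom plateaus are recovered along any ray", {
  sp <- small_spec(n_vasa = 0L, rbc_density = 0, speckle_sigma = 0,
                   read_noise_sigma = 0, texture_amplitude = 0,
                   n_slices = 1L)
  ph <- generate_phantom(sp)
  sec <- quiet_section(ph)
  for (ang in c(17, 200)) {
    prof <- radial_profile(sec, sp$center_px, ang, 0)
    mid <- function(lo, hi) prof$intensity[prof$radii_um > lo &
                                             prof$radii_um < hi]
    expect_lt(abs(mean(mid(10, 30)) - 550), 1)        # lumen
    expect_lt(abs(mean(mid(50, 58)) - 950), 1)        # intima
    expect_lt(abs(mean(mid(80, 120)) - 1600), 1)      # media
    expect_lt(abs(mean(mid(140, 165)) - 1150), 1)     # adventitia
  }
})

test_that("lumen center is recovered, mirrors with the image, and is robust to speckle", {
  sp <- small_spec(n_vasa = 0L, speckle_sigma = 0, read_noise_sigma = 0,
                   n_slices = 1L)
  ph <- generate_phantom(sp)
  sec <- quiet_section(ph)
  ctr <- estimate_center(sec)
  expect_lt(max(abs(ctr - sp$center_px)), 2)

  mirrored <- section_2d(sec$pixels[, ncol(sec$pixels):1], sec$pixel_size_um)
  ctr_m <- estimate_center(mirrored)
  expect_lt(abs(ctr_m[1] - ctr[1]), 1)
  expect_lt(abs(ctr_m[2] - (ncol(sec$pixels) + 1 - ctr[2])), 1)

  errs <- vapply(1:10, function(s) {
    p <- generate_phantom(small_spec(seed = 300L + s, n_slices = 5L))
    max(abs(estimate_center(quiet_section(p)) - p$spec$center_px))
  }, numeric(1))
  expect_lte(mean(errs), 3)
  expect_error(estimate_center(section_2d(matrix(1, 32, 32), 1.5)),
               "constant")
})

test_that("layer thicknesses and I/M are recovered on a noise-free phantom", {
  sp <- phantom_spec(image_size_px = c(448L, 448L), lumen_radius_um = 40,
                     intima_thickness_um = 60, media_thickness_um = 150,
                     adventitia_thickness_um = 35, n_vasa = 0L,
                     speckle_sigma = 0, read_noise_sigma = 0, n_slices = 1L,
                     seed = 5L)
  ph <- generate_phantom(sp)
  m <- measure_layers(quiet_section(ph), estimate_center(quiet_section(ph)))
  expect_lt(abs(m$intima_um - 60), 2 * sp$pixel_size_um)
  expect_equal(m$im_ratio, 0.4, tolerance = 0.1)
  expect_identical(m$class_label, "normal")
  expect_identical(m$n_profiles_used, 3L)

  # additivity of the averaged thicknesses over the selected angles
  tab <- m$angle_table
  selrows <- tab[tab$angle_deg %in% m$selected_angles, ]
  expect_equal(m$intima_um + m$media_um + m$adventitia_um,
               mean(selrows$outer_edge_um - selrows$lumen_edge_um))
})

test_that("reported thicknesses scale with pixel size; I/M does not", {
  sp <- small_spec(n_vasa = 0L, speckle_sigma = 0, read_noise_sigma = 0,
                   n_slices = 1L)
  ph <- generate_phantom(sp)
  sec1 <- quiet_section(ph)
  sec2 <- section_2d(sec1$pixels, 2 * sec1$pixel_size_um)
  ctr <- estimate_center(sec1)
  m1 <- measure_layers(sec1, ctr, smoothing_window_um = 6)
  m2 <- measure_layers(sec2, ctr, smoothing_window_um = 12)
  expect_equal(m2$intima_um, 2 * m1$intima_um)
  expect_equal(m2$media_um, 2 * m1$media_um)
  expect_equal(m2$im_ratio, m1$im_ratio)
})

test_that("remodeled (neo-intima) walls are mostly unquantifiable per angle", {
  fr <- vapply(1:3, function(s) {
    ph <- generate_phantom(small_gca_spec(seed = 40L + s, n_slices = 5L))
    m <- measure_layers(quiet_section(ph), estimate_center(quiet_section(ph)))
    mean(!m$angle_table$complete)
  }, numeric(1))
  expect_gt(mean(fr), 0.6)
})

test_that("I/M classification follows the published group bounds", {
  expect_identical(classify_im(0.5), "normal")
  expect_identical(classify_im(1.5), "hyperplasia")
  expect_identical(classify_im(3.0), "gca_like")
  expect_identical(classify_im(0), "normal")
  expect_identical(classify_im(1), "hyperplasia")   # closed endpoints
  expect_identical(classify_im(2), "hyperplasia")
  expect_identical(classify_im(2 + 1e-9), "gca_like")
  expect_identical(classify_im(NA), "unquantifiable")
  expect_identical(classify_im(c(0.2, 1.1, 5)),
                   c("normal", "hyperplasia", "gca_like"))
  expect_error(classify_im(-0.1), "non-negative")
})
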