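test_that("ground-truth ratio and class are forced by construction", {
  sp <- small_spec(intima_thickness_um = 50, media_thickness_um = 150,
                   lumen_radius_um = 30, adventitia_thickness_um = 25,
                   image_size_px = c(384L, 384L), n_slices = 1L)
  ph <- generate_phantom(sp)
  expect_equal(ph$truth$true_im_ratio, 1 / 3, tolerance = 1e-12)
  expect_identical(ph$truth$true_class, "normal")
  expect_equal(unname(ph$truth$true_thicknesses_um["media"]), 150)
})

test_that("disorder 0 without neo-intima gives an exactly tangential field", {
  sp <- small_spec(disorder = 0, n_vasa = 0L, n_slices = 1L,
                   speckle_sigma = 0, read_noise_sigma = 0)
  ph <- generate_phantom(sp)
  fld <- ph$truth$orientation_field
  defined <- which(!is.na(fld))
  ctr <- sp$center_px
  rr <- ((defined - 1L) %% nrow(fld)) + 1L
  cc <- ((defined - 1L) %/% nrow(fld)) + 1L
  tangent <- ((atan2(rr - ctr[1], cc - ctr[2]) * 180 / pi) + 90) %% 180
  expect_equal(fld[defined], tangent, tolerance = 1e-9)
})

test_that("identical specs reproduce identical stacks bit for bit", {
  sp <- small_spec(seed = 99L, n_slices = 3L)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$label_map, b$truth$label_map)
})

test_that("intima-labelled pixels lie in the intima annulus (within one pixel)", {
  sp <- small_spec(n_slices = 1L)
  ph <- generate_phantom(sp)
  lab <- ph$truth$label_map
  ctr <- sp$center_px
  idx <- which(lab == WALL_LABELS[["intima"]])
  rr <- ((idx - 1L) %% nrow(lab)) + 1L
  cc <- ((idx - 1L) %/% nrow(lab)) + 1L
  r_um <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2) * sp$pixel_size_um
  lo <- sp$lumen_radius_um - sp$pixel_size_um
  hi <- sp$lumen_radius_um + sp$intima_thickness_um + sp$pixel_size_um
  expect_true(all(r_um >= lo & r_um <= hi))
})

test_that("noise-free plateaus equal the nominal layer means; texture averages out", {
  sp <- small_spec(n_vasa = 0L, rbc_density = 0, speckle_sigma = 0,
                   read_noise_sigma = 0, texture_amplitude = 0, n_slices = 1L)
  ph <- generate_phantom(sp)
  img <- ph$stack$voxels[1, , ]
  lab <- ph$truth$label_map
  for (nm in c("lumen", "intima", "media", "adventitia", "background")) {
    expect_equal(unique(img[lab == WALL_LABELS[[nm]]]),
                 sp$layer_mean_intensity[[nm]])
  }
  # with texture on, the per-annulus mean still recovers the plateau
  sp2 <- small_spec(n_vasa = 0L, rbc_density = 0, speckle_sigma = 0,
                    read_noise_sigma = 0, n_slices = 1L)
  ph2 <- generate_phantom(sp2)
  img2 <- ph2$stack$voxels[1, , ]
  lab2 <- ph2$truth$label_map
  med <- mean(img2[lab2 == WALL_LABELS[["media"]]])
  expect_equal(med, sp2$layer_mean_intensity[["media"]], tolerance = 0.02)
})

test_that("stronger speckle strictly increases repeated-draw pixel variance", {
  var_at <- function(sigma) {
    stacks <- lapply(1:5, function(s) {
      generate_phantom(small_spec(seed = 100L + s, n_slices = 1L,
                                  speckle_sigma = sigma))$stack$voxels[1, , ]
    })
    arr <- simplify2array(stacks)
    mean(apply(arr[100:140, 100:140, ], c(1, 2), var))
  }
  expect_lt(var_at(0.1), var_at(0.3))
})

test_that("invalid geometries and parameters are rejected", {
  expect_error(small_spec(lumen_radius_um = 400), "geometry overflow")
  expect_error(small_spec(slice_spacing_um = 0), "positive")
  expect_error(small_spec(vasa_diameter_um_range = c(10, 50)), "vasa")
  expect_error(small_spec(media_thickness_um = -5), "positive")
  expect_error(small_spec(disorder = 1.5), "disorder")
})

test_that("cohort generation respects classes, ranges and determinism", {
  coh <- generate_cohort(3, classes = "normal", seed = 7, n_slices = 1L)
  expect_length(coh, 3)
  expect_true(all(vapply(coh, function(p) p$truth$true_class,
                         character(1)) == "normal"))
  man <- attr(coh, "manifest")
  expect_true(all(man$true_im_ratio >= 0.3 & man$true_im_ratio <= 0.8))

  coh2 <- generate_cohort(3, classes = "normal", seed = 7, n_slices = 1L)
  expect_identical(attr(coh2, "manifest"), man)

  # class ranges violating the I/M bounds are rejected
  bad <- default_class_specs()
  bad$normal$im_range <- c(0.5, 1.5)
  expect_error(generate_cohort(2, classes = "normal", class_specs = bad),
               "violates")
})

test_that("cohort ratios fall in the three disjoint class ranges", {
  man <- NULL
  for (cl in c("normal", "hyperplasia", "gca")) {
    coh <- generate_cohort(2, classes = cl, seed = 11, n_slices = 1L)
    man <- rbind(man, attr(coh, "manifest"))
  }
  r <- split(man$true_im_ratio, man$class)
  expect_true(all(r$normal < 1))
  expect_true(all(r$hyperplasia >= 1.2 & r$hyperplasia <= 1.8))
  expect_true(all(r$gca > 2))
})
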