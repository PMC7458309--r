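# Compact phantom geometries for fast unit tests, plus a cache for the
# full-scale cohorts shared by the cohort-level tests.

small_spec <- function(seed = 1L, ...) {
  args <- list(
    image_size_px = c(256L, 256L),
    lumen_radius_um = 40, intima_thickness_um = 25,
    media_thickness_um = 70, adventitia_thickness_um = 35,
    n_vasa = 1L, seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(phantom_spec, args)
}

small_gca_spec <- function(seed = 1L, ...) {
  small_spec(seed = seed,
             image_size_px = c(400L, 400L),
             lumen_radius_um = 35, intima_thickness_um = 150,
             media_thickness_um = 50, adventitia_thickness_um = 35,
             neo_intima = TRUE, disorder = 0.9, ...)
}

quiet_section <- function(phantom, method = "mean") {
  suppressWarnings(zproject(phantom$stack, method))
}

# full-scale measured cohorts (acceptance conditions), built once per run
.cohort_cache <- new.env(parent = emptyenv())

measured_cohort <- function(class, n = 20L, seed = 1234L) {
  key <- paste(class, n, seed, sep = "_")
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  coh <- generate_cohort(n, classes = class, seed = seed)
  manifest <- attr(coh, "manifest")
  rows <- lapply(seq_along(coh), function(i) {
    ph <- coh[[i]]
    sec <- zproject(ph$stack)
    m <- measure_layers(sec, estimate_center(sec))
    data.frame(
      true_im = manifest$true_im_ratio[i],
      true_intima = manifest$intima_um[i],
      true_media = manifest$media_um[i],
      meas_im = m$im_ratio,
      meas_intima = m$intima_um,
      meas_media = m$media_um,
      class_label = m$class_label,
      n_complete = sum(m$angle_table$complete)
    )
  })
  out <- do.call(rbind, rows)
  .cohort_cache[[key]] <- out
  out
}

make_grating <- function(angle_deg, wavelength_px, n = 160L,
                         pixel_size_um = 1.5) {
  g <- seq_len(n)
  x <- matrix(g, n, n, byrow = TRUE)
  y <- matrix(g, n, n)
  b <- (angle_deg + 90) * pi / 180
  u <- x * cos(b) + y * sin(b)
  section_2d(1000 + 300 * cos(2 * pi * u / wavelength_px), pixel_size_um)
}
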