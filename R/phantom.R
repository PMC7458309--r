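# Synthetic phantom generator: temporal-artery-biopsy-like cross sections
# with the wall architecture seen in en-face FF-OCT — three concentric
# tunicae with distinct reflectivity (media hyper-reflective relative to the
# intima), a thin hypo-reflective internal elastic lamina (IEL) at the
# intima/media junction, tangential fiber texture, vasa vasorum at the
# media/adventitia junction, red blood cells, multiplicative speckle — plus
# exact per-pixel ground truth.

#' Tunica label codes used in ground-truth label maps
#'
#' Integer codes for the per-pixel label map of a phantom:
#' background, lumen, intima, IEL, media, adventitia, vasa, rbc.
#'
#' @export
WALL_LABELS <- c(
  background = 0L, lumen = 1L, intima = 2L, iel = 3L,
  media = 4L, adventitia = 5L, vasa = 6L, rbc = 7L
)

default_layer_means <- function(neo_intima = FALSE) {
  if (neo_intima) {
    # GCA remodeling: dense reticular neo-intima, media destruction ->
    # intima/media mean contrast collapsed (below the detection threshold).
    c(background = 520, lumen = 550, intima = 1280, media = 1430,
      adventitia = 1130)
  } else {
    c(background = 520, lumen = 550, intima = 950, media = 1600,
      adventitia = 1150)
  }
}

#' Specification of a synthetic artery-section phantom
#'
#' Collects the geometry, reflectivity, texture and noise parameters of one
#' synthetic transverse artery section. Intensities are in arbitrary units
#' on the 500--2000 scale typical of en-face OCT plot profiles. All
#' geometric parameters are in micrometers.
#'
#' @param image_size_px integer pair, (rows, cols). Default 640 x 640.
#' @param pixel_size_um in-plane pixel size, micrometers (default 1.5).
#' @param n_slices number of depth slices in the generated stack.
#' @param slice_spacing_um depth spacing between slices (default 1.5).
#' @param center_px lumen center (row, col), 1-based pixel coordinates;
#'   default is the image center.
#' @param lumen_radius_um lumen radius.
#' @param intima_thickness_um,media_thickness_um,adventitia_thickness_um
#'   tunica thicknesses.
#' @param layer_mean_intensity named numeric vector with entries
#'   \code{background, lumen, intima, media, adventitia}; defaults depend on
#'   \code{neo_intima} (contrast collapse under GCA-like remodeling).
#' @param iel_width_um width of the hypo-reflective IEL band straddling the
#'   intima/media interface.
#' @param iel_contrast in [0,1]; the IEL intensity is
#'   \code{(1 - iel_contrast) * intima mean}.
#' @param iel_retained_fraction fraction of the circumference on which the
#'   IEL band is rendered; \code{NULL} resolves to 1 for intact walls and to
#'   0.18 under \code{neo_intima} (IEL fragmentation).
#' @param fiber_wavelength_um wavelength of the oriented band-pass fiber
#'   texture.
#' @param texture_amplitude relative modulation depth of the fiber texture.
#' @param disorder in [0,1]: standard deviation of the wrapped-normal
#'   orientation jitter is \code{disorder * 90} degrees (0 = perfectly
#'   tangential fibers, 1 = near-isotropic).
#' @param neo_intima logical; GCA-like remodeling (collapsed intima/media
#'   contrast, reticular isotropic texture in the two inner tunicae,
#'   fragmented IEL).
#' @param n_vasa number of vasa vasorum placed at the media/adventitia
#'   junction.
#' @param vasa_diameter_um_range diameter range, must lie within [20, 80].
#' @param rbc_density expected red blood cells per 1000 square micrometers
#'   of vasa lumen.
#' @param speckle_sigma log-normal multiplicative speckle parameter (0 = no
#'   speckle).
#' @param read_noise_sigma additive Gaussian read-noise standard deviation
#'   (arbitrary units).
#' @param ellipticity stretch factor along the column axis (1 = circular).
#' @param seed integer seed; identical specs reproduce identical stacks.
#' @return an object of class \code{phantom_spec}.
#' @seealso [generate_phantom()], [generate_cohort()]
#' @export
phantom_spec <- function(image_size_px = c(640L, 640L),
                         pixel_size_um = 1.5,
                         n_slices = 20L,
                         slice_spacing_um = 1.5,
                         center_px = NULL,
                         lumen_radius_um = 90,
                         intima_thickness_um = 50,
                         media_thickness_um = 130,
                         adventitia_thickness_um = 60,
                         layer_mean_intensity = NULL,
                         iel_width_um = 7.5,
                         iel_contrast = 0.4,
                         iel_retained_fraction = NULL,
                         fiber_wavelength_um = 12,
                         texture_amplitude = 0.18,
                         disorder = 0.05,
                         neo_intima = FALSE,
                         n_vasa = 4L,
                         vasa_diameter_um_range = c(20, 80),
                         rbc_density = 1,
                         speckle_sigma = 0.25,
                         read_noise_sigma = 15,
                         ellipticity = 1,
                         seed = 1L) {
  if (is.null(center_px)) {
    center_px <- (image_size_px + 1) / 2
  }
  if (is.null(layer_mean_intensity)) {
    layer_mean_intensity <- default_layer_means(neo_intima)
  }
  if (is.null(iel_retained_fraction)) {
    iel_retained_fraction <- if (neo_intima) 0.18 else 1
  }
  spec <- structure(list(
    image_size_px = as.integer(image_size_px),
    pixel_size_um = pixel_size_um,
    n_slices = as.integer(n_slices),
    slice_spacing_um = slice_spacing_um,
    center_px = as.numeric(center_px),
    lumen_radius_um = lumen_radius_um,
    intima_thickness_um = intima_thickness_um,
    media_thickness_um = media_thickness_um,
    adventitia_thickness_um = adventitia_thickness_um,
    layer_mean_intensity = layer_mean_intensity,
    iel_width_um = iel_width_um,
    iel_contrast = iel_contrast,
    iel_retained_fraction = iel_retained_fraction,
    fiber_wavelength_um = fiber_wavelength_um,
    texture_amplitude = texture_amplitude,
    disorder = disorder,
    neo_intima = isTRUE(neo_intima),
    n_vasa = as.integer(n_vasa),
    vasa_diameter_um_range = as.numeric(vasa_diameter_um_range),
    rbc_density = rbc_density,
    speckle_sigma = speckle_sigma,
    read_noise_sigma = read_noise_sigma,
    ellipticity = ellipticity,
    seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(s) {
  stopifnot(length(s$image_size_px) == 2, all(s$image_size_px >= 32))
  if (s$pixel_size_um <= 0 || s$slice_spacing_um <= 0) {
    stop("pixel and slice spacings must be strictly positive")
  }
  if (s$n_slices < 1) stop("n_slices must be >= 1")
  th <- c(s$lumen_radius_um, s$intima_thickness_um, s$media_thickness_um,
          s$adventitia_thickness_um, s$iel_width_um, s$fiber_wavelength_um)
  if (any(th <= 0)) stop("all radii and thicknesses must be strictly positive")
  if (s$disorder < 0 || s$disorder > 1) stop("disorder must lie in [0, 1]")
  if (s$iel_contrast < 0 || s$iel_contrast > 1) {
    stop("iel_contrast must lie in [0, 1]")
  }
  rng <- s$vasa_diameter_um_range
  if (length(rng) != 2 || rng[1] > rng[2] || rng[1] < 20 || rng[2] > 80) {
    stop("vasa_diameter_um_range must be an increasing interval within [20, 80] um")
  }
  if (s$n_vasa < 0 || s$rbc_density < 0 || s$speckle_sigma < 0 ||
      s$read_noise_sigma < 0) {
    stop("counts, densities and noise levels must be non-negative")
  }
  if (s$ellipticity <= 0) stop("ellipticity must be strictly positive")
  outer_um <- s$lumen_radius_um + s$intima_thickness_um +
    s$media_thickness_um + s$adventitia_thickness_um
  stretch <- max(s$ellipticity, 1)
  outer_px <- outer_um / s$pixel_size_um
  if (s$center_px[1] - outer_px < 1 ||
      s$center_px[1] + outer_px > s$image_size_px[1] ||
      s$center_px[2] - outer_px * stretch < 1 ||
      s$center_px[2] + outer_px * stretch > s$image_size_px[2]) {
    stop("geometry overflow: lumen plus wall layers exceed the image bounds")
  }
  invisible(s)
}

#' Container for a 3-D intensity stack
#'
#' @param voxels 3-D numeric array (slice, row, col), finite and
#'   non-negative, arbitrary intensity units.
#' @param pixel_size_um,slice_spacing_um physical spacings, micrometers.
#' @return an object of class \code{image_stack}.
#' @export
image_stack <- function(voxels, pixel_size_um, slice_spacing_um) {
  stopifnot(length(dim(voxels)) == 3, dim(voxels)[1] >= 1)
  if (pixel_size_um <= 0 || slice_spacing_um <= 0) {
    stop("spacings must be strictly positive")
  }
  if (!all(is.finite(voxels)) || any(voxels < 0)) {
    stop("voxel intensities must be finite and non-negative")
  }
  structure(list(voxels = voxels, pixel_size_um = pixel_size_um,
                 slice_spacing_um = slice_spacing_um),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d slices of %d x %d px (%.3g um/px, %.3g um between slices)\n",
              d[1], d[2], d[3], x$pixel_size_um, x$slice_spacing_um))
  invisible(x)
}

# Classification of a true I/M ratio into the study's three groups.
true_class_from_ratio <- function(im_ratio) {
  if (im_ratio < 1) "normal" else if (im_ratio <= 2) "hyperplasia" else "gca"
}

#' Generate one synthetic artery-section stack with ground truth
#'
#' Renders the wall as concentric annuli at the specified radii with the
#' specified mean reflectivities, adds oriented band-pass fiber texture
#' (tangential plus wrapped-normal jitter scaled by \code{disorder}, or
#' isotropic reticular texture in the two inner tunicae when
#' \code{neo_intima} is set), the hypo-reflective IEL band, vasa vasorum
#' with red blood cells, and per-slice multiplicative log-normal speckle
#' plus additive read noise. Identical specs (including the seed) reproduce
#' the stack bit-for-bit.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class \code{tab_phantom}: a list with elements
#'   \code{stack} (an [image_stack()]) and \code{truth} (class
#'   \code{wall_ground_truth}: per-pixel \code{label_map}, the true
#'   \code{orientation_field} in degrees mod 180 (NA where undefined), the
#'   true thicknesses, I/M ratio, class and center).
#' @examples
#' ph <- generate_phantom(phantom_spec(image_size_px = c(192, 192),
#'   lumen_radius_um = 30, intima_thickness_um = 20,
#'   media_thickness_um = 50, adventitia_thickness_um = 25,
#'   n_slices = 2, seed = 7))
#' ph$truth$true_im_ratio
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  H <- spec$image_size_px[1]; W <- spec$image_size_px[2]
  px <- spec$pixel_size_um
  cr <- spec$center_px[1]; cc <- spec$center_px[2]
  e <- spec$ellipticity

  dr <- matrix(seq_len(H) - cr, H, W)
  dc <- matrix(seq_len(W) - cc, H, W, byrow = TRUE)
  r_um <- sqrt((dc / e)^2 + dr^2) * px
  theta <- (atan2(dr, dc / e) * 180 / pi) %% 360

  R0 <- spec$lumen_radius_um
  R1 <- R0 + spec$intima_thickness_um
  R2 <- R1 + spec$media_thickness_um
  R3 <- R2 + spec$adventitia_thickness_um
  half_iel <- spec$iel_width_um / 2

  lab <- matrix(WALL_LABELS[["background"]], H, W)
  lab[r_um < R3] <- WALL_LABELS[["adventitia"]]
  lab[r_um < R2] <- WALL_LABELS[["media"]]
  lab[r_um < R1] <- WALL_LABELS[["intima"]]
  lab[r_um < R0] <- WALL_LABELS[["lumen"]]

  # IEL: hypo-reflective band straddling the intima/media interface,
  # possibly fragmented (retained only on a subset of angular arcs).
  iel_band <- abs(r_um - R1) <= half_iel
  if (spec$iel_retained_fraction < 1) {
    n_arcs <- 6L
    arc_len <- spec$iel_retained_fraction * 360 / n_arcs
    starts <- stats::runif(n_arcs, 0, 360)
    keep <- matrix(FALSE, H, W)
    for (a in starts) {
      keep <- keep | ((theta - a) %% 360) < arc_len
    }
    iel_band <- iel_band & keep
  }
  lab[iel_band] <- WALL_LABELS[["iel"]]

  mu <- spec$layer_mean_intensity
  img <- matrix(mu[["background"]], H, W)
  img[lab == WALL_LABELS[["adventitia"]]] <- mu[["adventitia"]]
  img[lab == WALL_LABELS[["media"]]] <- mu[["media"]]
  img[lab == WALL_LABELS[["intima"]]] <- mu[["intima"]]
  img[lab == WALL_LABELS[["lumen"]]] <- mu[["lumen"]]
  img[lab == WALL_LABELS[["iel"]]] <- (1 - spec$iel_contrast) * mu[["intima"]]

  # Oriented fiber texture on the three tunicae, rendered patch-wise in
  # polar coordinates (angular sectors x radial bands) so each patch is a
  # locally planar grating with its own orientation and random phase.
  orient <- matrix(NA_real_, H, W)
  tex_labels <- c(WALL_LABELS[["intima"]], WALL_LABELS[["media"]],
                  WALL_LABELS[["adventitia"]])
  idx <- which(lab %in% tex_labels)
  if (length(idx) > 0 && spec$texture_amplitude > 0) {
    sector_w <- 5.625      # degrees (64 sectors)
    band_h_px <- 16
    band <- floor((r_um[idx] / px) / band_h_px)
    sector <- floor(theta[idx] / sector_w)
    reticular <- spec$neo_intima &
      lab[idx] %in% c(WALL_LABELS[["intima"]], WALL_LABELS[["media"]])
    pid <- paste(band, sector, reticular)
    groups <- split(seq_along(idx), pid)
    groups <- groups[order(names(groups))]
    lambda_px <- spec$fiber_wavelength_um / px
    amp <- spec$texture_amplitude
    jitter_sd <- spec$disorder * 90
    for (g in groups) {
      gi <- idx[g]
      if (reticular[g[1]]) {
        alpha <- stats::runif(1, 0, 180)
        field <- alpha
      } else {
        sector_mid <- (sector[g[1]] + 0.5) * sector_w
        jit <- stats::rnorm(1, 0, jitter_sd)
        alpha <- axial_mod(sector_mid + 90 + jit)
        field <- axial_mod(theta[gi] + 90 + jit)
      }
      phase <- stats::runif(1, 0, 2 * pi)
      beta <- (alpha + 90) * pi / 180
      u <- dc[gi] * cos(beta) + dr[gi] * sin(beta)
      img[gi] <- img[gi] * (1 + amp * cos(2 * pi * u / lambda_px + phase))
      orient[gi] <- field
    }
  } else if (length(idx) > 0) {
    # texture disabled: the field is still defined (tangential) on tunicae
    orient[idx] <- axial_mod(theta[idx] + 90)
  }

  # Vasa vasorum at the media/adventitia junction: hypo-reflective discs
  # with a thin bright rim; red blood cells inside as iso-reflective dots
  # with a hypo-reflective annulus.
  if (spec$n_vasa > 0) {
    v_theta <- stats::runif(spec$n_vasa, 0, 360)
    v_diam <- stats::runif(spec$n_vasa, spec$vasa_diameter_um_range[1],
                           spec$vasa_diameter_um_range[2])
    for (v in seq_len(spec$n_vasa)) {
      vt <- v_theta[v] * pi / 180
      vr <- R2
      vrow <- cr + (vr / px) * sin(vt)
      vcol <- cc + (vr / px) * cos(vt) * e
      d_um <- sqrt(((matrix(seq_len(W), H, W, byrow = TRUE) - vcol) / e)^2 +
                     (matrix(seq_len(H), H, W) - vrow)^2) * px
      rim <- d_um <= v_diam[v] / 2 + 2.5 & d_um > v_diam[v] / 2
      core <- d_um <= v_diam[v] / 2
      img[rim] <- 1800
      img[core] <- 600
      lab[rim | core] <- WALL_LABELS[["vasa"]]
      orient[rim | core] <- NA_real_
      lumen_area <- pi * (v_diam[v] / 2)^2
      n_rbc <- stats::rpois(1, spec$rbc_density * lumen_area / 1000)
      if (n_rbc > 0 && v_diam[v] / 2 > 8) {
        rr <- (v_diam[v] / 2 - 6) * sqrt(stats::runif(n_rbc))
        ra <- stats::runif(n_rbc, 0, 2 * pi)
        for (b in seq_len(n_rbc)) {
          brow <- vrow + (rr[b] / px) * sin(ra[b])
          bcol <- vcol + (rr[b] / px) * cos(ra[b])
          db <- sqrt((matrix(seq_len(W), H, W, byrow = TRUE) - bcol)^2 +
                       (matrix(seq_len(H), H, W) - brow)^2) * px
          ann <- db <= 4 & db > 2.5
          dot <- db <= 2.5
          img[ann] <- 550
          img[dot] <- 1450
          lab[dot] <- WALL_LABELS[["rbc"]]
          orient[ann | dot] <- NA_real_
        }
      }
    }
  }

  img[img < 0] <- 0

  vox <- array(0, dim = c(spec$n_slices, H, W))
  s2 <- spec$speckle_sigma
  for (s in seq_len(spec$n_slices)) {
    slice <- img
    if (s2 > 0) {
      slice <- slice * exp(stats::rnorm(H * W, 0, s2) - s2^2 / 2)
    }
    if (spec$read_noise_sigma > 0) {
      slice <- slice + stats::rnorm(H * W, 0, spec$read_noise_sigma)
    }
    vox[s, , ] <- pmax(slice, 0)
  }

  ratio <- spec$intima_thickness_um / spec$media_thickness_um
  truth <- structure(list(
    label_map = lab,
    orientation_field = orient,
    true_thicknesses_um = c(intima = spec$intima_thickness_um,
                            media = spec$media_thickness_um,
                            adventitia = spec$adventitia_thickness_um),
    true_im_ratio = ratio,
    true_class = true_class_from_ratio(ratio),
    lumen_radius_um = R0,
    center_px = spec$center_px
  ), class = "wall_ground_truth")

  structure(list(
    stack = image_stack(vox, px, spec$slice_spacing_um),
    truth = truth,
    spec = spec
  ), class = "tab_phantom")
}

#' @export
print.tab_phantom <- function(x, ...) {
  cat(sprintf("tab_phantom: class %s, true I/M = %.3f\n",
              x$truth$true_class, x$truth$true_im_ratio))
  print(x$stack)
  invisible(x)
}

#' Default per-class phantom parameter ranges
#'
#' Parameter ranges for the three study groups: thin-intima ("normal",
#' true I/M drawn in [0.3, 0.8]), intimal hyperplasia ([1.2, 1.8]) and
#' GCA-like remodeling ([2.5, 4.0], neo-intima on, fragmented IEL,
#' near-isotropic texture). Geometry ranges are chosen so the thickest
#' admissible wall still fits the default 640 px field of view.
#'
#' @return named list of per-class parameter range lists.
#' @export
default_class_specs <- function() {
  list(
    normal = list(im_range = c(0.3, 0.8), media_range = c(110, 150),
                  lumen_range = c(80, 100), adventitia_range = c(55, 75),
                  neo_intima = FALSE, disorder = 0.05),
    hyperplasia = list(im_range = c(1.2, 1.8), media_range = c(85, 110),
                       lumen_range = c(65, 85), adventitia_range = c(50, 70),
                       neo_intima = FALSE, disorder = 0.05),
    gca = list(im_range = c(2.5, 4.0), media_range = c(45, 62),
               lumen_range = c(45, 60), adventitia_range = c(45, 60),
               neo_intima = TRUE, disorder = 0.9)
  )
}

class_im_bounds <- list(normal = c(0, 1), hyperplasia = c(1, 2),
                        gca = c(2, Inf))

#' Generate a cohort of phantoms across wall classes
#'
#' Draws \code{n_per_class} phantoms for each requested class with true I/M
#' ratios sampled uniformly from the class ranges. Per-phantom seeds are
#' derived deterministically from the master seed by a counter scheme, so
#' extending the cohort never perturbs existing samples.
#'
#' @param n_per_class phantoms per class (>= 1).
#' @param classes character vector among \code{"normal"},
#'   \code{"hyperplasia"}, \code{"gca"}.
#' @param class_specs per-class parameter ranges, see
#'   [default_class_specs()]. Ranges must respect the class I/M bounds
#'   (normal within [0,1), hyperplasia within [1,2], gca above 2).
#' @param seed master seed.
#' @param ... further arguments passed to every [phantom_spec()] call
#'   (e.g. \code{image_size_px}, \code{n_slices}, \code{speckle_sigma}).
#' @return list of \code{tab_phantom} objects with a \code{manifest}
#'   attribute (data frame of true parameters per sample).
#' @export
generate_cohort <- function(n_per_class,
                            classes = c("normal", "hyperplasia", "gca"),
                            class_specs = default_class_specs(),
                            seed = 1L, ...) {
  stopifnot(n_per_class >= 1)
  classes <- match.arg(classes, c("normal", "hyperplasia", "gca"),
                       several.ok = TRUE)
  for (cl in classes) {
    rng <- class_specs[[cl]]$im_range
    bounds <- class_im_bounds[[cl]]
    if (rng[1] < bounds[1] || rng[2] > bounds[2] || rng[1] > rng[2]) {
      stop(sprintf("class '%s' I/M range [%g, %g] violates its bounds (%g, %g]",
                   cl, rng[1], rng[2], bounds[1], bounds[2]))
    }
  }
  out <- list()
  manifest <- NULL
  k <- 0L
  for (cl in classes) {
    cs <- class_specs[[cl]]
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      set.seed(derive_seed(seed, 2L * k))
      ratio <- stats::runif(1, cs$im_range[1], cs$im_range[2])
      media <- stats::runif(1, cs$media_range[1], cs$media_range[2])
      lumen <- stats::runif(1, cs$lumen_range[1], cs$lumen_range[2])
      advent <- stats::runif(1, cs$adventitia_range[1], cs$adventitia_range[2])
      sp <- phantom_spec(
        lumen_radius_um = lumen,
        intima_thickness_um = ratio * media,
        media_thickness_um = media,
        adventitia_thickness_um = advent,
        neo_intima = cs$neo_intima,
        disorder = cs$disorder,
        seed = derive_seed(seed, 2L * k + 1L),
        ...
      )
      out[[k]] <- generate_phantom(sp)
      manifest <- rbind(manifest, data.frame(
        sample_id = sprintf("%s_%02d", cl, i),
        class = cl,
        seed = sp$seed,
        true_im_ratio = ratio,
        lumen_radius_um = lumen,
        intima_um = ratio * media,
        media_um = media,
        adventitia_um = advent,
        stringsAsFactors = FALSE
      ))
    }
  }
  names(out) <- manifest$sample_id
  attr(out, "manifest") <- manifest
  out
}
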