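# TIFF/PNG/JSON input-output. Stacks travel as multi-page 16-bit TIFF with
# a JSON sidecar recording physical spacings and the linear intensity
# scaling; orientation maps as 2-page scaled 16-bit TIFF.

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image stack as multi-page 16-bit TIFF
#'
#' Intensities are linearly mapped to the 16-bit range; the scale and the
#' physical spacings are recorded in a JSON sidecar next to the TIFF.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  v <- stack$voxels
  scale <- max(v, 1e-12)
  pages <- lapply(seq_len(dim(v)[1]), function(s) v[s, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(intensity_scale = scale,
                            pixel_size_um = stack$pixel_size_um,
                            slice_spacing_um = stack$slice_spacing_um),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' @param path TIFF path; a JSON sidecar written by [write_stack_tiff()]
#'   restores intensity scaling and spacings when present.
#' @param pixel_size_um,slice_spacing_um spacings used when no sidecar is
#'   found.
#' @return an [image_stack()].
#' @export
read_stack_tiff <- function(path, pixel_size_um = 1.5,
                            slice_spacing_um = 1.5) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- 1
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    scale <- meta$intensity_scale %||% 1
    pixel_size_um <- meta$pixel_size_um %||% pixel_size_um
    slice_spacing_um <- meta$slice_spacing_um %||% slice_spacing_um
  }
  v <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (s in seq_along(pages)) v[s, , ] <- pages[[s]] * scale
  image_stack(v, pixel_size_um, slice_spacing_um)
}

#' Write a section as single-page 16-bit TIFF (with JSON sidecar)
#'
#' @param section a [section_2d()].
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_section_tiff <- function(section, path) {
  scale <- max(section$pixels, 1e-12)
  tiff::writeTIFF(section$pixels / scale, path, bits.per.sample = 16L,
                  compression = "none")
  jsonlite::write_json(list(intensity_scale = scale,
                            pixel_size_um = section$pixel_size_um,
                            provenance = section$provenance),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a single-page TIFF section
#'
#' @param path TIFF path (JSON sidecar restores scale and pixel size).
#' @param pixel_size_um fallback pixel size without a sidecar.
#' @return a [section_2d()].
#' @export
read_section_tiff <- function(path, pixel_size_um = 1.5) {
  px <- tiff::readTIFF(path)
  scale <- 1
  prov <- list(n_slices_used = 1L, projection_method = "unknown")
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    scale <- meta$intensity_scale %||% 1
    pixel_size_um <- meta$pixel_size_um %||% pixel_size_um
    if (!is.null(meta$provenance)) prov <- meta$provenance
  }
  section_2d(px * scale, pixel_size_um, prov)
}

#' Write an orientation map as a 2-page 16-bit TIFF
#'
#' Page 1 holds the angle in centidegrees (angle * 100), page 2 the
#' confidence scaled by 10000; undefined pixels store 65535 in the angle
#' page. Scalings are recorded in the JSON sidecar.
#'
#' @param map an \code{orientation_map}.
#' @param path output TIFF path.
#' @param png_path optional path for a PNG rendering
#'   (see [render_orientation()]).
#' @return \code{path}, invisibly.
#' @export
write_orientation_tiff <- function(map, path, png_path = NULL) {
  a <- map$angle_deg
  undef <- is.na(a)
  a_page <- round(a * 100)
  a_page[undef] <- 65535
  c_page <- round(map$confidence * 10000)
  tiff::writeTIFF(list(a_page / 65535, c_page / 65535), path,
                  bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(angle_scale = 100, confidence_scale = 10000,
                            undefined_value = 65535),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  if (!is.null(png_path)) {
    png::writePNG(render_orientation(map), png_path)
  }
  invisible(path)
}

#' Read an orientation map written by [write_orientation_tiff()]
#'
#' @param path TIFF path.
#' @return an \code{orientation_map}.
#' @export
read_orientation_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  a <- round(pages[[1]] * 65535)
  conf <- round(pages[[2]] * 65535) / 10000
  ang <- a / 100
  ang[a == 65535] <- NA_real_
  conf[a == 65535] <- 0
  as_orientation_map(ang, conf)
}
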