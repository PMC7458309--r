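# Axial reconstruction: collapse a depth stack into a single en-face
# section by pixel-wise z-projection.

#' Construct a 2-D en-face section
#'
#' @param pixels 2-D non-negative numeric matrix.
#' @param pixel_size_um in-plane pixel size, micrometers.
#' @param provenance list recording at least \code{n_slices_used} and
#'   \code{projection_method}.
#' @return object of class \code{section_2d}.
#' @export
section_2d <- function(pixels, pixel_size_um,
                       provenance = list(n_slices_used = 1L,
                                         projection_method = "none")) {
  stopifnot(is.matrix(pixels), pixel_size_um > 0)
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 provenance = provenance),
            class = "section_2d")
}

#' @export
print.section_2d <- function(x, ...) {
  cat(sprintf("section_2d: %d x %d px (%.3g um/px), %s projection of %d slices\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              x$provenance$projection_method, x$provenance$n_slices_used))
  invisible(x)
}

#' Display a section as a grayscale image
#'
#' @param x a \code{section_2d}.
#' @param ... passed to [graphics::image()].
#' @export
plot.section_2d <- function(x, ...) {
  p <- x$pixels
  graphics::image(t(p[nrow(p):1, ]), col = grDevices::gray.colors(256),
                  asp = nrow(p) / ncol(p), axes = FALSE, ...)
  invisible(x)
}

#' Z-project an image stack into an en-face section
#'
#' Pixel-wise projection of the selected depth slices. Averaging at least
#' 20 slices is the recommended acquisition practice; projecting fewer
#' raises a warning (not an error).
#'
#' @param stack an [image_stack()].
#' @param method projection statistic: \code{"mean"} (default; averages
#'   speckle and so sharpens the radial plateau structure), \code{"max"} or
#'   \code{"median"}.
#' @param slice_range optional integer pair (first, last) selecting a
#'   contiguous slice interval; default all slices.
#' @return a [section_2d()] with provenance recording the number of slices
#'   and method used.
#' @examples
#' st <- image_stack(array(rep(c(0, 1), each = 4), c(2, 2, 2)), 1, 1)
#' zproject(st, "mean")$pixels   # constant 0.5
#' @export
zproject <- function(stack, method = c("mean", "max", "median"),
                     slice_range = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "image_stack"))
  n <- dim(stack$voxels)[1]
  if (is.null(slice_range)) {
    sel <- seq_len(n)
  } else {
    stopifnot(length(slice_range) == 2)
    if (slice_range[1] > slice_range[2] || slice_range[1] < 1 ||
        slice_range[2] > n) {
      stop("slice_range must be a non-empty interval within the stack")
    }
    sel <- seq.int(slice_range[1], slice_range[2])
  }
  if (length(sel) < 20) {
    warning(sprintf("projecting %d slices; at least 20 are recommended",
                    length(sel)))
  }
  v <- stack$voxels[sel, , , drop = FALSE]
  px <- switch(method,
    mean = colMeans(v, dims = 1),
    max = {
      m <- v[1, , ]
      for (s in seq_along(sel)[-1]) m <- pmax(m, v[s, , ])
      m
    },
    median = apply(v, c(2, 3), stats::median)
  )
  section_2d(px, stack$pixel_size_um,
             provenance = list(n_slices_used = length(sel),
                               projection_method = method))
}
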