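# Fiber orientation mapping with a Gabor filter bank: per-pixel dominant
# axial (mod-180) orientation with a confidence derived from doubled-angle
# circular statistics of the orientation-response distribution.

#' Gabor filter-bank specification
#'
#' @param n_orientations number of orientations sampling [0, 180)
#'   uniformly (default 18, i.e. 10-degree steps).
#' @param wavelengths_um carrier wavelengths in micrometers (default
#'   6, 12, 24); responses are max-pooled across wavelengths.
#' @param bandwidth_octaves spatial-frequency bandwidth (default 1);
#'   fixes the Gaussian envelope width relative to the wavelength.
#' @param envelope_aspect ratio of the envelope width across the stripes
#'   to the width along them (default 0.5: elongated along the stripes).
#' @return object of class \code{gabor_bank}.
#' @export
gabor_bank <- function(n_orientations = 18L, wavelengths_um = c(6, 12, 24),
                       bandwidth_octaves = 1, envelope_aspect = 0.5) {
  stopifnot(n_orientations >= 4, all(wavelengths_um > 0),
            bandwidth_octaves > 0, envelope_aspect > 0)
  structure(list(n_orientations = as.integer(n_orientations),
                 wavelengths_um = wavelengths_um,
                 bandwidth_octaves = bandwidth_octaves,
                 envelope_aspect = envelope_aspect),
            class = "gabor_bank")
}

# sigma of the Gaussian envelope across the stripes, from the octave
# bandwidth (standard Gabor relation).
gabor_sigma <- function(lambda, b) {
  lambda / pi * sqrt(log(2) / 2) * (2^b + 1) / (2^b - 1)
}

# Complex Gabor kernel pair for stripes oriented at theta_deg (the filter
# responds maximally to texture whose stripes run along theta_deg).
gabor_kernel <- function(lambda_px, theta_deg, bandwidth_octaves,
                         envelope_aspect) {
  su <- gabor_sigma(lambda_px, bandwidth_octaves)   # across stripes
  sv <- su / envelope_aspect                        # along stripes
  half <- ceiling(max(2.5 * su, 1.5 * sv))
  g <- seq(-half, half)
  x <- matrix(g, length(g), length(g), byrow = TRUE)  # col offset
  y <- matrix(g, length(g), length(g))                # row offset
  b <- (theta_deg + 90) * pi / 180    # modulation direction, across stripes
  u <- x * cos(b) + y * sin(b)
  v <- -x * sin(b) + y * cos(b)
  env <- exp(-(u^2 / (2 * su^2) + v^2 / (2 * sv^2)))
  even <- env * cos(2 * pi * u / lambda_px)
  even <- even - mean(even)           # zero DC response
  odd <- env * sin(2 * pi * u / lambda_px)
  list(even = even, odd = odd, half = half)
}

gabor_max_half <- function(bank, pixel_size_um) {
  max(vapply(bank$wavelengths_um / pixel_size_um, function(l) {
    su <- gabor_sigma(l, bank$bandwidth_octaves)
    ceiling(max(2.5 * su, 1.5 * su / bank$envelope_aspect))
  }, numeric(1)))
}

pad_reflect <- function(m, p) {
  ri <- c(seq.int(p + 1, 2, -1), seq_len(nrow(m)),
          seq.int(nrow(m) - 1, nrow(m) - p))
  ci <- c(seq.int(p + 1, 2, -1), seq_len(ncol(m)),
          seq.int(ncol(m) - 1, ncol(m) - p))
  m[ri, ci]
}

#' Construct an orientation map from explicit angle and confidence arrays
#'
#' Mostly useful for constructing reference fields (e.g. a phantom's true
#' orientation field) to score with [symmetry_score()].
#'
#' @param angle_deg 2-D array of axial angles; values outside [0, 180) are
#'   reduced mod 180; NA marks undefined pixels.
#' @param confidence matching 2-D array in [0, 1], or a scalar.
#' @param bank optional [gabor_bank()] echo.
#' @return object of class \code{orientation_map}.
#' @export
as_orientation_map <- function(angle_deg, confidence = 1, bank = NULL) {
  stopifnot(is.matrix(angle_deg))
  if (length(confidence) == 1) {
    confidence <- matrix(confidence, nrow(angle_deg), ncol(angle_deg))
  }
  stopifnot(all(dim(confidence) == dim(angle_deg)))
  a <- axial_mod(angle_deg)
  confidence[is.na(a)] <- 0
  a[confidence <= 0] <- NA_real_
  structure(list(angle_deg = a, confidence = confidence, bank = bank),
            class = "orientation_map")
}

#' Per-pixel dominant fiber orientation by Gabor filtering
#'
#' For every pixel, filter-magnitude responses are computed at each bank
#' orientation (quadrature pair, FFT convolution with reflective padding)
#' and max-pooled over wavelengths. The dominant angle is the argmax
#' orientation refined by three-point quadratic interpolation, so results
#' are not quantized to the bank's angular step. Confidence is the
#' resultant length of the response mass in doubled-angle space (1 =
#' sharply tuned, 0 = isotropic response). Pixels whose peak response
#' falls below \code{confidence_floor} times the image's maximum response,
#' and pixels within half the filter support of the border, are undefined.
#'
#' @param section a [section_2d()].
#' @param bank a [gabor_bank()].
#' @param confidence_floor relative response-energy floor in [0, 1).
#' @return object of class \code{orientation_map} with fields
#'   \code{angle_deg} (degrees in [0, 180), NA undefined),
#'   \code{confidence} in [0, 1] (0 where undefined), \code{bank}.
#' @export
orientation_map <- function(section, bank = gabor_bank(),
                            confidence_floor = 0.05) {
  img <- section$pixels
  H <- nrow(img); W <- ncol(img)
  P <- gabor_max_half(bank, section$pixel_size_um)
  if (min(H, W) <= 2 * P + 1) {
    stop(sprintf("section (%d x %d) smaller than the largest filter support (%d px)",
                 H, W, 2 * P + 1))
  }
  K <- bank$n_orientations
  thetas <- seq(0, 180, length.out = K + 1L)[seq_len(K)]
  padded <- pad_reflect(img, P)
  M <- matrix(0, H * W, K)
  for (k in seq_len(K)) {
    resp <- NULL
    for (lam in bank$wavelengths_um / section$pixel_size_um) {
      kr <- gabor_kernel(lam, thetas[k], bank$bandwidth_octaves,
                         bank$envelope_aspect)
      fe <- EBImage::filter2(padded, kr$even, boundary = "circular")
      fo <- EBImage::filter2(padded, kr$odd, boundary = "circular")
      mag <- sqrt(as.matrix(fe)^2 + as.matrix(fo)^2)
      mag <- mag[seq.int(P + 1, P + H), seq.int(P + 1, P + W)]
      resp <- if (is.null(resp)) mag else pmax(resp, mag)
    }
    M[, k] <- resp
  }
  peak <- do.call(pmax, lapply(seq_len(K), function(k) M[, k]))
  rngI <- diff(range(img))
  gmax <- max(peak)
  defined <- if (rngI <= 0 || gmax <= 0) rep(FALSE, H * W) else
    peak >= confidence_floor * gmax & peak > 0
  # border of half the filter support is undefined
  bm <- matrix(TRUE, H, W)
  bm[seq_len(P), ] <- FALSE; bm[seq.int(H - P + 1, H), ] <- FALSE
  bm[, seq_len(P)] <- FALSE; bm[, seq.int(W - P + 1, W)] <- FALSE
  defined <- defined & as.vector(bm)

  kmax <- max.col(M, ties.method = "first")
  step <- 180 / K
  idx <- cbind(seq_len(H * W), kmax)
  r0 <- M[idx]
  km <- ifelse(kmax == 1L, K, kmax - 1L)
  kp <- ifelse(kmax == K, 1L, kmax + 1L)
  rm <- M[cbind(seq_len(H * W), km)]
  rp <- M[cbind(seq_len(H * W), kp)]
  den <- rm - 2 * r0 + rp
  delta <- ifelse(abs(den) > .Machine$double.eps * pmax(r0, 1),
                  0.5 * (rm - rp) / den, 0)
  delta <- pmax(pmin(delta, 0.5), -0.5)
  ang <- axial_mod(thetas[kmax] + delta * step)

  t2 <- thetas * pi / 90            # doubled angles in radians
  sM <- rowSums(M)
  num <- sqrt((M %*% cos(t2))^2 + (M %*% sin(t2))^2)
  conf <- as.vector(ifelse(sM > 0, num / sM, 0))
  conf <- pmax(pmin(conf, 1), 0)

  ang[!defined] <- NA_real_
  conf[!defined] <- 0
  structure(list(angle_deg = matrix(ang, H, W),
                 confidence = matrix(conf, H, W),
                 bank = bank),
            class = "orientation_map")
}

#' @export
print.orientation_map <- function(x, ...) {
  nd <- sum(!is.na(x$angle_deg))
  cat(sprintf("orientation_map: %d x %d px, %d defined pixels (%.1f%%), mean confidence %.3f\n",
              nrow(x$angle_deg), ncol(x$angle_deg), nd,
              100 * nd / length(x$angle_deg),
              mean(x$confidence[!is.na(x$angle_deg)])))
  invisible(x)
}

# vectorized HSV -> RGB (h, s, v in [0,1]); returns list(r, g, b)
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
         ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
         ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
         ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

#' Render an orientation map as a color image
#'
#' Cyclic hue encodes the axial angle (hue = angle / 180), brightness
#' encodes confidence, undefined pixels are black. Because hue is a
#' function of the mod-180 angle alone, antipodal points of a perfectly
#' tangential field receive identical hue — the paired-color appearance of
#' an intact circularly symmetric wall. The mapping is deterministic.
#'
#' @param map an \code{orientation_map}.
#' @return numeric array (rows x cols x 3) of RGB values in [0, 1].
#' @export
render_orientation <- function(map) {
  a <- map$angle_deg
  conf <- map$confidence
  h <- a / 180
  v <- conf
  undef <- is.na(a)
  h[undef] <- 0; v[undef] <- 0
  rgb <- hsv_to_rgb(as.vector(h), 1, as.vector(v))
  out <- array(0, dim = c(nrow(a), ncol(a), 3))
  out[, , 1] <- rgb$r; out[, , 2] <- rgb$g; out[, , 3] <- rgb$b
  out
}

#' @export
plot.orientation_map <- function(x, ...) {
  img <- render_orientation(x)
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = dim(img)[1] / dim(img)[2])
  graphics::rasterImage(grDevices::as.raster(img), 0, 0, 1, 1)
  invisible(x)
}
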