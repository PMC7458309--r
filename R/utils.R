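# Internal helpers shared across modules: axial-angle arithmetic, bilinear
# sampling, boxcar smoothing and deterministic seed derivation.

#' Axial (mod-180) angular distance
#'
#' Distance between two orientations of undirected lines, in degrees.
#' Orientations are equivalent mod 180, so the distance lies in [0, 90].
#'
#' @param a,b numeric vectors of angles in degrees.
#' @return numeric vector of distances in degrees, in [0, 90].
#' @export
axial_distance <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Reduce any angle (degrees) to the axial range [0, 180).
axial_mod <- function(a) {
  a <- a %% 180
  neg <- !is.na(a) & a < 0
  a[neg] <- a[neg] + 180
  a
}

# Bilinear interpolation of a matrix at continuous (row, col) coordinates
# (1-based, pixel centers at integers). Points outside the image return NA.
bilinear <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(NA_real_, length(r))
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- r0 + (c0 - 1) * nr
  v <- img[i00] * (1 - fr) * (1 - fc) +
    img[i00 + 1] * fr * (1 - fc) +
    img[i00 + nr] * (1 - fr) * fc +
    img[i00 + nr + 1] * fr * fc
  out[ok] <- v
  out
}

# Centered boxcar (moving-average) smoothing; the window shrinks at the ends
# so the output keeps the input length. w is the full window in samples.
boxcar <- function(x, w) {
  n <- length(x)
  if (w <= 1 || n < 2) return(x)
  h <- floor(w / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Deterministic per-sample seed derivation from a master seed: extensible
# (sample i's seed never depends on how many samples follow) and kept
# within the 32-bit integer range.
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) + as.numeric(i) * 7919) %% 2147483629 + 1)
}

# Wrapped-normal draw on the axial circle: tangent +/- jitter, degrees.
rwrapped_axial <- function(n, mean_deg, sd_deg) {
  axial_mod(stats::rnorm(n, mean_deg, sd_deg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
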