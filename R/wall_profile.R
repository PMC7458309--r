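# Contrast-based wall quantification: lumen center estimation, radial
# plot profiles, tunica boundary detection from contrast ruptures, layer
# thickness measurement and I/M classification.

#' I/M classification bounds
#'
#' The intima-to-media ratio groups: normal on [0, 1), intimal hyperplasia
#' on [1, 2] (closed at both ends), GCA-like on (2, Inf). Centralized so the
#' endpoint convention lives in one place.
#'
#' @export
IM_CLASS_BOUNDS <- list(normal = c(0, 1), hyperplasia = c(1, 2),
                        gca_like = c(2, Inf))

#' Classify an intima-to-media ratio
#'
#' @param im_ratio non-negative ratio, or \code{NA} when the wall could not
#'   be quantified.
#' @return one of \code{"normal"}, \code{"hyperplasia"}, \code{"gca_like"},
#'   \code{"unquantifiable"}.
#' @examples
#' classify_im(0.5)   # normal
#' classify_im(1.5)   # hyperplasia
#' classify_im(3.0)   # gca_like
#' @export
classify_im <- function(im_ratio) {
  if (length(im_ratio) != 1) {
    return(vapply(im_ratio, classify_im, character(1)))
  }
  if (is.na(im_ratio)) return("unquantifiable")
  if (im_ratio < 0) stop("im_ratio must be non-negative")
  if (im_ratio < IM_CLASS_BOUNDS$normal[2]) "normal"
  else if (im_ratio <= IM_CLASS_BOUNDS$hyperplasia[2]) "hyperplasia"
  else "gca_like"
}

#' Estimate the lumen center of a section
#'
#' The lumen is hypo-reflective: the estimate is the centroid of the
#' largest connected low-intensity region that does not touch the image
#' border (the background does), refined by a sub-pixel grid search that
#' minimizes the angular intensity variance over concentric annuli
#' (a circularly symmetric wall is angularly homogeneous about its true
#' center).
#'
#' @param section a [section_2d()].
#' @param refine logical; perform the sub-pixel annular refinement.
#' @return numeric pair, (row, col) center in 1-based pixel coordinates.
#' @export
estimate_center <- function(section, refine = TRUE) {
  img <- section$pixels
  rng <- range(img)
  if (diff(rng) <= 0) stop("section is constant; center undetectable")
  thr <- tryCatch(EBImage::otsu(EBImage::Image((img - rng[1]) / diff(rng))),
                  error = function(e) 0.5)
  mask <- (img - rng[1]) / diff(rng) < thr
  labs <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- EBImage::imageData(labs)
  border_labels <- unique(c(labm[1, ], labm[nrow(labm), ],
                            labm[, 1], labm[, ncol(labm)]))
  tab <- tabulate(labm[labm > 0])
  tab[intersect(border_labels, seq_along(tab))] <- 0L
  if (all(tab == 0)) {
    stop("no interior low-intensity region found; center undetectable")
  }
  lumen_lab <- which.max(tab)
  idx <- which(labm == lumen_lab, arr.ind = TRUE)
  ctr <- colMeans(idx)
  if (refine) {
    rmax <- min(ctr[1] - 1, nrow(img) - ctr[1],
                ctr[2] - 1, ncol(img) - ctr[2])
    radii <- seq(0.25, 0.8, length.out = 12) * rmax
    ang <- seq(0, 2 * pi, length.out = 37)[-37]
    score <- function(cr, cc) {
      s <- 0
      for (rr in radii) {
        v <- bilinear(img, cr + rr * sin(ang), cc + rr * cos(ang))
        s <- s + stats::var(v, na.rm = TRUE)
      }
      s
    }
    grid <- expand.grid(dr = seq(-1.5, 1.5, by = 0.5),
                        dc = seq(-1.5, 1.5, by = 0.5))
    sc <- mapply(function(a, b) score(ctr[1] + a, ctr[2] + b),
                 grid$dr, grid$dc)
    best <- which.min(sc)
    ctr <- c(ctr[1] + grid$dr[best], ctr[2] + grid$dc[best])
  }
  unname(ctr)
}

#' Extract a radial intensity profile
#'
#' Samples the section by bilinear interpolation along the ray from the
#' center toward \code{angle_deg}, at one-pixel steps until the image
#' border, then applies boxcar smoothing over the stated window.
#'
#' @param section a [section_2d()].
#' @param center (row, col) center, inside the image.
#' @param angle_deg ray direction in degrees in [0, 360), measured from the
#'   +col axis toward +row.
#' @param smoothing_window_um full boxcar window in micrometers; 0 returns
#'   the raw interpolated samples.
#' @return object of class \code{radial_profile} with fields
#'   \code{radii_um}, \code{intensity}, \code{angle_deg},
#'   \code{smoothing_window_um}.
#' @export
radial_profile <- function(section, center, angle_deg,
                           smoothing_window_um = 6) {
  img <- section$pixels
  if (center[1] < 1 || center[1] > nrow(img) ||
      center[2] < 1 || center[2] > ncol(img)) {
    stop("center lies outside the image")
  }
  a <- angle_deg * pi / 180
  dr <- sin(a); dc <- cos(a)
  # steps until the ray exits the image
  tmax_r <- if (abs(dr) < 1e-12) Inf else
    if (dr > 0) (nrow(img) - center[1]) / dr else (1 - center[1]) / dr
  tmax_c <- if (abs(dc) < 1e-12) Inf else
    if (dc > 0) (ncol(img) - center[2]) / dc else (1 - center[2]) / dc
  tmax <- floor(min(tmax_r, tmax_c))
  t <- seq(0, max(tmax, 1))
  val <- bilinear(img, center[1] + t * dr, center[2] + t * dc)
  keep <- !is.na(val)
  t <- t[keep]; val <- val[keep]
  w <- round(smoothing_window_um / section$pixel_size_um)
  if (w > 1) val <- boxcar(val, w)
  structure(list(angle_deg = angle_deg %% 360,
                 radii_um = t * section$pixel_size_um,
                 intensity = val,
                 smoothing_window_um = smoothing_window_um,
                 pixel_size_um = section$pixel_size_um),
            class = "radial_profile")
}

#' @export
plot.radial_profile <- function(x, ...) {
  graphics::plot(x$radii_um, x$intensity, type = "l",
                 xlab = "radius (um)", ylab = "intensity (a.u.)", ...)
  invisible(x)
}

undetectable_boundaries <- function() {
  structure(list(lumen_edge_um = NA_real_, iel_um = NA_real_,
                 media_adventitia_um = NA_real_, outer_edge_um = NA_real_,
                 confidence = c(lumen_edge = 0, iel = 0,
                                media_adventitia = 0, outer_edge = 0)),
            class = "boundary_set")
}

#' Detect tunica boundaries on a radial profile
#'
#' Boundaries are placed at contrast ruptures: local extrema of the
#' smoothed profile's finite-difference jump whose magnitude exceeds
#' \code{min_jump_fraction} of the profile's dynamic range. The lumen edge
#' is the first upward rupture; the IEL is the hypo-reflective dip between
#' the lumen edge and the outer wall (when deep enough); the
#' media/adventitia boundary is the strongest remaining qualifying rupture
#' between the IEL (or lumen edge) and the outer edge; the outer edge is
#' the last downward rupture to background. Each boundary carries a
#' confidence equal to its jump magnitude relative to the dynamic range;
#' boundaries failing the threshold are flagged undetectable (NA) rather
#' than raising an error — profiles through remodeled GCA walls routinely
#' show no quantifiable layering.
#'
#' @param profile a [radial_profile()] with at least 16 samples.
#' @param min_jump_fraction rupture threshold as a fraction of the
#'   profile's max minus min (default 0.15).
#' @param min_dip_fraction IEL dip criterion: the dip bottom must undercut
#'   the median level of its flanking plateaus by at least this fraction
#'   of that level (default 0.25) — a scale-free test that the shallow
#'   periodic dips of fiber texture fail.
#' @return object of class \code{boundary_set}: radial positions (um) of
#'   \code{lumen_edge_um}, \code{iel_um}, \code{media_adventitia_um},
#'   \code{outer_edge_um} (NA when undetectable) with per-boundary
#'   confidences in [0, 1].
#' @export
detect_boundaries <- function(profile, min_jump_fraction = 0.15,
                              min_dip_fraction = 0.25) {
  y <- profile$intensity
  r <- profile$radii_um
  n <- length(y)
  if (n < 16) stop("profile must have at least 16 samples")
  rng <- max(y) - min(y)
  if (rng <= 0) return(undetectable_boundaries())
  px <- profile$pixel_size_um %||% diff(r[1:2])
  h <- max(2L, round((profile$smoothing_window_um / px) / 2))
  i <- seq.int(h + 1L, n - h)
  jump <- y[i + h] - y[i - h]
  thr <- min_jump_fraction * rng
  aj <- abs(jump)
  # local maxima of |jump| above threshold, flat-top safe
  loc <- which(aj >= thr &
                 aj >= c(-Inf, aj[-length(aj)]) &
                 aj > c(aj[-1], -Inf))
  if (length(loc) == 0) return(undetectable_boundaries())
  pos <- i[loc]                     # sample index of each rupture
  jmp <- jump[loc]
  # merge ruptures closer than h samples, keeping the strongest
  keep <- rep(TRUE, length(pos))
  o <- order(-abs(jmp))
  taken <- integer(0)
  for (k in o) {
    if (any(abs(pos[k] - taken) <= h)) keep[k] <- FALSE else
      taken <- c(taken, pos[k])
  }
  pos <- pos[keep]; jmp <- jmp[keep]
  ord <- order(pos)
  pos <- pos[ord]; jmp <- jmp[ord]

  out <- undetectable_boundaries()
  up <- which(jmp > 0)
  if (length(up) == 0) return(out)
  i_lumen <- pos[up[1]]
  out$lumen_edge_um <- r[i_lumen]
  out$confidence["lumen_edge"] <- min(abs(jmp[up[1]]) / rng, 1)

  down_after <- which(jmp < 0 & pos > i_lumen)
  i_outer <- NA_integer_
  if (length(down_after) > 0) {
    i_outer <- pos[down_after[length(down_after)]]
    out$outer_edge_um <- r[i_outer]
    out$confidence["outer_edge"] <-
      min(abs(jmp[down_after[length(down_after)]]) / rng, 1)
  }

  # IEL dip: deepest local minimum between the lumen edge and the outer
  # edge (or profile end), judged against the plateaus on both sides.
  i_hi <- if (is.na(i_outer)) n - h else i_outer
  dip_idx <- NA_integer_
  dip_halfwidth <- 0L
  if (i_hi - i_lumen > 4 * h) {
    seg <- seq.int(i_lumen + h, i_hi - h)
    ys <- y[seg]
    # local minima, innermost first: the IEL is the *first* qualifying
    # hypo-reflective band after the lumen edge (vasa vasorum dips sit
    # further out, at the media/adventitia junction)
    mins <- seg[which(ys <= c(Inf, ys[-length(ys)]) &
                        ys < c(ys[-1], Inf))]
    # the IEL dip must clearly undercut the *typical* (median) level of
    # its flanking plateaus, by a fraction of that level: a scale-free
    # criterion that fiber-texture dips (modulation-depth sized) fail and
    # a genuinely hypo-reflective band passes
    for (i_min in mins) {
      lw0 <- max(i_min - 5L * h, i_lumen); lw1 <- max(i_min - h, i_lumen)
      rw0 <- min(i_min + h, i_hi); rw1 <- min(i_min + 5L * h, i_hi)
      left_lvl <- stats::median(y[seq.int(lw0, lw1)])
      right_lvl <- stats::median(y[seq.int(rw0, rw1)])
      flank <- min(left_lvl, right_lvl)
      depth <- flank - y[i_min]
      if (flank > 0 && depth >= min_dip_fraction * flank) {
        dip_idx <- i_min
        out$iel_um <- r[i_min]
        out$confidence["iel"] <- min(depth / rng, 1)
        half_level <- y[i_min] + depth / 2
        lw <- i_min; while (lw > i_lumen && y[lw] < half_level) lw <- lw - 1L
        rw <- i_min; while (rw < i_hi && y[rw] < half_level) rw <- rw + 1L
        dip_halfwidth <- max(i_min - lw, rw - i_min)
        break
      }
    }
  }

  # media/adventitia: strongest qualifying rupture strictly between the
  # IEL dip (or lumen edge) and the outer edge, excluding the dip's own
  # flanks and the outer edge itself.
  lo_bound <- if (is.na(dip_idx)) i_lumen else dip_idx
  excl <- max(2L * h, 2L * dip_halfwidth)
  cand <- which(pos > lo_bound + (if (is.na(dip_idx)) h else excl) &
                  (if (is.na(i_outer)) TRUE else pos < i_outer - h))
  if (!is.na(dip_idx)) {
    cand <- cand[abs(pos[cand] - dip_idx) > excl]
  }
  if (length(cand) > 0) {
    best <- cand[which.max(abs(jmp[cand]))]
    out$media_adventitia_um <- r[pos[best]]
    out$confidence["media_adventitia"] <- min(abs(jmp[best]) / rng, 1)
  }

  # enforce ordering: lumen < iel < media/adv < outer where defined
  b <- c(out$lumen_edge_um, out$iel_um, out$media_adventitia_um,
         out$outer_edge_um)
  defd <- which(!is.na(b))
  if (any(diff(b[defd]) <= 0)) {
    bad <- defd[-1][diff(b[defd]) <= 0]
    nm <- c("lumen_edge", "iel", "media_adventitia", "outer_edge")[bad]
    for (j in seq_along(bad)) {
      out[[paste0(nm[j], "_um")]] <- NA_real_
      out$confidence[nm[j]] <- 0
    }
  }
  out
}

#' @export
print.boundary_set <- function(x, ...) {
  cat("boundary_set (radial positions, um):\n")
  for (nm in c("lumen_edge", "iel", "media_adventitia", "outer_edge")) {
    v <- x[[paste0(nm, "_um")]]
    cat(sprintf("  %-17s %s (confidence %.2f)\n", nm,
                if (is.na(v)) "undetectable" else sprintf("%7.1f", v),
                x$confidence[[nm]]))
  }
  invisible(x)
}

#' Measure tunica thicknesses and the I/M ratio of a section
#'
#' Casts radial profiles at 64 equally spaced angles, detects boundaries on
#' each, keeps the \code{n_profiles} most confident complete profiles
#' (or fixed angles), and averages the per-tunica thicknesses: intima =
#' IEL - lumen edge, media = media/adventitia - IEL, adventitia = outer
#' edge - media/adventitia. The reported thicknesses are the means over the
#' selected profiles (three representative measurements by default). When
#' fewer than \code{n_profiles} angles yield complete boundaries the
#' section is classed \code{unquantifiable}.
#'
#' @param section a [section_2d()].
#' @param center (row, col) lumen center; default [estimate_center()].
#' @param n_profiles number of representative profiles to average
#'   (default 3).
#' @param selection \code{"best_confidence"} (default: top angles by their
#'   minimum boundary confidence) or \code{"fixed_angles"} (0, 120, 240
#'   degrees for \code{n_profiles = 3}; equally spaced otherwise).
#' @param n_angles number of candidate angles scanned (default 64).
#' @param smoothing_window_um,min_jump_fraction,min_dip_fraction passed to
#'   [radial_profile()] and [detect_boundaries()].
#' @return object of class \code{layer_measurement}: mean thicknesses (um),
#'   \code{im_ratio} (NA when unquantifiable), \code{class_label},
#'   \code{n_profiles_used}, the center used, and the per-angle boundary
#'   table in \code{angle_table}.
#' @export
measure_layers <- function(section, center = NULL, n_profiles = 3L,
                           selection = c("best_confidence", "fixed_angles"),
                           n_angles = 64L, smoothing_window_um = 6,
                           min_jump_fraction = 0.15,
                           min_dip_fraction = 0.25) {
  selection <- match.arg(selection)
  stopifnot(n_profiles >= 1)
  if (is.null(center)) center <- estimate_center(section)
  angles <- seq(0, 360, length.out = n_angles + 1L)[seq_len(n_angles)]
  rows <- vector("list", n_angles)
  for (k in seq_len(n_angles)) {
    prof <- radial_profile(section, center, angles[k], smoothing_window_um)
    bs <- if (length(prof$intensity) >= 16) {
      detect_boundaries(prof, min_jump_fraction, min_dip_fraction)
    } else undetectable_boundaries()
    rows[[k]] <- data.frame(
      angle_deg = angles[k],
      lumen_edge_um = bs$lumen_edge_um, iel_um = bs$iel_um,
      media_adventitia_um = bs$media_adventitia_um,
      outer_edge_um = bs$outer_edge_um,
      min_confidence = min(bs$confidence),
      complete = !anyNA(c(bs$lumen_edge_um, bs$iel_um,
                          bs$media_adventitia_um, bs$outer_edge_um))
    )
  }
  tab <- do.call(rbind, rows)
  complete <- which(tab$complete)
  if (selection == "fixed_angles") {
    want <- (seq_len(n_profiles) - 1) * (360 / n_profiles)
    sel <- vapply(want, function(a) {
      d <- abs(((tab$angle_deg - a + 180) %% 360) - 180)
      which.min(d)
    }, integer(1))
    sel <- sel[tab$complete[sel]]
  } else {
    sel <- complete[order(-tab$min_confidence[complete])]
    sel <- sel[seq_len(min(n_profiles, length(sel)))]
  }
  quantifiable <- length(complete) >= n_profiles && length(sel) >= n_profiles
  if (quantifiable) {
    sel <- sel[seq_len(n_profiles)]
    intima <- mean(tab$iel_um[sel] - tab$lumen_edge_um[sel])
    media <- mean(tab$media_adventitia_um[sel] - tab$iel_um[sel])
    advent <- mean(tab$outer_edge_um[sel] - tab$media_adventitia_um[sel])
    ratio <- if (media > 0) intima / media else NA_real_
  } else {
    intima <- media <- advent <- ratio <- NA_real_
    sel <- integer(0)
  }
  structure(list(
    intima_um = intima, media_um = media, adventitia_um = advent,
    im_ratio = ratio,
    class_label = classify_im(ratio),
    n_profiles_used = length(sel),
    center_px = center,
    selected_angles = tab$angle_deg[sel],
    angle_table = tab
  ), class = "layer_measurement")
}

#' @export
print.layer_measurement <- function(x, ...) {
  cat("layer_measurement\n")
  if (is.na(x$im_ratio)) {
    cat(sprintf("  class: %s (%d complete profiles of %d required)\n",
                x$class_label, sum(x$angle_table$complete),
                max(x$n_profiles_used, 3)))
  } else {
    cat(sprintf("  intima %.1f um, media %.1f um, adventitia %.1f um\n",
                x$intima_um, x$media_um, x$adventitia_um))
    cat(sprintf("  I/M = %.3f -> %s (mean of %d profiles)\n",
                x$im_ratio, x$class_label, x$n_profiles_used))
  }
  invisible(x)
}
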