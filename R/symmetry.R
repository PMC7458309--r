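# 180-degree rotational-symmetry scoring of an orientation field: in a
# healthy circular wall the fiber orientation at any point is parallel to
# that at its antipode through the lumen center; GCA remodeling destroys
# this match.

#' Rotational-symmetry score of an orientation map
#'
#' For each defined, confident, in-mask pixel p whose antipode
#' p' = 2 * center - p (nearest pixel) is also defined, confident and
#' in-mask, the axial mismatch D(p) = axial distance between the two
#' orientations (in [0, 90] degrees) is computed. The score is the
#' confidence-weighted mean of cos^2(D), with pair weight
#' min(confidence(p), confidence(p')) and each unordered pair counted
#' once. cos^2 of the axial mismatch is the natural axial-data analogue of
#' cosine similarity (alignment of doubled-angle unit vectors): 1 for a
#' perfect match, 0.5 for independent uniform orientations, 0 for
#' systematically perpendicular antipodes.
#'
#' @param map an \code{orientation_map} (from [orientation_map()] or
#'   [as_orientation_map()]).
#' @param center (row, col) rotation center, inside the image.
#' @param mask optional logical matrix restricting the scored region
#'   (e.g. the wall annulus); default: all pixels.
#' @param confidence_floor minimum per-pixel confidence for a pixel to
#'   participate (default 0, i.e. any defined pixel).
#' @return object of class \code{symmetry_result}: \code{score} in [0, 1],
#'   \code{n_pixel_pairs}, \code{mean_axial_mismatch_deg} (unweighted),
#'   \code{mask_description}.
#' @export
symmetry_score <- function(map, center, mask = NULL, confidence_floor = 0) {
  a <- map$angle_deg
  conf <- map$confidence
  H <- nrow(a); W <- ncol(a)
  if (center[1] < 1 || center[1] > H || center[2] < 1 || center[2] > W) {
    stop("center lies outside the image")
  }
  mask_desc <- if (is.null(mask)) "whole image" else "user mask"
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  ok <- mask & !is.na(a) & conf >= confidence_floor & conf > 0
  idx <- which(ok)
  if (length(idx) == 0) {
    stop("no qualifying pixel: mask too small or confidence floor too high")
  }
  rr <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  ar <- round(2 * center[1] - rr)
  ac <- round(2 * center[2] - cc)
  inb <- ar >= 1 & ar <= H & ac >= 1 & ac <= W
  aidx <- rep(NA_integer_, length(idx))
  aidx[inb] <- (ac[inb] - 1L) * H + ar[inb]
  valid <- inb & !is.na(aidx) & ok[pmax(aidx, 1L)] & aidx != idx
  # count each unordered pair once
  pairsel <- valid & idx < aidx
  if (!any(pairsel)) {
    stop("no qualifying antipodal pixel pair: mask too small or confidence floor too high")
  }
  p <- idx[pairsel]; q <- aidx[pairsel]
  d <- axial_distance(a[p], a[q])
  w <- pmin(conf[p], conf[q])
  score <- sum(w * cos(d * pi / 180)^2) / sum(w)
  structure(list(score = score,
                 n_pixel_pairs = length(p),
                 mean_axial_mismatch_deg = mean(d),
                 mask_description = mask_desc,
                 confidence_floor = confidence_floor),
            class = "symmetry_result")
}

#' @export
print.symmetry_result <- function(x, ...) {
  cat(sprintf("symmetry_result: score %.4f over %d antipodal pairs (mean axial mismatch %.2f deg; %s)\n",
              x$score, x$n_pixel_pairs, x$mean_axial_mismatch_deg,
              x$mask_description))
  invisible(x)
}

#' Separation of symmetry scores between two cohorts
#'
#' Summarizes healthy-versus-GCA score separation: group medians and
#' interquartile ranges, the rank-sum comparison (see [rank_sum_test()]),
#' and the score threshold maximizing balanced accuracy for classifying
#' healthy (score above threshold) versus GCA.
#'
#' @param healthy_scores,gca_scores non-empty numeric vectors.
#' @return object of class \code{symmetry_separation} with the summary
#'   statistics, the rank-sum comparison and the best threshold with its
#'   balanced accuracy.
#' @export
cohort_separation <- function(healthy_scores, gca_scores) {
  if (length(healthy_scores) < 1 || length(gca_scores) < 1) {
    stop("both score vectors must be non-empty")
  }
  rs <- rank_sum_test(healthy_scores, gca_scores)
  vals <- sort(unique(c(healthy_scores, gca_scores)))
  cand <- if (length(vals) > 1) {
    (vals[-1] + vals[-length(vals)]) / 2
  } else vals
  bacc <- vapply(cand, function(thr) {
    sens <- mean(healthy_scores > thr)
    spec <- mean(gca_scores <= thr)
    (sens + spec) / 2
  }, numeric(1))
  best <- which.max(bacc)
  structure(list(
    healthy_median = stats::median(healthy_scores),
    gca_median = stats::median(gca_scores),
    healthy_iqr = unname(stats::quantile(healthy_scores, c(0.25, 0.75))),
    gca_iqr = unname(stats::quantile(gca_scores, c(0.25, 0.75))),
    rank_sum = rs,
    threshold = cand[best],
    balanced_accuracy = bacc[best]
  ), class = "symmetry_separation")
}

#' @export
print.symmetry_separation <- function(x, ...) {
  cat(sprintf("symmetry_separation: healthy median %.3f [%.3f, %.3f] vs gca median %.3f [%.3f, %.3f]\n",
              x$healthy_median, x$healthy_iqr[1], x$healthy_iqr[2],
              x$gca_median, x$gca_iqr[1], x$gca_iqr[2]))
  cat(sprintf("  rank-sum p = %.4g; balanced accuracy %.3f at threshold %.3f\n",
              x$rank_sum$p_two_tailed, x$balanced_accuracy, x$threshold))
  invisible(x)
}

#' Wall-annulus mask from a layer measurement
#'
#' Builds the default symmetry-scoring mask: the annulus between the lumen
#' edge and the outer wall edge as measured by [measure_layers()]. Falls
#' back to \code{NULL} (whole confident region) when the boundaries are
#' undetectable — which is precisely the remodeled GCA case.
#'
#' @param measurement a \code{layer_measurement}.
#' @param dim_px image dimensions (rows, cols).
#' @param pixel_size_um pixel size in micrometers.
#' @return logical matrix, or \code{NULL} when no complete boundaries are
#'   available.
#' @export
wall_annulus_mask <- function(measurement, dim_px, pixel_size_um) {
  tab <- measurement$angle_table
  comp <- tab[tab$complete, , drop = FALSE]
  if (nrow(comp) == 0) return(NULL)
  r_in <- stats::median(comp$lumen_edge_um) / pixel_size_um
  r_out <- stats::median(comp$outer_edge_um) / pixel_size_um
  ctr <- measurement$center_px
  dr <- matrix(seq_len(dim_px[1]) - ctr[1], dim_px[1], dim_px[2])
  dc <- matrix(seq_len(dim_px[2]) - ctr[2], dim_px[1], dim_px[2],
               byrow = TRUE)
  rpx <- sqrt(dr^2 + dc^2)
  rpx >= r_in & rpx <= r_out
}
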