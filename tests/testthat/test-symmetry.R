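tangential_map <- function(n = 128L, ctr = c((n + 1) / 2, (n + 1) / 2),
                           r_min = 5) {
  rr <- matrix(seq_len(n), n, n); cc <- t(rr)
  a <- ((atan2(rr - ctr[1], cc - ctr[2]) * 180 / pi) + 90) %% 180
  a[sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2) < r_min] <- NA
  as_orientation_map(a, 1)
}

test_that("an ideal tangential field scores exactly 1", {
  n <- 128L
  res <- symmetry_score(tangential_map(n), c((n + 1) / 2, (n + 1) / 2))
  expect_equal(res$score, 1.0)
  expect_equal(res$mean_axial_mismatch_deg, 0)
  expect_gte(res$n_pixel_pairs, 1)
})

test_that("systematically perpendicular antipodes score exactly 0", {
  n <- 64L
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  a <- matrix(NA_real_, n, n)
  # upper half 10 degrees, lower half 100 degrees: every antipodal pair
  # differs by exactly 90
  a[seq_len(n / 2 - 1), ] <- 10
  a[seq.int(n / 2 + 2, n), ] <- 100
  res <- symmetry_score(as_orientation_map(a, 1), ctr)
  expect_equal(res$score, 0.0)
  expect_equal(res$mean_axial_mismatch_deg, 90)
})

test_that("iid uniform axial angles score 0.5, matching a sampling oracle", {
  n <- 512L
  set.seed(77)
  a <- matrix(runif(n * n, 0, 180), n, n)
  res <- symmetry_score(as_orientation_map(a, 1), c((n + 1) / 2, (n + 1) / 2))
  expect_gte(res$n_pixel_pairs, 1e5)
  expect_equal(res$score, 0.5, tolerance = 0.02 / 0.5)

  # independent Monte-Carlo oracle on fresh uniform pairs
  t1 <- runif(2e5, 0, 180); t2 <- runif(2e5, 0, 180)
  oracle <- mean(cos(axial_distance(t1, t2) * pi / 180)^2)
  expect_equal(res$score, oracle, tolerance = 0.02 / 0.5)
})

test_that("score is invariant to 180-degree shifts and bounded in [0,1]", {
  n <- 96L
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  set.seed(5)
  a <- matrix(runif(n * n, 0, 180), n, n)
  conf <- matrix(runif(n * n, 0.2, 1), n, n)
  base <- symmetry_score(as_orientation_map(a, conf), ctr)
  shifted <- symmetry_score(as_orientation_map(a + 180 * 3, conf), ctr)
  expect_equal(shifted$score, base$score)
  expect_identical(shifted$n_pixel_pairs, base$n_pixel_pairs)
  expect_true(base$score >= 0 && base$score <= 1)

  # adding a global rotation offset to all angles preserves a perfect score
  tm <- tangential_map(96L)
  rot <- as_orientation_map(tm$angle_deg + 37, 1)
  expect_equal(symmetry_score(rot, ctr)$score, 1.0)
})

test_that("degenerate masks raise a descriptive error", {
  tm <- tangential_map(64L)
  m <- matrix(FALSE, 64, 64); m[2, 2] <- TRUE
  expect_error(symmetry_score(tm, c(32.5, 32.5), m), "mask|pair")
  expect_error(symmetry_score(tm, c(1000, 10)), "outside")
})

test_that("mean symmetry score does not increase with phantom disorder", {
  score_at <- function(d) {
    mean(vapply(1:3, function(s) {
      ph <- generate_phantom(small_spec(seed = 600L + s, disorder = d,
                                        n_vasa = 0L, n_slices = 5L))
      fld <- ph$truth$orientation_field
      symmetry_score(as_orientation_map(fld, 1), ph$spec$center_px)$score
    }, numeric(1)))
  }
  s <- vapply(c(0, 0.3, 0.7), score_at, numeric(1))
  expect_true(all(diff(s) <= 0.02))
  expect_equal(s[1], 1.0)
})

test_that("cohort separation reports medians, rank-sum and best threshold", {
  cs <- cohort_separation(rep(0.95, 5), rep(0.40, 5))
  expect_equal(cs$balanced_accuracy, 1.0)
  expect_true(cs$threshold > 0.40 && cs$threshold < 0.95)
  expect_equal(cs$healthy_median, 0.95)

  same <- cohort_separation(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(same$balanced_accuracy, 0.5)
  expect_error(cohort_separation(numeric(0), 1), "non-empty")
})
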