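# full-enumeration oracle for the exact two-tailed rank-sum p value
enum_rank_sum_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sets <- utils::combn(na + nb, na)
  u_all <- apply(sets, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

test_that("rank-sum U and exact p match hand enumeration on the small cases", {
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$u_statistic, 0)
  expect_equal(rs$p_two_tailed, 0.1)
  expect_identical(rs$method, "exact")

  rs2 <- rank_sum_test(1, 2)
  expect_equal(rs2$p_two_tailed, 1.0)

  x <- c(3, 1, 4, 1, 5)
  rs3 <- rank_sum_test(x, x)
  expect_equal(rs3$u_statistic, length(x)^2 / 2)   # identical multisets
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("exact p equals the enumeration oracle for all group sizes <= 6", {
  set.seed(314)
  for (rep in 1:20) {
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    v <- sample(1:100, na + nb)   # no ties
    a <- v[seq_len(na)]; b <- v[-seq_len(na)]
    rs <- rank_sum_test(a, b)
    expect_identical(rs$method, "exact")
    expect_equal(rs$p_two_tailed, enum_rank_sum_p(a, b), tolerance = 1e-12)
  }
})

test_that("rank-sum is invariant under strictly monotone transforms and falls back with ties", {
  set.seed(8)
  a <- rnorm(7); b <- rnorm(5) + 1
  r1 <- rank_sum_test(a, b)
  r2 <- rank_sum_test(exp(a), exp(b))
  expect_equal(r1$u_statistic, r2$u_statistic)
  expect_equal(r1$p_two_tailed, r2$p_two_tailed)

  rt <- rank_sum_test(c(1, 2, 2), c(2, 3, 4))
  expect_identical(rt$method, "normal_approx")
  big <- rank_sum_test(rnorm(30), rnorm(25))
  expect_identical(big$method, "normal_approx")
  expect_true(big$p_two_tailed > 0 && big$p_two_tailed <= 1)
})

test_that("medians and interquartile ranges use interpolated quartiles", {
  rs <- rank_sum_test(c(1, 2, 3, 4), c(10, 20, 30))
  expect_equal(rs$group_a_median, 2.5)
  expect_equal(rs$group_iqrs$a, c(1.75, 3.25))
  expect_equal(rs$group_b_median, 20)
})

test_that("pearson correlation obeys the exact algebraic identities", {
  expect_equal(pearson_correlation(1:4, 1:4)$r, 1)
  expect_equal(pearson_correlation(1:4, -(1:4))$r, -1)
  expect_equal(pearson_correlation(c(1, 2, 3, 4), c(2, 4, 6, 8))$r, 1)

  set.seed(21)
  x <- rnorm(15); y <- x + rnorm(15, sd = 0.5)
  base <- pearson_correlation(x, y)
  aff <- pearson_correlation(3 * x + 7, 0.5 * y - 2)
  expect_equal(aff$r, base$r)
  expect_equal(aff$p_two_tailed, base$p_two_tailed)
  neg <- pearson_correlation(x, -y)
  expect_equal(neg$r, -base$r)

  # agrees with the closed-form t-transform
  tstat <- base$r * sqrt((base$n - 2) / (1 - base$r^2))
  expect_equal(base$p_two_tailed, 2 * pt(-abs(tstat), base$n - 2))
})

test_that("degenerate correlation inputs are rejected", {
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
  expect_error(pearson_correlation(1:4, 1:5), "equal length")
})
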