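test_that("quantile normalization matches the rank-mean oracle", {
  # hand oracle: sorted columns (1,2,3) and (4,5,6) -> reference (2.5,3.5,4.5)
  x <- cbind(a = c(1, 2, 3), b = c(6, 4, 5))
  qn <- quantile_normalize(x)
  expect_equal(qn[, "a"], c(2.5, 3.5, 4.5), ignore_attr = TRUE)
  expect_equal(qn[, "b"], c(4.5, 2.5, 3.5), ignore_attr = TRUE)

  # identical columns and single columns are fixed points
  y <- cbind(c(3, 1, 2), c(3, 1, 2))
  expect_equal(quantile_normalize(y), y, ignore_attr = TRUE)
  z <- matrix(c(5, 1, 9), ncol = 1)
  expect_equal(quantile_normalize(z), z, ignore_attr = TRUE)

  expect_error(quantile_normalize(cbind(c(1, NA), c(2, 3))),
               class = "sennet_value_error")
})

test_that("quantile normalization is idempotent and agrees with limma", {
  set.seed(11)
  x <- matrix(rnorm(400), 100, 4)
  qn <- quantile_normalize(x)
  expect_equal(quantile_normalize(qn), qn, tolerance = 1e-9)
  # every column shares one sorted multiset
  s <- apply(qn, 2, sort)
  expect_equal(s[, 1], s[, 3], tolerance = 1e-12)
  skip_if_not_installed("limma")
  expect_equal(qn, limma::normalizeQuantiles(x), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("feature_statistic reproduces textbook values", {
  # intensity-scale medians 8 vs 4 -> LMR = 1
  fs <- feature_statistic(c(7, 8, 9), c(3, 4, 5), scale = "intensity")
  expect_equal(fs$LMR, 1)
  expect_equal(fs$direction, "up")

  # identical groups
  fs0 <- feature_statistic(c(1, 2, 3), c(1, 2, 3))
  expect_equal(fs0$T, 0)
  expect_equal(fs0$LMR, 0)
  expect_equal(fs0$direction, "none")

  # pooled-t oracle: A = (1,2,3), B = (4,5,6) on the analysis scale;
  # means 2 and 5, pooled var 1 -> t = -3/sqrt(2/3) = -3.674
  fs2 <- feature_statistic(c(1, 2, 3), c(4, 5, 6))
  expect_equal(fs2$T, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(fs2$T, 3), -3.674)
  # cross-check against stats::t.test with pooled variance
  expect_equal(fs2$T, unname(t.test(1:3, 4:6, var.equal = TRUE)$statistic),
               tolerance = 1e-12)

  # degenerate cases are flagged, not NaN'd
  flat <- feature_statistic(c(2, 2), c(3, 3))
  expect_false(flat$t_defined)
  expect_error(feature_statistic(1, numeric(0)), NA)
})

test_that("empirical_p follows the add-one counting contract", {
  expect_equal(empirical_p(0, c(-2, -1, 1, 2), tail = "two"), 1)
  # observed beats all 99 null values, right tail -> 1/100
  expect_equal(empirical_p(1000, seq_len(99), tail = "right"), 1 / 100)
  # count-by-hand oracle: null {-2,-1,0,1,2}, obs 1.5 -> (1+2)/6
  expect_equal(empirical_p(1.5, c(-2, -1, 0, 1, 2), tail = "two"), 3 / 6)
  expect_error(empirical_p(1, numeric(0)), class = "sennet_value_error")

  # antitone in |observed| (two) and observed (right)
  set.seed(4)
  null <- rnorm(500)
  obs <- sort(abs(rnorm(50)))
  expect_true(all(diff(empirical_p(obs, null, "two")) <= 0))
  expect_true(all(diff(empirical_p(sort(rnorm(50)), null, "right")) <= 0))
})

test_that("stouffer_combine matches the normal-CDF oracle and closed form", {
  # p = 1 on both sides: z = 0, overall 1
  expect_equal(stouffer_combine(1, 1, "up", "up")$overall_p, 1)
  # opposite directions cancel exactly
  expect_equal(stouffer_combine(0.03, 0.03, "up", "down")$overall_p, 1)
  # oracle: two-tailed 0.05 -> one-sided z = qnorm(0.975) = 1.960;
  # combined z = 2 * 1.960 / sqrt(2) = 2.772 -> two-sided p = 0.00556
  res <- stouffer_combine(0.05, 0.05, "up", "up")
  expect_equal(res$z_T, qnorm(0.975), tolerance = 1e-12)
  expect_equal(res$overall_p, 2 * pnorm(-sqrt(2) * qnorm(0.975)),
               tolerance = 1e-12)
  expect_equal(round(res$overall_p, 5), 0.00557)

  # closed-form agreement on 1000 random triples
  set.seed(9)
  p1 <- runif(1000, 1e-6, 1); p2 <- runif(1000, 1e-6, 1)
  d1 <- sample(c(1, -1), 1000, TRUE); d2 <- sample(c(1, -1), 1000, TRUE)
  got <- stouffer_combine(p1, p2, d1, d2)$overall_p
  z1 <- qnorm(1 - p1 / 2) * d1; z2 <- qnorm(1 - p2 / 2) * d2
  expect_equal(got, pmin(2 * (1 - pnorm(abs(z1 + z2) / sqrt(2))), 1),
               tolerance = 1e-9)

  # zero p needs an explicit floor
  expect_error(stouffer_combine(0, 0.5, "up", "up"), class = "sennet_value_error")
  expect_warning(out <- stouffer_combine(0, 0.5, "up", "up", p_floor = 1 / 101))
  expect_equal(out$p_T, 1 / 101)
})

test_that("z_from_p matches the inverse-normal oracle", {
  expect_equal(z_from_p(0.5), 0)
  expect_equal(round(z_from_p(0.05), 3), 1.645)
  expect_equal(round(z_from_p(0.001), 3), 3.090)
  expect_equal(z_from_p(0.05), -qnorm(0.05), tolerance = 1e-12)
  expect_true(all(diff(z_from_p(c(0.01, 0.05, 0.5, 0.9))) < 0))
  expect_error(z_from_p(0), class = "sennet_value_error")
  expect_error(z_from_p(1), class = "sennet_value_error")
})

test_that("build_empirical_null is deterministic and enumerates small designs", {
  set.seed(2)
  m <- matrix(rnorm(50 * 6, 8), 50, 6)
  labs <- rep(c("a", "b"), each = 3)
  n1 <- suppressWarnings(build_empirical_null(m, labs, n_perm = 100, seed = 5))
  n2 <- suppressWarnings(build_empirical_null(m, labs, n_perm = 100, seed = 5))
  expect_identical(n1$null_T, n2$null_T)
  expect_identical(n1$null_LMR, n2$null_LMR)
  # 3v3 has choose(6,3) = 20 distinct relabelings: all enumerated, warned
  expect_warning(build_empirical_null(m, labs, n_perm = 100, seed = 5),
                 "20 distinct relabelings")
  expect_equal(n1$n_perm, 20L)
  expect_length(n1$null_T, 20L * 50L)

  # enumerated relabelings make the pooled LMR null exactly symmetric,
  # so the cutoff equals the upper-percentile magnitude
  q <- quantile(n1$null_LMR, c(0.05, 0.95), names = FALSE)
  expect_equal(q[1], -q[2], tolerance = 1e-12)
  expect_equal(n1$lmr_cutoff, abs(q[2]), tolerance = 1e-12)

  expect_error(build_empirical_null(m, rep("a", 6), n_perm = 10),
               class = "sennet_config_error")
  expect_error(build_empirical_null(m[, 1:3], c("a", "a", "b"), n_perm = 10),
               class = "sennet_config_error")
})

test_that("null empirical p-values are approximately uniform with type-I control", {
  set.seed(31)
  m <- matrix(rnorm(2000 * 6, 8), 2000, 6)
  labs <- rep(c("a", "b"), each = 3)
  null <- suppressWarnings(build_empirical_null(m, labs, n_perm = 1000, seed = 1))
  st <- sennet:::row_feature_stats(m, 1:3, 4:6)
  p <- empirical_p(st$T, null$null_T, tail = "two")
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
  for (alpha in c(0.01, 0.05)) {
    rate <- mean(p < alpha)
    band <- 3 * sqrt(alpha * (1 - alpha) / length(p))
    expect_lt(abs(rate - alpha), band + 1e-12)
  }
})
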