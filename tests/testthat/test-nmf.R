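test_that("nonneg_embed splits signs losslessly", {
  set.seed(3)
  fc <- matrix(rnorm(60), 20, 3, dimnames = list(paste0("g", 1:20),
                                                 paste0("m", 1:3)))
  v <- nonneg_embed(fc)
  expect_true(all(v >= 0))
  expect_equal(ncol(v), 6L)
  # reconstruction: up minus down recovers the input
  rec <- v[, seq(1, 6, 2)] - v[, seq(2, 6, 2)]
  expect_equal(unname(rec), unname(fc))
  # all-positive input leaves the negative-part columns at zero
  vp <- nonneg_embed(abs(fc))
  expect_true(all(vp[, seq(2, 6, 2)] == 0))
  # a single -2 lands in the down column
  one <- nonneg_embed(matrix(-2, 1, 1, dimnames = list("g", "m")))
  expect_equal(unname(one[1, ]), c(0, 2))
})

test_that("fit_nmf factorizes exactly, monotonically and deterministically", {
  set.seed(7)
  w <- abs(rnorm(30)); h <- abs(rnorm(4))
  rank1 <- outer(w, h)
  f1 <- fit_nmf(rank1, k = 1)
  expect_lt(sum((rank1 - f1$basis %*% f1$pattern)^2), 1e-6)

  # loss is non-increasing at every iteration
  v <- matrix(runif(200), 20, 10)
  f <- fit_nmf(v, k = 3, seed = 5, init = "random")
  expect_true(all(diff(f$loss) <= 1e-8 * f$loss[1]))
  expect_true(all(f$basis >= 0) && all(f$pattern >= 0))

  # determinism, both initializations
  f2 <- fit_nmf(v, k = 3, seed = 5, init = "random")
  expect_identical(f$basis, f2$basis)
  g1 <- fit_nmf(v, k = 3)
  g2 <- fit_nmf(v, k = 3)
  expect_identical(g1$basis, g2$basis)

  expect_error(fit_nmf(v, k = 11), class = "sennet_config_error")
  expect_error(fit_nmf(v - 1, k = 2), class = "sennet_value_error")
})

test_that("two-block matrices are recovered perfectly", {
  blocks <- rbind(cbind(matrix(2, 20, 2), matrix(0, 20, 2)),
                  cbind(matrix(0, 20, 2), matrix(3, 20, 2)))
  rownames(blocks) <- paste0("g", 1:40)
  f <- fit_nmf(blocks, k = 2)
  lab <- hard_clusters(f)
  expect_equal(adjusted_rand_index(lab, rep(1:2, each = 20)), 1)
})

test_that("activation significance controls the null and finds planted blocks", {
  sim <- simulate_model_fc(n_genes = 160, n_models = 4,
                           block_spec = list(
                             list(n = 30, models = c(1L, 2L), sign = 1, fc = 2),
                             list(n = 30, models = c(3L, 4L), sign = -1, fc = 2)),
                           noise_sigma = 0.1, seed = 17)
  v <- nonneg_embed(sim$matrix)
  p <- activation_significance(v, k = 4, n_perm = 200, seed = 17)
  planted <- sim$truth$block > 0
  # planted genes are significant in their argmax cluster (a small noise
  # tail can sit just past 0.01, never past 0.05)
  fit <- attr(p, "fit")
  best <- cbind(seq_len(nrow(v)), hard_clusters(fit))
  expect_gte(mean(p[best][planted] < 0.01), 0.9)
  expect_lt(max(p[best][planted]), 0.05)

  # shuffled input as "observed": no structure, membership rate near nominal
  vs <- with(list(), {set.seed(99); matrix(sample(v), nrow(v), ncol(v))})
  dimnames(vs) <- dimnames(v)
  p0 <- activation_significance(vs, k = 4, n_perm = 60, seed = 4)
  expect_lte(mean(p0 < 0.01), 0.02)

  # n_perm = 1: add-one floor bounds every p away from 0
  p1 <- activation_significance(v, k = 4, n_perm = 1, seed = 1)
  expect_true(all(p1 >= 1 / (1 + nrow(v) * 4)))
})

test_that("rank_and_select orders by Euclidean norm with index tie-break", {
  sim <- simulate_model_fc(seed = 2)
  cl <- nmf_cluster(sim$matrix, k = 6, n_perm = 20, seed = 2)
  rk <- rank_and_select(cl, m = 3)
  expect_equal(rk$norm, sort(cl$norms, decreasing = TRUE)[1:3],
               ignore_attr = TRUE)
  expect_error(rank_and_select(cl, m = 7), class = "sennet_config_error")

  # synthetic clustering with known norms (3, 5, 1) -> order (2, 1)
  fake <- cl
  fake$norms <- c(3, 5, 1, 0, 0, 0)
  fake$ranking <- order(-fake$norms, seq_along(fake$norms))
  rk2 <- rank_and_select(fake, m = 2)
  expect_equal(rk2$cluster, c("C2", "C1"))
  # equal norms: lower index first
  fake$norms <- c(2, 2, 1, 0, 0, 0)
  fake$ranking <- order(-fake$norms, seq_along(fake$norms))
  expect_equal(rank_and_select(fake, m = 2)$cluster, c("C1", "C2"))

  # the dominant planted block outranks the rest
  dom <- simulate_model_fc(n_genes = 150, n_models = 4,
                           block_spec = list(
                             list(n = 30, models = 1:4, sign = 1, fc = 3),
                             list(n = 20, models = c(1L, 2L), sign = -1, fc = 1)),
                           noise_sigma = 0.05, seed = 31)
  cl2 <- nmf_cluster(dom$matrix, k = 4, n_perm = 30, seed = 31)
  top <- rank_and_select(cl2, m = 1)
  members <- attr(top, "members")[[1]]
  big_block <- dom$truth$gene_id[dom$truth$block == 1]
  expect_gt(mean(big_block %in% members), 0.9)
})

test_that("planted four-block structure is recovered across seeds", {
  aris <- vapply(1:5, function(s) {
    sim <- simulate_model_fc(seed = s)
    fit <- fit_nmf(nonneg_embed(sim$matrix), k = 8)
    planted_ari(fit, sim$truth)
  }, numeric(1))
  expect_true(all(aris >= 0.9))
  # degradation check: noise far above signal destroys recovery
  noisy <- simulate_model_fc(noise_sigma = 20, seed = 1)
  fit <- fit_nmf(nonneg_embed(noisy$matrix), k = 8)
  expect_lt(planted_ari(fit, noisy$truth), 0.1)
})
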