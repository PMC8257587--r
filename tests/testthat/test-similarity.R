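test_that("consistent_sibling_peptides matches direction with the DEP", {
  de <- data.frame(peptide_id = c("p1", "p2", "p3", "p4", "p5"),
                   protein_group = c("A", "A", "B", "B", "C"),
                   direction = c("up", "down", "up", "up", "up"),
                   is_de = c(TRUE, TRUE, TRUE, TRUE, TRUE),
                   stringsAsFactors = FALSE)
  deps <- data.frame(protein_group = c("A", "B"), direction = c("up", "up"),
                     stringsAsFactors = FALSE)
  # A(up): p1 only (p2 is down); B(up): p3 and p4; C is not a DEP
  expect_equal(consistent_sibling_peptides(de, deps), c("p1", "p3", "p4"))
  # 2 DEPs x 2 consistent peptides each -> 4
  de$direction[2] <- "up"
  expect_length(consistent_sibling_peptides(de, deps), 4L)
})

test_that("fc_correlation recovers exact and permuted behavior", {
  set.seed(12)
  feats <- paste0("f", 1:12)
  mk_exp <- function(base, shift, sd = 0.05) {
    m <- cbind(matrix(rep(base + shift, 3), ncol = 3) + rnorm(36, 0, sd),
               matrix(rep(base, 3), ncol = 3) + rnorm(36, 0, sd))
    rownames(m) <- feats
    list(mat = m, labels = rep(c("case", "ctrl"), each = 3))
  }
  shift <- rnorm(12, 0, 1.5)
  ea <- mk_exp(rnorm(12, 8), shift)

  # identical experiments: rho = 1, slope 1
  r_same <- suppressWarnings(fc_correlation(feats, ea, ea, n_perm = 500, seed = 3))
  expect_equal(r_same$rho, 1, tolerance = 1e-12)
  expect_equal(r_same$regression$slope, 1, tolerance = 1e-12)
  expect_equal(r_same$regression$r_squared, 1, tolerance = 1e-12)
  expect_lt(r_same$p_perm, 0.05)

  # negated partner: rho = -1, right-sided p near 1
  eb <- ea
  eb$mat <- ea$mat[, c(4:6, 1:3)]  # swap case/ctrl columns -> negated LMR
  r_neg <- suppressWarnings(fc_correlation(feats, ea, eb, n_perm = 500, seed = 3))
  expect_equal(r_neg$rho, -1, tolerance = 1e-12)
  expect_gt(r_neg$p_perm, 0.5)

  # symmetry of the statistic in its two arguments
  ec <- mk_exp(rnorm(12, 8), shift + rnorm(12, 0, 0.3))
  r_ab <- suppressWarnings(fc_correlation(feats, ea, ec, n_perm = 400, seed = 9))
  r_ba <- suppressWarnings(fc_correlation(feats, ec, ea, n_perm = 400, seed = 9))
  expect_equal(r_ab$rho, r_ba$rho, tolerance = 1e-12)

  # reproducible under a fixed seed
  r2 <- suppressWarnings(fc_correlation(feats, ea, ec, n_perm = 400, seed = 9))
  expect_identical(r_ab$p_perm, r2$p_perm)

  expect_error(fc_correlation(feats[1:2], ea, ea), class = "sennet_value_error")
})

test_that("null fc_correlation p-values are roughly uniform", {
  # independent experiments: permutation p approximately Uniform(0,1)
  ps <- vapply(1:120, function(r) {
    set.seed(1000 + r)
    feats <- paste0("f", 1:10)
    mk <- function() {
      m <- matrix(rnorm(60, 8, 0.5), 10, 6, dimnames = list(feats, NULL))
      list(mat = m, labels = rep(c("case", "ctrl"), each = 3))
    }
    suppressWarnings(fc_correlation(feats, mk(), mk(), n_perm = 400,
                                    seed = r)$p_perm)
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("dep_overlap_test matches exhaustive hypergeometric enumeration", {
  # all-overlap toy: p = 1 / C(20,5)
  u <- paste0("u", 1:20)
  res <- dep_overlap_test(u[1:5], u[1:5], 20)
  expect_equal(res$overlap, 5L)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)

  # zero overlap has right-tail p = 1
  expect_equal(dep_overlap_test(u[1:5], u[6:10], 20)$p, 1)
  # degenerate: both sets are the universe
  expect_equal(dep_overlap_test(u, u, 20)$p, 1)
  expect_error(dep_overlap_test(paste0("x", 1:30), u[1:3], 20),
               class = "sennet_value_error")

  # randomized agreement with the choose()-based oracle, universes <= 25
  set.seed(77)
  for (i in 1:25) {
    N <- sample(8:25, 1)
    uni <- paste0("g", seq_len(N))
    a <- sample(uni, sample(2:(N - 2), 1))
    b <- sample(uni, sample(2:(N - 2), 1))
    got <- dep_overlap_test(a, b, N)
    expect_equal(got$p,
                 hyper_tail_oracle(got$overlap, length(a), length(b), N),
                 tolerance = 1e-12)
  }
})

test_that("cluster_models reproduces average-linkage arithmetic", {
  # three 1-D points 0, 1, 3: merges at 1, then (2 + 3) / 2 = 2.5
  fc <- rbind(a = c(0, 1, 3))
  colnames(fc) <- c("m1", "m2", "m3")
  hc <- cluster_models(fc)
  expect_equal(hc$height, c(1, 2.5))

  # duplicate columns merge first at height 0
  fc2 <- matrix(rnorm(40), 10, 4,
                dimnames = list(NULL, c("w", "x", "y", "z")))
  fc2[, "y"] <- fc2[, "x"]
  hc2 <- cluster_models(fc2)
  expect_equal(min(hc2$height), 0)
  first <- sort(hc2$labels[-hc2$merge[which.min(hc2$height), ]])
  expect_equal(first, c("x", "y"))

  # heights invariant to column order
  hc3 <- cluster_models(fc2[, c(3, 1, 4, 2)])
  expect_equal(hc3$height, hc2$height, tolerance = 1e-12)

  expect_error(cluster_models(fc[, 1, drop = FALSE]),
               class = "sennet_config_error")

  # a planted correlated pair merges before cross-pair merges
  set.seed(5)
  base1 <- rnorm(50); base2 <- rnorm(50)
  fc4 <- cbind(nbis = base1 + rnorm(50, 0, 0.1),
               rs = base1 + rnorm(50, 0, 0.1),
               ois = base2 + rnorm(50, 0, 0.4),
               ddis = base2 + rnorm(50, 0, 0.4))
  hc4 <- cluster_models(fc4)
  pair <- sort(hc4$labels[-hc4$merge[1, ]])
  expect_equal(pair, c("nbis", "rs"))
})

test_that("sample_correlation returns a proper correlation matrix", {
  set.seed(2)
  m <- matrix(rnorm(200, 10), 50, 4)
  cc <- sample_correlation(m)
  expect_equal(dim(cc), c(4L, 4L))
  expect_equal(diag(cc), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(abs(cc) <= 1 + 1e-12))
})
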