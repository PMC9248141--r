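# brute-force CR oracle: direct trace formula over explicit submatrices
cr_oracle <- function(S, groups) {
  mods <- unique(groups)
  prs <- utils::combn(mods, 2)
  vals <- apply(prs, 2, function(pr) {
    A <- which(groups == pr[1]); B <- which(groups == pr[2])
    sab <- S[A, B, drop = FALSE]
    saa <- S[A, A]; diag(saa) <- 0
    sbb <- S[B, B]; diag(sbb) <- 0
    sqrt(sum(diag(t(sab) %*% sab)) /
           sqrt(sum(diag(saa %*% saa)) * sum(diag(sbb %*% sbb))))
  })
  mean(vals)
}

test_that("block-diagonal covariance has CR = 0", {
  S <- as.matrix(Matrix::bdiag(matrix(c(1, .5, .5, 1), 2),
                               matrix(c(1, .3, .3, 1), 2)))
  expect_equal(cr_from_cov(S, c(1, 1, 2, 2))$cr, 0)
})

test_that("the equal-covariance hand case gives CR = sqrt(2)", {
  S <- matrix(0.4, 4, 4); diag(S) <- 1
  expect_equal(cr_from_cov(S, c("a", "a", "b", "b"))$cr, sqrt(2),
               tolerance = 1e-12)
})

test_that("cr_from_cov matches the brute-force trace oracle", {
  set.seed(6)
  # fixed printed 4-trait covariance, two modules
  S4 <- matrix(c(2.0, 0.6, 0.3, 0.1,
                 0.6, 1.5, 0.2, 0.4,
                 0.3, 0.2, 1.8, 0.7,
                 0.1, 0.4, 0.7, 1.2), 4, 4)
  expect_equal(cr_from_cov(S4, c(1, 1, 2, 2))$cr,
               cr_oracle(S4, c(1, 1, 2, 2)), tolerance = 1e-12)
  # and random larger cases with 3 modules
  for (rep in 1:5) {
    a <- matrix(rnorm(144), 12)
    S <- crossprod(a)
    g <- rep(1:3, each = 4)
    res <- cr_from_cov(S, g)
    expect_equal(res$cr, cr_oracle(S, g), tolerance = 1e-10)
    expect_equal(res$pairwise[1, 2], cr_oracle(S[1:8, 1:8], g[1:8]),
                 tolerance = 1e-10)
  }
  expect_error(cr_from_cov(diag(4), c(1, 1, 2, 2)), "undefined")
})

test_that("cr_statistic is invariant to specimen order and common rotation", {
  ds <- modular_dataset(n = 30, k = 8, seed = 9)
  map <- toy_map(8, 2)
  fit <- gpa(ds)
  base <- cr_statistic(fit$aligned, map, landmark_ids = ds$landmark_ids)
  perm <- fit$aligned[, , sample(30)]
  expect_equal(cr_statistic(perm, map, landmark_ids = ds$landmark_ids)$cr,
               base$cr, tolerance = 1e-10)
  r <- rand_rot()
  rot <- fit$aligned
  for (i in 1:30) rot[, , i] <- rot[, , i] %*% r
  expect_equal(cr_statistic(rot, map, landmark_ids = ds$landmark_ids)$cr,
               base$cr, tolerance = 1e-8)
})

# draw shapes whose landmark-level covariance is an explicit 2-block
# structure (each coordinate dimension independent): within-block landmark
# correlation rho_w, between-block rho_b
block_shapes <- function(n, k, rho_w, rho_b, seed) {
  set.seed(seed)
  sig <- matrix(rho_b, k, k)
  half <- k / 2
  sig[1:half, 1:half] <- rho_w
  sig[(half + 1):k, (half + 1):k] <- rho_w
  diag(sig) <- 1
  flat <- matrix(rnorm(n * 3 * k), n * 3, k) %*% chol(sig)
  shapes <- array(NA_real_, c(k, 3, n))
  for (i in seq_len(n))
    shapes[, , i] <- t(flat[(3 * i - 2):(3 * i), ])
  shapes
}

test_that("cr_test finds strong modularity and rejects degenerate maps", {
  hits <- vapply(1:10, function(s) {
    shapes <- block_shapes(100, 16, 0.6, 0.05, seed = s)
    res <- cr_test(shapes, toy_map(16, 2), n_perm = 199, seed = s)
    res$p_value <= 0.05 && res$z_score < 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  shapes <- block_shapes(50, 16, 0.6, 0.05, seed = 99)
  expect_gte(cr_test(shapes, toy_map(16, 2), n_perm = 199,
                     seed = 1)$p_value, 1 / 200)
  one_mod <- module_map("one", stats::setNames(rep("all", 16), 1:16))
  expect_error(cr_test(shapes, one_mod, n_perm = 99), "single-module")
})

test_that("weakening between-module covariance never increases CR (in expectation)", {
  set.seed(12)
  lambdas <- c(1, 0.5, 0)
  mean_cr <- vapply(lambdas, function(lam) {
    crs <- vapply(1:25, function(r) {
      within <- matrix(0.6, 5, 5); diag(within) <- 1
      S <- as.matrix(Matrix::bdiag(within, within))
      S[1:5, 6:10] <- lam * 0.3
      S[6:10, 1:5] <- lam * 0.3
      x <- matrix(rnorm(60 * 10), 60) %*% chol(S + diag(1e-8, 10))
      cr_from_cov(cov(x), rep(1:2, each = 5))$cr
    }, numeric(1))
    mean(crs)
  }, numeric(1))
  expect_true(all(diff(mean_cr) < 0))
})

test_that("compare_cr: self-comparison is null, closed form holds", {
  ds <- modular_dataset(n = 40, k = 8, seed = 13)
  shapes <- gpa(ds)$aligned
  r1 <- cr_test(shapes, toy_map(8, 2), n_perm = 99, seed = 1,
                landmark_ids = ds$landmark_ids)
  cmp_self <- compare_cr(list(a = r1, b = r1))
  expect_equal(unname(cmp_self$statistic[1, 2]), 0)
  expect_equal(unname(cmp_self$p_value[1, 2]), 1)

  r2 <- r1; r2$z_score <- -9; r2$map_name <- "strong"
  r3 <- r1; r3$z_score <- -2; r3$map_name <- "weak"
  cmp <- compare_cr(list(r2, r3))
  expect_equal(abs(unname(cmp$statistic["strong", "weak"])), 7 / sqrt(2),
               tolerance = 1e-12)
  expect_lt(cmp$p_value["strong", "weak"], 1e-6)
  expect_equal(cmp$strongest, "strong")

  r4 <- r1; r4$data_signature <- r1$data_signature + 1
  expect_error(compare_cr(list(r1, r4)), "same shape data")
  r5 <- r1; r5$n_perm <- 199L
  expect_error(compare_cr(list(r1, r5)), "permutation counts")
})
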