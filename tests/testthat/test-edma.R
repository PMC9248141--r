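test_that("form matrix: closed form, rigid invariance, scale homogeneity", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 2))
  fm <- form_matrix(tri)
  expect_equal(fm[1, 2], 1)
  expect_equal(fm[1, 3], 1)
  expect_equal(fm[2, 3], 2)
  expect_equal(diag(fm), rep(0, 4), ignore_attr = TRUE)
  set.seed(2)
  moved <- tri %*% rand_rot() + matrix(rnorm(3), 4, 3, byrow = TRUE)
  expect_equal(form_matrix(moved), fm, tolerance = 1e-9)
  expect_equal(form_matrix(2.5 * tri), 2.5^2 * fm, tolerance = 1e-9)
  expect_error(form_matrix(rbind(c(NA, 0, 0), tri)), "missing")
})

test_that("mean form of identical noise-free configurations is exact", {
  set.seed(5)
  cfg <- ellipsoid_template(9) * 4
  coords <- array(NA_real_, c(9, 3, 6))
  for (i in 1:6)
    coords[, , i] <- cfg %*% rand_rot() + matrix(rnorm(3), 9, 3,
                                                 byrow = TRUE)
  fit <- edma_mean_form(landmark_dataset(coords))
  expect_equal(fit$mean_form_sq, form_matrix(cfg), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(max(abs(fit$sigma_k)), 1e-9)
})

test_that("perturbation-model estimates recover form and covariance scale", {
  set.seed(8)
  k <- 12; n <- 500; sigma <- 0.05
  template <- ellipsoid_template(k) * 3
  coords <- array(NA_real_, c(k, 3, n))
  for (i in seq_len(n))
    coords[, , i] <- (template + matrix(rnorm(k * 3, 0, sigma), k, 3)) %*%
      rand_rot()
  fit <- edma_mean_form(landmark_dataset(coords))
  expect_equal(fit$mean_form_sq, form_matrix(template), tolerance = 0.02,
               ignore_attr = TRUE)
  # the centering-adjusted covariance target, brute forced numerically:
  # E[sigma_k] = H Sigma H with Sigma = sigma^2 I under the isotropic model
  H <- diag(k) - matrix(1 / k, k, k)
  target <- sigma^2 * H
  expect_equal(mean(diag(fit$sigma_k)) / mean(diag(target)), 1,
               tolerance = 0.15)
})

test_that("mean form is invariant to per-specimen rigid motions", {
  ds <- modular_dataset(n = 20, k = 10, seed = 3, rigid_motions = FALSE)
  fit1 <- edma_mean_form(ds)
  set.seed(99)
  coords2 <- ds$coords
  for (i in seq_len(20))
    coords2[, , i] <- coords2[, , i] %*% rand_rot() +
      matrix(rnorm(3, sd = 5), 10, 3, byrow = TRUE)
  fit2 <- edma_mean_form(landmark_dataset(coords2))
  expect_equal(fit2$mean_form_sq, fit1$mean_form_sq, tolerance = 1e-8)
  expect_equal(fit2$sigma_k, fit1$sigma_k, tolerance = 1e-8)
})

test_that("degenerate inputs are rejected", {
  expect_error(edma_mean_form(array(rnorm(2 * 3 * 5), c(2, 3, 5))),
               "at least 4")
  expect_error(edma_mean_form(array(rnorm(5 * 3 * 1), c(5, 3, 1))),
               "at least 2")
})

test_that("trait distances satisfy the covariance Gram identity", {
  set.seed(13)
  for (rep in 1:5) {
    a <- matrix(rnorm(64), 8)
    S <- crossprod(a)                     # random PSD
    ts <- trait_distances(S)
    oracle <- sqrt(outer(diag(S), diag(S), "+") - 2 * S)
    expect_equal(ts$distances, oracle, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(ts$n_dropped, 0)
  }
  ident <- trait_distances(diag(5))
  off <- ident$distances[upper.tri(ident$distances)]
  expect_equal(off, rep(sqrt(2), 10), tolerance = 1e-12)
})

test_that("negative covariance modes are dropped, distances from the PSD part", {
  set.seed(14)
  q <- qr.Q(qr(matrix(rnorm(36), 6)))
  vals <- c(5, 3, 2, 1, 0.5, -0.8)
  S <- q %*% diag(vals) %*% t(q)
  S <- (S + t(S)) / 2
  ts <- trait_distances(S)
  expect_equal(ts$n_dropped, 1)
  S_pos <- q[, 1:5] %*% diag(vals[1:5]) %*% t(q[, 1:5])
  oracle <- sqrt(outer(diag(S_pos), diag(S_pos), "+") - 2 * S_pos)
  expect_equal(ts$distances, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(trait_distances(matrix(rnorm(16), 4)), "symmetric")
})

test_that("variance filter: clean data passes, noisy landmark is excluded", {
  # noise-free: all distance variances are exactly 0
  cfg <- ellipsoid_template(8)
  coords <- array(rep(cfg, 10), c(8, 3, 10))
  expect_length(variance_filter(landmark_dataset(coords))$excluded, 0)

  # one landmark placed right on top of another and heavily jittered: the
  # jitter variance exceeds the short distance's mean (in these units),
  # which is the filter's trigger
  set.seed(31)
  k <- 8; n <- 200
  base <- ellipsoid_template(k) * 300
  base[2, ] <- base[1, ] + c(0.05, 0, 0)
  coords <- array(NA_real_, c(k, 3, n))
  for (i in seq_len(n)) {
    c_i <- base
    c_i[2, ] <- c_i[2, ] + rnorm(3, 0, 5)
    coords[, , i] <- c_i
  }
  vf <- variance_filter(landmark_dataset(coords))
  # only the short noisy distance triggers; both its endpoints go
  expect_true(2L %in% vf$excluded)
  expect_true(all(vf$excluded %in% c(1L, 2L)))
  trig <- vf$table[vf$table$trigger, ]
  expect_equal(nrow(trig), 1L)
  expect_setequal(c(trig$id_a, trig$id_b), c(1L, 2L))

  # same construction but the pair is bilateral: retained with a warning
  ds_b <- landmark_dataset(coords, bilateral_pairs = cbind(2L, 6L))
  expect_warning(vf_b <- variance_filter(ds_b), "bilateral")
  expect_false(2L %in% vf_b$excluded)
  expect_true(2L %in% vf_b$protected)
})
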