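test_that("spec validation rejects degenerate settings", {
  map <- toy_map(8, 2)
  expect_error(synth_spec(10, map, noise_sd = 0), "positive")
  bad <- matrix(c(1, 0.5, 0.4, 1), 2)
  expect_error(synth_spec(10, map, between_corr = bad), "symmetric")
  notpsd <- matrix(c(1, 2, 2, 1), 2)
  expect_error(synth_spec(10, map, between_corr = notpsd),
               "semidefinite")
  expect_error(synth_spec(10, map, missing_rate = 1), "missing_rate")
})

test_that("generation is reproducible and carries ground truth", {
  spec <- synth_spec(8, toy_map(10, 2), seed = 99, missing_rate = 0.05)
  d1 <- generate_landmarks(spec)
  d2 <- generate_landmarks(spec)
  expect_equal(d1$coords, d2$coords)
  gt <- attr(d1, "ground_truth")
  expect_named(gt, c("spec", "scores", "sizes", "loadings", "directions",
                     "template", "allometry_field"))
  expect_equal(dim(gt$scores), c(8, 2))
  # first specimen always complete; nobody loses everything
  expect_false(any(d1$missing[, 1]))
  expect_true(all(colSums(!d1$missing) >= 5))
})

test_that("large-sample landmark covariance converges to the model", {
  k <- 8
  map <- toy_map(k, 2)
  spec <- synth_spec(5000, map, within_strength = 0.15, size_sd = 0,
                     noise_sd = 0.02, rigid_motions = FALSE, seed = 5)
  ds <- generate_landmarks(spec)
  gt <- attr(ds, "ground_truth")
  flat <- t(apply(ds$coords, 3, function(m) as.vector(t(m))))
  emp <- cov(flat)
  implied <- diag(0.02^2, 3 * k)
  for (m in names(gt$loadings)) {
    l <- as.vector(t(gt$loadings[[m]])) * 0.15
    implied <- implied + outer(l, l)
  }
  rel <- norm(emp - implied, "F") / norm(implied, "F")
  expect_lt(rel, 0.05)
})

test_that("without rigid motions the generated data is a GPA fixed point", {
  spec <- synth_spec(15, toy_map(8, 2), size_sd = 0, rigid_motions = FALSE,
                     seed = 6)
  ds <- generate_landmarks(spec)
  fit <- gpa(ds)
  refit <- gpa(fit$aligned)
  expect_equal(refit$aligned, fit$aligned, tolerance = 1e-7,
               ignore_attr = TRUE)
})

test_that("allometric variance share matches the ground-truth oracle", {
  k <- 10; n <- 400
  spec <- synth_spec(n, toy_map(k, 2), within_strength = 0.02,
                     allometry_strength = 0.25, size_sd = 0.08,
                     noise_sd = 0.01, seed = 7)
  ds <- generate_landmarks(spec)
  fit <- gpa(ds)
  al <- allometry_correct(fit, n_perm = 99, seed = 1)
  gt <- attr(ds, "ground_truth")
  # variance decomposition: allometric vs factor + noise shape variance
  var_allo <- 0.25^2 * var(gt$sizes)
  var_fact <- 2 * 0.02^2   # two unit-norm fields at strength 0.02
  var_noise <- 3 * k * 0.01^2
  share <- var_allo / (var_allo + var_fact + var_noise)
  expect_equal(al$r_squared, share, tolerance = 0.15)
  expect_true(al$applied)
})

test_that("the study-like suite spans the intended regimes", {
  suite <- make_paperlike_suite(3)
  expect_named(suite, c("n74_seven_module_negative", "n35_six_module",
                        "n12_seven_module"))
  expect_equal(n_specimens(suite$n74_seven_module_negative$dataset), 74)
  expect_equal(n_specimens(suite$n35_six_module$dataset), 35)
  expect_equal(n_specimens(suite$n12_seven_module$dataset), 12)
  expect_equal(n_landmarks(suite$n74_seven_module_negative$dataset), 54)
  expect_equal(
    n_modules(suite$n74_seven_module_negative$spec$module_map), 7L)
  expect_equal(n_modules(suite$n35_six_module$spec$module_map), 6L)
  bc <- suite$n74_seven_module_negative$spec$between_corr
  expect_equal(bc["oro-nasal", "molar-palate"], -0.5)

  # the minimal-sample regime must trigger downstream instability warnings
  small <- suite$n12_seven_module$dataset
  fit <- gpa(small)
  cm <- congruence_matrix(fit$aligned)
  expect_warning(
    fit_emmli(cm, list(m = toy_map(54, 2)),
              landmark_ids = small$landmark_ids),
    "small sample")
})

test_that("the signed negative between-module correlation is recovered", {
  suite <- make_paperlike_suite(11)
  ds <- suite$n74_seven_module_negative$dataset
  fit <- gpa(ds)
  al <- allometry_correct(fit, n_perm = 199, seed = 1)
  cm <- congruence_matrix(fit$aligned)
  reg <- architecture_registry()
  fs <- fit_emmli(cm, reg["VII"], abs = FALSE,
                  landmark_ids = ds$landmark_ids)
  expect_lt(fs$rho_between["oro-nasal", "molar-palate"], -0.1)
})

test_that("synthetic specs round-trip through YAML", {
  spec <- synth_spec(20, toy_map(6, 2), within_strength = 0.11,
                     allometry_strength = 0.05, seed = 17)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_synth_spec(spec, f)
  back <- read_synth_spec(f)
  expect_equal(back$n_specimens, 20L)
  expect_equal(back$within_strength, spec$within_strength)
  expect_equal(back$between_corr, spec$between_corr)
  expect_equal(back$seed, 17L)
  expect_equal(generate_landmarks(back)$coords,
               generate_landmarks(spec)$coords)
})
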