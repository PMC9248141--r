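test_that("correlation density: symmetry, normalisation, mode location", {
  r <- seq(-0.9, 0.9, 0.1)
  expect_equal(corr_density(r, 0, 30), corr_density(-r, 0, 30),
               tolerance = 1e-12)
  for (rho in c(0, 0.5, 0.9)) {
    for (n in c(15, 50)) {
      total <- integrate(function(x) corr_density(x, rho, n),
                         -1, 1, rel.tol = 1e-8)$value
      expect_equal(total, 1, tolerance = 1e-3)
    }
  }
  grid <- seq(-0.99, 0.99, 0.001)
  mode <- grid[which.max(corr_density(grid, 0.6, 100))]
  expect_lt(abs(mode - 0.6), 0.02)
  expect_error(corr_density(1, 0.5, 30), "< 1")
  expect_error(corr_density(0.5, 0.5, 4), "at least 5")
})

# correlation matrix with exact block structure
block_corr <- function(k_per = 10, n_block = 2, rho_w = 0.6, rho_b = 0.1) {
  k <- k_per * n_block
  m <- matrix(rho_b, k, k)
  for (b in seq_len(n_block)) {
    idx <- ((b - 1) * k_per + 1):(b * k_per)
    m[idx, idx] <- rho_w
  }
  diag(m) <- 1
  m
}

test_that("uniform correlations give the same rho everywhere, null wins", {
  m <- matrix(0.5, 20, 20); diag(m) <- 1
  maps <- list(two = toy_map(20, 2))
  fit <- fit_emmli(m, maps, n = 100)
  expect_equal(fit$best_architecture, "null.single.rho")
  tab <- fit$model_table
  # all parameterizations tie in likelihood; every fitted rho is 0.5
  expect_lt(diff(range(tab$logL)), 1e-8)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-9)
  fit2 <- fit_emmli(m, maps["two"], n = 100)
  d <- fit2$model_table
  expect_true(all(abs(d$AICc[d$architecture == "two"] -
                        min(d$AICc)) > 0))  # penalty decides
})

test_that("independent traits prefer the unstructured null", {
  set.seed(20)
  x <- matrix(rnorm(200 * 20), 200)
  fit <- fit_emmli(cor(x), list(two = toy_map(20, 2)), n = 200)
  expect_equal(fit$best_architecture, "null.single.rho")
})

test_that("a true 2-block structure is recovered against a shuffled map", {
  set.seed(21)
  sigma <- block_corr()
  x <- matrix(rnorm(100 * 20), 100) %*% chol(sigma)
  truth <- toy_map(20, 2, name = "truth")
  set.seed(4)
  shuffled <- module_map("shuffled",
                         stats::setNames(sample(truth$assignment), 1:20))
  fit <- fit_emmli(cor(x), list(truth = truth, shuffled = shuffled),
                   n = 100)
  expect_equal(fit$best_architecture, "truth")
  expect_lt(max(abs(fit$rho_within - 0.6)), 0.1)
  expect_true(all(fit$rho_within %in% seq(0, 0.99, 0.01)))  # on the grid
})

test_that("duplicate architectures do not change the winning AICc", {
  set.seed(22)
  x <- matrix(rnorm(80 * 12), 80) %*% chol(block_corr(6, 2))
  truth <- toy_map(12, 2, name = "truth")
  f1 <- fit_emmli(cor(x), list(truth = truth), n = 80)
  f2 <- fit_emmli(cor(x), list(truth = truth, again = truth), n = 80)
  expect_equal(min(f1$model_table$AICc), min(f2$model_table$AICc))
  expect_equal(f2$best_architecture, "truth")  # listed-order tie-break
})

test_that("likelihood is invariant to map-respecting relabeling", {
  set.seed(23)
  x <- matrix(rnorm(60 * 8), 60) %*% chol(block_corr(4, 2))
  cm <- cor(x)
  truth <- toy_map(8, 2)
  perm <- c(2, 1, 4, 3, 6, 5, 8, 7)      # permutes within modules
  f1 <- fit_emmli(cm, list(m = truth), n = 60)
  f2 <- fit_emmli(cm[perm, perm], list(m = truth), n = 60,
                  landmark_ids = 1:8)
  expect_equal(f1$model_table$logL, f2$model_table$logL, tolerance = 1e-9)
})

test_that("signed fits agree with absolute fits on positive data", {
  set.seed(24)
  x <- matrix(rnorm(120 * 12), 120) %*% chol(block_corr(6, 2, 0.5, 0.2))
  cm <- cor(x)
  fa <- fit_emmli(cm, list(m = toy_map(12, 2)), n = 120, abs = TRUE)
  fs <- fit_emmli(cm, list(m = toy_map(12, 2)), n = 120, abs = FALSE)
  expect_lte(max(abs(abs(fs$rho_within) - fa$rho_within)), 0.011)
})

test_that("unintegrated landmarks are excluded from the likelihood", {
  set.seed(25)
  cm <- block_corr(4, 3, 0.5, 0.1)
  full <- toy_map(12, 3, name = "full")
  asg <- full$assignment
  asg[asg == "M1"] <- NA
  partial <- module_map("partial", asg)
  f_full <- fit_emmli(cm, list(m = full), n = 50)
  f_part <- fit_emmli(cm, list(m = partial), n = 50)
  n_corr_full <- f_full$model_table$n_corr[1]
  n_corr_part <- f_part$model_table$n_corr[1]
  # dropping a 4-landmark module removes its 6 within pairs and 32 cross
  expect_equal(n_corr_full - n_corr_part, 6 + 4 * 8)
})

test_that("rho tables mirror the fitted classes, incl. single-pair modules", {
  vals <- diag(4)
  vals[1, 2] <- vals[2, 1] <- 0.83
  vals[3, 4] <- vals[4, 3] <- 0.41
  vals[1, 3] <- vals[3, 1] <- vals[1, 4] <- vals[4, 1] <- 0.1
  vals[2, 3] <- vals[3, 2] <- vals[2, 4] <- vals[4, 2] <- 0.1
  map <- module_map("pairs", stats::setNames(c("a", "a", "b", "b"), 1:4))
  fit <- fit_emmli(vals, list(pairs = map), n = 60)
  # grid MLE of a single correlation is its grid-rounded value
  expect_equal(unname(fit$rho_within["a"]), 0.83, tolerance = 0.011)
  expect_equal(unname(fit$rho_within["b"]), 0.41, tolerance = 0.011)
  tabs <- rho_tables(fit)
  expect_setequal(tabs$within$module, c("a", "b"))
  expect_equal(tabs$mean_rho, mean(fit$rho_within))
})

test_that("small samples and subsample edge cases behave", {
  expect_warning(fit_emmli(block_corr(3, 2), list(m = toy_map(6, 2)),
                           n = 12), "small sample")
  ds <- modular_dataset(n = 20, k = 8, seed = 6)
  sr <- subsample_robustness(ds, sizes = integer(), n_reps = 2,
                             maps = list(m = toy_map(8, 2)))
  expect_equal(nrow(sr$table), 0)
  expect_error(subsample_robustness(ds, sizes = 25,
                                    maps = list(m = toy_map(8, 2))),
               "smaller than N")
})

test_that("near-full subsamples reproduce the full-sample selection", {
  ds <- modular_dataset(n = 40, k = 12, n_mod = 2, within = 0.18, seed = 7)
  maps <- list(truth = toy_map(12, 2))
  fit <- gpa(ds)
  al <- allometry_correct(fit, n_perm = 99, seed = 1)
  full <- fit_emmli(congruence_matrix(gated_shapes(fit, al)), maps,
                    landmark_ids = ds$landmark_ids)
  sr <- subsample_robustness(ds, sizes = 39, n_reps = 5, seed = 2,
                             maps = maps, n_perm = 99)
  expect_gte(mean(sr$table$best == full$best_architecture), 0.95)
})
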