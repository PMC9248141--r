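# shared fixtures, all built in code

# small toy module map: k landmarks split evenly into n_mod named modules
toy_map <- function(k = 8, n_mod = 2, name = "toy",
                    labels = paste0("M", seq_len(n_mod))) {
  asg <- rep(labels, length.out = n_mod * ceiling(k / n_mod))[seq_len(k)]
  asg <- sort(asg)   # contiguous blocks
  module_map(name, stats::setNames(asg, seq_len(k)))
}

# quick random complete dataset (no structure)
random_dataset <- function(n = 5, k = 6, seed = 1, species = "testsp") {
  set.seed(seed)
  landmark_dataset(array(rnorm(k * 3 * n), c(k, 3, n)), species = species)
}

# modular synthetic dataset from the generator, toy scale. Template rows
# are shuffled so id-contiguous modules are spatially interleaved: module
# loading fields then lie outside the template's affine span, which the
# distance-based covariance estimator cannot separate from the mean form.
modular_dataset <- function(n = 60, k = 16, n_mod = 2, within = 0.15,
                            seed = 1, ...) {
  set.seed(seed + 1000)
  template <- ellipsoid_template(k)[sample(k), ]
  spec <- synth_spec(n, toy_map(k, n_mod), template = template,
                     within_strength = within, seed = seed,
                     loading_profile = "uniform", ...)
  generate_landmarks(spec)
}

# two-block dataset on an antipodally balanced template: each module holds
# point/antipode pairs, so both blocks share the template centroid and the
# block contrast is exactly orthogonal to the template's affine span — the
# geometry in which a distance-based (superimposition-free) covariance
# estimator can identify block structure without mean-form absorption
balanced_block_dataset <- function(n = 100, k = 20, within = 0.15,
                                   seed = 1, ...) {
  stopifnot(k %% 4 == 0 || k %% 2 == 0)
  set.seed(seed + 2000)
  half <- k / 2
  q <- ellipsoid_template(2 * k)[sample(2 * k, half), ]
  quarter <- half / 2
  tpl <- rbind(q[1:quarter, ], -q[1:quarter, ],
               q[(quarter + 1):half, ], -q[(quarter + 1):half, ])
  tpl <- sweep(tpl, 2, colMeans(tpl))
  tpl <- tpl / sqrt(sum(tpl^2))
  spec <- synth_spec(n, toy_map(k, 2), template = tpl,
                     within_strength = within,
                     loading_profile = "uniform", seed = seed, ...)
  generate_landmarks(spec)
}

# adjusted Rand index, brute force from the contingency table
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# random rotation with det +1
rand_rot <- function() {
  q <- qr(matrix(rnorm(9), 3))
  r <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(r) < 0) r[, 3] <- -r[, 3]
  r
}

# search locations for a user-supplied copy of the deposited cranial
# landmark file (466 specimens x 54 landmarks); not distributed with the
# package, so replication tests fail cleanly when it is absent
deposited_data_path <- function() {
  candidates <- c(
    testthat::test_path("data-deposited", "landmarks.csv"),
    system.file("extdata", "deposited", "landmarks.csv",
                package = "craniomod"))
  candidates <- candidates[nzchar(candidates)]
  hit <- candidates[file.exists(candidates)]
  if (length(hit)) hit[1] else NA_character_
}
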