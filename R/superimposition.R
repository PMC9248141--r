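#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the landmarks to their
#' centroid; the size measure used throughout (GPA scaling, allometry
#' regressor). Homogeneous of degree 1 in scale.
#'
#' @param config K x 3 numeric matrix, no missing landmarks.
#' @return positive scalar (0 for a fully degenerate point).
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  if (anyNA(config))
    stop("configuration has missing landmarks; run estimate_missing() first")
  ctr <- colMeans(config)
  sqrt(sum(sweep(config, 2, ctr)^2))
}

#' Generalized Procrustes Analysis
#'
#' Iterative least-squares superimposition: every configuration is translated
#' to its centroid, scaled to unit centroid size, and rotated (rotation only,
#' `det(R) = +1`; reflections are never allowed, as biological specimens
#' share chirality) onto the running consensus; the consensus is the mean of
#' the aligned configurations, re-standardised each round. Iteration stops
#' when the summed squared Procrustes distance changes by less than `tol`.
#' The final orientation is canonicalised to the consensus' principal axes,
#' which makes the output invariant to any common rigid motion or scaling of
#' the input.
#'
#' @param x a [landmark_dataset()] without missing landmarks, or a K x 3 x N
#'   array.
#' @param tol convergence tolerance on the change in total Procrustes sum of
#'   squares (default 1e-11).
#' @param max_iter iteration cap (default 200).
#' @return An object of class `gpa_fit`: `aligned` (K x 3 x N dimensionless
#'   shape coordinates), `consensus` (K x 3, unit centroid size),
#'   `centroid_sizes` (N, original units), `iterations`, `rss`.
#' @export
gpa <- function(x, tol = 1e-11, max_iter = 200L) {
  coords <- if (inherits(x, "landmark_dataset")) {
    if (any(x$missing))
      stop("dataset has missing landmarks; run estimate_missing() first")
    x$coords
  } else x
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  k <- dim(coords)[1]; n <- dim(coords)[3]
  if (k < 4) stop("GPA needs at least 4 landmarks")
  cs <- numeric(n)
  aligned <- array(NA_real_, dim(coords))
  for (i in seq_len(n)) {
    cfg <- coords[, , i]
    ci <- centroid_size(cfg)
    if (ci < 1e-12)
      stop("degenerate configuration (zero centroid size): specimen ", i)
    cs[i] <- ci
    aligned[, , i] <- sweep(cfg, 2, colMeans(cfg)) / ci
  }
  consensus <- aligned[, , 1]
  rss_old <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in seq_len(n))
      aligned[, , i] <- aligned[, , i] %*% rotation_onto(aligned[, , i],
                                                         consensus)
    consensus <- apply(aligned, 1:2, mean)
    consensus <- sweep(consensus, 2, colMeans(consensus))
    consensus <- consensus / sqrt(sum(consensus^2))
    rss <- sum(vapply(seq_len(n),
                      function(i) sum((aligned[, , i] - consensus)^2),
                      numeric(1)))
    if (abs(rss_old - rss) < tol || iter >= max_iter) break
    rss_old <- rss
  }
  if (iter >= max_iter && abs(rss_old - rss) >= tol)
    stop(sprintf("GPA did not converge in %d iterations (delta %.3e)",
                 max_iter, abs(rss_old - rss)))
  rot <- principal_axes(consensus)
  for (i in seq_len(n)) aligned[, , i] <- aligned[, , i] %*% rot
  # the reported consensus is the plain mean of the aligned shapes
  consensus <- apply(aligned, 1:2, mean)
  dimnames(aligned) <- dimnames(coords)
  structure(list(aligned = aligned, consensus = consensus,
                 centroid_sizes = cs, iterations = iter, rss = rss),
            class = "gpa_fit")
}

# optimal rotation (no reflection) of a onto b, both centered
rotation_onto <- function(a, b) {
  s <- svd(crossprod(a, b))
  r <- s$u %*% t(s$v)
  if (det(r) < 0) {
    u <- s$u; u[, 3] <- -u[, 3]
    r <- u %*% t(s$v)
  }
  r
}

# canonical orientation: principal axes with deterministic sign, det +1
principal_axes <- function(m) {
  e <- eigen(crossprod(m), symmetric = TRUE)
  v <- e$vectors
  scores <- m %*% v
  for (j in 1:3) {
    pick <- which.max(abs(scores[, j]))
    if (scores[pick, j] < 0) v[, j] <- -v[, j]
  }
  if (det(v) < 0) v[, 3] <- -v[, 3]
  v
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat(sprintf("<gpa_fit> %d specimens x %d landmarks, %d iterations, RSS %.4g\n",
              dim(x$aligned)[3], dim(x$aligned)[1], x$iterations, x$rss))
  invisible(x)
}

#' Static allometry correction by Procrustes regression on centroid size
#'
#' Regresses the flattened aligned shape coordinates on centroid size (one
#' predictor), measures the explained fraction of shape variance under the
#' Procrustes metric, and assesses significance by permuting size labels
#' (statistic: model sum of squares). Allometry-corrected shapes are the
#' regression residuals added back to the consensus. When `p_value > alpha`
#' the correction is *not applied*: downstream analyses should use the raw
#' aligned shapes (`applied` records the decision; `corrected` is always
#' returned for sensitivity analysis).
#'
#' @param fit a [gpa()] result.
#' @param n_perm number of size-label permutations (default 999; the observed
#'   statistic is always included in the null).
#' @param seed integer seed for the permutations.
#' @param alpha significance gate for "static allometry detected"
#'   (default 0.05).
#' @param log_size regress on log centroid size instead of raw size
#'   (default `FALSE`).
#' @return An object of class `allometry_fit`: `r_squared`, `p_value`,
#'   `applied`, `corrected` (K x 3 x N), `slope` (3K), plus the inputs'
#'   metadata (`n_perm`, `seed`, `alpha`, `log_size`).
#' @export
allometry_correct <- function(fit, n_perm = 999L, seed = NULL, alpha = 0.05,
                              log_size = FALSE) {
  stopifnot(inherits(fit, "gpa_fit"))
  n <- dim(fit$aligned)[3]
  if (n < 3) stop("allometry regression needs at least 3 specimens")
  if (!is.null(seed)) set.seed(seed)
  y <- t(apply(fit$aligned, 3, as.vector))          # N x 3K
  x <- if (log_size) log(fit$centroid_sizes) else fit$centroid_sizes
  if (stats::var(x) < .Machine$double.eps)
    stop("centroid sizes are constant; no allometry regressor")
  xc <- x - mean(x)
  yc <- sweep(y, 2, colMeans(y))
  ss_tot <- sum(yc^2)
  b <- crossprod(xc, yc) / sum(xc^2)                # 1 x 3K slope
  ss_mod <- sum(xc^2) * sum(b^2)
  perm_stats <- vapply(seq_len(n_perm), function(i) {
    xp <- sample(xc)
    sum(crossprod(xp, yc)^2) / sum(xp^2)
  }, numeric(1))
  p <- (sum(perm_stats >= ss_mod) + 1) / (n_perm + 1)
  resid <- yc - outer(as.vector(xc), as.vector(b))
  corrected <- array(t(resid + rep(as.vector(fit$consensus),
                                   each = n)),
                     dim(fit$aligned), dimnames(fit$aligned))
  structure(list(r_squared = ss_mod / ss_tot, p_value = p,
                 applied = p <= alpha, corrected = corrected,
                 slope = as.vector(b), consensus = fit$consensus,
                 n_perm = n_perm, seed = seed, alpha = alpha,
                 log_size = log_size),
            class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf(
    "<allometry_fit> r2 = %.4f, p = %.4g (%d perms), correction %s\n",
    x$r_squared, x$p_value, x$n_perm,
    if (x$applied) "APPLIED" else "not applied"))
  invisible(x)
}

#' Shapes selected by the allometry gate
#'
#' The reporting rule of the pipeline: allometry-corrected shapes when static
#' allometry was detected (`p <= alpha`), raw aligned shapes otherwise.
#'
#' @param fit a [gpa()] result.
#' @param allom the matching [allometry_correct()] result.
#' @param force `NULL` for the gate, or `"raw"`/`"corrected"` to force a
#'   branch for sensitivity analysis.
#' @return K x 3 x N array.
#' @export
gated_shapes <- function(fit, allom, force = NULL) {
  branch <- force %||% (if (allom$applied) "corrected" else "raw")
  switch(match.arg(branch, c("raw", "corrected")),
         raw = fit$aligned, corrected = allom$corrected)
}
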