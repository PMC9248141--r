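#' Squared-distance form matrix of a configuration
#'
#' Entry (i, j) is the squared Euclidean distance between landmarks i and j.
#' Invariant to rotation and translation; scales with the square of size.
#'
#' @param config K x 3 numeric matrix, no missing landmarks.
#' @return K x K symmetric matrix with zero diagonal.
#' @export
form_matrix <- function(config) {
  config <- as.matrix(config)
  if (anyNA(config)) stop("configuration has missing landmarks")
  as.matrix(stats::dist(config))^2
}

#' EDMA mean form and landmark covariance
#'
#' Moment estimator under the Gaussian perturbation model, operating purely
#' on interlandmark distances (no superimposition). For each specimen the
#' squared-distance matrix `D_i` is double-centered, `B_i = -1/2 H D_i H`
#' (`H = I - 11'/K`), and averaged. Under isotropic landmark noise the
#' expected average is the mean-form Gram matrix plus a noise term that is
#' (close to) a multiple of `H`, so the noise level is estimated from the
#' eigenvalues beyond rank 3 and subtracted from the leading three before
#' reconstructing the mean shape. The landmark covariance is then
#' `sigma_k = (B_bar - G_M) / 3` (divided by the number of coordinate
#' dimensions), with `G_M` the reconstructed Gram matrix.
#'
#' @param x a [landmark_dataset()] without missing landmarks, or a
#'   K x 3 x N array. N >= 2, K >= 4.
#' @return An object of class `edma_fit`: `mean_shape` (K x 3, defined up to
#'   rigid motion), `mean_form_sq` (K x K estimated squared distances),
#'   `sigma_k` (K x K landmark covariance), `noise_level` (estimated
#'   per-eigenvalue noise), `negative_clamped` (count of clamped negative
#'   squared distances, normally 0).
#' @export
edma_mean_form <- function(x) {
  coords <- if (inherits(x, "landmark_dataset")) {
    if (any(x$missing)) stop("dataset has missing landmarks")
    x$coords
  } else x
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  k <- dim(coords)[1]; n <- dim(coords)[3]
  if (k < 4) stop("EDMA mean form needs at least 4 landmarks")
  if (n < 2) stop("EDMA mean form needs at least 2 specimens")
  H <- diag(k) - matrix(1 / k, k, k)
  b_bar <- matrix(0, k, k)
  for (i in seq_len(n))
    b_bar <- b_bar + (-0.5) * H %*% form_matrix(coords[, , i]) %*% H
  b_bar <- b_bar / n
  e <- eigen(b_bar, symmetric = TRUE)
  # centered space has rank K-1; eigenvalues 4..K-1 estimate the noise floor
  noise <- if (k > 4) mean(e$values[4:(k - 1)]) else e$values[4]
  noise <- max(noise, 0)
  lead <- e$values[1:3] - noise
  if (any(lead <= 0))
    warning("fewer than 3 positive noise-corrected eigenvalues; ",
            "mean shape is rank deficient")
  mean_shape <- e$vectors[, 1:3] %*% diag(sqrt(pmax(lead, 0)))
  mean_form_sq <- as.matrix(stats::dist(mean_shape))^2
  g_m <- tcrossprod(mean_shape)
  sigma_k <- (b_bar - g_m) / 3
  sigma_k <- (sigma_k + t(sigma_k)) / 2
  rownames(mean_shape) <- dimnames(coords)[[1]]
  dimnames(sigma_k) <- dimnames(mean_form_sq) <-
    list(dimnames(coords)[[1]], dimnames(coords)[[1]])
  structure(list(mean_shape = mean_shape, mean_form_sq = mean_form_sq,
                 sigma_k = sigma_k, noise_level = noise,
                 negative_clamped = 0L, n = n),
            class = "edma_fit")
}

#' @export
print.edma_fit <- function(x, ...) {
  cat(sprintf("<edma_fit> K=%d landmarks from %d specimens, noise ~ %.3g\n",
              nrow(x$mean_shape), x$n, x$noise_level))
  invisible(x)
}

#' Inter-trait Euclidean distances from a landmark covariance matrix
#'
#' Eigen-decomposes `sigma_k`, keeps the strictly positive eigenvalues,
#' scales the eigenvectors by the square roots of their eigenvalues (so that
#' on a positive semidefinite input the pairwise distances reproduce the Gram
#' identity `d(i,j) = sqrt(S_ii + S_jj - 2 S_ij)` exactly), and returns the
#' Euclidean distance matrix between the resulting trait rows.
#'
#' @param sigma_k K x K symmetric matrix (PSD not required; non-positive
#'   modes are dropped and counted).
#' @return A list of class `trait_space`: `distances` (K x K), `coords`
#'   (K x d trait coordinates), `n_dropped` (non-positive eigenvalues
#'   dropped).
#' @export
trait_distances <- function(sigma_k) {
  sigma_k <- as.matrix(sigma_k)
  stopifnot(nrow(sigma_k) == ncol(sigma_k))
  if (max(abs(sigma_k - t(sigma_k))) > 1e-8 * max(1, max(abs(sigma_k))))
    stop("sigma_k must be symmetric")
  e <- eigen((sigma_k + t(sigma_k)) / 2, symmetric = TRUE)
  keep <- e$values > 0
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
  rownames(coords) <- rownames(sigma_k)
  d <- as.matrix(stats::dist(coords))
  structure(list(distances = d, coords = coords,
                 n_dropped = sum(!keep)),
            class = "trait_space")
}

#' Distance-variance landmark filter
#'
#' For every landmark pair the across-specimen mean and variance of the
#' (unsquared) interlandmark distance are computed; a landmark is flagged for
#' exclusion when at least one of its distances has variance larger than its
#' mean (a symptom of landmarks placed exceptionally close together, where
#' digitizing noise swamps the signal). Members of bilateral pairs are never
#' removed: if one side triggers, both are retained and a warning is issued,
#' so anatomical regions stay integrally represented.
#'
#' @param dataset a [landmark_dataset()] without missing landmarks, N >= 2.
#' @return A list of class `variance_filter`: `kept` / `excluded` landmark
#'   ids, `protected` (triggered but bilateral, retained), and `table` (one
#'   row per pair: ids, mean, variance, trigger flag).
#' @export
variance_filter <- function(dataset) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  if (any(dataset$missing)) stop("dataset has missing landmarks")
  n <- n_specimens(dataset); k <- n_landmarks(dataset)
  if (n < 2) stop("variance filter needs at least 2 specimens")
  dists <- vapply(seq_len(n),
                  function(i) as.vector(stats::dist(dataset$coords[, , i])),
                  numeric(k * (k - 1) / 2))
  mu <- rowMeans(dists)
  v <- apply(dists, 1, stats::var)
  pair_idx <- which(lower.tri(matrix(0, k, k)), arr.ind = TRUE)
  tab <- data.frame(id_a = dataset$landmark_ids[pair_idx[, 2]],
                    id_b = dataset$landmark_ids[pair_idx[, 1]],
                    mean = mu, variance = v,
                    trigger = v > mu)
  flagged <- unique(c(tab$id_a[tab$trigger], tab$id_b[tab$trigger]))
  bilateral <- unique(as.vector(dataset$bilateral_pairs))
  protected <- intersect(flagged, bilateral)
  excluded <- setdiff(flagged, bilateral)
  if (length(protected))
    warning("bilateral landmark(s) triggered the variance filter but are ",
            "retained: #", paste(protected, collapse = ", #"))
  structure(list(kept = setdiff(dataset$landmark_ids, excluded),
                 excluded = excluded, protected = protected, table = tab),
            class = "variance_filter")
}

#' @export
print.variance_filter <- function(x, ...) {
  cat(sprintf("<variance_filter> %d kept, %d excluded%s\n",
              length(x$kept), length(x$excluded),
              if (length(x$protected))
                sprintf(", %d bilateral protected", length(x$protected))
              else ""))
  invisible(x)
}
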