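#' Fit a thin-plate spline map between two point sets
#'
#' Biharmonic spline in 3D with kernel U(r) = r (the 2D variant
#' U(r) = r^2 log r is available for completeness). The map interpolates
#' `target` exactly at `source` and extends smoothly elsewhere; its affine
#' part absorbs translation, rotation and uniform scaling, so warping a
#' configuration onto a rigidly moved copy of itself reproduces the motion
#' exactly.
#'
#' @param source m x d matrix of control points (d = 2 or 3).
#' @param target m x d matrix of their images.
#' @return A list of class `tps_map` with the spline weights and affine part.
#' @export
tps_fit <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(nrow(source) == nrow(target), ncol(source) == ncol(target))
  d <- ncol(source)
  m <- nrow(source)
  if (m < d + 1) stop("need at least ", d + 1, " control points")
  if (qr(cbind(1, source))$rank < d + 1)
    stop("degenerate (collinear/coplanar) control point set")
  K <- tps_kernel(as.matrix(stats::dist(source)), d)
  P <- cbind(1, source)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, d + 1, d + 1)))
  rhs <- rbind(target, matrix(0, d + 1, d))
  sol <- solve(L, rhs)
  structure(list(source = source, weights = sol[seq_len(m), , drop = FALSE],
                 affine = sol[(m + 1):(m + d + 1), , drop = FALSE], dim = d),
            class = "tps_map")
}

tps_kernel <- function(r, d) {
  if (d == 3L) r else ifelse(r == 0, 0, r^2 * log(r))
}

#' Apply a fitted thin-plate spline map to new points
#' @param map a [tps_fit()] result.
#' @param x q x d matrix of points to warp.
#' @return q x d matrix of warped points.
#' @export
tps_apply <- function(map, x) {
  x <- matrix(x, ncol = map$dim)
  dists <- sqrt(outer(rowSums(x^2), rowSums(map$source^2), "+") -
                  2 * x %*% t(map$source))
  dists[dists < 0 | is.nan(dists)] <- 0
  cbind(1, x) %*% map$affine + tps_kernel(dists, map$dim) %*% map$weights
}

#' Estimate missing landmarks by thin-plate spline interpolation
#'
#' For each incomplete specimen, a TPS map is fitted from the reference's
#' landmarks present in that specimen to the specimen's observed landmarks,
#' and the reference positions of the missing landmarks are pushed through
#' the map. The reference is the Procrustes consensus of the complete
#' specimens of the dataset (a single complete specimen serves directly).
#' Complete specimens are returned unchanged, so the operation is idempotent
#' on complete datasets.
#'
#' @param dataset a [landmark_dataset()]; must contain at least one complete
#'   specimen, and every incomplete specimen needs >= 4 non-coplanar present
#'   landmarks.
#' @return A [landmark_dataset()] with every missing mask cleared; the number
#'   of imputed landmark slots is attached as attribute `imputed_count`.
#' @export
estimate_missing <- function(dataset) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  if (!any(dataset$missing)) {
    attr(dataset, "imputed_count") <- 0L
    return(dataset)
  }
  complete <- which(colSums(dataset$missing) == 0)
  if (!length(complete))
    stop("no complete specimen available to build the TPS reference; ",
         "supply a manual reference or impute in stages")
  reference <- if (length(complete) == 1) {
    dataset$coords[, , complete]
  } else {
    gpa(subset_specimens(dataset, complete))$consensus
  }
  coords <- dataset$coords
  imputed <- 0L
  for (s in which(colSums(dataset$missing) > 0)) {
    present <- !dataset$missing[, s]
    if (sum(present) < 4)
      stop("specimen ", dataset$specimen_ids[s],
           " has fewer than 4 present landmarks")
    map <- tryCatch(
      tps_fit(reference[present, , drop = FALSE],
              coords[present, , s]),
      error = function(e) stop("degenerate landmark support for specimen ",
                               dataset$specimen_ids[s], ": ",
                               conditionMessage(e)))
    coords[!present, , s] <- tps_apply(map,
                                       reference[!present, , drop = FALSE])
    imputed <- imputed + sum(!present)
  }
  out <- landmark_dataset(coords, species = dataset$species,
                          specimen_ids = dataset$specimen_ids,
                          landmark_ids = dataset$landmark_ids,
                          landmark_labels = dataset$landmark_labels,
                          bilateral_pairs = dataset$bilateral_pairs)
  attr(out, "imputed_count") <- imputed
  out
}
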