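#' Congruence-coefficient landmark correlation matrix
#'
#' For two landmarks a and b, each landmark's coordinates are centered by
#' their per-dimension mean across specimens, giving N x 3 deviation
#' matrices A and B; the congruence coefficient is the uncentered vector
#' correlation pooled over the three dimensions,
#' `sum(A * B) / sqrt(sum(A^2) * sum(B^2))`. A single coefficient per
#' landmark pair (not a per-dimension average). The diagonal is exactly 1.
#' In the degenerate 1-D case (y = z = 0) the coefficient reduces to the
#' Pearson correlation of the x deviations.
#'
#' @param shapes K x 3 x N array of aligned (or allometry-corrected) shape
#'   coordinates, N >= 3.
#' @param source `"raw_aligned"` or `"allometry_corrected"`, recorded for
#'   provenance.
#' @return An object of class `congruence_matrix`: `values` (K x K symmetric,
#'   unit diagonal, entries in \[-1, 1\]), `n_specimens`, `source`.
#' @export
congruence_matrix <- function(shapes,
                              source = c("raw_aligned",
                                         "allometry_corrected")) {
  source <- match.arg(source)
  stopifnot(length(dim(shapes)) == 3L, dim(shapes)[2] == 3L)
  k <- dim(shapes)[1]; n <- dim(shapes)[3]
  if (n < 3) stop("congruence matrix needs at least 3 specimens")
  # deviations: center each landmark's trajectory across specimens
  dev <- array(NA_real_, c(n, 3, k))
  for (l in seq_len(k)) {
    traj <- t(shapes[l, , ])               # N x 3
    dev[, , l] <- sweep(traj, 2, colMeans(traj))
  }
  flat <- matrix(dev, n * 3, k)            # 3N x K, pooled dimensions
  norms <- sqrt(colSums(flat^2))
  zero <- which(norms < 1e-12)
  if (length(zero))
    stop("zero-variance landmark(s): ",
         paste(dimnames(shapes)[[1]][zero] %||% zero, collapse = ", "),
         " (filter or jitter upstream)")
  values <- crossprod(flat) / tcrossprod(norms)
  values <- (values + t(values)) / 2
  values[values > 1] <- 1; values[values < -1] <- -1
  diag(values) <- 1
  dimnames(values) <- list(dimnames(shapes)[[1]], dimnames(shapes)[[1]])
  structure(list(values = values, n_specimens = n, source = source),
            class = "congruence_matrix")
}

#' @export
print.congruence_matrix <- function(x, ...) {
  cat(sprintf("<congruence_matrix> %d landmarks, N=%d, source=%s\n",
              nrow(x$values), x$n_specimens, x$source))
  invisible(x)
}
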