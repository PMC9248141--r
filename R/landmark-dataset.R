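#' Construct a multi-specimen landmark dataset
#'
#' The central data container of the package: a set of N specimen
#' configurations, each of K 3D landmarks, for one species. Missing landmarks
#' are carried explicitly as a logical mask (and as `NA` coordinates), never
#' as silent zeros.
#'
#' @param coords numeric array of dimension `K x 3 x N` (landmark, coordinate
#'   dimension, specimen), in the original length units (e.g. mm). `NA` rows
#'   mark missing landmarks.
#' @param species single character string naming the species.
#' @param specimen_ids character vector of length N; must be unique for a
#'   valid dataset (duplicates are reported by [validate_landmarks()]).
#' @param landmark_ids integer vector of length K. 1-based anatomical
#'   numbering (the "#n" convention); internal array indexing is positional.
#' @param landmark_labels optional character vector of length K.
#' @param bilateral_pairs optional two-column integer matrix of
#'   (left_id, right_id) landmark id pairs.
#' @param missing optional `K x N` logical mask; derived from `NA` coordinates
#'   when omitted.
#'
#' @return An object of class `landmark_dataset`: a list with elements
#'   `coords`, `missing`, `species`, `specimen_ids`, `landmark_ids`,
#'   `landmark_labels`, `bilateral_pairs`.
#' @export
landmark_dataset <- function(coords, species = "unknown",
                             specimen_ids = NULL,
                             landmark_ids = NULL,
                             landmark_labels = NULL,
                             bilateral_pairs = NULL,
                             missing = NULL) {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  k <- dim(coords)[1]
  n <- dim(coords)[3]
  if (n < 1L) stop("a landmark dataset needs at least one configuration")
  if (is.null(specimen_ids)) specimen_ids <- sprintf("spec_%03d", seq_len(n))
  if (length(specimen_ids) != n) stop("specimen_ids length must equal N")
  if (is.null(landmark_ids)) landmark_ids <- seq_len(k)
  landmark_ids <- as.integer(landmark_ids)
  if (length(landmark_ids) != k) stop("landmark_ids length must equal K")
  if (anyDuplicated(landmark_ids)) stop("landmark_ids must be unique")
  if (is.null(landmark_labels)) landmark_labels <- sprintf("LM%02d", landmark_ids)
  if (length(landmark_labels) != k) stop("landmark_labels length must equal K")
  derived_missing <- matrix(apply(is.na(coords), c(1, 3), any), k, n)
  if (is.null(missing)) {
    missing <- derived_missing
  } else {
    missing <- matrix(as.logical(missing), k, n)
    if (any(derived_missing & !missing))
      stop("non-missing landmark rows contain non-finite values")
  }
  # a flagged-missing row must not keep stale coordinates
  for (j in seq_len(n)) coords[missing[, j], , j] <- NA_real_
  present <- coords[!is.na(coords)]
  if (length(present) && !all(is.finite(present)))
    stop("non-missing landmark coordinates must be finite")
  if (!is.null(bilateral_pairs)) {
    bilateral_pairs <- matrix(as.integer(bilateral_pairs), ncol = 2L)
    if (!all(bilateral_pairs %in% landmark_ids))
      stop("bilateral pair references unknown landmark id")
  }
  dimnames(coords) <- list(landmark_labels, c("x", "y", "z"), specimen_ids)
  structure(list(coords = coords, missing = missing, species = species,
                 specimen_ids = specimen_ids, landmark_ids = landmark_ids,
                 landmark_labels = landmark_labels,
                 bilateral_pairs = bilateral_pairs),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat(sprintf("<landmark_dataset> %s: %d specimens x %d landmarks\n",
              x$species, n_specimens(x), n_landmarks(x)))
  nm <- sum(x$missing)
  if (nm > 0) cat(sprintf("  %d missing landmark slots (%.1f%%)\n",
                          nm, 100 * nm / length(x$missing)))
  if (!is.null(x$bilateral_pairs))
    cat(sprintf("  %d bilateral pairs\n", nrow(x$bilateral_pairs)))
  invisible(x)
}

#' Number of specimens / landmarks in a dataset
#' @param dataset a [landmark_dataset()].
#' @return integer count.
#' @export
n_specimens <- function(dataset) dim(dataset$coords)[3]

#' @rdname n_specimens
#' @export
n_landmarks <- function(dataset) dim(dataset$coords)[1]

#' Extract one configuration as a K x 3 matrix
#' @param dataset a [landmark_dataset()].
#' @param i specimen index or id.
#' @return K x 3 numeric matrix (`NA` rows where missing).
#' @export
configuration <- function(dataset, i) {
  if (is.character(i)) i <- match(i, dataset$specimen_ids)
  dataset$coords[, , i]
}

#' Subset a dataset by specimens
#' @param dataset a [landmark_dataset()].
#' @param idx integer or logical specimen index.
#' @return a [landmark_dataset()] with the selected specimens.
#' @export
subset_specimens <- function(dataset, idx) {
  landmark_dataset(dataset$coords[, , idx, drop = FALSE],
                   species = dataset$species,
                   specimen_ids = dataset$specimen_ids[idx],
                   landmark_ids = dataset$landmark_ids,
                   landmark_labels = dataset$landmark_labels,
                   bilateral_pairs = dataset$bilateral_pairs)
}

#' Validate a landmark dataset and report structural issues
#'
#' Report-only check: lists duplicate specimen ids, landmarks missing in every
#' specimen, zero-variance landmarks, and a K/N summary. Never mutates data.
#'
#' @param dataset a [landmark_dataset()].
#' @return A list of class `landmark_validation` with elements `n_specimens`,
#'   `n_landmarks`, `issues` (character vector, empty when clean),
#'   `duplicated_specimens`, `all_missing_landmarks`,
#'   `zero_variance_landmarks`.
#' @export
validate_landmarks <- function(dataset) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  issues <- character()
  dup <- unique(dataset$specimen_ids[duplicated(dataset$specimen_ids)])
  if (length(dup))
    issues <- c(issues, sprintf("duplicate specimen id: %s", dup))
  all_missing <- dataset$landmark_ids[rowSums(!dataset$missing) == 0]
  if (length(all_missing))
    issues <- c(issues, sprintf("landmark #%d missing in every specimen",
                                all_missing))
  zv <- integer()
  if (n_specimens(dataset) >= 2) {
    for (l in seq_len(n_landmarks(dataset))) {
      xs <- dataset$coords[l, , !dataset$missing[l, ], drop = FALSE]
      if (dim(xs)[3] >= 2 &&
          all(apply(xs, 1:2, stats::var)[1, ] < .Machine$double.eps))
        zv <- c(zv, dataset$landmark_ids[l])
    }
    if (length(zv))
      issues <- c(issues, sprintf("landmark #%d has zero variance", zv))
  }
  structure(list(n_specimens = n_specimens(dataset),
                 n_landmarks = n_landmarks(dataset),
                 issues = issues,
                 duplicated_specimens = dup,
                 all_missing_landmarks = all_missing,
                 zero_variance_landmarks = zv),
            class = "landmark_validation")
}

#' @export
print.landmark_validation <- function(x, ...) {
  cat(sprintf("<validation> N=%d K=%d: %s\n", x$n_specimens, x$n_landmarks,
              if (length(x$issues)) paste(length(x$issues), "issue(s)")
              else "clean"))
  for (i in x$issues) cat(" -", i, "\n")
  invisible(x)
}
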