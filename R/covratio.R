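# Covariance-ratio (CR) modularity statistic, permutation test, effect size
# and pairwise architecture comparison.

#' Covariance ratio from a trait covariance matrix
#'
#' For modules A and B with between-block covariance `S_AB` and within-block
#' covariances with zeroed diagonals `S~_AA`, `S~_BB`:
#' `CR_AB = sqrt( tr(S_AB' S_AB) / sqrt( tr(S~_AA S~_AA) tr(S~_BB S~_BB) ) )`.
#' With more than two modules the overall CR is the unweighted mean of the
#' pairwise values. Values below 1 indicate relatively weak between-module
#' covariance, i.e. modularity.
#'
#' @param S trait covariance matrix (symmetric).
#' @param groups factor/character of length `ncol(S)` assigning each trait
#'   to a module.
#' @param blocks optional trait -> block labels: traits sharing a block (a
#'   landmark's x, y, z columns) have their mutual covariances excluded from
#'   the within-module denominator along with the diagonal, which keeps the
#'   statistic invariant to a common rotation of the coordinate system.
#'   Default: every trait is its own block (only the diagonal is zeroed).
#' @return list with `cr` (overall) and `pairwise` (module x module matrix).
#' @export
cr_from_cov <- function(S, groups, blocks = NULL) {
  S <- as.matrix(S)
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(S))
  if (is.null(blocks)) blocks <- seq_len(ncol(S))
  stopifnot(length(blocks) == ncol(S))
  mods <- levels(droplevels(groups))
  if (length(mods) < 2)
    stop("covariance ratio undefined for fewer than 2 modules")
  P <- S^2
  same_block <- outer(blocks, blocks, "==")
  # within-module sum of squared entries outside same-block cells = tr(S~ S~)
  wss <- vapply(mods, function(m) {
    idx <- which(groups == m)
    sum(P[idx, idx][!same_block[idx, idx]])
  }, numeric(1))
  if (any(wss <= 0))
    stop("module(s) with no within-module covariance (CR undefined): ",
         paste(mods[wss <= 0], collapse = ", "))
  pairwise <- matrix(NA_real_, length(mods), length(mods),
                     dimnames = list(mods, mods))
  for (i in seq_along(mods)) for (j in seq_along(mods)) {
    if (j <= i) next
    num <- sum(P[groups == mods[i], groups == mods[j]])
    pairwise[i, j] <- pairwise[j, i] <- sqrt(num / sqrt(wss[i] * wss[j]))
  }
  list(cr = mean(pairwise[upper.tri(pairwise)]), pairwise = pairwise)
}

# expand a module map over landmarks to per-coordinate trait groups;
# unintegrated landmarks form their own module ("unintegrated")
map_to_groups <- function(map, landmark_ids) {
  asg <- map$assignment[as.character(landmark_ids)]
  asg[is.na(asg)] <- "unintegrated"
  rep(asg, each = 3)
}

#' Covariance-ratio statistic of a modular architecture on shape data
#'
#' Builds the 3K x 3K specimen covariance matrix of the flattened aligned
#' coordinates (each landmark's three coordinates travel together) and
#' evaluates [cr_from_cov()] under the architecture. Unintegrated landmarks
#' are treated as a module of their own, so an architecture that differs
#' from another only by marking a module unintegrated scores identically.
#'
#' @param shapes K x 3 x N array of (aligned or corrected) shapes, N >= 3.
#' @param map a [module_map()].
#' @param landmark_ids ids linking array rows to the map (default 1..K).
#' @return list with `cr` and `pairwise` (see [cr_from_cov()]).
#' @export
cr_statistic <- function(shapes, map, landmark_ids = NULL) {
  stopifnot(length(dim(shapes)) == 3L, dim(shapes)[2] == 3L)
  k <- dim(shapes)[1]
  if (dim(shapes)[3] < 3) stop("CR needs at least 3 specimens")
  if (is.null(landmark_ids)) landmark_ids <- seq_len(k)
  S <- stats::cov(t(apply(shapes, 3, function(m) as.vector(t(m)))))
  cr_from_cov(S, map_to_groups(map, landmark_ids),
              blocks = rep(seq_len(k), each = 3))
}

#' Permutation test and effect size for the covariance ratio
#'
#' The null distribution is generated by randomly reassigning whole
#' landmarks (their three coordinates together) to modules while preserving
#' module sizes, recomputing CR each time. Modularity is evidenced by a
#' *small* observed CR, so `p = (#\{CR_perm <= CR_obs\} + 1) / (n_perm + 1)`.
#' The effect size standardises a variance-stabilising transform of CR
#' (log by default) against the same permutation draw:
#' `Z_CR = (t(CR_obs) - mean t(CR_perm)) / sd t(CR_perm)`; more negative
#' values mean stronger modular signal.
#'
#' @param shapes K x 3 x N array.
#' @param map a [module_map()] (must yield >= 2 modules, counting
#'   unintegrated landmarks as one).
#' @param n_perm permutations (default 999; fewer than 99 draws a warning).
#' @param seed integer seed.
#' @param landmark_ids ids linking array rows to the map.
#' @param transform variance-stabilising transform for the effect size
#'   (`"log"`, the default, or `"identity"`).
#' @return An object of class `cr_test`: `cr`, `pairwise`, `p_value`,
#'   `z_score`, `perm_mean`, `perm_sd` (on the transformed scale), `n_perm`,
#'   `seed`, `transform`, `map_name`, `data_signature`.
#' @export
cr_test <- function(shapes, map, n_perm = 999L, seed = NULL,
                    landmark_ids = NULL, transform = c("log", "identity")) {
  transform <- match.arg(transform)
  tf <- if (transform == "log") log else identity
  k <- dim(shapes)[1]
  if (is.null(landmark_ids)) landmark_ids <- seq_len(k)
  if (n_perm < 99) warning("fewer than 99 permutations")
  if (!is.null(seed)) set.seed(seed)
  groups_lm <- {
    asg <- map$assignment[as.character(landmark_ids)]
    asg[is.na(asg)] <- "unintegrated"
    asg
  }
  if (length(unique(groups_lm)) < 2)
    stop("CR test undefined for a single-module architecture")
  S <- stats::cov(t(apply(shapes, 3, function(m) as.vector(t(m)))))
  blocks <- rep(seq_len(k), each = 3)
  obs <- cr_from_cov(S, rep(groups_lm, each = 3), blocks = blocks)
  perm <- vapply(seq_len(n_perm), function(i) {
    cr_from_cov(S, rep(sample(groups_lm), each = 3), blocks = blocks)$cr
  }, numeric(1))
  p <- (sum(perm <= obs$cr) + 1) / (n_perm + 1)
  tperm <- tf(perm)
  z <- (tf(obs$cr) - mean(tperm)) / stats::sd(tperm)
  structure(list(cr = obs$cr, pairwise = obs$pairwise, p_value = p,
                 z_score = z, perm_mean = mean(tperm),
                 perm_sd = stats::sd(tperm), n_perm = n_perm, seed = seed,
                 transform = transform, map_name = map$name,
                 data_signature = data_signature(shapes)),
            class = "cr_test")
}

data_signature <- function(shapes) {
  c(dim(shapes), sum(shapes), sum(shapes^2))
}

#' @export
print.cr_test <- function(x, ...) {
  cat(sprintf("<cr_test> %s: CR = %.3f, p = %.4g, Z_CR = %.2f (%d perms)\n",
              x$map_name, x$cr, x$p_value, x$z_score, x$n_perm))
  invisible(x)
}

#' Pairwise comparison of covariance-ratio effect sizes
#'
#' Compares competing architectures tested on the same shapes: for each pair
#' the statistic is `(Z_A - Z_B) / sqrt(2)` referred to a standard normal
#' (each Z is standardised to unit variance under its own permutation null;
#' the two-sample form is an approximation of the published pairwise
#' procedure). The architecture with the most negative Z carries the
#' strongest modular signal.
#'
#' @param results list of [cr_test()] objects computed on the same shapes
#'   with the same `n_perm`.
#' @return A list of class `cr_comparison`: `z_scores` (named), `statistic`
#'   and `p_value` (architecture x architecture matrices), `strongest`.
#' @export
compare_cr <- function(results) {
  if (inherits(results, "cr_test")) results <- list(results)
  stopifnot(all(vapply(results, inherits, logical(1), "cr_test")))
  if (length(results) < 2) stop("need at least two CR results to compare")
  sigs <- lapply(results, `[[`, "data_signature")
  if (!all(vapply(sigs, identical, logical(1), sigs[[1]])))
    stop("CR results were not computed on the same shape data")
  nperms <- vapply(results, `[[`, numeric(1), "n_perm")
  if (length(unique(nperms)) != 1)
    stop("CR results use different permutation counts")
  nms <- vapply(results, `[[`, character(1), "map_name")
  z <- stats::setNames(vapply(results, `[[`, numeric(1), "z_score"), nms)
  stat <- outer(z, z, `-`) / sqrt(2)
  p <- 2 * stats::pnorm(-base::abs(stat))
  structure(list(z_scores = z, statistic = stat, p_value = p,
                 strongest = unname(nms[which.min(z)])),
            class = "cr_comparison")
}

#' @export
print.cr_comparison <- function(x, ...) {
  cat("<cr_comparison> Z_CR:\n")
  print(round(x$z_scores, 2))
  cat("strongest modular signal:", x$strongest, "\n")
  invisible(x)
}
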