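# Exploratory clustering arm: Ward trees over trait distances, Gap-statistic
# selection of k, bootstrap Jaccard stability, and the reduction loop that
# shrinks k until every cluster is stable.

ward_cut <- function(x, k) {
  list(cluster = stats::cutree(
    stats::hclust(stats::dist(x), method = "ward.D2"), k = k))
}

#' Ward clustering of traits at a fixed number of clusters
#'
#' Agglomerative clustering with the Ward criterion (squared-distance
#' variant, "ward.D2") on a trait distance matrix, cut into `k` clusters.
#'
#' @param trait_distance K' x K' symmetric distance matrix (or `dist`).
#' @param k number of clusters, `2 <= k <= K'`.
#' @return integer vector of cluster labels (1..k, tree-cut order).
#' @export
cluster_traits <- function(trait_distance, k) {
  d <- stats::as.dist(trait_distance)
  kp <- attr(d, "Size")
  if (k < 1 || k > kp) stop("k must be between 1 and ", kp)
  stats::cutree(stats::hclust(d, method = "ward.D2"), k = k)
}

#' Gap-statistic selection of the number of clusters
#'
#' Computes `Gap(k) = mean_b log(W*_kb) - log(W_k)` for k = 1..`k_max`, with
#' W the within-cluster sum of pairwise-distance dispersion, Ward clustering,
#' and reference sets drawn uniformly over the observed per-feature ranges
#' (via [cluster::clusGap()]). Two selection rules are reported:
#' * primary — the smallest k with `Gap(k) >= Gap(k+1) - SE(k+1)`
#'   (Tibshirani's one-standard-error rule);
#' * plateau fallback — the smallest k after which every further split gains
#'   less than `plateau_tol` (default: the median standard error of the Gap
#'   curve). Used when the primary rule returns k = 1 while the curve keeps
#'   rising, the situation observed for weakly separated cranial data.
#'
#' @param trait_coords K' x d trait coordinate matrix (from
#'   [trait_distances()]).
#' @param k_max largest k examined (default 10).
#' @param n_ref number of uniform reference datasets (default 100).
#' @param seed integer seed.
#' @param plateau_tol plateau tolerance; default median SE of the gap curve.
#' @return A list of class `gap_curve`: `table` (k, gap, se), `primary_k`,
#'   `plateau_k`, `selected_k`, `plateau_tol`.
#' @export
select_k_gap <- function(trait_coords, k_max = 10L, n_ref = 100L,
                         seed = NULL, plateau_tol = NULL) {
  trait_coords <- as.matrix(trait_coords)
  if (k_max < 2) stop("k_max must be at least 2")
  if (k_max > nrow(trait_coords)) stop("k_max exceeds the number of traits")
  if (!is.null(seed)) set.seed(seed)
  cg <- cluster::clusGap(trait_coords, FUNcluster = ward_cut, K.max = k_max,
                         B = n_ref, spaceH0 = "original", verbose = FALSE)
  gap <- cg$Tab[, "gap"]
  se <- cg$Tab[, "SE.sim"]
  primary <- cluster::maxSE(gap, se, method = "Tibs2001SEmax")
  if (is.null(plateau_tol)) plateau_tol <- stats::median(se)
  gains <- diff(gap)
  plateau <- k_max
  for (k in seq_len(k_max - 1)) {
    if (all(gains[k:(k_max - 1)] < plateau_tol)) { plateau <- k; break }
  }
  selected <- if (primary >= 2) primary else plateau
  structure(list(table = data.frame(k = seq_len(k_max), gap = gap, se = se),
                 primary_k = primary, plateau_k = plateau,
                 selected_k = selected, plateau_tol = plateau_tol,
                 n_ref = n_ref),
            class = "gap_curve")
}

#' Plateau rule on a precomputed Gap curve
#'
#' Smallest k such that every subsequent step of the Gap curve gains less
#' than `plateau_tol`. Exposed separately so the rule can be audited on any
#' curve.
#'
#' @param gap numeric Gap values for k = 1..k_max.
#' @param plateau_tol gain threshold.
#' @return integer k.
#' @export
gap_plateau_k <- function(gap, plateau_tol) {
  k_max <- length(gap)
  gains <- diff(gap)
  for (k in seq_len(k_max - 1))
    if (all(gains[k:(k_max - 1)] < plateau_tol)) return(k)
  k_max
}

#' Bootstrap Jaccard stability of trait clusters
#'
#' For each bootstrap replicate the trait rows are resampled with
#' replacement, the resample is reclustered (Ward, cut at `k`), and each
#' original cluster records the maximum Jaccard similarity with any bootstrap
#' cluster, computed on the points present in the resample. The per-cluster
#' stability is the mean over replicates; a cluster that vanishes from a
#' replicate scores 0 for that replicate. Clusters below 0.70 (or a laxer
#' 0.60) are conventionally deemed unstable.
#'
#' @param trait_coords K' x d trait coordinate matrix.
#' @param k number of clusters (>= 2).
#' @param n_boot bootstrap replicates (default 1000; use >= 100).
#' @param seed integer seed.
#' @return A list of class `jaccard_stability`: `jaccard` (per-cluster mean
#'   similarity in \[0, 1\]), `labels` (the clustering assessed), `n_boot`.
#' @export
jaccard_stability <- function(trait_coords, k, n_boot = 1000L, seed = NULL) {
  trait_coords <- as.matrix(trait_coords)
  n <- nrow(trait_coords)
  if (k < 2) stop("k must be at least 2")
  if (n_boot < 100) warning("fewer than 100 bootstrap replicates")
  if (!is.null(seed)) set.seed(seed)
  base <- ward_cut(trait_coords, k)$cluster
  sums <- numeric(k)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    uniq <- sort(unique(idx))
    kb <- min(k, length(uniq) - 1L)
    if (kb < 1) next
    bl <- ward_cut(trait_coords[uniq, , drop = FALSE], max(kb, 1L))$cluster
    for (cl in seq_len(k)) {
      orig <- intersect(which(base == cl), uniq)
      if (!length(orig)) next        # vanished: contributes 0
      best <- 0
      for (bcl in unique(bl)) {
        boot_set <- uniq[bl == bcl]
        j <- length(intersect(orig, boot_set)) /
          length(union(orig, boot_set))
        if (j > best) best <- j
      }
      sums[cl] <- sums[cl] + best
    }
  }
  structure(list(jaccard = sums / n_boot, labels = base, k = k,
                 n_boot = n_boot),
            class = "jaccard_stability")
}

#' Reduce the number of clusters until all are stable
#'
#' Starting from `k_start` (typically the Gap-selected k), the clustering is
#' re-evaluated with [jaccard_stability()] and k decremented until every
#' cluster's Jaccard coefficient reaches `threshold` or k = 2. Both the
#' conservative 0.70 and the laxer 0.60 thresholds are evaluated on the same
#' bootstrap draw so their final k values can be compared (the laxer
#' threshold never retains fewer clusters).
#'
#' @param trait_coords K' x d trait coordinate matrix.
#' @param k_start starting number of clusters (>= 2).
#' @param threshold stability threshold used for the reported partition
#'   (default 0.70).
#' @param n_boot bootstrap replicates per k (default 1000).
#' @param seed integer seed.
#' @return A list of class `stable_partition`: `final_k`, `final_labels`,
#'   `jaccard` (for the final k), `trace` (per-k minimum Jaccard),
#'   `final_k_by_threshold` (named vector for 0.70 and 0.60), `threshold`.
#' @export
stable_partition <- function(trait_coords, k_start, threshold = 0.70,
                             n_boot = 1000L, seed = NULL) {
  if (k_start < 2) stop("k_start must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  trace <- data.frame(k = integer(), min_jaccard = double())
  stab_by_k <- list()
  for (k in seq(k_start, 2)) {
    st <- jaccard_stability(trait_coords, k, n_boot = n_boot)
    stab_by_k[[as.character(k)]] <- st
    trace <- rbind(trace, data.frame(k = k, min_jaccard = min(st$jaccard)))
    if (min(st$jaccard) >= threshold) break
  }
  pick_k <- function(th) {
    ok <- trace$k[trace$min_jaccard >= th]
    if (length(ok)) max(ok) else min(trace$k)
  }
  final_k <- pick_k(threshold)
  by_threshold <- c(`0.7` = pick_k(0.70), `0.6` = pick_k(0.60))
  st <- stab_by_k[[as.character(final_k)]]
  structure(list(final_k = final_k, final_labels = st$labels,
                 jaccard = st$jaccard, trace = trace,
                 final_k_by_threshold = by_threshold,
                 threshold = threshold, n_boot = n_boot),
            class = "stable_partition")
}

#' Full exploratory EDMA clustering of a species sample
#'
#' Chains the exploratory arm: distance-variance landmark filter, EDMA mean
#' form and landmark covariance on the *unsuperimposed* configurations,
#' eigen-scaled trait coordinates, Gap-statistic selection of k (with plateau
#' fallback), and the Jaccard stability reduction. Runs on raw coordinates by
#' design — no Procrustes step is involved.
#'
#' @param dataset a complete [landmark_dataset()].
#' @param k_max largest k examined by the Gap statistic (default 10).
#' @param n_ref Gap reference sets (default 100).
#' @param n_boot bootstrap replicates for stability (default 1000).
#' @param threshold Jaccard stability threshold (default 0.70).
#' @param seed integer seed.
#' @param filter apply [variance_filter()] first (default `TRUE`).
#' @return A list of class `trait_clustering`: `trait_distance`, `linkage`
#'   (hclust tree), `gap` ([select_k_gap()] result), `stability`
#'   ([stable_partition()] result), `final_labels` (named by landmark id),
#'   `excluded_landmarks`, `edma` (the [edma_mean_form()] fit).
#' @export
edma_cluster <- function(dataset, k_max = 10L, n_ref = 100L, n_boot = 1000L,
                         threshold = 0.70, seed = NULL, filter = TRUE) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  vf <- if (filter) variance_filter(dataset) else NULL
  kept_ids <- if (filter) vf$kept else dataset$landmark_ids
  keep_idx <- match(kept_ids, dataset$landmark_ids)
  sub <- dataset
  if (length(keep_idx) < n_landmarks(dataset)) {
    sub <- landmark_dataset(dataset$coords[keep_idx, , , drop = FALSE],
                            species = dataset$species,
                            specimen_ids = dataset$specimen_ids,
                            landmark_ids = kept_ids,
                            landmark_labels = dataset$landmark_labels[keep_idx])
  }
  fit <- edma_mean_form(sub)
  ts <- trait_distances(fit$sigma_k)
  k_max_eff <- min(k_max, nrow(ts$coords) - 1L)
  gap <- select_k_gap(ts$coords, k_max = k_max_eff, n_ref = n_ref,
                      seed = seed)
  stab <- stable_partition(ts$coords, k_start = max(gap$selected_k, 2L),
                           threshold = threshold, n_boot = n_boot)
  labels <- stab$final_labels
  names(labels) <- kept_ids
  structure(list(trait_distance = ts$distances,
                 linkage = stats::hclust(stats::as.dist(ts$distances),
                                         method = "ward.D2"),
                 gap = gap, stability = stab, final_labels = labels,
                 excluded_landmarks = if (filter) vf$excluded else integer(),
                 variance_filter = vf, edma = fit),
            class = "trait_clustering")
}

#' @export
print.trait_clustering <- function(x, ...) {
  cat(sprintf(
    "<trait_clustering> %d traits -> %d clusters (gap k=%d, min Jaccard %.2f)%s\n",
    length(x$final_labels), x$stability$final_k, x$gap$selected_k,
    min(x$stability$jaccard),
    if (length(x$excluded_landmarks))
      sprintf(", %d landmarks excluded", length(x$excluded_landmarks))
    else ""))
  invisible(x)
}

#' Export a trait-cluster dendrogram as Newick
#'
#' @param clustering a [edma_cluster()] result (or any hclust tree).
#' @param path optional file; when `NULL` the Newick string is returned.
#' @return Newick string, invisibly when written to file.
#' @export
export_newick <- function(clustering, path = NULL) {
  tree <- if (inherits(clustering, "trait_clustering")) clustering$linkage
          else clustering
  nw <- hclust_to_newick(tree)
  if (is.null(path)) return(nw)
  writeLines(nw, path)
  invisible(nw)
}

hclust_to_newick <- function(h) {
  labs <- h$labels %||% as.character(seq_along(h$order))
  rec <- function(i) {
    if (i < 0) return(labs[-i])
    pair <- h$merge[i, ]
    sprintf("(%s:%f,%s:%f)", rec(pair[1]), h$height[i],
            rec(pair[2]), h$height[i])
  }
  paste0(rec(nrow(h$merge)), ";")
}
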