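#' Default per-species pipeline configuration
#'
#' @param seed master seed; stage seeds are derived deterministically.
#' @param n_perm permutations for the allometry and CR tests (default 999).
#' @param alpha allometry detection gate (default 0.05).
#' @param k_max,gap_n_ref,n_boot,jaccard_threshold exploratory-arm settings
#'   (see [edma_cluster()]).
#' @param run_edma,run_cr toggles for the exploratory arm and the CR tests.
#' @param force_branch `NULL` for the allometry gate, or `"raw"` /
#'   `"corrected"` to force a branch for sensitivity analysis.
#' @return named list of settings.
#' @export
pipeline_config <- function(seed = 1L, n_perm = 999L, alpha = 0.05,
                            k_max = 10L, gap_n_ref = 100L, n_boot = 1000L,
                            jaccard_threshold = 0.70, run_edma = TRUE,
                            run_cr = TRUE, force_branch = NULL) {
  list(seed = as.integer(seed), n_perm = as.integer(n_perm), alpha = alpha,
       k_max = as.integer(k_max), gap_n_ref = as.integer(gap_n_ref),
       n_boot = as.integer(n_boot), jaccard_threshold = jaccard_threshold,
       run_edma = run_edma, run_cr = run_cr, force_branch = force_branch)
}

#' Run the full per-species modularity analysis
#'
#' Orchestrates the two arms exactly as they must be kept apart: missing
#' landmarks are imputed, the exploratory EDMA clustering runs on the raw
#' (unsuperimposed) configurations, while the confirmatory arm (congruence
#' matrix, likelihood-based architecture selection in absolute and signed
#' mode, covariance-ratio tests and their pairwise comparison) runs on
#' Procrustes-aligned shapes — allometry-corrected when static allometry is
#' detected at the configured gate. Deterministic under a fixed seed.
#'
#' @param dataset a [landmark_dataset()].
#' @param architectures named list of [module_map()] (default: bundled
#'   registry including the single-module null).
#' @param config a [pipeline_config()].
#' @return An object of class `species_report`; see the elements
#'   `allometry`, `edma`, `emmli_abs`, `emmli_signed`, `cr`, `cr_comparison`,
#'   `table_row`, `provenance`.
#' @export
run_species <- function(dataset, architectures = NULL,
                        config = pipeline_config()) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  if (is.null(architectures)) architectures <- architecture_registry()
  stage_seed <- function(offset) (config$seed + offset) %% .Machine$integer.max

  imputed <- 0L
  if (any(dataset$missing)) {
    dataset <- estimate_missing(dataset)
    imputed <- attr(dataset, "imputed_count")
  }
  fit <- gpa(dataset)
  allom <- allometry_correct(fit, n_perm = config$n_perm,
                             seed = stage_seed(1L), alpha = config$alpha)
  shapes <- gated_shapes(fit, allom, force = config$force_branch)
  branch <- if (!is.null(config$force_branch)) config$force_branch
            else if (allom$applied) "corrected" else "raw"

  edma_res <- NULL
  if (config$run_edma)
    edma_res <- edma_cluster(dataset, k_max = config$k_max,
                             n_ref = config$gap_n_ref,
                             n_boot = config$n_boot,
                             threshold = config$jaccard_threshold,
                             seed = stage_seed(2L))

  cm <- congruence_matrix(shapes,
                          source = if (branch == "corrected")
                            "allometry_corrected" else "raw_aligned")
  emmli_abs <- fit_emmli(cm, architectures, abs = TRUE,
                         landmark_ids = dataset$landmark_ids)
  emmli_signed <- fit_emmli(cm, architectures, abs = FALSE,
                            landmark_ids = dataset$landmark_ids)

  cr_res <- NULL; cr_cmp <- NULL; best_cr <- NULL
  if (config$run_cr) {
    testable <- Filter(function(m) {
      asg <- m$assignment
      asg[is.na(asg)] <- "unintegrated"
      length(unique(asg)) >= 2
    }, architectures)
    cr_res <- lapply(seq_along(testable), function(i)
      cr_test(shapes, testable[[i]], n_perm = config$n_perm,
              seed = stage_seed(10L + i),
              landmark_ids = dataset$landmark_ids))
    names(cr_res) <- names(testable)
    if (length(cr_res) >= 2) cr_cmp <- compare_cr(cr_res)
    best_cr <- cr_res[[emmli_abs$best_architecture]] %||% NULL
  }

  tabs <- if (!is.null(emmli_abs$rho_within))
    rho_tables(emmli_abs, emmli_signed) else NULL
  table_row <- data.frame(
    species = dataset$species,
    N = n_specimens(dataset),
    MLi = emmli_abs$best_architecture,
    n_modules = if (!is.null(emmli_abs$rho_within))
      length(emmli_abs$rho_within) else NA_integer_,
    CR = if (!is.null(best_cr)) best_cr$cr else NA_real_,
    CR_p = if (!is.null(best_cr)) best_cr$p_value else NA_real_,
    rho_abs_1_2 = if (!is.null(tabs)) tabs$signed_between else NA_real_,
    mean_rho = emmli_abs$mean_rho %||% NA_real_,
    allometry_r2 = allom$r_squared,
    allometry_p = allom$p_value,
    branch = branch,
    imputed = imputed)

  structure(list(species = dataset$species,
                 n_specimens = n_specimens(dataset),
                 imputed_count = imputed,
                 gpa = fit, allometry = allom, branch = branch,
                 edma = edma_res,
                 congruence = cm,
                 emmli_abs = emmli_abs, emmli_signed = emmli_signed,
                 rho_tables = tabs,
                 cr = cr_res, cr_comparison = cr_cmp,
                 table_row = table_row,
                 provenance = list(seed = config$seed,
                                   n_perm = config$n_perm,
                                   alpha = config$alpha,
                                   jaccard_threshold =
                                     config$jaccard_threshold,
                                   package_version =
                                     as.character(utils::packageVersion(
                                       "craniomod")))),
            class = "species_report")
}

#' @export
print.species_report <- function(x, ...) {
  cat(sprintf("<species_report> %s (N=%d, %d imputed)\n", x$species,
              x$n_specimens, x$imputed_count))
  cat(sprintf("  allometry: r2=%.3f p=%.3g -> %s shapes\n",
              x$allometry$r_squared, x$allometry$p_value, x$branch))
  if (!is.null(x$edma))
    cat(sprintf("  EDMA: %d stable clusters (gap k=%d)\n",
                x$edma$stability$final_k, x$edma$gap$selected_k))
  cat(sprintf("  EMMLi best: %s (mean rho %.2f)\n",
              x$emmli_abs$best_architecture, x$emmli_abs$mean_rho %||% NA))
  if (!is.null(x$cr_comparison))
    cat(sprintf("  strongest CR signal: %s\n", x$cr_comparison$strongest))
  invisible(x)
}

#' Serialise a species report to JSON
#'
#' Numbers are taken from the stage outputs without recomputation.
#'
#' @param report a [run_species()] result.
#' @param path optional file.
#' @return JSON string (invisibly when written to file).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "species_report"))
  x <- list(
    species = report$species,
    n_specimens = report$n_specimens,
    imputed_count = report$imputed_count,
    allometry = list(r_squared = report$allometry$r_squared,
                     p_value = report$allometry$p_value,
                     applied = report$allometry$applied,
                     n_perm = report$allometry$n_perm),
    branch = report$branch,
    edma = if (!is.null(report$edma)) list(
      selected_k = report$edma$gap$selected_k,
      primary_k = report$edma$gap$primary_k,
      plateau_k = report$edma$gap$plateau_k,
      final_k = report$edma$stability$final_k,
      min_jaccard = min(report$edma$stability$jaccard),
      excluded_landmarks = report$edma$excluded_landmarks),
    emmli = list(best = report$emmli_abs$best_architecture,
                 mean_rho = report$emmli_abs$mean_rho,
                 rho_within = as.list(report$emmli_abs$rho_within),
                 signed_best = report$emmli_signed$best_architecture),
    cr = lapply(report$cr, function(r)
      list(cr = r$cr, p = r$p_value, z = r$z_score)),
    strongest_cr = if (!is.null(report$cr_comparison))
      report$cr_comparison$strongest else NULL,
    provenance = report$provenance)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
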