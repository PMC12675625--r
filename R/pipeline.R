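#' Pipeline configuration
#'
#' Collects every threshold, size and seed of the end-to-end analysis.
#' Defaults follow the reference analysis settings (FA threshold 0.2, GM
#' threshold 0.65 in more than 75% of subjects, Gaussian fill sigma 2 mm,
#' TFCE-corrected permutation inference, k-medoids with silhouette
#' selection and 1000 bootstrap resamples); simulation sizes default to
#' desk-scale values so a demonstration run completes in minutes.
#'
#' @param n_control,n_patient Imaging subjects per group.
#' @param grid_shape,voxel_size_mm Phantom geometry.
#' @param s0,noise_sigma DWI signal level and Rician noise scale.
#' @param max_b,include_max_b Tensor shell filter (see
#'   [fit_tensor_lls()]).
#' @param fa_threshold,gm_threshold,subject_frac,sigma_mm,search_mm
#'   Skeleton / projection settings.
#' @param n_perm Permutations for voxelwise inference (study setting
#'   5000; lower for demonstrations).
#' @param tfce_e,tfce_h TFCE exponents.
#' @param n_clinical_control,n_clinical_patient Clinical cohort sizes.
#' @param k_range,n_boot Clustering settings.
#' @param patient_params Condition overrides passed to [make_phantom()]
#'   for the patient group; e.g.
#'   `list(odi_delta = 0, perivascular_gain = 1.6)` yields a null
#'   (zero-effect) run.
#' @param seed Global seed; every stochastic stage derives its seed from
#'   it and logs the value used.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_control = 10, n_patient = 10,
                            grid_shape = c(24L, 28L, 24L),
                            voxel_size_mm = 2, s0 = 1000, noise_sigma = 20,
                            max_b = 1000, include_max_b = TRUE,
                            fa_threshold = 0.2, gm_threshold = 0.65,
                            subject_frac = 0.75, sigma_mm = 2,
                            search_mm = 6, n_perm = 500,
                            tfce_e = 0.5, tfce_h = 2,
                            n_clinical_control = 52, n_clinical_patient = 44,
                            k_range = 2:6, n_boot = 1000,
                            patient_params = list(), seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the end-to-end analysis on synthetic data
#'
#' Executes simulate -> tensor fit -> ALPS -> skeleton + projection ->
#' permutation statistics -> clinical cohort + clustering, and returns a
#' structured report (suitable for JSON serialization) in which every
#' threshold, seed and exclusion is logged. Stage failures halt with the
#' failing stage named; completed stage outputs are preserved in the
#' partial report attached to the error condition.
#'
#' @param config A [pipeline_config()].
#' @param keep_intermediates If `TRUE`, phantom/fit objects are attached
#'   to the result (memory-heavy).
#' @return A list of class `pipeline_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), keep_intermediates = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(config = config[setdiff(names(config), "")], stages = list())
  stage <- "simulate"
  res <- tryCatch({
    groups <- c(rep("control", config$n_control),
                rep("patient", config$n_patient))
    seeds <- config$seed * 1000L + seq_along(groups)
    tensors <- vector("list", length(groups))
    fa_maps <- vector("list", length(groups))
    truth_c <- make_phantom(config$grid_shape, config$voxel_size_mm,
                            "control", seed = config$seed)
    truth_p <- make_phantom(config$grid_shape, config$voxel_size_mm,
                            "patient", condition_params = config$patient_params,
                            seed = config$seed)
    scheme <- default_scheme()
    stage <- "fit"
    for (i in seq_along(groups)) {
      tr <- if (groups[i] == "control") truth_c else truth_p
      dwi <- synthesize_dwi(tr, scheme, s0 = config$s0,
                            noise_sigma = config$noise_sigma,
                            seed = seeds[i])
      tensors[[i]] <- fit_tensor_lls(dwi, mask = phantom_mask(tr),
                                     max_b = config$max_b,
                                     include_max_b = config$include_max_b)
      fa_maps[[i]] <- tensors[[i]]$fa_map
    }
    names(tensors) <- sprintf("%s%03d", substr(groups, 1, 1), seq_along(groups))
    report$stages$simulate <- list(
      n_subjects = length(groups), seeds = seeds,
      grid = config$grid_shape, noise_sigma = config$noise_sigma
    )

    stage <- "alps"
    roi <- default_alps_roi(truth_c)
    alps_tab <- alps_cohort(tensors, roi, group = groups)
    report$stages$alps <- list(
      roi = list(center_proj = roi$center_proj,
                 center_assoc = roi$center_assoc, edge_mm = roi$edge_mm),
      group_means = as.data.frame(glance.alps_cohort(alps_tab)),
      n_failed = length(attr(alps_tab, "failed"))
    )

    stage <- "skeleton"
    mfa <- mean_map(fa_maps)
    skel <- skeletonize(mfa, config$fa_threshold,
                        voxel_size_mm = config$voxel_size_mm)
    proj <- vapply(seq_along(groups), function(i) {
      project_wm_metric(fa_maps[[i]], fa_maps[[i]], skel,
                        search_mm = config$search_mm)
    }, numeric(length(skel$idx)))
    report$stages$skeleton <- list(
      n_skeleton_voxels = length(skel$idx),
      fa_threshold = config$fa_threshold
    )

    stage <- "stats"
    design <- design_spec(groups, covariates = NULL,
                          contrast = "group2_greater")
    perm <- permutation_inference(
      proj, skel$idx, dim(mfa), design,
      tfce_params = list(E = config$tfce_e, H = config$tfce_h, dh = NULL,
                         connectivity = 26),
      n_perm = config$n_perm, seed = config$seed + 77L
    )
    report$stages$stats <- list(
      n_perm = perm$n_perm, seed = config$seed + 77L,
      min_p = min(perm$p), n_significant = sum(perm$p < 0.05)
    )

    stage <- "cluster"
    cohort <- make_clinical_table(config$n_clinical_control,
                                  config$n_clinical_patient,
                                  seed = config$seed + 99L)
    patients <- cohort[cohort$group == "patient", ]
    spec <- gower_spec_from_registry(attr(cohort, "registry"))
    dmat <- gower_distance(patients, spec)
    sol <- flag_unassigned(select_k(dmat, config$k_range))
    boot <- bootstrap_stability(patients, spec, k = sol$k,
                                n_boot = config$n_boot,
                                seed = config$seed + 123L)
    report$stages$cluster <- list(
      seed = config$seed + 99L, k = sol$k,
      mean_silhouette = sol$mean_silhouette,
      sizes = as.integer(table(sol$labels)),
      n_unassigned = length(sol$unassigned),
      bootstrap_mean_ari = boot$mean, n_boot = boot$n_boot,
      truth_ari = adjusted_rand_index(sol$labels, patients$truth_cluster)
    )

    out <- list(report = report, alps = alps_tab, permutation = perm,
                solution = sol, bootstrap = boot, cohort = cohort)
    if (keep_intermediates) {
      out$tensors <- tensors
      out$skeleton <- skel
      out$truth <- list(control = truth_c, patient = truth_p)
    }
    out
  }, error = function(e) {
    e$message <- sprintf("pipeline stage '%s' failed: %s", stage,
                         conditionMessage(e))
    e$partial_report <- report
    stop(e)
  })
  class(res) <- "pipeline_report"
  res
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$report$stages
  cat("<pipeline_report>\n")
  cat(sprintf("  simulate: %d subjects on %s grid (noise sigma %g)\n",
              s$simulate$n_subjects, paste(s$simulate$grid, collapse = "x"),
              s$simulate$noise_sigma))
  gm <- s$alps$group_means
  cat(sprintf("  alps: %s\n", paste(sprintf("%s %.3f", gm$group,
                                            gm$mean_index), collapse = ", ")))
  cat(sprintf("  stats: min FWER p = %.4g (%d significant voxels, %d perms)\n",
              s$stats$min_p, s$stats$n_significant, s$stats$n_perm))
  cat(sprintf("  cluster: k = %d, truth ARI %.3f, bootstrap mean ARI %.3f\n",
              s$cluster$k, s$cluster$truth_ari, s$cluster$bootstrap_mean_ari))
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' @param result A `pipeline_report`.
#' @param path Output path.
#' @export
write_pipeline_report <- function(result, path) {
  jsonlite::write_json(result$report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
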