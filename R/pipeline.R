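#' Full-pipeline configuration
#'
#' One object drives all stages: synthesis (or input location), scrubbing,
#' static contrasts, dynamic clustering and the statistical settings. Its
#' hash is stamped into every output sidecar.
#'
#' @param sim a `sim_config` for the synthetic stage, or NULL to read an
#'   existing cohort from `input_dir`.
#' @param input_dir directory holding `manifest.csv` and acquisition files
#'   (ignored when `sim` is given).
#' @param scrub a `scrub_config`.
#' @param n_animals,acquisitions_per_condition,conditions cohort shape for
#'   the synthetic stage.
#' @param contrasts list of length-2 character vectors of condition labels
#'   for the static stage.
#' @param k number of brain states (default 7).
#' @param restarts k-means restarts (default 500).
#' @param outlier_z cofluctuation outlier threshold (default 3).
#' @param q false discovery rate (default 0.05).
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            scrub = scrub_config(), n_animals = 6,
                            acquisitions_per_condition = 2,
                            conditions = c("15C", "25C", "35C", "CFD"),
                            contrasts = list(c("25C", "15C"),
                                             c("25C", "35C")),
                            k = 7, restarts = 500, outlier_z = 3, q = 0.05,
                            seed = 1) {
  if (is.null(sim) && is.null(input_dir)) {
    stop("either a sim_config or an input_dir is required")
  }
  for (cp in contrasts) {
    stopifnot(length(cp) == 2, all(cp %in% thermal_conditions()))
  }
  structure(list(sim = sim, input_dir = input_dir, scrub = scrub,
                 n_animals = n_animals,
                 acquisitions_per_condition = acquisitions_per_condition,
                 conditions = conditions, contrasts = contrasts, k = k,
                 restarts = restarts, outlier_z = outlier_z, q = q,
                 seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> scrub -> static edge contrasts -> cofluctuation /
#' outlier rejection -> L1 k-means brain states -> occurrence-rate
#' statistics, returning one report bundle. With `out_dir` set, all tables
#' and matrices are written as delimited text with JSON provenance
#' sidecars. A stage failure halts with the failing stage named; outputs of
#' completed stages are retained.
#'
#' @param config a `pipeline_config`.
#' @param out_dir optional output directory.
#' @return report list: `manifest`, `scrub_report`, `condition_means`,
#'   `static` (per contrast), `model`, `occurrence`, `occurrence_stats`,
#'   `homogeneity`, `outliers_removed`, `n_frames`, `seed`, `config_hash`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  hash <- config_hash(config)
  roi <- if (!is.null(config$sim)) config$sim$roi else default_roi_set()

  # --- cohort ---
  cohort <- stage("simulate/load", {
    if (!is.null(config$sim)) {
      simulate_cohort(config$sim, config$n_animals,
                      config$acquisitions_per_condition, config$conditions,
                      seed = config$seed)
    } else {
      man <- read_manifest(file.path(config$input_dir, "manifest.csv"))
      acqs <- lapply(seq_len(nrow(man)), function(r) {
        read_acquisition(file.path(config$input_dir,
                                   basename(man$path[r])),
                         man$acquisition_id[r], man$animal_id[r],
                         man$condition[r], man$fs_hz[r], roi = roi)
      })
      names(acqs) <- man$acquisition_id
      list(manifest = man, acquisitions = acqs, ground_truth = NULL)
    }
  })
  manifest <- cohort$manifest

  # --- preprocess ---
  pre <- stage("preprocess", preprocess_cohort(cohort$acquisitions,
                                               config$scrub))
  ok <- vapply(pre$clean, function(cs) cs$status == "ok", logical(1))
  if (!any(ok)) stop("pipeline stage 'preprocess' discarded every acquisition")

  # --- static FC ---
  obs <- stage("staticfc", edge_observations(pre$clean, manifest, roi))
  cond_means <- lapply(stats::setNames(nm = unique(manifest$condition)),
                       function(cc) {
                         condition_mean_matrix(pre$clean, manifest, cc)
                       })
  static <- lapply(config$contrasts, function(cp) {
    stage(paste0("staticfc ", cp[1], ":", cp[2]),
          compare_conditions(obs, cp, q = config$q, roi = roi))
  })
  names(static) <- vapply(config$contrasts, paste, "", collapse = ":")

  # --- dynamic FC ---
  cofl <- stage("dynfc", {
    series <- lapply(pre$clean[ok], function(cs) {
      cofluctuation_series(zscore_series(cs), cs$source_id)
    })
    concatenate_cohort(series)
  })
  cofl_kept <- stage("dynfc", filter_outliers(cofl, config$outlier_z))
  model <- stage("dynfc", kmeans_l1(cofl_kept, config$k,
                                    restarts = config$restarts,
                                    seed = config$seed))
  occ <- stage("dynfc", occurrence_rates(model, cofl_kept$frames, manifest))
  homo <- stage("dynfc",
                animal_state_homogeneity(model, cofl_kept$frames, manifest))
  occ_stats <- stage("dynfc", compare_occurrence(occ, q = config$q))

  report <- list(manifest = manifest, scrub_report = pre$report,
                 condition_means = cond_means, static = static,
                 model = model, occurrence = occ,
                 occurrence_stats = occ_stats, homogeneity = homo,
                 outliers_removed = attr(cofl_kept, "outliers"),
                 n_frames = nrow(cofl$values),
                 n_frames_clustered = nrow(cofl_kept$values),
                 ground_truth = cohort$ground_truth, clean = pre$clean,
                 seed = config$seed, config_hash = hash)
  if (!is.null(out_dir)) write_report(report, config, out_dir, roi)
  report
}

write_report <- function(report, config, out_dir, roi) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  meta <- list(seed = config$seed, config_hash = report$config_hash)
  put <- function(x, name, writer = write_table) {
    p <- file.path(out_dir, name)
    writer(x, p)
    write_sidecar(p, meta)
  }
  put(report$scrub_report, "scrub_report.csv")
  for (cc in names(report$condition_means)) {
    put(report$condition_means[[cc]],
        paste0("mean_correlation_", cc, ".csv"), write_matrix)
  }
  for (nm in names(report$static)) {
    s <- report$static[[nm]]
    tag <- gsub(":", "_vs_", nm)
    put(s$results, paste0("static_edges_", tag, ".csv"))
    put(s$significance * 1, paste0("static_significance_", tag, ".csv"),
        write_matrix)
    put(s$delta_z, paste0("static_delta_z_", tag, ".csv"), write_matrix)
  }
  for (s in seq_len(report$model$k)) {
    put(state_matrix(report$model, s, roi),
        sprintf("state_%02d_centroid.csv", s), write_matrix)
  }
  put(report$occurrence, "occurrence_rates.csv")
  put(report$occurrence_stats$omnibus, "occurrence_omnibus.csv")
  if (!is.null(report$occurrence_stats$pairwise)) {
    put(report$occurrence_stats$pairwise, "occurrence_pairwise.csv")
  }
  put(as.data.frame(report$homogeneity$composition),
      "animal_state_composition.csv")
  summary <- list(seed = config$seed, config_hash = report$config_hash,
                  n_acquisitions = nrow(report$manifest),
                  n_discarded = sum(report$scrub_report$status ==
                                      "discarded"),
                  n_frames = report$n_frames,
                  n_frames_clustered = report$n_frames_clustered,
                  outliers_removed = report$outliers_removed,
                  k = report$model$k,
                  occurrence_overall =
                    report$model$counts / sum(report$model$counts),
                  homogeneity_chisq = report$homogeneity$chisq)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
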