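#' Write/read tab-separated tables
#'
#' Plain TSV with a header row, no quoting surprises, no row names;
#' byte-stable across runs for identical inputs.
#'
#' @param x data frame.
#' @param path file path.
#' @return `path` (writer) or a data frame (reader).
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' End-to-end pipeline configuration
#'
#' Collects the full analysis configuration with the reference defaults:
#' 1 mm smoothing kernel; 10,000 Monte-Carlo iterations at cluster
#' alpha = .05; fiber filtering at 0.1% visitation probability, 70-degree
#' curvature and the 5% / +/-15-degree crossing rule; 25% bundle-atlas
#' projection threshold; 100 fibers per region with 1% elimination and a
#' 10% display threshold for lesion mapping. All randomness derives from
#' the single `seed`.
#'
#' @param cohort a [cohort_spec()].
#' @param phantom a [phantom_spec()].
#' @param contrast analysis contrast (see [vba_design()]).
#' @param sigma_mm smoothing kernel SD.
#' @param cft_p,alpha,n_iter,connectivity cluster-correction settings.
#' @param tract list: `step_mm`, `max_angle_deg`, `n_seeds_per_bundle`,
#'   `min_prob`, `max_turn_deg`, `cross_tol_deg`, `cross_min_fraction`,
#'   `atlas_min_prob`, `atlas_subjects` (`NULL` = all controls).
#' @param lesionmap list: `n_per_roi`, `fiber_min`, `display_threshold`,
#'   `max_subjects` (`NULL` = all subjects).
#' @param seed master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), phantom = phantom_spec(),
                            contrast = "seiz-vs-hc", sigma_mm = 1,
                            cft_p = 0.001, alpha = 0.05, n_iter = 10000,
                            connectivity = 26,
                            tract = list(), lesionmap = list(), seed = 1L) {
  tdef <- list(step_mm = 0.5, max_angle_deg = 60, n_seeds_per_bundle = 100,
               min_prob = 0.001, max_turn_deg = 70, cross_tol_deg = 15,
               cross_min_fraction = 0.05, atlas_min_prob = 0.25,
               atlas_subjects = NULL)
  ldef <- list(n_per_roi = 100, fiber_min = 0.01, display_threshold = 10,
               max_subjects = NULL)
  tract <- utils::modifyList(tdef, tract)
  lesionmap <- utils::modifyList(ldef, lesionmap)
  check_number(sigma_mm, "sigma_mm", 0, Inf, closed_lower = FALSE)
  check_number(cft_p, "cft_p", 0, 1, closed_lower = FALSE, closed_upper = FALSE)
  check_number(alpha, "alpha", 0, 1, closed_lower = FALSE)
  check_count(n_iter, "n_iter", min = 100L)
  check_number(tract$min_prob, "min_prob", 0, 1, closed_lower = FALSE,
               closed_upper = FALSE)
  check_number(tract$max_turn_deg, "max_turn_deg", 0, 180, closed_lower = FALSE,
               closed_upper = FALSE)
  check_number(tract$cross_min_fraction, "cross_min_fraction", 0, 1)
  check_number(tract$atlas_min_prob, "atlas_min_prob", 0, 1)
  check_number(lesionmap$fiber_min, "fiber_min", 0, 1, closed_lower = FALSE,
               closed_upper = FALSE)
  check_number(lesionmap$display_threshold, "display_threshold", 0, 100)
  structure(list(cohort = cohort, phantom = phantom, contrast = contrast,
                 sigma_mm = sigma_mm, cft_p = cft_p, alpha = alpha,
                 n_iter = as.integer(n_iter), connectivity = connectivity,
                 tract = tract, lesionmap = lesionmap, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar overrides for the cohort/phantom specs and all analysis, tract
#' and lesion-map settings; custom bundle geometries are an R-API feature.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- do.call(cohort_spec, y$cohort %||% list())
  phantom <- do.call(phantom_spec, y$phantom %||% list())
  args <- y[setdiff(names(y), c("cohort", "phantom"))]
  do.call(pipeline_config, c(list(cohort = cohort, phantom = phantom), args))
}

stage <- function(name, log, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  log(sprintf("[%s] done in %.1f s", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates the phantom cohort, scores the heartbeat-tracking data, runs
#' the voxel-based analysis with Monte-Carlo cluster correction, projects
#' the retained clusters onto the control-based bundle atlas, and performs
#' network lesion mapping; writes all tables, volumes, a ground-truth
#' manifest and a run manifest (config hash, seed, version) to `out_dir`.
#' Given identical config and seed, outputs are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "pipeline.log")
  if (file.exists(logfile)) unlink(logfile)
  log <- function(msg) cat(msg, "\n", sep = "", file = logfile, append = TRUE)
  fail_marker <- file.path(out_dir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)
  on.exit({
    # retain partial outputs with a failure marker when any stage aborts
    if (!file.exists(file.path(out_dir, "manifest.json")))
      writeLines("pipeline aborted; partial outputs retained", fail_marker)
  })
  seed <- config$seed
  config$cohort$seed <- derive_seed(seed, "cohort")
  config$phantom$seed <- derive_seed(seed, "phantom")

  sim <- stage("simulate", log, {
    phantom <- generate_phantom(config$phantom)
    cohort <- generate_cohort(config$cohort)
    trials <- generate_cohort_trials(cohort, seed = derive_seed(seed, "trials"))
    fa <- generate_subject_fa(phantom, cohort, seed = derive_seed(seed, "fa"))
    write_tsv(cohort, file.path(out_dir, "cohort.tsv"))
    write_tsv(trials, file.path(out_dir, "trials.tsv"))
    write_volume(phantom$wm_mask, file.path(out_dir, "wm_mask.nii.gz"))
    write_volume(phantom$labels, file.path(out_dir, "labels.nii.gz"))
    truth <- phantom$truth
    jsonlite::write_json(list(blob = truth$blob, correlate = truth$correlate,
                              blob_bundle = truth$blob_bundle,
                              correlate_bundle = truth$correlate_bundle,
                              bundle_labels = lapply(truth$bundles, function(b)
                                c(b$start_label, b$end_label))),
                         file.path(out_dir, "ground_truth.json"))
    log(sprintf("[simulate] %d subjects, %d usable ECG", nrow(cohort),
                sum(cohort$usable_ecg)))
    list(phantom = phantom, cohort = cohort, trials = trials, fa = fa)
  })

  scores <- stage("score", log, {
    sc <- score_cohort(sim$cohort, sim$trials)
    st <- behavioral_group_stats(sc, sim$cohort)
    write_tsv(sc, file.path(out_dir, "scores.tsv"))
    jsonlite::write_json(st, file.path(out_dir, "behavioral_stats.json"),
                         digits = NA)
    log(sprintf("[score] %d subjects scored (%d excluded for ECG)",
                nrow(sc), nrow(sim$cohort) - nrow(sc)))
    sc
  })

  vba <- stage("vba", log, {
    sm <- smooth_stack(sim$fa, config$sigma_mm, sim$phantom$wm_mask)
    design <- vba_design(sim$cohort, config$contrast, scores = scores)
    stat <- fit_voxelwise_glm(sm, design, sim$phantom$wm_mask)
    clusters <- cluster_correct_mc(stat, n_iter = config$n_iter,
                                   cft_p = config$cft_p, alpha = config$alpha,
                                   connectivity = config$connectivity,
                                   seed = derive_seed(seed, "mc"))
    blob <- cluster_mask(clusters, sim$phantom$wm_mask)
    write_volume(volume3d(ifelse(is.na(stat$t), 0, stat$t), stat$affine, stat$space),
                 file.path(out_dir, "tmap.nii.gz"))
    write_volume(blob, file.path(out_dir, "blob.nii.gz"))
    jsonlite::write_json(as.data.frame(clusters),
                         file.path(out_dir, "clusters.json"), digits = NA)
    log(sprintf("[vba] %d clusters, %d retained", nrow(clusters),
                sum(clusters$retained)))
    list(stat = stat, clusters = clusters, blob = blob)
  })

  tract <- stage("tracts", log, {
    tc <- config$tract
    phantom <- sim$phantom
    controls <- sim$cohort$id[sim$cohort$group == "HC"]
    if (!is.null(tc$atlas_subjects))
      controls <- controls[seq_len(min(tc$atlas_subjects, length(controls)))]
    queries <- stats::setNames(lapply(names(phantom$truth$bundles), function(qn) {
      b <- phantom$truth$bundles[[qn]]
      bundle_query(qn, b$start_label, b$end_label)
    }), names(phantom$truth$bundles))
    atlas <- list(); counts <- c(tracked = 0L, filtered = 0L)
    per_bundle_subjects <- stats::setNames(
      rep(list(list()), length(queries)), names(queries))
    for (s in controls) {
      seeds <- do.call(rbind, lapply(names(phantom$spec$bundles), function(b)
        bundle_seeds(phantom, b, n = tc$n_seeds_per_bundle,
                     seed = derive_seed(seed, paste0("seeds", s, b)))))
      sls <- suppressWarnings(
        track_streamlines(phantom$field, seeds, step_mm = tc$step_mm,
                          max_angle_deg = tc$max_angle_deg, subject = s))
      counts["tracked"] <- counts["tracked"] + length(sls$points)
      vmap <- visitation_map(sls, phantom$wm_mask)
      sls <- filter_voxel_probability(sls, vmap, tc$min_prob)
      sls <- filter_curvature(sls, tc$max_turn_deg)
      sls <- filter_crossing(sls, phantom$wm_mask, tc$cross_tol_deg,
                             tc$cross_min_fraction)
      counts["filtered"] <- counts["filtered"] + length(sls$points)
      for (qn in names(queries)) {
        sel <- select_by_query(sls, phantom$labels, queries[[qn]])
        per_bundle_subjects[[qn]][[s]] <- sel
      }
    }
    for (qn in names(queries))
      atlas[[qn]] <- build_bundle_atlas(per_bundle_subjects[[qn]], phantom$wm_mask)
    report <- if (sum(vba$blob$grid) > 0)
      project_blob_to_bundles(vba$blob, atlas, tc$atlas_min_prob)
    else data.frame(bundle = character(0), fraction = numeric(0),
                    n_blob_voxels = integer(0))
    jsonlite::write_json(report, file.path(out_dir, "bundle_report.json"),
                         digits = NA)
    log(sprintf("[tracts] %d fibers tracked, %d after filtering, %d bundles implicated",
                counts["tracked"], counts["filtered"], nrow(report)))
    list(atlas = atlas, report = report, bundles = per_bundle_subjects)
  })

  lm_tab <- stage("lesionmap", log, {
    lc <- config$lesionmap
    subjects <- sim$cohort$id
    if (!is.null(lc$max_subjects))
      subjects <- subjects[seq_len(min(lc$max_subjects, length(subjects)))]
    tab <- if (sum(vba$blob$grid) > 0)
      lesion_map(vba$blob, sim$phantom$labels, sim$phantom$field, subjects,
                 n_per_roi = lc$n_per_roi, vmap_min = lc$fiber_min,
                 display_threshold = lc$display_threshold,
                 step_mm = config$tract$step_mm,
                 max_angle_deg = config$tract$max_angle_deg,
                 seed = derive_seed(seed, "lesionmap"))
    else aggregate_lesion_map(
      stats::setNames(list(0), "0"), lc$display_threshold)[0, ]
    write_tsv(as.data.frame(tab), file.path(out_dir, "lesionmap.tsv"))
    log(sprintf("[lesionmap] %d regions displayed",
                if (nrow(tab)) sum(tab$displayed) else 0L))
    tab
  })

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  jsonlite::write_json(list(config_hash = fnv1a_hash(as.character(cfg_json)),
                            seed = seed,
                            package_version = tryCatch(
                              as.character(utils::packageVersion("intertract")),
                              error = function(e) "dev"),
                            contrast = config$contrast),
                       file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  log("[pipeline] complete")
  invisible(list(out_dir = out_dir, sim = sim, scores = scores, vba = vba,
                 tracts = tract, lesionmap = lm_tab))
}
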