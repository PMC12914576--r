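## End-to-end orchestration: simulate/load -> frequency maps -> voxel stats
## -> ROI table -> survival report, with a resolved-config snapshot and a
## structured log of per-stage subject counts.

#' Build a run configuration
#'
#' @param cohort_dir directory with `masks/` and `clinical.csv`, or `NULL`
#'   to simulate a cohort.
#' @param out_dir output directory for the run.
#' @param atlas path to an atlas NIfTI (optional; default: synthetic octant
#'   atlas on the cohort grid).
#' @param atlas_labels optional `label,name` CSV for the atlas.
#' @param linear_attributes continuous attributes for t-maps.
#' @param logistic_groups binary groups for z-maps.
#' @param roi_group group used for the ROI association table.
#' @param alpha significance level for thresholded maps.
#' @param correction `"fdr"` or `"uncorrected"`.
#' @param min_count per-voxel coverage threshold.
#' @param survival_cutoff_days survival dichotomization cutoff.
#' @param eval survival evaluation mode, `"in_sample"` or `"loo"`.
#' @param simulate a [synth_params()] (used when `cohort_dir` is `NULL`).
#' @param seed integer seed for any simulation.
#' @return object of class `run_config` (a named list, YAML-serializable).
#' @export
run_config <- function(cohort_dir = NULL, out_dir = "gliomamap_run",
                       atlas = NULL, atlas_labels = NULL,
                       linear_attributes = c("volume_ml", "age_years",
                                             "os_days"),
                       logistic_groups = c("idh", "mgmt", "codel_1p19q",
                                           "sex"),
                       roi_group = "idh",
                       alpha = 0.001, correction = c("fdr", "uncorrected"),
                       min_count = 5, survival_cutoff_days = 365,
                       eval = c("in_sample", "loo"),
                       simulate = NULL, seed = 1L) {
  correction <- match.arg(correction)
  eval <- match.arg(eval)
  known_lin <- c("volume_ml", "age_years", "os_days")
  known_log <- c("idh", "mgmt", "codel_1p19q", "sex")
  if (length(bad <- setdiff(linear_attributes, known_lin)))
    stop("unknown linear attribute(s): ", paste(bad, collapse = ", "))
  if (length(bad <- setdiff(logistic_groups, known_log)))
    stop("unknown logistic group(s): ", paste(bad, collapse = ", "))
  if (!roi_group %in% known_log) stop("unknown roi_group: ", roi_group)
  stopifnot(alpha > 0, alpha <= 1, min_count >= 1)
  structure(list(cohort_dir = cohort_dir, out_dir = out_dir, atlas = atlas,
                 atlas_labels = atlas_labels,
                 linear_attributes = linear_attributes,
                 logistic_groups = logistic_groups, roi_group = roi_group,
                 alpha = alpha, correction = correction,
                 min_count = min_count,
                 survival_cutoff_days = survival_cutoff_days, eval = eval,
                 simulate = simulate, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file with `run_config` fields (unknown fields rejected).
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulate)) {
    sim <- raw$simulate
    if (!is.null(sim$centre_means)) sim$centre_means <-
        lapply(sim$centre_means, as.numeric)
    for (fld in c("group_fracs", "grid_shape", "voxel_size_mm",
                  "radius_lognorm", "age_mean_sd"))
      if (!is.null(sim[[fld]])) sim[[fld]] <- unlist(sim[[fld]])
    raw$simulate <- do.call(synth_params, sim)
  }
  known <- names(formals(run_config))
  if (length(bad <- setdiff(names(raw), known)))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(run_config, raw)
}

write_run_config <- function(config, path) {
  cfg <- unclass(config)
  if (!is.null(cfg$simulate)) {
    cfg$simulate <- unclass(cfg$simulate)
    cfg$simulate$centre_means <- lapply(cfg$simulate$centre_means, as.numeric)
    # named vectors must go out as YAML maps to keep their names
    cfg$simulate$group_fracs <- as.list(cfg$simulate$group_fracs)
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

log_line <- function(con, ...) {
  msg <- paste0(...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full mapping pipeline
#'
#' Stages, in order: cohort load/simulation; frequency maps (overall, volume
#' tertiles, molecular/sex subgroups, age decades, survival bands);
#' voxel-wise t-maps and z-maps with thresholded masks; ROI association
#' table; survival ROC report. Every output lands under `config$out_dir`
#' next to the resolved config (`config.yaml`) and the stage log
#' (`run.log`); identical config + seed gives identical outputs.
#'
#' @param config a [run_config()].
#' @return the run directory, invisibly; the in-memory results as attribute
#'   `"results"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(config$out_dir, "run.log"), open = "wt")
  on.exit(close(logf))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  results <- list()

  ## stage: cohort
  cohort <- stage("cohort", {
    if (!is.null(config$cohort_dir)) {
      read_cohort(config$cohort_dir)
    } else {
      sp <- if (is.null(config$simulate)) synth_params(seed = config$seed)
      else { p <- config$simulate; p$seed <- config$seed; p }
      generate_cohort(sp)$cohort
    }
  })
  n <- n_subjects(cohort)
  log_line(logf, "cohort: n = ", n, " subjects on grid ",
           paste(cohort$grid$shape, collapse = "x"))

  ## stage: frequency maps
  stage("frequency_maps", {
    map_dir <- file.path(config$out_dir, "maps")
    dir.create(map_dir, showWarnings = FALSE)
    write_frequency_map(sum_map(cohort), file.path(map_dir, "all"))
    tm <- tertile_maps(cohort)
    tert <- attr(tm, "tertiles")
    for (nm in names(tm))
      write_frequency_map(tm[[nm]], file.path(map_dir, paste0("volume_", nm)))
    utils::write.csv(data.frame(subject_id = names(tert$labels),
                                label = as.character(tert$labels)),
                     file.path(map_dir, "tertiles.csv"), row.names = FALSE)
    jsonlite::write_json(as.list(tert$cutoffs),
                         file.path(map_dir, "tertile_cutoffs.json"),
                         auto_unbox = TRUE, digits = NA)
    log_line(logf, "frequency_maps: tertile sizes ",
             paste(tert$sizes, collapse = "/"))
    for (attrb in c(intersect(config$logistic_groups,
                              c("idh", "mgmt", "codel_1p19q", "sex")),
                    "age_years", "os_days")) {
      sm <- subgroup_maps(cohort, attrb)
      for (nm in names(sm))
        write_frequency_map(sm[[nm]], file.path(map_dir, nm))
      log_line(logf, "frequency_maps: ", attrb, " -> ",
               length(sm), " subgroup map(s) (n = ",
               paste(vapply(sm, `[[`, integer(1), "n"), collapse = "/"), ")")
    }
    results$tertiles <- tert
  })

  ## stage: voxel statistics
  stage("voxelstats", {
    st_dir <- file.path(config$out_dir, "stats")
    dir.create(st_dir, showWarnings = FALSE)
    for (attrb in config$linear_attributes) {
      ok <- sum(!is.na(cohort$clinical[[attrb]]))
      if (ok < 3) { log_line(logf, "voxelstats: skip ", attrb,
                             " (", ok, " complete cases)"); next }
      sm <- voxelwise_linear(cohort, attrb, min_count = config$min_count)
      write_stat_map(sm, file.path(st_dir, paste0("t_", attrb)))
      thr <- threshold_map(sm, config$alpha, config$correction)
      write_mask(array(as.integer(thr$mask), dim = sm$grid$shape),
                 file.path(st_dir, paste0("t_", attrb, "_sig.nii.gz")),
                 grid = sm$grid)
      log_line(logf, "voxelstats: t-map ", attrb, " n_used = ", sm$n_used,
               " (", n - sm$n_used, " dropped missing), ",
               thr$n_voxels, " significant voxel(s)")
      results$stat_maps[[attrb]] <- sm
    }
    for (grp in config$logistic_groups) {
      tab <- table(cohort$clinical[[grp]])
      if (length(tab) < 2 || any(tab < 2)) {
        log_line(logf, "voxelstats: skip ", grp, " (class counts ",
                 paste(tab, collapse = "/"), ")")
        next
      }
      sm <- voxelwise_logistic(cohort, grp, min_count = config$min_count)
      write_stat_map(sm, file.path(st_dir, paste0("z_", grp)))
      log_line(logf, "voxelstats: z-map ", grp, " n_used = ", sm$n_used,
               " (", n - sm$n_used, " dropped missing), ",
               sm$n_invalid_separation, " separated voxel(s)")
      results$stat_maps[[grp]] <- sm
    }
  })

  ## stage: ROI analysis
  stage("roi", {
    atlas <- if (is.null(config$atlas)) octant_atlas(cohort$grid)
    else read_atlas(config$atlas, config$atlas_labels)
    loads <- roi_load(cohort, atlas)
    utils::write.csv(as.data.frame(loads),
                     file.path(config$out_dir, "roi_loads.csv"))
    grp <- cohort$clinical[[config$roi_group]]
    keep <- !is.na(grp)
    tab <- table(grp[keep])
    if (length(tab) >= 2 && all(tab >= 2)) {
      rt <- roi_group_test(loads[keep, , drop = FALSE], grp[keep], atlas)
      write_roi_table(rt, file.path(config$out_dir, "roi_table.tsv"))
      log_line(logf, "roi: ", nrow(rt), " ROI(s), ", sum(rt$testable),
               " testable, group ", config$roi_group, " n = ", sum(keep))
      results$roi_table <- rt
    } else log_line(logf, "roi: skip association (class counts ",
                    paste(tab, collapse = "/"), ")")
  })

  ## stage: survival
  stage("survival", {
    ok <- sum(!is.na(cohort$clinical$os_days) &
                !is.na(cohort$clinical$age_years))
    if (ok >= 10) {
      rep <- survival_roc(cohort, eval = config$eval,
                          cutoff_days = config$survival_cutoff_days,
                          min_count = config$min_count)
      out <- list(eval = rep$eval, n_used = rep$n_used,
                  cutoff_days = rep$cutoff_days,
                  auc = as.list(rep$auc),
                  delong = lapply(rep$delong, function(d)
                    list(auc_a = d$auc_a, auc_b = d$auc_b, z = d$z,
                         p_two_sided = d$p_two_sided)),
                  roc = lapply(rep$roc, function(r)
                    list(fpr = r$fpr, tpr = r$tpr)))
      jsonlite::write_json(out, file.path(config$out_dir,
                                          "survival_report.json"),
                           auto_unbox = TRUE, digits = NA)
      log_line(logf, "survival: n_used = ", rep$n_used, " (",
               n - rep$n_used, " dropped), AUC ",
               paste(sprintf("%s=%.3f", names(rep$auc), rep$auc),
                     collapse = ", "))
      results$survival <- rep
    } else log_line(logf, "survival: skip (", ok, " complete cases)")
  })

  write_run_config(config, file.path(config$out_dir, "config.yaml"))
  out <- config$out_dir
  attr(out, "results") <- results
  invisible(out)
}
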