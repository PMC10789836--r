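#' Write cohort CSV files
#'
#' Serializes a [simulate_cohort()] result into the package's CSV dialects:
#' `mmtt.csv` (`subject_id`, `visit_week`, `time_min`, `glucose_mmol_l`,
#' `insulin_pmol_l`, `cpeptide_pmol_l`), `cgm.csv` (`subject_id`,
#' `timestamp` ISO-8601, `glucose_mmol_l`), `trial_table.csv`,
#' `diaries.csv`, `diary_assessments.csv`, `subjects.csv`, and a
#' `ground_truth.json` sidecar with the per-subject generating parameters.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put <- function(df, name) {
    path <- file.path(dir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  mmtt <- do.call(rbind, lapply(names(cohort$mmtt), function(sid) {
    do.call(rbind, lapply(names(cohort$mmtt[[sid]]), function(w) {
      d <- cohort$mmtt[[sid]][[w]]$data
      data.frame(subject_id = sid, visit_week = as.integer(w),
                 time_min = d$time, glucose_mmol_l = d$glucose,
                 insulin_pmol_l = d$insulin, cpeptide_pmol_l = d$cpeptide)
    }))
  }))
  put(mmtt, "mmtt.csv")
  cgm <- do.call(rbind, lapply(names(cohort$cgm), function(sid) {
    tr <- cohort$cgm[[sid]]
    data.frame(subject_id = sid,
               timestamp = format(tr$timestamps, "%Y-%m-%dT%H:%M:%S"),
               glucose_mmol_l = tr$glucose)
  }))
  put(cgm, "cgm.csv")
  put(cohort$trial$table, "trial_table.csv")
  put(cohort$trial$diaries, "diaries.csv")
  put(cohort$trial$assessments, "diary_assessments.csv")
  put(cohort$trial$subjects, "subjects.csv")
  truth <- lapply(cohort$trial$truth, function(s) {
    list(id = s$id,
         glucose_sensitivity = s$betacell$glucose_sensitivity,
         isr_at_5_5 = s$betacell$isr_at_5_5,
         rate_sensitivity = s$betacell$rate_sensitivity,
         pot_ratio = s$pot_ratio, clearance = s$clearance,
         fasting_glucose = s$fasting_glucose,
         kinetics = s$kinetics[c("k01", "k12", "k21", "V")])
  })
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(dir, "ground_truth.json"))
  invisible(files)
}

# run one pipeline stage with resume support: skip when all outputs exist
run_stage <- function(name, outputs, resume, log, fun) {
  if (resume && all(file.exists(outputs))) {
    log(sprintf("stage %-12s skipped (outputs present)", name))
    return(invisible(NULL))
  }
  log(sprintf("stage %-12s running", name))
  tryCatch(fun(), error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(NULL)
}

#' Run the full synthetic-trial analysis pipeline
#'
#' Orchestrates simulate, deconvolve, beta cell fit, metabolic indices, CGM
#' summaries and trial statistics into one reproducible run.  Each stage
#' writes CSV outputs under `out_dir`; with `resume = TRUE` stages whose
#' outputs already exist are skipped.  A machine-readable run manifest
#' (`manifest.json`: config hash, seed, package version, file inventory,
#' CONSORT-style subject accounting) and a human-readable `report.txt` are
#' written at the end.
#'
#' @param config a [simulation_config()] (or path to a YAML file of
#'   overrides for it).
#' @param out_dir output directory.
#' @param seed overrides `config$seed` when given.
#' @param resume skip stages whose outputs exist (default FALSE).
#' @param quiet suppress progress messages.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir,
                         seed = NULL, resume = FALSE, quiet = FALSE) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) {
    cfg <- unclass(config)
    cfg$seed <- seed
    config <- do.call(simulation_config, cfg)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- if (quiet) function(msg) invisible() else function(msg) message(msg)
  pth <- function(name) file.path(out_dir, name)
  warnings_log <- character()

  sim_files <- pth(c("mmtt.csv", "cgm.csv", "trial_table.csv", "diaries.csv",
                     "diary_assessments.csv", "subjects.csv",
                     "ground_truth.json"))
  run_stage("simulate", sim_files, resume, log, function() {
    cohort <- simulate_cohort(config)
    write_cohort_csv(cohort, out_dir)
  })
  subjects <- read.csv(pth("subjects.csv"), stringsAsFactors = FALSE)
  mmtt <- read.csv(pth("mmtt.csv"), stringsAsFactors = FALSE)

  run_stage("deconvolve", pth("isr.csv"), resume, log, function() {
    out <- list()
    for (key in unique(paste(mmtt$subject_id, mmtt$visit_week))) {
      d <- mmtt[paste(mmtt$subject_id, mmtt$visit_week) == key, ]
      s <- subjects[subjects$id == d$subject_id[1], ]
      kin <- population_kinetics(s$age, s$sex, s$height_cm, s$weight_kg,
                                 diabetes = TRUE)
      cp <- pmax(d$cpeptide_pmol_l, 1)
      # discrepancy target from the known assay SD of the simulated data
      tr <- deconvolve_isr(d$time_min, cp, kin,
                           target_cv = config$noise_sd$mmtt_cpeptide /
                             mean(cp))
      out[[key]] <- data.frame(subject_id = d$subject_id[1],
                               visit_week = d$visit_week[1],
                               time_min = tr$time, isr_pmol_min = tr$isr)
    }
    write.csv(do.call(rbind, out), pth("isr.csv"), row.names = FALSE)
  })
  isr_all <- read.csv(pth("isr.csv"), stringsAsFactors = FALSE)

  run_stage("betacell", pth("betacell.csv"), resume, log, function() {
    out <- list()
    for (key in unique(paste(mmtt$subject_id, mmtt$visit_week))) {
      d <- mmtt[paste(mmtt$subject_id, mmtt$visit_week) == key, ]
      i <- isr_all[paste(isr_all$subject_id, isr_all$visit_week) == key, ]
      fit <- fit_beta_cell(d$time_min, pmax(d$glucose_mmol_l, 0.5),
                           isr_trace(i$time_min, i$isr_pmol_min),
                           seed = config$seed)
      if (!fit$converged) {
        warnings_log <<- c(warnings_log,
                           paste("betacell non-convergence:", key))
      }
      out[[key]] <- data.frame(
        subject_id = d$subject_id[1], visit_week = d$visit_week[1],
        beta_gs = fit$glucose_sensitivity, isr_5_5 = fit$isr_at_5_5,
        beta_rs = fit$rate_sensitivity, pot_ratio = fit$potentiation_ratio,
        resid_sd = fit$resid_sd, converged = fit$converged)
    }
    write.csv(do.call(rbind, out), pth("betacell.csv"), row.names = FALSE)
  })

  run_stage("indices", pth("indices.csv"), resume, log, function() {
    out <- list()
    for (key in unique(paste(mmtt$subject_id, mmtt$visit_week))) {
      d <- mmtt[paste(mmtt$subject_id, mmtt$visit_week) == key, ]
      i <- isr_all[paste(isr_all$subject_id, isr_all$visit_week) == key, ]
      tr <- isr_trace(i$time_min, i$isr_pmol_min)
      g <- pmax(d$glucose_mmol_l, 0.5)
      ins <- pmax(d$insulin_pmol_l, 1)
      out[[key]] <- data.frame(
        subject_id = d$subject_id[1], visit_week = d$visit_week[1],
        homa_ir = homa_ir(g[d$time_min == 0], ins[d$time_min == 0]),
        matsuda = matsuda(d$time_min, g, ins),
        clear_fast = insulin_clearance(tr, d$time_min, ins, "fasting"),
        clear_total = insulin_clearance(tr, d$time_min, ins, "total"))
    }
    write.csv(do.call(rbind, out), pth("indices.csv"), row.names = FALSE)
  })

  run_stage("cgm", pth("cgm_summary.csv"), resume, log, function() {
    cgm <- read.csv(pth("cgm.csv"), stringsAsFactors = FALSE)
    out <- lapply(split(cgm, cgm$subject_id), function(d) {
      s <- cgm_summary(cgm_trace(d$timestamp, d$glucose_mmol_l,
                                 config$cgm_interval))
      data.frame(subject_id = d$subject_id[1], mean = s$mean, cv = s$cv,
                 tbr_3_9 = s$tbr_3_9, tir_3_9_10 = s$tir_3_9_10,
                 tar_10 = s$tar_10, t_above_7_8 = s$t_above_7_8,
                 t_above_6_7 = s$t_above_6_7)
    })
    write.csv(do.call(rbind, out), pth("cgm_summary.csv"), row.names = FALSE)
  })

  run_stage("stats", pth("trial_effects.csv"), resume, log, function() {
    tab <- read.csv(pth("trial_table.csv"), stringsAsFactors = FALSE)
    effects <- do.call(rbind, lapply(names(config$effect_sizes), function(v) {
      res <- tryCatch(rm_anova(tab, v), error = function(e) NULL)
      if (is.null(res)) return(NULL)
      res$variable <- v
      res
    }))
    write.csv(effects, pth("trial_effects.csv"), row.names = FALSE)

    diaries <- read.csv(pth("diaries.csv"), stringsAsFactors = FALSE)
    W <- max(config$visit_weeks)
    changes <- do.call(rbind, lapply(split(tab, tab$variable), function(d) {
      wide <- merge(d[d$visit_week == 0, c("subject_id", "value")],
                    d[d$visit_week == W, c("subject_id", "value")],
                    by = "subject_id")
      data.frame(subject_id = wide$subject_id, variable = d$variable[1],
                 change = wide$value.y - wide$value.x)
    }))
    tert <- tryCatch(tertile_stratify(diaries, changes),
                     error = function(e) NULL)
    if (!is.null(tert)) {
      write.csv(tert$comparisons, pth("tertile_comparisons.csv"),
                row.names = FALSE)
      write.csv(tert$metric, pth("after_lunch_share.csv"), row.names = FALSE)
    }
    assess <- read.csv(pth("diary_assessments.csv"), stringsAsFactors = FALSE)
    write.csv(reconcile_diaries(assess), pth("diary_consensus.csv"),
              row.names = FALSE)
  })

  # CONSORT-style accounting and manifest
  acct <- lapply(c("eTRC", "Med"), function(a) {
    rand <- sum(subjects$arm == a)
    comp <- sum(subjects$arm == a & !subjects$dropout)
    list(arm = a, randomised = rand, completed = comp,
         completion_pct = round_half_up(comp / rand * 100, 1))
  })
  files <- list.files(out_dir, pattern = "\\.(csv|json)$")
  files <- setdiff(files, "manifest.json")
  cfg_resolved <- unclass(config)
  cfg_resolved <- cfg_resolved[order(names(cfg_resolved))]
  manifest <- list(
    config_hash = fnv1a_hash(paste(deparse(cfg_resolved), collapse = "\n")),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("mealtrial")),
    files = sort(files),
    accounting = acct,
    n_analysed = sum(!subjects$dropout),
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  rep <- c(
    "Synthetic dietary trial pipeline report",
    sprintf("seed %s, config %s", config$seed, manifest$config_hash),
    "",
    vapply(acct, function(a) sprintf(
      "%s: randomised %d, completed %d (%.1f%%)",
      a$arm, a$randomised, a$completed, a$completion_pct), character(1)),
    "",
    sprintf("outputs: %s", paste(manifest$files, collapse = ", ")),
    if (length(warnings_log)) c("", "warnings:", warnings_log) else character()
  )
  writeLines(rep, pth("report.txt"))
  log("pipeline complete")
  invisible(manifest)
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file of overrides and merges it over the
#' [simulation_config()] defaults.  Invalid keys are reported all at once.
#'
#' @param path YAML file path.
#' @return a [simulation_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  for (nm in intersect(names(raw), c("n_per_arm", "dropouts_per_arm",
                                     "meal_hours", "cgm_bump_amplitude",
                                     "after_lunch_share"))) {
    raw[[nm]] <- unlist(raw[[nm]])
  }
  for (nm in intersect(names(raw), c("effect_sizes", "baselines"))) {
    raw[[nm]] <- lapply(raw[[nm]], unlist)
  }
  do.call(simulation_config, raw)
}
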