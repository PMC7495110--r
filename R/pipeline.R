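# Orchestration: configuration, delimited-text I/O, manifest handling,
# stage ordering, provenance, and the command-line entry point.

PIPELINE_STAGES <- c("simulate", "preprocess", "features", "estimate-k",
                     "fit-states", "dynamics", "compare")

#' Default pipeline configuration
#'
#' All stage parameters with their standard values: 3 discarded volumes,
#' 22-TR sliding window shifted by 1 TR, 25-window ASWC average, 0.01-0.15 Hz
#' fifth-order band-pass, candidate k 2-10, 33 k-means replicates with at
#' most 4000 iterations, 100000 permutations at alpha 0.05.
#'
#' @param ... Named overrides for any config field; unknown names are an
#'   error.
#' @return A named list of class `pipeline_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    n_discard = 3L,
    regress_motion = FALSE,
    mad_threshold = 4,
    low_hz = 0.01, high_hz = 0.15, filter_order = 5L,
    swc_window = 22L, swc_step = 1L, aswc_window = 25L,
    k_min = 2L, k_max = 10L, k = NA_integer_,
    replicates = 33L, max_iter = 4000L,
    n_perm = 100000L, alpha = 0.05,
    seed = 1L,
    # synthetic-cohort fields (simulate stage only)
    n_per_group = 17L, n_components = 53L, n_volumes = 225L,
    tr_seconds = 2.0, k_true = 4L, separation = 0.8,
    mean_dwell_target = 40, noise_sd = 0.3, group_effect = 0,
    motion_amplitude = 0.02
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Read a configuration file (JSON)
#'
#' @param path Path to a JSON file whose keys are config fields.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_config, vals)
}

#' Read a component time-course matrix from delimited text
#'
#' Rows are volumes, columns are components. A header row of column names is
#' auto-detected. Ragged or non-numeric rows raise an error naming the line.
#'
#' @param path File path (whitespace- or tab-delimited).
#' @param subject_id,group,tr_seconds Metadata for the returned object.
#' @param expect_dim Optional `c(T, C)`; a mismatch warns.
#' @return A [component_timecourses()] object.
#' @export
read_timecourses <- function(path, subject_id = basename(path),
                             group = "control", tr_seconds = 2.0,
                             expect_dim = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("%s: empty file", path)
  toks <- strsplit(trimws(lines), "[\t ,]+")
  has_header <- anyNA(suppressWarnings(as.numeric(toks[[1L]])))
  start <- if (has_header) 2L else 1L
  if (start > length(toks)) stopf("%s: header only, no data rows", path)
  ncols <- length(toks[[start]])
  rows <- vector("list", length(toks) - start + 1L)
  for (i in start:length(toks)) {
    if (length(toks[[i]]) != ncols) {
      stopf("%s: line %d has %d fields, expected %d", path, i,
            length(toks[[i]]), ncols)
    }
    v <- suppressWarnings(as.numeric(toks[[i]]))
    if (anyNA(v)) stopf("%s: non-numeric value on line %d", path, i)
    rows[[i - start + 1L]] <- v
  }
  m <- do.call(rbind, rows)
  if (has_header) colnames(m) <- toks[[1L]]
  if (!is.null(expect_dim) && any(dim(m) != expect_dim)) {
    warnf("%s: matrix is %d x %d, expected %d x %d", path, nrow(m), ncol(m),
          expect_dim[1L], expect_dim[2L])
  }
  component_timecourses(subject_id, group, m, tr_seconds)
}

#' Write a component time-course matrix as tab-delimited text
#'
#' Full-precision output, so a write/read round trip reproduces finite
#' values bit-exactly.
#'
#' @param tc A [component_timecourses()] object (or a bare matrix).
#' @param path Output path.
#' @export
write_timecourses <- function(tc, path) {
  m <- if (inherits(tc, "component_timecourses")) tc$data else as.matrix(tc)
  dt <- data.table::as.data.table(formatC(m, format = "g", digits = 17))
  if (!is.null(colnames(m))) data.table::setnames(dt, colnames(m))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE,
                     col.names = !is.null(colnames(m)))
  invisible(path)
}

#' Read a cohort manifest
#'
#' Tab-delimited with columns `subject_id`, `group`, optional `path`,
#' `motion_path`, `cgi`, `bdi`, `bai`.
#'
#' @param path Manifest file path.
#' @return A data.frame; duplicate ids or bad group labels are errors.
#' @export
read_manifest <- function(path) {
  man <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("subject_id", "group")
  missing <- setdiff(need, names(man))
  if (length(missing)) stopf("manifest lacks column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(man$subject_id)) stopf("duplicate subject ids in manifest")
  bad <- setdiff(unique(man$group), c("patient", "control"))
  if (length(bad)) stopf("manifest group labels must be patient/control, found: %s",
                         paste(bad, collapse = ", "))
  man
}

#' @rdname read_manifest
#' @param manifest Data frame to write.
#' @export
write_manifest <- function(manifest, path) {
  data.table::fwrite(manifest, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

write_provenance <- function(dir, config, stage, inputs = character(0)) {
  jsonlite::write_json(
    list(stage = stage,
         config = unclass(config),
         package_version = as.character(utils::packageVersion("dfcstates")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         input_checksums = as.list(tools::md5sum(inputs[file.exists(inputs)]))),
    file.path(dir, paste0(stage, "_provenance.json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null", na = "null")
}

log_line <- function(out_dir, fmt, ...) {
  cat(sprintf(paste0("[%s] ", fmt, "\n"), format(Sys.time(), "%H:%M:%S"), ...),
      file = file.path(out_dir, "pipeline.log"), append = TRUE)
}

require_stage <- function(out_dir, stage, prerequisite, force = FALSE) {
  marker <- file.path(out_dir, paste0(".done_", prerequisite))
  if (!file.exists(marker) && !force) {
    stopf("stage '%s' requires completed stage '%s' in %s (run it first or use force = TRUE)",
          stage, prerequisite, out_dir)
  }
}

mark_done <- function(out_dir, stage) {
  writeLines(format(Sys.time()), file.path(out_dir, paste0(".done_", stage)))
}

load_cohort_features <- function(out_dir, man, config) {
  lapply(seq_len(nrow(man)), function(i) {
    f <- read_matrix_tsv(file.path(out_dir, "features",
                                paste0(man$subject_id[i], "_features.tsv")))
    aswc_cols <- seq_len(ncol(f) %/% 2L)
    structure(list(subject_id = man$subject_id[i], group = man$group[i],
                   aswc = f[, aswc_cols, drop = FALSE],
                   derivatives = f[, -aswc_cols, drop = FALSE],
                   features = f, zscored = TRUE,
                   window_size_tr = config$swc_window,
                   aswc_window = config$aswc_window,
                   tr_seconds = config$tr_seconds),
              class = "dfc_features")
  })
}

read_matrix_tsv <- function(path) {
  as.matrix(data.table::fread(path, sep = "\t"))
}

#' Run pipeline stages
#'
#' Stages write delimited-text artifacts plus a JSON provenance sidecar
#' (resolved config, package version, input checksums) into `out_dir` and
#' log to `pipeline.log`. The stage order simulate/ingest -> preprocess ->
#' features -> estimate-k -> fit-states -> dynamics -> compare is enforced
#' through completion markers; `"all"` runs the whole chain on a synthetic
#' cohort.
#'
#' @param command One of `simulate`, `preprocess`, `features`, `estimate-k`,
#'   `fit-states`, `dynamics`, `compare`, `all`.
#' @param config A [default_config()] (or overrides list).
#' @param out_dir Artifact directory (created if needed).
#' @param force Skip the stage-order check.
#' @return Invisibly, a list of the stage's main results.
#' @export
run_pipeline <- function(command, config = default_config(), out_dir = ".",
                         force = FALSE) {
  command <- match.arg(command, c(PIPELINE_STAGES, "all"))
  if (!inherits(config, "pipeline_config")) config <- do.call(default_config, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (command == "all") {
    for (st in PIPELINE_STAGES) run_pipeline(st, config, out_dir, force = force)
    return(invisible(list(out_dir = out_dir)))
  }

  log_line(out_dir, "stage %s starting", command)
  result <- switch(
    command,
    "simulate" = {
      cc <- cohort_config(
        n_per_group = config$n_per_group, n_components = config$n_components,
        n_volumes = config$n_volumes, tr_seconds = config$tr_seconds,
        k_true = config$k_true, mean_dwell_target = config$mean_dwell_target,
        noise_sd = config$noise_sd, group_effect = config$group_effect,
        separation = config$separation,
        motion_amplitude = config$motion_amplitude, seed = config$seed
      )
      cohort <- simulate_cohort(cc)
      cdir <- file.path(out_dir, "cohort")
      dir.create(cdir, showWarnings = FALSE)
      for (i in seq_along(cohort$subjects)) {
        sid <- cohort$subjects[[i]]$subject_id
        write_timecourses(cohort$subjects[[i]],
                          file.path(cdir, paste0(sid, "_timecourses.tsv")))
        utils::write.table(t(cohort$ground_truth$motion[[sid]]),
                           file.path(cdir, paste0(sid, "_motion.tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      }
      write_manifest(cohort$manifest, file.path(cdir, "manifest.tsv"))
      jsonlite::write_json(
        list(states = cohort$ground_truth$states,
             markov_matrix = cc$markov_matrix, k_true = cc$k_true,
             seed = cc$seed),
        file.path(cdir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
      mark_done(out_dir, "simulate")
      list(manifest = cohort$manifest)
    },
    "preprocess" = {
      require_stage(out_dir, "preprocess", "simulate", force)
      cdir <- file.path(out_dir, "cohort")
      man <- read_manifest(file.path(cdir, "manifest.tsv"))
      pdir <- file.path(out_dir, "preprocessed")
      dir.create(pdir, showWarnings = FALSE)
      fd_rows <- list()
      for (i in seq_len(nrow(man))) {
        sid <- man$subject_id[i]
        tc <- read_timecourses(file.path(cdir, paste0(sid, "_timecourses.tsv")),
                               subject_id = sid, group = man$group[i],
                               tr_seconds = config$tr_seconds)
        mpath <- file.path(cdir, paste0(sid, "_motion.tsv"))
        motion <- if (file.exists(mpath)) t(read_matrix_tsv(mpath)) else NULL
        tc <- preprocess_timecourses(
          tc, n_discard = config$n_discard, motion = motion,
          regress_motion = config$regress_motion,
          mad_threshold = config$mad_threshold,
          low_hz = config$low_hz, high_hz = config$high_hz,
          order = config$filter_order)
        write_timecourses(tc, file.path(pdir, paste0(sid, "_clean.tsv")))
        if (!is.null(motion)) {
          fd <- framewise_displacement(motion)
          fd_rows[[sid]] <- data.frame(subject_id = sid, group = man$group[i],
                                       mean_fd = fd$mean_fd)
        }
        log_line(out_dir, "preprocess %s: %d volumes retained", sid, nrow(tc$data))
      }
      if (length(fd_rows)) {
        data.table::fwrite(do.call(rbind, fd_rows),
                           file.path(pdir, "framewise_displacement.tsv"), sep = "\t")
      }
      mark_done(out_dir, "preprocess")
      list(n_subjects = nrow(man))
    },
    "features" = {
      require_stage(out_dir, "features", "preprocess", force)
      cdir <- file.path(out_dir, "cohort")
      man <- read_manifest(file.path(cdir, "manifest.tsv"))
      fdir <- file.path(out_dir, "features")
      dir.create(fdir, showWarnings = FALSE)
      for (i in seq_len(nrow(man))) {
        sid <- man$subject_id[i]
        tc <- read_timecourses(file.path(out_dir, "preprocessed",
                                         paste0(sid, "_clean.tsv")),
                               subject_id = sid, group = man$group[i],
                               tr_seconds = config$tr_seconds)
        swc <- sliding_window_correlations(tc, config$swc_window, config$swc_step)
        fs <- zscore_feature_blocks(aswc_and_derivatives(swc, config$aswc_window))
        data.table::fwrite(data.table::as.data.table(fs$features),
                           file.path(fdir, paste0(sid, "_features.tsv")), sep = "\t")
        if (i == 1L) {
          data.table::fwrite(fs$pair_index, file.path(fdir, "pair_index.tsv"),
                             sep = "\t")
          jsonlite::write_json(
            list(swc_window = config$swc_window, swc_step = config$swc_step,
                 aswc_window = config$aswc_window,
                 n_windows = nrow(fs$features), n_features = ncol(fs$features),
                 alignment = "drop_last_raw_aswc_window", zscored = TRUE),
            file.path(fdir, "feature_params.json"), auto_unbox = TRUE)
        }
        log_line(out_dir, "features %s: %d windows x %d features", sid,
                 nrow(fs$features), ncol(fs$features))
      }
      mark_done(out_dir, "features")
      list(n_subjects = nrow(man))
    },
    "estimate-k" = {
      require_stage(out_dir, "estimate-k", "features", force)
      man <- read_manifest(file.path(out_dir, "cohort", "manifest.tsv"))
      fsets <- load_cohort_features(out_dir, man, config)
      ex <- select_exemplars(fsets)
      curve <- estimate_k(ex, k_range = config$k_min:config$k_max,
                          replicates = config$replicates,
                          max_iter = config$max_iter, seed = config$seed)
      sdir <- file.path(out_dir, "states")
      dir.create(sdir, showWarnings = FALSE)
      data.table::fwrite(curve$curve, file.path(sdir, "validity_curve.tsv"), sep = "\t")
      jsonlite::write_json(
        list(chosen_k = curve$chosen_k, db_k = curve$db_k,
             chooser = curve$chooser, n_exemplars = nrow(ex$data)),
        file.path(sdir, "chosen_k.json"), auto_unbox = TRUE)
      log_line(out_dir, "estimate-k: chosen k = %d (RT), DB minimizer = %d",
               curve$chosen_k, curve$db_k)
      mark_done(out_dir, "estimate-k")
      list(curve = curve)
    },
    "fit-states" = {
      require_stage(out_dir, "fit-states", "features", force)
      man <- read_manifest(file.path(out_dir, "cohort", "manifest.tsv"))
      fsets <- load_cohort_features(out_dir, man, config)
      sdir <- file.path(out_dir, "states")
      dir.create(sdir, showWarnings = FALSE)
      k <- config$k
      if (is.na(k)) {
        kfile <- file.path(sdir, "chosen_k.json")
        if (!file.exists(kfile)) {
          stopf("no k override in config and no estimate-k result; run estimate-k or set k")
        }
        k <- jsonlite::read_json(kfile)$chosen_k
      }
      cohort <- concatenate_cohort(fsets)
      fit <- kmeans_correlation(cohort$features, k,
                                replicates = config$replicates,
                                max_iter = config$max_iter, seed = config$seed)
      seqs <- assign_states(fit$model, fsets)
      data.table::fwrite(data.table::as.data.table(fit$model$centroids),
                         file.path(sdir, "centroids.tsv"), sep = "\t")
      jsonlite::write_json(
        list(k = fit$model$k, cost = fit$model$cost,
             replicates = fit$model$replicates, seed = fit$model$seed,
             relabel_map = fit$model$relabel_map),
        file.path(sdir, "state_model.json"), auto_unbox = TRUE, digits = NA)
      for (sq in seqs) {
        utils::write.table(data.frame(state = sq$states),
                           file.path(sdir, paste0(sq$subject_id, "_states.tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      }
      log_line(out_dir, "fit-states: k = %d, cost %.4f", k, fit$model$cost)
      mark_done(out_dir, "fit-states")
      list(model = fit$model, sequences = seqs)
    },
    "dynamics" = {
      require_stage(out_dir, "dynamics", "fit-states", force)
      man <- read_manifest(file.path(out_dir, "cohort", "manifest.tsv"))
      sdir <- file.path(out_dir, "states")
      k <- jsonlite::read_json(file.path(sdir, "state_model.json"))$k
      metrics <- lapply(seq_len(nrow(man)), function(i) {
        st <- as.integer(read_matrix_tsv(file.path(sdir, paste0(man$subject_id[i], "_states.tsv"))))
        m <- state_metrics(st, k)
        m$subject_id <- man$subject_id[i]
        m$group <- man$group[i]
        m
      })
      ddir <- file.path(out_dir, "dynamics")
      dir.create(ddir, showWarnings = FALSE)
      data.table::fwrite(metrics_table(metrics),
                         file.path(ddir, "state_metrics.tsv"), sep = "\t")
      for (grp in c("control", "patient")) {
        tm <- pool_transitions(metrics[man$group == grp], k, group = grp)
        at <- extract_attractor(tm)
        jsonlite::write_json(
          list(group = grp, counts = tm$counts, probs = tm$probs,
               probs_with_self = tm$probs_with_self,
               successor = at$successor, cycles = at$cycles,
               attractor_states = at$on_cycle),
          file.path(ddir, paste0("transitions_", grp, ".json")),
          digits = NA, na = "null")
      }
      mark_done(out_dir, "dynamics")
      list(metrics = metrics)
    },
    "compare" = {
      require_stage(out_dir, "compare", "dynamics", force)
      man <- read_manifest(file.path(out_dir, "cohort", "manifest.tsv"))
      sdir <- file.path(out_dir, "states")
      k <- jsonlite::read_json(file.path(sdir, "state_model.json"))$k
      metrics <- lapply(seq_len(nrow(man)), function(i) {
        st <- as.integer(read_matrix_tsv(file.path(sdir, paste0(man$subject_id[i], "_states.tsv"))))
        m <- state_metrics(st, k)
        m$subject_id <- man$subject_id[i]
        m$group <- man$group[i]
        m
      })
      report <- run_group_analysis(metrics, k, n_perm = config$n_perm,
                                   alpha = config$alpha, seed = config$seed,
                                   manifest = man)
      rdir <- file.path(out_dir, "compare")
      dir.create(rdir, showWarnings = FALSE)
      data.table::fwrite(report$tests, file.path(rdir, "group_tests.tsv"), sep = "\t")
      if (!is.null(report$clinical)) {
        data.table::fwrite(report$clinical,
                           file.path(rdir, "clinical_correlations.tsv"), sep = "\t")
      }
      mark_done(out_dir, "compare")
      list(report = report)
    }
  )
  write_provenance(out_dir, config, command)
  log_line(out_dir, "stage %s done", command)
  invisible(result)
}

#' Command-line entry point
#'
#' Thin wrapper used by the `inst/cli/dfcstates` script:
#' `dfcstates <command> --out DIR [--config FILE] [--seed N] [--k N] ...`.
#'
#' @param args Character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status (0 on success), invisibly.
#' @export
dfc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1L] %in% c("-h", "--help")) {
    cat("usage: dfcstates <", paste(c(PIPELINE_STAGES, "all"), collapse = "|"),
        "> [--out DIR] [--config FILE] [--seed N] [--k N] [--force]\n", sep = "")
    return(invisible(0L))
  }
  command <- args[1L]
  rest <- args[-1L]
  getopt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i)) rest[i[1L] + 1L] else default
  }
  config <- if (!is.null(getopt("--config"))) read_config(getopt("--config")) else default_config()
  if (!is.null(getopt("--seed"))) config$seed <- as.integer(getopt("--seed"))
  if (!is.null(getopt("--k"))) config$k <- as.integer(getopt("--k"))
  out_dir <- getopt("--out", default = ".")
  status <- tryCatch({
    run_pipeline(command, config, out_dir, force = "--force" %in% rest)
    0L
  }, error = function(e) {
    message("pipeline failure: ", conditionMessage(e))
    writeLines(conditionMessage(e), file.path(out_dir, "FAILED"))
    1L
  })
  invisible(status)
}
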