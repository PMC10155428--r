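#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with the protocol
#' defaults: 10-300 Hz order-6 Butterworth band-pass (upper edge capped
#' below Nyquist at application time), kernel-5 median filter on artifact
#' channels, 100 ms RMS windows, 7000-point time normalization, VAF
#' threshold 0.85 over k = 1..10 with 100 NNMF restarts, Higuchi
#' k_max = 512.
#'
#' @param filter_low,filter_high band edges (Hz).
#' @param filter_order total Butterworth order (even).
#' @param median_kernel odd median-filter length (samples).
#' @param rms_window_ms RMS window (ms).
#' @param n_timepoints time-normalized trial length.
#' @param vaf_threshold VAF threshold in (0, 1).
#' @param k_range candidate synergy counts.
#' @param n_restarts NNMF restarts.
#' @param hfd_kmax Higuchi largest lag.
#' @param normalization amplitude-normalization scope.
#' @param r2_method VAF definition (see [vaf_curve()]).
#' @param seed master seed for every stochastic stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(filter_low = 10, filter_high = 300,
                            filter_order = 6, median_kernel = 5,
                            rms_window_ms = 100, n_timepoints = 7000,
                            vaf_threshold = 0.85, k_range = 1:10,
                            n_restarts = 100, hfd_kmax = 512,
                            normalization = c("per_muscle_session",
                                              "per_trial"),
                            r2_method = c("centered", "literal"),
                            seed = 1L) {
  normalization <- match.arg(normalization)
  r2_method <- match.arg(r2_method)
  num <- c(filter_low = filter_low, filter_high = filter_high,
           filter_order = filter_order, median_kernel = median_kernel,
           rms_window_ms = rms_window_ms, n_timepoints = n_timepoints,
           n_restarts = n_restarts, hfd_kmax = hfd_kmax)
  if (any(num <= 0)) stop("all numeric settings must be positive")
  if (vaf_threshold <= 0 || vaf_threshold >= 1)
    stop("vaf_threshold must be in (0, 1)")
  if (any(k_range < 1) || any(k_range > 10))
    stop("k_range must lie within 1..10 (the channel count)")
  structure(list(filter_low = filter_low, filter_high = filter_high,
                 filter_order = filter_order,
                 median_kernel = median_kernel,
                 rms_window_ms = rms_window_ms,
                 n_timepoints = n_timepoints,
                 vaf_threshold = vaf_threshold, k_range = k_range,
                 n_restarts = n_restarts, hfd_kmax = hfd_kmax,
                 normalization = normalization, r2_method = r2_method,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_try <- function(stage, session_id, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed for session '%s': %s", stage,
                 session_id, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' For each session: preprocessing, complexity (HFD) table, spinal maps of
#' every movement/condition ensemble, and synergy model fits. Across
#' sessions: template-based synergy matching (per movement/condition,
#' among sessions sharing the selected k) and the group statistics
#' battery. Deterministic given `config$seed`.
#'
#' @param sessions list of [session_record()] objects and/or session
#'   container paths.
#' @param chart a [load_myotomal_chart()] object or chart CSV path
#'   (`NULL` = built-in default).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, every stage's
#'   tables are written as TSV/JSON with a `manifest.json`.
#' @param stages subset of stages to run (later stages require earlier
#'   ones and are pulled in automatically).
#' @return object of class `analysis_bundle`.
#' @export
run_full_analysis <- function(sessions, chart = NULL,
                              config = pipeline_config(),
                              out_dir = NULL,
                              stages = c("hfd", "spinalmap", "synergy",
                                         "match", "stats")) {
  if (inherits(sessions, "session_record")) sessions <- list(sessions)
  if (!length(sessions)) stop("need at least one session")
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.character(chart) || is.null(chart))
    chart <- load_myotomal_chart(chart)

  recs <- lapply(sessions, function(s) {
    if (inherits(s, "session_record")) s else read_session(s)
  })
  ids <- vapply(recs, function(r)
    sprintf("%s#%d", r$participant_id, r$session_index), character(1))
  names(recs) <- ids

  pp <- lapply(ids, function(id)
    stage_try("preprocess", id, preprocess_session(recs[[id]], config)))
  names(pp) <- ids

  hfd_tables <- NULL
  if ("hfd" %in% stages || "stats" %in% stages) {
    hfd_tables <- do.call(rbind, lapply(ids, function(id) {
      tb <- stage_try("hfd", id, complexity_table(pp[[id]],
                                                  config$hfd_kmax))
      tb$participant <- recs[[id]]$participant_id
      tb$session <- recs[[id]]$session_index
      tb$group <- recs[[id]]$group
      tb
    }))
    class(hfd_tables) <- c("hfd_table", "data.frame")
  }

  spinal_maps <- NULL
  if ("spinalmap" %in% stages) {
    spinal_maps <- lapply(ids, function(id)
      stage_try("spinalmap", id,
                lapply(pp[[id]]$ensembles, map_to_segments, chart = chart)))
    names(spinal_maps) <- ids
  }

  synergy_sets <- NULL
  if (any(c("synergy", "match") %in% stages)) {
    synergy_sets <- lapply(ids, function(id)
      stage_try("synergy", id, {
        ens <- pp[[id]]$ensembles
        fits <- lapply(seq_along(ens), function(i)
          synergy_fit(ens[[i]], k_range = config$k_range,
                      vaf_threshold = config$vaf_threshold,
                      n_restarts = config$n_restarts,
                      seed = config$seed + 100L * i,
                      r2_method = config$r2_method))
        names(fits) <- names(ens)
        fits
      }))
    names(synergy_sets) <- ids
  }

  matches <- NULL
  if ("match" %in% stages && length(ids) >= 2L) {
    keys <- unique(unlist(lapply(synergy_sets, names)))
    matches <- list()
    for (key in keys) {
      sets <- lapply(synergy_sets, function(s) s[[key]])
      sets <- sets[!vapply(sets, is.null, TRUE)]
      ks <- vapply(sets, function(s) s$k, integer(1))
      common <- as.integer(names(which.max(table(ks))))
      sets <- sets[ks == common]
      if (length(sets) >= 2L)
        matches[[key]] <- stage_try("match", key, compare_synergies(sets))
    }
  }

  stats_report <- NULL
  if ("stats" %in% stages) {
    conds <- unique(hfd_tables$condition)
    cmps <- c(if (all(c("stim", "no_stim") %in% conds)) "stim_vs_nostim",
              if (all(c("control", "stim") %in% conds)) "control_vs_stim")
    if (length(cmps))
      stats_report <- stage_try("stats", "cohort",
                                run_group_analysis(hfd_tables,
                                                   comparisons = cmps))
  }

  bundle <- structure(list(hfd_table = hfd_tables,
                           spinal_maps = spinal_maps,
                           synergy_sets = synergy_sets,
                           matches = matches,
                           stats_report = stats_report,
                           preprocessed = pp, config = config,
                           session_ids = ids),
                      class = "analysis_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat("BMCA analysis bundle:", length(x$session_ids), "session(s)\n")
  cat("  sessions:", paste(x$session_ids, collapse = ", "), "\n")
  if (!is.null(x$hfd_table))
    cat("  HFD table:", nrow(x$hfd_table), "cells\n")
  if (!is.null(x$synergy_sets)) {
    ks <- unlist(lapply(x$synergy_sets, vapply, function(f) f$k,
                        integer(1)))
    cat("  synergy fits:", length(ks), " selected k range:",
        paste(range(ks), collapse = "-"), "\n")
  }
  if (!is.null(x$stats_report)) print(x$stats_report)
  invisible(x)
}

# serialize every stage table as TSV/JSON plus a manifest
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, name)
  }
  if (!is.null(bundle$hfd_table)) wt(bundle$hfd_table, "hfd_table.tsv")
  if (!is.null(bundle$spinal_maps))
    for (id in names(bundle$spinal_maps))
      for (key in names(bundle$spinal_maps[[id]])) {
        nm <- sprintf("spinalmap_%s_%s.tsv", gsub("[^A-Za-z0-9]", "_", id),
                      gsub("[^A-Za-z0-9]", "_", key))
        m <- unclass(bundle$spinal_maps[[id]][[key]])
        wt(data.frame(segment = rownames(m), m[, seq(1, ncol(m), by = 70)],
                      check.names = FALSE), nm)
      }
  if (!is.null(bundle$synergy_sets))
    for (id in names(bundle$synergy_sets))
      for (key in names(bundle$synergy_sets[[id]])) {
        fit <- bundle$synergy_sets[[id]][[key]]
        base <- sprintf("synergy_%s_%s", gsub("[^A-Za-z0-9]", "_", id),
                        gsub("[^A-Za-z0-9]", "_", key))
        wt(data.frame(muscle = rownames(fit$W), fit$W), paste0(base,
                                                               "_W.tsv"))
        if (!is.null(fit$r2_curve))
          wt(data.frame(k = as.integer(names(fit$r2_curve)),
                        r2 = fit$r2_curve), paste0(base, "_r2.tsv"))
      }
  if (!is.null(bundle$stats_report)) {
    wt(bundle$stats_report$tests, "stats_tests.tsv")
    writeLines(jsonlite::toJSON(bundle$stats_report$bonferroni,
                                auto_unbox = TRUE),
               file.path(out_dir, "bonferroni.json"))
    files <- c(files, "bonferroni.json")
  }
  manifest <- list(format = "synergykit-bundle", version = 1L,
                   sessions = bundle$session_ids,
                   seed = bundle$config$seed, files = sort(files))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}
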