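#' Full-pipeline configuration
#'
#' Aggregates the per-stage configurations. Every analysis threshold
#' defaults to the stated value of the procedure it implements (1.5/0.8
#' sigma thresholds, 200 ms deletion, 300 ms merge, 1 sigma population
#' confirmation, 0.55 ms trough-to-peak cutoff, 2 sigma / 5 min / 25 min
#' activation rule, 0.3 spikes/s rate filter, 4 consecutive bins in the
#' 4-9 ms window, 90% posterior cutoff) and is overridable here.
#'
#' @param simulation A [sim_params()].
#' @param detection A [detection_config()].
#' @param response A [response_config()].
#' @param connectivity List: `min_rate`, `top_n`, `bin_ms`, `window_ms`,
#'   `test_window_ms`, `min_consecutive`.
#' @param celltype List: `posterior_threshold`, `centroids`.
#' @param tp_cutoff_ms Waveform classification boundary (default 0.55).
#' @param stages Character vector of stages to run, in dependency order.
#' @param seed Pipeline seed (propagated to the simulation).
#' @return List of class `so_pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_params(),
                            detection = detection_config(),
                            response = response_config(),
                            connectivity = list(min_rate = 0.3, top_n = 20,
                                                bin_ms = 1, window_ms = 50,
                                                test_window_ms = c(4, 9),
                                                min_consecutive = 4),
                            celltype = list(posterior_threshold = 0.9,
                                            centroids = DEFAULT_CENTROIDS),
                            tp_cutoff_ms = 0.55,
                            stages = c("simulate", "detect", "units",
                                       "connectivity", "celltype"),
                            seed = 1) {
  if (connectivity$min_rate < 0)
    stop("invalid field connectivity$min_rate: must be >= 0")
  if (celltype$posterior_threshold <= 0 || celltype$posterior_threshold > 1)
    stop("invalid field celltype$posterior_threshold: must lie in (0, 1]")
  if (tp_cutoff_ms <= 0)
    stop("invalid field tp_cutoff_ms: must be > 0")
  validate_detection_config(detection)
  simulation$seed <- seed
  structure(list(simulation = simulation, detection = detection,
                 response = response, connectivity = connectivity,
                 celltype = celltype, tp_cutoff_ms = tp_cutoff_ms,
                 stages = stages, seed = seed),
            class = "so_pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on a simulated
#' recording: `simulate` generates all inputs with ground truth; `detect`
#' selects the detection channel, computes population activity, and runs
#' the in vivo upstate detector; `units` applies quality control, waveform
#' classification, and (when a drug epoch is configured) drug-response
#' classification; `connectivity` screens and classifies inhibitory
#' connections on the coupled-train fixture; `celltype` fits and applies
#' the PCA + Gaussian-mixture typing model. Tables, a summary, and a
#' machine-readable manifest are written to `out_dir`; identical
#' configuration and seed give byte-identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`upstates`,
#'   `units`, `connections`, `celltypes`, `summary`).
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir) {
  stopifnot(inherits(cfg, "so_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  if (!("simulate" %in% cfg$stages))
    stop("stage 'simulate' is required: no external inputs were given")
  rec <- generate_so_recording(cfg$simulation)
  write_lfp_bin(rec$lfp, rec$lfp_fs, file.path(out_dir, "lfp.bin"))
  write_spike_table(rec$trains, file.path(out_dir, "spikes.tsv"),
                    rec$amplitudes)
  write_intervals(rec$truth$upstate_intervals,
                  file.path(out_dir, "truth_upstates.tsv"), "upstate")
  note("simulate: %d upstates, %d units", nrow(rec$truth$upstate_intervals),
       length(rec$trains))

  if ("detect" %in% cfg$stages) {
    ch <- select_detection_channel(rec$lfp, rec$lfp_fs,
                                   c(0, cfg$detection$baseline_duration_s))
    lfp_ts <- so_ts(rec$lfp[, ch], rec$lfp_fs)
    pop <- population_rate(rec$trains, cfg$detection$pop_window_s,
                           0, ts_duration(lfp_ts))
    ev <- detect_upstates_invivo(lfp_ts, pop, cfg$detection)
    qual <- match_intervals(ev, rec$truth$upstate_intervals)
    res$upstates <- ev
    write_intervals(ev, file.path(out_dir, "upstates.tsv"))
    write_table_c14n(as.data.frame(ev), file.path(out_dir,
                                                  "upstate_metrics.tsv"))
    note("detect: channel %d, %d events, F1 %.4f vs ground truth", ch,
         nrow(ev), qual$f1)
    res$detection_f1 <- qual$f1
  }

  if ("units" %in% cfg$stages) {
    wf_fs <- attr(rec$waveforms, "fs")
    dur <- cfg$simulation$duration_s
    rows <- lapply(names(rec$trains), function(id) {
      st <- rec$trains[[id]]
      qc <- qc_unit(st, rec$amplitudes[[id]])
      feat <- waveform_features(rec$waveforms[[id]], wf_fs)
      cls <- if (qc$pass) classify_unit_type(feat$tp_latency_ms,
                                             cfg$tp_cutoff_ms) else NA_character_
      resp <- NA_character_
      onset <- rec$truth$drug_onset_s
      if (qc$pass && !is.null(onset)) {
        rc <- cfg$response
        # clip the response windows to the recording
        rc$baseline_min <- min(rc$baseline_min, onset / 60)
        rc$eval_window_min <- min(rc$eval_window_min, (dur - onset) / 60)
        rc$sustain_min <- min(rc$sustain_min, rc$eval_window_min)
        resp <- classify_drug_response(st, onset, rc)$response
      }
      data.frame(unit_id = id, n_spikes = length(st), qc_pass = qc$pass,
                 qc_reason = qc$reason, tp_latency_ms = feat$tp_latency_ms,
                 repolarization_ms = feat$repolarization_time_ms,
                 class = cls, response = resp, stringsAsFactors = FALSE)
    })
    units <- do.call(rbind, rows)
    res$units <- units
    write_table_c14n(units, file.path(out_dir, "units.tsv"))
    note("units: %d/%d passed QC", sum(units$qc_pass), nrow(units))
  }

  if ("connectivity" %in% cfg$stages) {
    cc <- cfg$connectivity
    conn_sim <- generate_connected_trains(cfg$simulation)
    kept <- rate_filter(conn_sim$trains, conn_sim$duration_s, cc$min_rate)
    note("connectivity: %d/%d units passed the rate filter", length(kept),
         length(conn_sim$trains))
    cand <- screen_connections(kept, top_n = cc$top_n, bin_ms = cc$bin_ms,
                               window_ms = cc$window_ms,
                               test_window_ms = cc$test_window_ms,
                               min_consecutive = cc$min_consecutive)
    attr(cand, "ccgs") <- NULL
    res$connections <- cand
    write_table_c14n(cand, file.path(out_dir, "connections.tsv"))
    note("connectivity: %d candidates, %d inhibitory", nrow(cand),
         sum(cand$is_inhibitory))
  }

  if ("celltype" %in% cfg$stages) {
    ft <- generate_feature_table(cfg$simulation)
    model <- fit_celltype_model(ft$features,
                                centroids = cfg$celltype$centroids,
                                posterior_threshold =
                                  cfg$celltype$posterior_threshold)
    asg <- assign_celltype(model, ft$features)
    asg <- cbind(cell_id = ft$features$cell_id, asg,
                 planted = ft$labels, stringsAsFactors = FALSE)
    res$celltypes <- asg
    write_table_c14n(asg, file.path(out_dir, "celltypes.tsv"))
    note("celltype: %d assigned, %d unassigned",
         sum(asg$label != "unassigned"), sum(asg$label == "unassigned"))
  }

  res$summary <- pipeline_summary(res, rec, cfg)
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(package = "slowosc",
                   version = as.character(utils::packageVersion("slowosc")),
                   seed = cfg$seed, stages = cfg$stages,
                   config = serialize_config(cfg), log = log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

pipeline_summary <- function(res, rec, cfg) {
  out <- list(seed = cfg$seed)
  dur <- cfg$simulation$duration_s
  onset <- rec$truth$drug_onset_s
  if (!is.null(res$upstates)) {
    if (!is.null(onset)) {
      pre <- upstate_metrics(res$upstates, c(0, onset))
      post <- upstate_metrics(res$upstates, c(onset, dur))
      out$incidence_pre_per_min <- pre$incidence_per_min
      out$incidence_post_per_min <- post$incidence_per_min
    } else {
      out$incidence_per_min <-
        upstate_metrics(res$upstates, c(0, dur))$incidence_per_min
    }
    out$detection_f1 <- res$detection_f1
  }
  if (!is.null(res$units)) {
    cl <- res$units[res$units$qc_pass, ]
    out$n_units <- nrow(res$units)
    out$n_qc_pass <- nrow(cl)
    out$n_exc <- sum(cl$class == "Exc", na.rm = TRUE)
    out$n_int <- sum(cl$class == "Int", na.rm = TRUE)
    if (!is.null(onset)) {
      act <- sum(cl$response == "activated", na.rm = TRUE)
      out$n_activated <- act
      out$activated_fraction <- act / nrow(cl)
    }
  }
  if (!is.null(res$connections))
    out$n_inhibitory <- sum(res$connections$is_inhibitory)
  if (!is.null(res$celltypes)) {
    out$celltype_counts <- as.list(table(res$celltypes$label))
  }
  out
}

# config rendered to plain lists for the manifest
serialize_config <- function(cfg) {
  strip <- function(x) {
    if (is.matrix(x)) return(apply(x, 1, as.list, simplify = FALSE))
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  strip(unclass(cfg))
}
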