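#' Pipeline configuration
#'
#' Bundles every knob of the simulate-to-evaluate pipeline.  Defaults match
#' the standard analysis: 0.5–40 Hz FIR band-pass, 200 Hz target rate,
#' +/-100 uV rejection, `T1 = [100, 300)` / `T2 = [300, 600)` ms constraint
#' windows, correlation threshold 0.7, 10-fold linear SVM.
#'
#' @param design An [session_design()].
#' @param generator An [generator_config()].
#' @param low,high Filter band edges (Hz).
#' @param target_rate Decimation target (Hz).
#' @param eog_proxy_channels Optional ICA proxy channels (`NULL` disables
#'   the artifact stage).
#' @param ica_threshold ICA component-correlation threshold.
#' @param reject_uV Amplitude rejection threshold (uV).
#' @param windows List of [constraint_window()]s.
#' @param c_threshold Adjacent-correlation threshold.
#' @param folds,cost SVM cross-validation folds and cost.
#' @param seed Integer seed for simulation and fold assignment.
#' @param out_dir Output directory for artifacts.
#' @return Object of class `aerp_config` (a validated list).
#' @export
pipeline_config <- function(design = session_design(),
                            generator = generator_config(),
                            low = 0.5, high = 40, target_rate = 200,
                            eog_proxy_channels = NULL, ica_threshold = 0.8,
                            reject_uV = 100,
                            windows = default_windows(),
                            c_threshold = 0.7, folds = 10, cost = 1,
                            seed = 1, out_dir = tempfile("aerp_run_")) {
  structure(list(design = design, generator = generator, low = low,
                 high = high, target_rate = target_rate,
                 eog_proxy_channels = eog_proxy_channels,
                 ica_threshold = ica_threshold, reject_uV = reject_uV,
                 windows = windows, c_threshold = c_threshold,
                 folds = folds, cost = cost, seed = seed,
                 out_dir = out_dir),
            class = "aerp_config")
}

#' Read/write a pipeline configuration as YAML
#'
#' The YAML mirrors the [pipeline_config()] fields (designs and generator
#' flattened to plain scalars/lists).  Components are rebuilt per condition
#' at run time, so only their overrides are stored.
#'
#' @param config An `aerp_config` object.
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns an `aerp_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "aerp_config"))
  y <- list(
    design = list(n_blocks = config$design$n_blocks,
                  n_repetitions = config$design$n_repetitions,
                  names = config$design$names,
                  target = config$design$target,
                  stimulus_duration_ms = config$design$stimulus_duration_ms,
                  isi_range_ms = config$design$isi_range_ms,
                  mode = config$design$mode,
                  nontarget_type = config$design$nontarget_type),
    generator = list(sampling_rate = config$generator$sampling_rate,
                     noise_1f_exponent = config$generator$noise_1f_exponent,
                     noise_sd = config$generator$noise_sd,
                     noise_band_hz = config$generator$noise_band_hz),
    preprocessing = list(low = config$low, high = config$high,
                         target_rate = config$target_rate,
                         eog_proxy_channels = config$eog_proxy_channels,
                         ica_threshold = config$ica_threshold,
                         reject_uV = config$reject_uV),
    selection = list(windows = lapply(config$windows, function(w) {
                       list(label = w$label, start_ms = w$start_ms,
                            end_ms = w$end_ms)
                     }),
                     c_threshold = config$c_threshold),
    classifier = list(folds = config$folds, cost = config$cost),
    seed = config$seed,
    out_dir = config$out_dir
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    design = session_design(n_blocks = y$design$n_blocks,
                            n_repetitions = y$design$n_repetitions,
                            names = y$design$names,
                            target = y$design$target,
                            stimulus_duration_ms = y$design$stimulus_duration_ms,
                            isi_range_ms = unlist(y$design$isi_range_ms),
                            mode = y$design$mode,
                            nontarget_type = y$design$nontarget_type),
    generator = generator_config(sampling_rate = y$generator$sampling_rate,
                                 noise_1f_exponent = y$generator$noise_1f_exponent,
                                 noise_sd = y$generator$noise_sd,
                                 noise_band_hz = unlist(y$generator$noise_band_hz)),
    low = y$preprocessing$low, high = y$preprocessing$high,
    target_rate = y$preprocessing$target_rate,
    eog_proxy_channels = y$preprocessing$eog_proxy_channels,
    ica_threshold = y$preprocessing$ica_threshold,
    reject_uV = y$preprocessing$reject_uV,
    windows = lapply(y$selection$windows, function(w) {
      constraint_window(w$label, w$start_ms, w$end_ms)
    }),
    c_threshold = y$selection$c_threshold,
    folds = y$classifier$folds, cost = y$classifier$cost,
    seed = y$seed, out_dir = y$out_dir
  )
}

.log_line <- function(log_path, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...))
  cat(line, "\n", sep = "", file = log_path, append = TRUE)
  message(line)
}

.stage <- function(name, log_path, expr) {
  tryCatch(expr, error = function(e) {
    .log_line(log_path, "stage %s FAILED: %s", name, conditionMessage(e))
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full simulate-to-evaluate pipeline
#'
#' Executes simulate, preprocess, discriminability map, range selection,
#' feature extraction, classification and ERP measurement in order, writing
#' every stage's artifact, a plain-text log with stage counts and a manifest
#' (config hash + seed) to `config$out_dir`.  Rerunning with the same config
#' reproduces every table byte for byte.
#'
#' @param config An [pipeline_config()] object.
#' @return An `aerp_fit` object (invisibly); artifacts on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "aerp_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  cat("", file = log_path)  # truncate
  cfg_path <- file.path(config$out_dir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                   seed = config$seed,
                   package_version = as.character(packageVersion("aerp")))

  session <- .stage("simulate", log_path, {
    s <- generate_session(config$design, config$generator, seed = config$seed)
    write_event_table(s$events, file.path(config$out_dir, "events.tsv"))
    .log_line(log_path, "simulate: %d events (%d targets), %d channels x %d samples",
              nrow(s$events), sum(s$events$is_target), nrow(s$recording),
              ncol(s$recording))
    s
  })
  epochs <- .stage("preprocess", log_path, {
    ep <- preprocess(session, low = config$low, high = config$high,
                     target_rate = config$target_rate,
                     eog_proxy_channels = config$eog_proxy_channels,
                     ica_threshold = config$ica_threshold,
                     reject_uV = config$reject_uV, seed = config$seed)
    write_epoch_container(ep, file.path(config$out_dir, "epochs"))
    .log_line(log_path,
              "preprocess: epochs_in=%d rejected=%d epochs_used=%d",
              length(ep$rejected), sum(ep$rejected), sum(!ep$rejected))
    ep
  })
  fit <- .stage("analyse", log_path, {
    f <- aerp_fit(epochs, windows = config$windows,
                  c_threshold = config$c_threshold, folds = config$folds,
                  cost = config$cost, seed = config$seed)
    write_r2_map(f$map, file.path(config$out_dir, "r2_map.tsv"))
    ranges_df <- do.call(rbind, lapply(f$ranges, function(r) {
      data.frame(window = r$window_label, t_start_ms = r$t_start_ms,
                 t_end_ms = r$t_end_ms,
                 score_max = max(r$score_trace))
    }))
    write.table(ranges_df, file.path(config$out_dir, "selected_ranges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (r in f$ranges) {
      .log_line(log_path, "select: %s -> %g..%g ms", r$window_label,
                r$t_start_ms, r$t_end_ms)
    }
    write_feature_matrix(f$features,
                         file.path(config$out_dir, "features.tsv"))
    fold_df <- do.call(rbind, lapply(names(f$cv$pairings), function(nm) {
      cbind(pairing = nm, f$cv$pairings[[nm]])
    }))
    write.table(fold_df, file.path(config$out_dir, "fold_accuracies.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(f$repetition,
                file.path(config$out_dir, "repetition_accuracy.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(f$roc, file.path(config$out_dir, "roc_points.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    .log_line(log_path, "classify: accuracy=%.2f%% auc=%.3f",
              f$cv$accuracy, f$auc)
    f
  })
  .stage("evaluate", log_path, {
    avg_t <- erp_average(epochs, "target")
    avg_n <- erp_average(epochs, "nontarget")
    p300 <- measure_window(avg_t, "Pz", c(300, 600), epochs$time_ms, 1)
    p200 <- measure_window(avg_n, "Fz", c(100, 300), epochs$time_ms, 1)
    meas <- data.frame(
      stimulus_class = c("target", "nontarget"),
      channel = c("Pz", "Fz"),
      window = c("300-600", "100-300"),
      mean_amplitude_uV = c(p300$mean_amplitude, p200$mean_amplitude),
      peak_amplitude_uV = c(p300$peak_amplitude, p200$peak_amplitude),
      peak_latency_ms = c(p300$peak_latency_ms, p200$peak_latency_ms))
    write.table(meas, file.path(config$out_dir, "erp_measures.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    .log_line(log_path, "evaluate: target Pz peak %.2f uV @ %g ms",
              p300$peak_amplitude, p300$peak_latency_ms)
  })
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(fit)
}
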