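#' Demo pipeline configuration
#'
#' A small, fully synthetic end-to-end configuration: a 32 x 32 px evoked
#' imaging session with 10 stimulation trials, a matching multichannel
#' electrode recording, and a short spreading-depression session, all
#' desk-scale.
#'
#' @param seed integer seed for every stochastic stage.
#' @return A nested configuration list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    spectra = list(extinction = NULL, pathlength = NULL),
    simulation = list(
      height = 32, width = 32, pixel_pitch_um = 50, frame_rate = 5,
      wavelengths_nm = c(494, 560, 575, 595), noise_sigma = 0.005,
      region_radius_px = 7,
      evoked = list(time_to_peak = 3, peak_fraction = 0.05,
                    undershoot_fraction = 0.01, stimulus_duration = 2,
                    hbr_mode = "biphasic", triphasic_bump_fraction = 0),
      stimulus_onsets = seq(5, by = 25, length.out = 10),
      electrode = list(n_channels = 8, sampling_rate = 10000,
                       baseline_rate = 10, evoked_gain = 2,
                       spike_amplitude_sd_ratio = 50),
      csd = list(speed = 3, dip_fraction = 0.6, rebound_fraction = 1.1,
                 undershoot_fraction = 0.95, undershoot_decay_tau = 60,
                 duration = 220, frame_rate = 2)
    ),
    windows = list(baseline = c(0, 4)),
    plsa = list(enabled = FALSE, tol = 1e-4, max_iter = 20),
    roi = list(k_sd = 1.5),
    mua = list(cutoff = 500, bin_width = 0.1, k = 1.5,
               cortex_channels = NULL, heatmap_channels = c(4, 8)),
    figures = FALSE
  )
}

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  if (is.null(config$seed)) abort("config validation: 'seed' is required")
  if (is.null(config$simulation) && is.null(config$input))
    abort("config validation: either a 'simulation' block or 'input' paths are required")
  if (is.null(config$spectra))
    abort("config validation: a 'spectra' block is required (use nulls for the packaged tables)")
  for (f in c("extinction", "pathlength")) {
    p <- config$spectra[[f]]
    if (!is.null(p) && !file.exists(p))
      abort(sprintf("config validation: spectra %s path '%s' does not exist", f, p))
  }
  if (!is.null(config$input)) {
    for (f in c("stack", "electrode")) {
      p <- config$input[[f]]
      if (!is.null(p) && !file.exists(p))
        abort(sprintf("config validation: input %s path '%s' does not exist", f, p))
    }
  }
  config
}

#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates, in dependency order: data simulation (or ingestion of a
#' stack and an electrode recording), spectral conversion (single-pass or
#' path-length-scaled), activation map and automated ROI, ROI time series,
#' evoked trial metrics and HbR shape classification, the
#' spreading-depression session, multi-unit binning, and the neurovascular
#' coupling fit. Writes CSV tables, the ROI mask, an optional set of
#' figures, `summary.json` (carrying the config hash; bit-identical across
#' reruns of the same config and seed) and `run.log`.
#'
#' @param config nested list or YAML file path; see [demo_config()].
#' @param out_dir output directory (created).
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S "),
                            sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cfg_hash <- rlang::hash(config)
  cat(sprintf("pipeline run, config hash %s\n", cfg_hash), file = log_path)
  logf("resolved configuration: %s",
       jsonlite::toJSON(config, auto_unbox = TRUE, null = "null"))
  summary <- list(config_hash = cfg_hash, seed = config$seed)

  stage <- function(name, code) {
    logf("stage %s: start", name)
    out <- tryCatch(force(code), error = function(e)
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e))))
    logf("stage %s: done", name)
    out
  }

  sim <- config$simulation
  spectra <- stage("spectra", {
    if (is.null(config$spectra$extinction))
      default_spectra()
    else read_spectra(config$spectra$extinction, config$spectra$pathlength)
  })

  # ---- imaging: simulate or ingest -------------------------------------
  if (!is.null(sim)) {
    onsets <- sim$stimulus_onsets
    ev <- do.call(evoked_kernel_params, sim$evoked)
    cfg_img <- sim_config(
      height = sim$height, width = sim$width,
      pixel_pitch_um = sim$pixel_pitch_um, frame_rate = sim$frame_rate,
      duration = max(onsets) + ev$stimulus_duration + 20,
      wavelengths_nm = sim$wavelengths_nm, noise_sigma = sim$noise_sigma,
      seed = config$seed)
    truth <- stage("simulate_evoked", simulate_evoked_field(
      cfg_img, ev,
      active_region = disc_mask(cfg_img, radius_px = sim$region_radius_px),
      stimulus_onsets = onsets))
    stack <- stage("render", render_reflectance(truth, spectra, cfg_img))
    stim_dur <- ev$stimulus_duration
  } else {
    stack <- stage("read_stack", read_stack_tiff(config$input$stack))
    onsets <- stack$stim_onsets
    stim_dur <- config$windows$stim_duration %||% 2
  }

  baseline_win <- config$windows$baseline %||% c(max(0, onsets[1] - 4), onsets[1])
  atten <- stage("attenuation",
                 compute_attenuation(stack, unlist(baseline_win)))
  haem <- stage("unmix", {
    if (isTRUE(config$plsa$enabled))
      plsa_refine(atten, spectra, tol = config$plsa$tol %||% 1e-4,
                  max_iter = config$plsa$max_iter %||% 20)
    else unmix(atten, spectra)
  })

  # ---- ROI --------------------------------------------------------------
  stim_win <- config$windows$stim %||% c(onsets[1], onsets[1] + stim_dur + 2)
  amap <- stage("activation_map",
                activation_map(haem, unlist(stim_win), unlist(baseline_win)))
  roi <- stage("auto_roi", auto_roi(amap, k_sd = config$roi$k_sd %||% 1.5))
  series <- stage("extract_timeseries", extract_timeseries(haem, roi))
  write_mask(roi, file.path(out_dir, "roi_mask.tif"))
  write_roi_series(series, file.path(out_dir, "roi_series.csv"))
  summary$roi <- list(n_pixels = sum(roi), k_sd = attr(roi, "k_sd"))

  # ---- evoked metrics ---------------------------------------------------
  trials <- trial_set(onsets, stim_duration = stim_dur,
                      post_window = min(stim_dur + 13,
                                        min(diff(c(onsets, Inf))) - 4))
  avg <- stage("trial_average", trial_average(series, trials))
  esum <- stage("summarise_evoked", summarise_evoked(avg, stim_dur))
  hbr_class <- stage("classify_hbr", classify_hbr(avg))
  utils::write.csv(avg, file.path(out_dir, "trial_average.csv"),
                   row.names = FALSE)
  utils::write.csv(esum, file.path(out_dir, "evoked_summary.csv"),
                   row.names = FALSE)
  summary$evoked <- c(split(esum[-1], esum$component),
                      list(hbr_waveform = hbr_class))

  # ---- CSD session ------------------------------------------------------
  if (!is.null(sim$csd)) {
    csd_cfg <- sim_config(height = sim$height, width = sim$width,
                          pixel_pitch_um = sim$pixel_pitch_um,
                          frame_rate = sim$csd$frame_rate %||% 2,
                          duration = sim$csd$duration %||% 220,
                          wavelengths_nm = sim$wavelengths_nm,
                          noise_sigma = 0, seed = config$seed + 1L)
    csd_p <- do.call(csd_params,
                     sim$csd[setdiff(names(sim$csd),
                                     c("duration", "frame_rate"))])
    csd_truth <- stage("simulate_csd",
                       simulate_csd_field(csd_cfg, csd_p, t_insert = 0))
    csd_frac <- haem_fractional(csd_truth)
    csd_series <- haem_grid_mean(csd_frac)
    event <- stage("detect_csd", detect_csd(
      csd_series, t_insert = 0,
      late_window = unlist(config$csd_late_window %||%
                             c(0.6, 0.95) * csd_cfg$duration)))
    spd <- stage("wavefront_speed", wavefront_speed(csd_frac, t_insert = 0,
                                                    origin = attr(csd_truth, "csd_truth")$origin))
    utils::write.csv(csd_series, file.path(out_dir, "csd_series.csv"),
                     row.names = FALSE)
    summary$csd <- c(as.list(event), as.list(spd))
  }

  # ---- MUA --------------------------------------------------------------
  if (!is.null(sim$electrode) || !is.null(config$input$electrode)) {
    if (!is.null(sim$electrode)) {
      np <- do.call(neural_sim_params, sim$electrode)
      er <- stage("simulate_electrode", simulate_electrode(
        max(onsets) + stim_dur + 5, np, stimulus_onsets = onsets,
        stimulus_duration = stim_dur, seed = config$seed + 2L))
      rec <- er$recording
    } else {
      rec <- stage("read_electrode",
                   read_electrode_bin(config$input$electrode))
    }
    filt <- stage("highpass", highpass(rec, config$mua$cutoff %||% 500))
    mua <- stage("bin_threshold", bin_threshold(
      filt, unlist(baseline_win), bin_width = config$mua$bin_width %||% 0.1,
      k = config$mua$k %||% 1.5))
    cortex <- config$mua$cortex_channels
    if (!is.null(cortex)) mua <- depth_select(mua, cortex[1]:cortex[2])
    write_mua_csv(mua, file.path(out_dir, "mua.csv"))

    # ---- coupling -------------------------------------------------------
    pairs <- stage("build_pairs", build_pairs(mua, series, trials))
    fit <- stage("fit_line", fit_line(pairs))
    utils::write.csv(pairs, file.path(out_dir, "coupling_pairs.csv"),
                     row.names = FALSE)
    summary$coupling <- as.list(glance(fit))
  }

  # ---- figures ----------------------------------------------------------
  if (isTRUE(config$figures)) {
    stage("figures", {
      ggplot2::ggsave(file.path(out_dir, "activation_map.png"),
                      autoplot(amap), width = 5, height = 4, dpi = 120)
      ggplot2::ggsave(file.path(out_dir, "trial_average.png"),
                      plot_trial_average(avg), width = 6, height = 4,
                      dpi = 120)
      if (exists("mua", inherits = FALSE))
        ggplot2::ggsave(file.path(out_dir, "mua_heatmap.png"),
                        plot_mua_heatmap(mua), width = 6, height = 4,
                        dpi = 120)
      if (exists("fit", inherits = FALSE))
        ggplot2::ggsave(file.path(out_dir, "coupling.png"),
                        autoplot(fit), width = 5, height = 4, dpi = 120)
      invisible(NULL)
    })
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("pipeline complete")
  invisible(summary)
}
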