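# Run configuration and the one-command pipeline.

# registry of allowed flat config keys, with defaults and types
.config_registry <- function() {
  list(
    stages = list(default = "mt,kymo,binding", type = "character"),
    seed = list(default = 1, type = "numeric"),
    out_dir = list(default = ".", type = "character"),
    figures = list(default = FALSE, type = "logical"),
    # magnetic tweezers stage
    mt.n_beads = list(default = 10, type = "numeric"),
    mt.n_cycles = list(default = 5, type = "numeric"),
    mt.bridge_formation_prob = list(default = 0.7, type = "numeric"),
    mt.mean_lifetime_s = list(default = 26.3, type = "numeric"),
    mt.loop_min_um = list(default = 0.1, type = "numeric"),
    mt.loop_max_um = list(default = 0.5, type = "numeric"),
    mt.max_bridges = list(default = 3, type = "numeric"),
    mt.noise = list(default = TRUE, type = "logical"),
    mt.threshold_um = list(default = 0.05, type = "numeric"),
    mt.n_avg = list(default = 12, type = "numeric"),
    mt.bin_width_um = list(default = 0.02, type = "numeric"),
    mt.smooth = list(default = TRUE, type = "logical"),
    # kymograph / tracking stage
    kymo.n_kymographs = list(default = 20, type = "numeric"),
    kymo.diffusion_um2_s = list(default = 3.9, type = "numeric"),
    kymo.duration_s = list(default = 2.5, type = "numeric"),
    kymo.photons_per_line = list(default = 200, type = "numeric"),
    kymo.fit_lags = list(default = 5, type = "numeric"),
    # binding stage
    binding.kd_nM = list(default = 66, type = "numeric"),
    binding.model = list(default = "hyperbolic", type = "character"),
    binding.readout = list(default = "anisotropy", type = "character"),
    binding.probe_nM = list(default = 5, type = "numeric"),
    binding.noise_sd = list(default = 0, type = "numeric"),
    binding.n_boot = list(default = 200, type = "numeric")
  )
}

#' Read a flat key = value run configuration
#'
#' One \code{key = value} pair per line; \code{#} starts a comment. Unknown
#' keys are rejected. Missing keys take documented defaults
#' (\code{run_config()} with no file returns them all).
#'
#' @param path configuration file; NULL for all defaults.
#' @param overrides named list applied after the file.
#' @return named list of class \code{run_config}.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  reg <- .config_registry()
  cfg <- lapply(reg, `[[`, "default")
  set_kv <- function(key, value) {
    if (!key %in% names(reg))
      stop("unknown configuration key: '", key, "'", call. = FALSE)
    cfg[[key]] <<- switch(reg[[key]]$type,
      numeric = as.numeric(value),
      logical = as.logical(toupper(as.character(value))),
      character = as.character(value))
    if (is.na(cfg[[key]])) stop("bad value for key '", key, "'", call. = FALSE)
  }
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("bad config line: '", ln, "'")
      set_kv(trimws(kv[1]), trimws(kv[2]))
    }
  }
  for (k in names(overrides)) set_kv(k, overrides[[k]])
  structure(cfg, class = "run_config")
}

#' Run the full synthetic-plus-analysis pipeline
#'
#' Executes, per the configured stages, simulate-then-analyse for the
#' magnetic-tweezers bridging assay (\code{mt}), the kymograph tracking
#' assay (\code{kymo}) and the binding isotherm (\code{binding}), writing
#' CSV/JSON outputs and (optionally) summary figures into \code{out_dir}.
#' A \code{run_log.json} records every parameter and seed. All randomness
#' derives from the single configured seed, so identical configurations give
#' byte-identical outputs.
#'
#' @param config a \code{\link{run_config}} (or path to a config file).
#' @return invisible list with per-stage summaries and output paths.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- run_config(config)
  stopifnot(inherits(config, "run_config"))
  stages <- trimws(strsplit(config$stages, ",")[[1]])
  bad <- setdiff(stages, c("mt", "kymo", "binding"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list()

  if ("mt" %in% stages) {
    report$mt <- tryCatch(.stage_mt(config, out_dir),
                          error = function(e)
                            stop("stage 'mt' failed: ", conditionMessage(e),
                                 call. = FALSE))
  }
  if ("kymo" %in% stages) {
    report$kymo <- tryCatch(.stage_kymo(config, out_dir),
                            error = function(e)
                              stop("stage 'kymo' failed: ",
                                   conditionMessage(e), call. = FALSE))
  }
  if ("binding" %in% stages) {
    report$binding <- tryCatch(.stage_binding(config, out_dir),
                               error = function(e)
                                 stop("stage 'binding' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }

  log <- list(package_version = as.character(utils::packageVersion("smbridge")),
              r_version = R.version.string,
              timestamp = NA, # deliberately constant for byte-identical reruns
              config = unclass(config))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

.stage_mt <- function(config, out_dir) {
  protocol <- force_protocol(n_cycles = config$mt.n_cycles)
  bridging <- bridging_params(
    bridge_formation_prob = config$mt.bridge_formation_prob,
    mean_lifetime_s = config$mt.mean_lifetime_s,
    loop_size_range_um = c(config$mt.loop_min_um, config$mt.loop_max_um),
    max_bridges = config$mt.max_bridges)
  tether <- tether_model()
  n <- as.integer(config$mt.n_beads)
  tcs <- vector("list", n)
  recs <- vector("list", n)
  all_events <- vector("list", n)
  for (b in seq_len(n)) {
    sim <- simulate_bead_timecourse(protocol, tether, bridging,
                                    noise = config$mt.noise,
                                    seed = config$seed * 10000 + b,
                                    bead_id = sprintf("bead%03d", b))
    tc <- compute_relative_extension(sim, protocol)
    tcs[[b]] <- tc
    cr <- extract_cycle_features(tc, protocol, n_avg = config$mt.n_avg,
                                 threshold_um = config$mt.threshold_um,
                                 smooth = config$mt.smooth && config$mt.noise)
    recs[[b]] <- classify_events(cr, threshold_um = config$mt.threshold_um)
    ev <- sim$events
    if (nrow(ev)) ev$bead_id <- sprintf("bead%03d", b)
    all_events[[b]] <- ev
  }
  records <- do.call(rbind, recs)
  class(records) <- c("cycle_records", "data.frame")
  freqs <- class_frequencies(records)
  bridged <- records[records$event_class %in% c("II", "III", "IV", "V"), ]
  box <- boxplot_stats(bridged$dz0_um)
  hist_dz <- pooled_dz_histogram(tcs, protocol,
                                 bin_width_um = config$mt.bin_width_um)
  kin <- records[records$event_class %in% c("II", "III", "IV", "V"), ]
  curve <- if (nrow(kin)) rupture_survival(kin) else NULL

  write_cycle_records(records, file.path(out_dir, "cycle_records.csv"))
  write.csv(do.call(rbind, all_events),
            file.path(out_dir, "ground_truth_events.csv"), row.names = FALSE)
  write.csv(data.frame(mid_um = hist_dz$mids, density = hist_dz$density,
                       count = hist_dz$counts),
            file.path(out_dir, "dz_histogram.csv"), row.names = FALSE)
  if (!is.null(curve))
    write.csv(data.frame(time_s = curve$time_s, cum_prob = curve$cum_prob),
              file.path(out_dir, "rupture_curve.csv"), row.names = FALSE)
  summary <- list(
    n_beads = n, n_cycles = nrow(records),
    class_frequencies = as.list(freqs$frequencies),
    n_excluded = freqs$n_excluded,
    mean_class2_lifetime_s =
      mean(records$rupture_time_s[records$event_class == "II"]),
    dz0_boxplot = box)
  jsonlite::write_json(summary, file.path(out_dir, "mt_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (config$figures) {
    pdf(file.path(out_dir, "mt_figures.pdf"), width = 7, height = 5)
    plot(hist_dz, main = "Pooled relative extensions")
    barplot(freqs$frequencies, ylab = "Frequency", xlab = "Event class")
    if (!is.null(curve)) plot(curve)
    dev.off()
  }
  summary
}

.stage_kymo <- function(config, out_dir) {
  cfg <- kymo_config(diffusion_um2_s = config$kymo.diffusion_um2_s,
                     duration_s = config$kymo.duration_s,
                     photons_per_line = config$kymo.photons_per_line)
  n <- as.integer(config$kymo.n_kymographs)
  trajs <- list()
  for (k in seq_len(n)) {
    ky <- simulate_kymograph(cfg, seed = config$seed * 20000 + k)
    det <- localize_lines(ky)
    tr <- link_trajectories(det, cfg$line_time_s)
    if (!attr(tr, "discarded")) trajs <- c(trajs, tr)
  }
  if (!length(trajs)) stop("no trajectories recovered")
  fit <- estimate_diffusion(trajs, fit_lags = config$kymo.fit_lags,
                            line_time_s = cfg$line_time_s)
  write_trajectories(trajs, file.path(out_dir, "trajectories.csv"))
  write_msd(fit$ensemble_msd, file.path(out_dir, "msd.csv"))
  summary <- list(n_trajectories = fit$n_traj,
                  mean_d_um2_s = fit$mean_d, sem_d_um2_s = fit$sem_d,
                  ensemble_d_um2_s = fit$d_um2_s,
                  intercept_um2 = fit$intercept_um2,
                  fit_lags = fit$fit_lags)
  jsonlite::write_json(summary, file.path(out_dir, "diffusion_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (config$figures) {
    pdf(file.path(out_dir, "kymo_figures.pdf"), width = 7, height = 5)
    plot(fit)
    dev.off()
  }
  summary
}

.stage_binding <- function(config, out_dir) {
  iso <- simulate_isotherm(
    kd_nM = config$binding.kd_nM,
    model = config$binding.model,
    readout = config$binding.readout,
    probe_nM = config$binding.probe_nM,
    noise_sd = config$binding.noise_sd,
    seed = if (config$binding.noise_sd > 0) config$seed * 30000 + 1 else NULL)
  fit <- fit_isotherm(iso, model = config$binding.model,
                      n_boot = config$binding.n_boot,
                      seed = config$seed * 30000 + 2)
  write_isotherm(iso, file.path(out_dir, "isotherm.csv"))
  summary <- list(kd_nM = fit$kd_nM, ci_low_nM = fit$ci_low,
                  ci_high_nM = fit$ci_high, rmse = fit$rmse,
                  model = fit$model, readout = fit$readout,
                  weak_binding = fit$weak_binding)
  jsonlite::write_json(summary, file.path(out_dir, "binding_fit.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (config$figures) {
    pdf(file.path(out_dir, "binding_figures.pdf"), width = 6, height = 5)
    plot(fit)
    dev.off()
  }
  summary
}
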