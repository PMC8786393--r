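#' Pipeline configuration
#'
#' All tunables of the end-to-end chain in one validated list, with the
#' standard defaults: three-step thresholds 12/10/7 cm; sensitivity
#' vectorization threshold 0.01 of max; lambda1 = 0.01, lambda2 = 0.1;
#' smoothing FWHM 6 mm; resampling to 25 Hz; bandpass 0.016-0.5 Hz; pruning
#' window 80-130 dB; verification criterion 0.25; the default gamma HRF.
#' Unknown keys are rejected.
#'
#' @param ... Overrides of the defaults (see `pipeline_defaults()`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) || is.null(names(over)) || any(!nzchar(names(over))))
      stop_fnirsdot(paste0("unknown config key(s): ",
                           paste(bad, collapse = ", ")), "config_invalid")
    cfg[names(over)] <- over
  }
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
pipeline_defaults <- function() {
  list(
    threestep_d = c(12, 10, 7),      # cm
    template_threshold_cm = 10,
    vectorize_threshold = 0.01,
    lambda1 = 0.01,
    lambda2 = 0.1,
    fwhm_mm = 6,
    target_fs = 25,
    bandpass_hz = c(0.016, 0.5),
    prune_db = c(80, 130),
    criterion = 0.25,
    sphere_diameter_mm = 20,
    hrf = list(delay_response = 4, delay_undershoot = 15,
               dispersion_response = 1, dispersion_undershoot = 1,
               ratio = 6, onset = 0, kernel_length_s = 16),
    event_extent_s = 10,
    seed = 1
  )
}

validate_config <- function(cfg) {
  stopifnot(length(cfg$threestep_d) == 3L, all(diff(cfg$threestep_d) <= 0),
            cfg$threestep_d[3] > 0,
            cfg$vectorize_threshold > 0, cfg$vectorize_threshold < 1,
            cfg$lambda1 >= 0, cfg$lambda2 >= 0, cfg$fwhm_mm > 0,
            cfg$target_fs > 0, length(cfg$bandpass_hz) == 2L,
            cfg$bandpass_hz[1] < cfg$bandpass_hz[2],
            length(cfg$prune_db) == 2L, cfg$prune_db[1] < cfg$prune_db[2],
            cfg$criterion >= -1, cfg$criterion <= 1,
            cfg$event_extent_s >= 0, is.list(cfg$hrf))
  invisible(cfg)
}

#' Read a pipeline config from YAML or JSON
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(cfg), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

pipeline_stages <- c("simulate", "caps", "lightmodel", "preprocess",
                     "reconstruct", "glm", "verify")

stage_file <- function(out_dir, name) file.path(out_dir, paste0(name, ".rds"))

require_artifact <- function(out_dir, name, producer) {
  f <- stage_file(out_dir, name)
  if (!file.exists(f))
    stop_fnirsdot(sprintf("missing artifact '%s'; run stage '%s' first",
                          basename(f), producer), "missing_artifact")
  readRDS(f)
}

save_artifact <- function(obj, out_dir, name, hash) {
  saveRDS(obj, stage_file(out_dir, name), compress = FALSE)
  writeLines(hash, file.path(out_dir, paste0(name, ".confighash")))
}

#' Run the end-to-end pipeline on the synthetic fixture
#'
#' Executes the requested stages in order, handing artifacts off through files
#' in `out_dir` (each stamped with the config hash) so a run can be resumed
#' stage by stage. Stages: `simulate` (phantom, probe, sensitivities,
#' digitizations, channel data), `caps` (template build and three-step
#' correction, digpts export), `lightmodel` (vectorization), `preprocess`,
#' `reconstruct`, `glm`, `verify`. An empty `stages` vector is a no-op.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Working directory for artifacts.
#' @param stages Subset of stages to run (contiguity is the caller's concern;
#'   a stage errors informatively when its inputs are missing).
#' @return Invisibly, a list with the artifacts of the stages just run plus a
#'   `log` data frame.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = pipeline_stages) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(stages) == 0L) return(invisible(list(log = NULL)))
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hash <- config_hash(config)
  ran <- list()
  log <- list()
  say <- function(fmt, ...) message(sprintf(paste0("[fnirsdot] ", fmt), ...))

  for (st in pipeline_stages[pipeline_stages %in% stages]) {
    t0 <- Sys.time()
    if (st == "simulate") {
      spec <- phantom_spec()
      phantom <- generate_phantom_head(spec)
      probe <- probe_layout(spec)
      vols <- generate_sensitivity(phantom, probe)
      model0 <- vectorize_sensitivity(vols, config$vectorize_threshold,
                                      spec$voxel_size_mm, probe$measurements)
      cortex <- phantom$labels == 3L
      act_center <- cortical_peak_voxel(model0, cortex, channel_row = 1L)
      paradigm <- default_paradigm()
      sim <- generate_channel_data(
        model0, paradigm,
        activation = list(center = act_center, sigma_mm = 4,
                          hbo = c(A = 1, B = 0.5), hbr = c(A = -0.3, B = -0.15)),
        fs = 50, duration_s = 120,
        event_extent_s = config$event_extent_s,
        seed = config$seed)
      caps <- generate_caps(synthetic_template_cap(), n = 5, noise_sd_cm = 0.2,
                            seed = config$seed)
      bad_caps <- generate_caps(synthetic_template_cap(), n = 2,
                                noise_sd_cm = 0.2, n_outlier_points = 1,
                                seed = config$seed + 1L, id_prefix = "bad")
      obj <- list(spec = spec, phantom = phantom, probe = probe,
                  volumes = vols, sim = sim, caps = caps, bad_caps = bad_caps)
      save_artifact(obj, out_dir, "simulate", hash)
      ran$simulate <- obj
    } else if (st == "caps") {
      simd <- require_artifact(out_dir, "simulate", "simulate")
      template <- build_template(simd$caps, config$template_threshold_cm)
      corrected <- lapply(c(simd$caps, simd$bad_caps), function(cp)
        threestep_alignment(cp, template, config$threestep_d[1],
                            config$threestep_d[2], config$threestep_d[3]))
      save_digpts(lapply(corrected, `[[`, "cap"), file.path(out_dir, "digpts"))
      obj <- list(template = template, corrected = corrected)
      save_artifact(obj, out_dir, "caps", hash)
      ran$caps <- obj
    } else if (st == "lightmodel") {
      simd <- require_artifact(out_dir, "simulate", "simulate")
      model <- vectorize_sensitivity(simd$volumes, config$vectorize_threshold,
                                     simd$spec$voxel_size_mm,
                                     simd$probe$measurements)
      save_artifact(model, out_dir, "lightmodel", hash)
      ran$lightmodel <- model
    } else if (st == "preprocess") {
      simd <- require_artifact(out_dir, "simulate", "simulate")
      rec <- preprocess_recording(simd$sim$recording,
                                  low_db = config$prune_db[1],
                                  high_db = config$prune_db[2],
                                  f_hp = config$bandpass_hz[1],
                                  f_lp = config$bandpass_hz[2],
                                  target_fs = config$target_fs)
      save_artifact(rec, out_dir, "preprocess", hash)
      ran$preprocess <- rec
    } else if (st == "reconstruct") {
      model <- require_artifact(out_dir, "lightmodel", "lightmodel")
      rec <- require_artifact(out_dir, "preprocess", "preprocess")
      recon <- reconstruct_recording(model, rec, config$lambda1, config$lambda2,
                                     fwhm_mm = config$fwhm_mm)
      save_artifact(recon, out_dir, "reconstruct", hash)
      ran$reconstruct <- recon
    } else if (st == "glm") {
      recon <- require_artifact(out_dir, "reconstruct", "reconstruct")
      rec <- require_artifact(out_dir, "preprocess", "preprocess")
      # regressors are built and filtered at the acquisition rate and then
      # pushed through the same resampler as the data
      fs0 <- if (is.null(rec$acquisition_fs)) rec$fs else rec$acquisition_fs
      n0 <- round(ncol(recon$hbo) * fs0 / rec$fs)
      hrf <- do.call(gamma_hrf, c(list(fs = fs0), config$hrf))
      X <- build_design(rec$paradigm, hrf, fs0, n0,
                        event_extent_s = config$event_extent_s)
      X <- filter_design(X, fs0, config$bandpass_hz[1], config$bandpass_hz[2])
      X <- resample_design(X, ncol(recon$hbo))
      # the recorded global signals are NOT added as nuisance regressors here:
      # with a shared paradigm, the per-wavelength global means span the task
      # subspace and would absorb the task betas (see the methods vignette)
      obj <- list(hbo = fit_glm(recon$hbo, X), hbr = fit_glm(recon$hbr, X))
      save_artifact(obj, out_dir, "glm", hash)
      ran$glm <- obj
    } else if (st == "verify") {
      simd <- require_artifact(out_dir, "simulate", "simulate")
      model <- require_artifact(out_dir, "lightmodel", "lightmodel")
      rec <- require_artifact(out_dir, "preprocess", "preprocess")
      recon <- require_artifact(out_dir, "reconstruct", "reconstruct")
      vrep <- verify_reconstruction(recon, rec, model,
                                    simd$phantom$labels == 3L,
                                    criterion = config$criterion,
                                    diameter_mm = config$sphere_diameter_mm)
      jsonlite::write_json(vrep$results, file.path(out_dir, "verification.json"),
                           auto_unbox = TRUE, digits = NA)
      utils::write.table(vrep$results, file.path(out_dir, "verification.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      save_artifact(vrep, out_dir, "verify", hash)
      ran$verify <- vrep
    }
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    say("stage %-11s done in %.1f s", st, dt)
    log[[length(log) + 1L]] <- data.frame(stage = st, seconds = dt, hash = hash)
  }
  ran$log <- do.call(rbind, log)
  invisible(ran)
}

#' Voxel where a channel's cortex-restricted sensitivity peaks
#'
#' The canonical place to inject (or look for) activation for that channel.
#'
#' @param model A `sensitivity_model`.
#' @param cortex_mask 3D logical mask.
#' @param channel_row Row of the model whose sensitivity to use.
#' @return Linear voxel index into the full volume.
#' @export
cortical_peak_voxel <- function(model, cortex_mask, channel_row = 1L) {
  sens <- embed_to_volume(model$A[channel_row, ], model)
  roi <- sphere_at_channel_max(sens, cortex_mask, diameter_mm = 1,
                               voxel_size_mm = model$voxel_size_mm,
                               good_vox = model$good_vox)
  roi$center
}

#' Fixed event schedule of the synthetic fixture
#'
#' Two conditions, five events each, alternating every 11 s over a 120 s run.
#' The 11 s spacing keeps the task harmonics (multiples of 1/22 Hz) off the
#' 0.1 Hz systemic-physiology line of the synthetic noise model.
#' @export
default_paradigm <- function() {
  data.frame(onset_s = seq(5, by = 11, length.out = 10),
             condition = rep(c("A", "B"), 5))
}

#' Synthetic cap layout on a sphere
#'
#' A deterministic cap layout (5 landmarks, 8 sources, 8 detectors) on a
#' sphere of the given head circumference; the seed layout for the synthetic
#' digitization generator.
#' @param cap_size_cm Head circumference (default 48).
#' @export
synthetic_template_cap <- function(cap_size_cm = 48) {
  r <- cap_size_cm / (2 * pi)
  sph <- function(theta_deg, phi_deg)
    r * c(sin(theta_deg * pi / 180) * cos(phi_deg * pi / 180),
          sin(theta_deg * pi / 180) * sin(phi_deg * pi / 180),
          cos(theta_deg * pi / 180))
  lm <- rbind(nz = sph(90, 0), iz = sph(90, 180), ar = sph(90, -90),
              al = sph(90, 90), cz = sph(0, 0))
  src <- t(vapply(seq_len(8), function(k) sph(35, (k - 1) * 45), numeric(3)))
  det <- t(vapply(seq_len(8), function(k) sph(60, (k - 1) * 45 + 22.5), numeric(3)))
  new_cap(rbind(lm, src, det),
          roles = rep(c("landmark", "source", "detector"), c(5, 8, 8)),
          labels = c("nz", "iz", "ar", "al", "cz", paste0("s", 1:8),
                     paste0("d", 1:8)),
          cap_id = sprintf("template_%g", cap_size_cm), cap_size_cm = cap_size_cm)
}
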