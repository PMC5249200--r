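#' Configuration for the simulated end-to-end wear pipeline
#'
#' Collects every tunable of the phantom-to-agreement chain in one place.
#' Each simulated specimen is an independently worn cup: its worn state is
#' voxelized under an arbitrary rigid perturbation (emulating independent
#' scan poses), the measurement chain recovers the wear mass, and a
#' gravimetric weighing campaign with matching true mass loss provides the
#' reference value.
#'
#' @param penetrations_mm Per-specimen head penetration depths, mm.
#' @param materials Per-specimen material labels (recycled).
#' @param inner_diameter_mm,outer_diameter_mm Cup geometry (defaults
#'   32 / 50).
#' @param density_mg_mm3 Density for mass conversion (default 0.934; see
#'   [density_preset()]).
#' @param voxel_size_mm Phantom voxel size (default 0.3 at desk scale; the
#'   hardware value would be 0.031).
#' @param blur_sigma_mm Partial-volume blur (default one voxel).
#' @param noise_sd Gray-noise standard deviation (default 0).
#' @param supersample Occupancy supersampling factor.
#' @param adaptive,window Surface determination settings.
#' @param perturb_angle_deg,perturb_axis,perturb_translation_mm Rigid
#'   perturbation applied to each worn solid before voxelization (scaled by
#'   specimen index to make poses distinct).
#' @param cycles_mc Weighing grid, Mc.
#' @param soak_amplitude_mg,soak_tau_mc,balance_sd_mg,n_weighings
#'   Gravimetric simulation settings (see [simulate_weight_series()]).
#' @param steady_state_from_mc Wear-rate regression window start.
#' @param seed Global seed; every stochastic stage derives its own stream
#'   from it.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(penetrations_mm = c(0.2, 0.4, 0.6),
                            materials = c("XLPE", "STD_PE", "XLPE_VE"),
                            inner_diameter_mm = 32, outer_diameter_mm = 50,
                            density_mg_mm3 = density_preset("conversion"),
                            voxel_size_mm = 0.3,
                            blur_sigma_mm = voxel_size_mm,
                            noise_sd = 0, supersample = 3,
                            adaptive = TRUE, window = 5,
                            perturb_angle_deg = 2,
                            perturb_axis = c(1, 0, 0),
                            perturb_translation_mm = c(0.5, 0.3, -0.2),
                            cycles_mc = seq(0, 2, by = 0.4),
                            soak_amplitude_mg = 1, soak_tau_mc = 0.5,
                            balance_sd_mg = 0.01, n_weighings = 3,
                            steady_state_from_mc = 0.4, seed = 1) {
  cfg <- as.list(environment())
  n <- length(cfg$penetrations_mm)
  cfg$materials <- rep_len(cfg$materials, n)
  if (n < 1) stop_validation("need at least one specimen")
  if (any(cfg$penetrations_mm < 0))
    stop_validation("penetrations must be >= 0")
  structure(cfg, class = "pipeline_config")
}

#' Run the simulated CT-versus-gravimetric validation pipeline
#'
#' For each configured specimen: generate the unworn and worn cup solids,
#' voxelize both (the worn state under a distinct rigid pose), determine
#' both surfaces, register the worn onto the unworn state excluding the
#' articular calotte, difference the enclosed volumes and convert to mass;
#' in parallel, simulate the gravimetric weighing campaign whose true mass
#' loss matches the phantom's ground truth.  The per-specimen
#' (CT, gravimetric) pairs then feed the method-agreement analysis.
#' Deterministic for a given `seed`.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when given, the resolved
#'   configuration (`config.yaml`), the per-specimen results
#'   (`specimens.csv`) and the agreement report (`agreement.json`) are
#'   written next to each other.
#' @return An object of class `wear_pipeline_result`: `specimens` (data
#'   frame with true/CT/gravimetric masses per specimen), `agreement` (a
#'   [method_agreement()] fit), and `config`.
#' @export
run_wear_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  n <- length(config$penetrations_mm)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", what,
                   conditionMessage(e)), call. = FALSE))
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- cup_spec(config$inner_diameter_mm, config$outer_diameter_mm,
                     config$density_mg_mm3, config$materials[i])
    pattern <- wear_pattern(config$penetrations_mm[i])
    true_dv <- stage("truth", true_wear_volume(spec, pattern))
    true_dm <- mass_from_volume(true_dv, config$density_mg_mm3)

    unworn <- make_cup_geometry(spec)
    worn <- apply_wear(unworn, pattern)
    # each scan has its own mounting pose: unworn and worn states are
    # voxelized under distinct rigid perturbations
    tf_b <- rigid_transform(
      rotation_matrix(config$perturb_axis + c(0, 1, 0),
                      config$perturb_angle_deg * (i - 0.5)),
      config$perturb_translation_mm * (0.5 * i))
    tf_i <- rigid_transform(
      rotation_matrix(config$perturb_axis, config$perturb_angle_deg * i),
      config$perturb_translation_mm * i)
    unworn_posed <- transform_solid(unworn, tf_b)
    worn <- transform_solid(worn, tf_i)

    vol_b <- stage("phantom", voxelize(
      unworn_posed, config$voxel_size_mm, config$blur_sigma_mm,
      noise_sd = config$noise_sd, seed = config$seed + 1000L + i,
      supersample = config$supersample))
    vol_a <- stage("phantom", voxelize(
      worn, config$voxel_size_mm, config$blur_sigma_mm,
      noise_sd = config$noise_sd, seed = config$seed + 2000L + i,
      supersample = config$supersample))

    excl <- calotte_exclusion(
      radius = (config$inner_diameter_mm + config$outer_diameter_mm) / 4,
      center = tf_i$translation)
    res <- stage("wear", quantify_wear(
      vol_b, vol_a, density = config$density_mg_mm3, exclusion = excl,
      adaptive = config$adaptive, window = config$window))

    series <- stage("gravimetry", simulate_weight_series(
      rate = true_dm / max(config$cycles_mc),
      soak_amplitude = config$soak_amplitude_mg,
      soak_tau = config$soak_tau_mc,
      balance_sd = config$balance_sd_mg, n_weighings = config$n_weighings,
      cycles = config$cycles_mc, seed = config$seed + 3000L + i,
      specimen_id = sprintf("%s_%d", config$materials[i], i),
      material = config$materials[i]))
    grav <- analyze_weight_series(series, config$steady_state_from_mc)

    rows[[i]] <- data.frame(
      specimen_id = series$specimen_id,
      material = config$materials[i],
      penetration_mm = config$penetrations_mm[i],
      true_volume_mm3 = true_dv,
      true_mass_mg = true_dm,
      ct_volume_mm3 = res$delta_volume_mm3,
      ct_mass_mg = res$delta_mass_mg,
      grav_mass_mg = grav$cumulative_loss_mg[length(grav$cumulative_loss_mg)],
      registration_rms_mm = res$registration_rms_mm,
      stringsAsFactors = FALSE)
  }
  specimens <- do.call(rbind, rows)
  agreement <- stage("agreement", method_agreement(
    method_pairs(specimens$specimen_id, specimens$ct_mass_mg,
                 specimens$grav_mass_mg)))
  out <- structure(list(specimens = specimens, agreement = agreement,
                        config = config),
                   class = "wear_pipeline_result")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(unclass(config), file.path(outdir, "config.yaml"))
    write.csv(specimens, file.path(outdir, "specimens.csv"),
              row.names = FALSE)
    write_agreement_json(agreement, file.path(outdir, "agreement.json"))
  }
  out
}

#' @export
print.wear_pipeline_result <- function(x, ...) {
  cat(sprintf("wear_pipeline_result: %d specimens, voxel %g mm\n",
              nrow(x$specimens), x$config$voxel_size_mm))
  print(x$specimens[, c("specimen_id", "true_mass_mg", "ct_mass_mg",
                        "grav_mass_mg")], row.names = FALSE)
  cat(sprintf("agreement R^2 = %.4f, bias = %.3f mg\n",
              x$agreement$fit$r_squared, x$agreement$bland_altman$bias))
  invisible(x)
}

#' Read a plain-text `key: value` phantom/pipeline configuration
#'
#' YAML-compatible flat `key: value` files; keys must match
#' [pipeline_config()] arguments.  Unknown keys are an error so typos do
#' not pass silently.
#'
#' @param path Config file path.
#' @param ... Overrides applied after the file (flags win over file).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  dots <- list(...)
  vals[names(dots)] <- dots
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop_validation("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}
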