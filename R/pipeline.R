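#' Configuration for a full virtual implant-therapy run
#'
#' Bundles every tunable of the pipeline with defaults reproducing the
#' study conditions: a 50 N occlusal load at 45 degrees to the tooth axis
#' applied buccal-to-lingual, a 12-design grid of 3 diameters by 4 lengths,
#' and the synthetic mandibular phantom at 0.39 mm voxel size.
#'
#' @param phantom a [mandible_phantom_params()] object.
#' @param bone_threshold,tooth_threshold segmentation thresholds (CT units).
#' @param diameters,lengths design-grid factors (mm).
#' @param load_magnitude occlusal force (N).
#' @param load_angle_deg angle to the tooth axis (degrees).
#' @param supracrestal_height implant height above the crest (mm), identical
#'   for every design.
#' @param tooth_id target tooth for virtual extraction.
#' @param direct_dof_limit,tol solver settings.
#' @param seed root seed; the phantom noise seed is derived from it.
#' @param output_dir optional directory for the summary CSV and manifest.
#' @return An object of class `run_config`.
#' @export
run_config <- function(phantom = NULL,
                       bone_threshold = 1200, tooth_threshold = 17500,
                       diameters = c(3.8, 4.3, 6.0),
                       lengths = c(9.0, 11.0, 13.0, 16.0),
                       load_magnitude = 50, load_angle_deg = 45,
                       supracrestal_height = 8,
                       tooth_id = 1L,
                       direct_dof_limit = 3e5, tol = 1e-8,
                       seed = 1L, output_dir = NULL) {
  if (is.null(phantom)) {
    phantom <- mandible_phantom_params(seed = seed)
  }
  cfg <- list(
    phantom = phantom,
    bone_threshold = bone_threshold, tooth_threshold = tooth_threshold,
    diameters = diameters, lengths = lengths,
    load_magnitude = load_magnitude, load_angle_deg = load_angle_deg,
    supracrestal_height = supracrestal_height,
    tooth_id = as.integer(tooth_id),
    direct_dof_limit = direct_dof_limit, tol = tol,
    seed = as.integer(seed), output_dir = output_dir
  )
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Checks every invariant of the configuration and returns the violations
#' as data rather than raising conditions.
#'
#' @param config a [run_config()].
#' @return Character vector of violation messages; empty when the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (!inherits(config, "run_config")) {
    return("config: not a run_config object")
  }
  if (length(config$diameters) == 0) add("diameters: empty factor list")
  if (length(config$lengths) == 0) add("lengths: empty factor list")
  if (any(config$diameters <= 0)) add("diameters: must be positive")
  if (any(config$lengths <= 0)) add("lengths: must be positive")
  if (config$load_magnitude <= 0) add("load_magnitude: must be positive")
  if (config$load_angle_deg < 0 || config$load_angle_deg >= 90) {
    add("load_angle_deg: must lie in [0, 90)")
  }
  if (config$tooth_threshold <= config$bone_threshold) {
    add("tooth_threshold: must exceed bone_threshold")
  }
  if (config$supracrestal_height <= 0) {
    add("supracrestal_height: must be positive")
  }
  tab <- tryCatch(material_table(), error = function(e) conditionMessage(e))
  if (is.character(tab)) add(paste0("material_table: ", tab))
  ph <- config$phantom
  if (!inherits(ph, "mandible_phantom_params")) {
    add("phantom: not a mandible_phantom_params object")
  } else {
    if (ph$cortical_hu <= ph$trabecular_hu) {
      add("phantom: cortical_hu must exceed trabecular_hu")
    }
    if (ph$shell_thickness < ph$spacing) {
      add("phantom: shell_thickness below one voxel")
    }
  }
  v
}

#' Run the complete virtual implant-therapy pipeline
#'
#' Generates the synthetic CT volume, segments it, virtually extracts the
#' target tooth, and runs the design sweep, returning a manifest that fully
#' documents the run. Identical configuration (including seed) yields an
#' identical stress summary.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return A list of class `run_manifest` with elements `config`, `seed`,
#'   `summary` (the `stress_summary` tibble), `n_configurations`, `timings`
#'   (seconds per stage), `versions`, and `outputs` (paths written, if an
#'   output directory was configured).
#' @export
run_all <- function(config = run_config(), quiet = FALSE) {
  violations <- validate_config(config)
  if (length(violations) > 0) {
    stop("invalid configuration:\n  ", paste(violations, collapse = "\n  "),
         call. = FALSE)
  }
  timing <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    list(value = val, s = proc.time()[["elapsed"]] - t0)
  }
  st <- timing(generate_mandible_volume(config$phantom))
  vol <- st$value
  sg <- timing(fill_enclosed_pores(segment_roi(vol, config$bone_threshold,
                                               config$tooth_threshold)))
  vol <- sg$value
  ex <- timing(virtual_extraction(vol, config$tooth_id))
  vol <- ex$value
  grid <- enumerate_design_grid(config$diameters, config$lengths,
                                supracrestal_height =
                                  config$supracrestal_height)
  outputs <- list()
  csv <- NULL
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    csv <- file.path(config$output_dir, "stress_summary.csv")
  }
  sw <- timing(run_sweep(vol, grid,
                         load_magnitude = config$load_magnitude,
                         load_angle_deg = config$load_angle_deg,
                         direct_dof_limit = config$direct_dof_limit,
                         tol = config$tol, csv = csv, quiet = quiet))
  summary <- sw$value
  manifest <- list(
    config = config,
    seed = config$seed,
    n_configurations = nrow(summary),
    summary = summary,
    timings = c(generate = st$s, segment = sg$s, extract = ex$s,
                sweep = sw$s),
    versions = list(
      package = as.character(utils::packageVersion("implantfem")),
      R = paste(R.version$major, R.version$minor, sep = ".")
    ),
    outputs = outputs
  )
  class(manifest) <- "run_manifest"
  if (!is.null(config$output_dir)) {
    manifest$outputs$summary_csv <- csv
    manifest_path <- file.path(config$output_dir, "manifest.json")
    writeLines(manifest_json(manifest), manifest_path)
    manifest$outputs$manifest_json <- manifest_path
  }
  manifest
}

# JSON rendering of a manifest (config echo, versions, timings, summary)
manifest_json <- function(manifest) {
  cfg <- manifest$config
  cfg$phantom$teeth <- as.data.frame(cfg$phantom$teeth)
  jsonlite::toJSON(list(
    seed = manifest$seed,
    n_configurations = manifest$n_configurations,
    config = lapply(cfg, function(x) if (is.list(x) && !is.data.frame(x))
      unclass(x) else x),
    timings_s = as.list(round(manifest$timings, 3)),
    versions = manifest$versions,
    summary = as.data.frame(manifest$summary)
  ), auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d configurations, seed %d\n",
              x$n_configurations, x$seed))
  cat(sprintf("  timings (s): %s\n",
              paste(sprintf("%s=%.1f", names(x$timings), x$timings),
                    collapse = ", ")))
  print(x$summary)
  invisible(x)
}
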