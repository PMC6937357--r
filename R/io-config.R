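# Run configuration: a JSON text config (JSON is a strict YAML subset, so
# configs remain valid YAML documents), schema-validated with unknown keys
# rejected and defaults filled.

.config_schema <- function() list(
  seed = NULL, output_dir = NULL,
  grid = list(nx = 96, ny = 96, nz = SLICES_PER_BED_DEFAULT, dx_mm = 3.5),
  acquisition = list(time_per_bed = 60, angles = 120, radial_bins = NULL,
                     psf_fwhm = 5, calibration = 0.01,
                     half_life = F18_HALF_LIFE_MIN, start_time_offset = 0),
  geometry = list(slices_per_bed = SLICES_PER_BED_DEFAULT,
                  overlap_slices = OVERLAP_SLICES_DEFAULT, n_beds = 1),
  recon = list(),                                    # list of recon specs
  metrics = list(supersample = 2, central_slices = 11),
  experiment = list(name = NULL, times_min = 1:5,
                    ratio_cases = c("10:1", "4:1", "2:1"), n_patients = 8,
                    betas = c(low = 0.05, mid = 0.1, high = 0.2))
)

.recon_spec_keys <- c("algorithm", "iterations", "subsets", "psf_fwhm",
                      "beta", "gamma", "bpl_max_passes", "bpl_tol",
                      "relax0", "relax_H", "postfilter_fwhm",
                      "axial_weights", "epsilon", "label")

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown configuration key", if (length(bad) > 1) "s", " in ",
         where, ": ", paste(bad, collapse = ", "), call. = FALSE)
}

#' Load and validate a run configuration
#'
#' Parses a JSON (hence YAML-compatible) config file, rejects unknown keys
#' naming the offender, requires a seed (reproducibility contract), fills
#' the documented defaults and, when `output_dir` exists, writes an echo of
#' the effective configuration there.
#'
#' @param path config file path.
#' @param write_echo write `config_echo.json` into `output_dir`.
#' @return a `run_config` list.
#' @export
load_config <- function(path, write_echo = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  schema <- .config_schema()
  .check_keys(raw, names(schema), "top level")
  if (is.null(raw$seed))
    stop("configuration must provide a seed (reproducibility contract)",
         call. = FALSE)
  for (sec in c("grid", "acquisition", "geometry", "metrics", "experiment"))
    if (!is.null(raw[[sec]]))
      .check_keys(raw[[sec]], names(schema[[sec]]), sec)
  if (!is.null(raw$recon)) {
    rl <- raw$recon
    if (is.data.frame(rl)) rl <- split(rl, seq_len(nrow(rl)))
    for (r in rl) .check_keys(r, .recon_spec_keys, "recon entry")
  }
  cfg <- schema
  for (nm in names(raw)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(raw[[nm]]) &&
                     nm != "recon")
      modifyList(cfg[[nm]], raw[[nm]]) else raw[[nm]]
  }
  cfg <- structure(cfg, class = "run_config")
  if (write_echo && !is.null(cfg$output_dir) && dir.exists(cfg$output_dir))
    jsonlite::write_json(unclass(cfg),
                         file.path(cfg$output_dir, "config_echo.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  cfg
}

#' Build domain objects from a `run_config`
#' @param cfg a `run_config`.
#' @name config_builders
#' @export
config_grid <- function(cfg)
  voxel_grid(c(cfg$grid$nx, cfg$grid$ny, cfg$grid$nz),
             c(cfg$grid$dx_mm, cfg$grid$dx_mm,
               AXIAL_FOV_MM / SLICES_PER_BED_DEFAULT))

#' @rdname config_builders
#' @export
config_acquisition <- function(cfg) {
  a <- cfg$acquisition
  acquisition_config(time_per_bed = a$time_per_bed, seed = cfg$seed,
                     angles = a$angles, radial_bins = a$radial_bins,
                     psf_fwhm = a$psf_fwhm, calibration = a$calibration,
                     half_life = a$half_life,
                     start_time_offset = a$start_time_offset)
}

#' @rdname config_builders
#' @export
config_geometry <- function(cfg)
  bed_geometry(cfg$geometry$slices_per_bed, cfg$geometry$overlap_slices,
               cfg$geometry$n_beds)

#' @rdname config_builders
#' @export
config_recons <- function(cfg) {
  rl <- cfg$recon
  if (!length(rl)) {
    betas <- unlist(cfg$experiment$betas)
    return(recon_setting_list(betas,
                              subsets = .default_subsets(cfg)))
  }
  if (is.data.frame(rl)) rl <- split(rl, seq_len(nrow(rl)))
  out <- list()
  for (i in seq_along(rl)) {
    r <- as.list(rl[[i]])
    label <- r$label %||% paste0(r$algorithm, "_", i)
    r$label <- NULL
    if (is.null(r$subsets)) r$subsets <- .default_subsets(cfg)
    out[[label]] <- do.call(recon_config, r)
  }
  out
}

.default_subsets <- function(cfg) {
  ang <- cfg$acquisition$angles
  if (ang %% 24 == 0) 24L else {
    d <- which(ang %% seq_len(24) == 0)
    max(d)
  }
}
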