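# Digital phantoms: NEMA NU2 image-quality phantom, micro hollow-sphere
# phantom and patient-like multi-bed objects, plus their rasterization onto
# voxel grids. All world coordinates are millimetres; activity concentrations
# are kBq/ml; attenuation is 1/cm at 511 keV.

# Physical / geometric constants (not tunable per run)
MU_WATER_511 <- 0.096          # 1/cm, water-equivalent tissue at 511 keV
MU_LUNG_FRACTION <- 0.3        # lung insert (polystyrene beads) vs water
NEMA_SPHERE_DIAMS <- c(10, 13, 17, 22, 28, 37)   # mm, inner diameters
MICRO_SPHERE_DIAMS <- c(4, 5, 6, 8, 10)          # mm
NEMA_RING_RADIUS <- 57.2       # mm, NU2 sphere-ring radius
MICRO_RING_RADIUS <- 20        # mm, chosen so 4-10 mm spheres never overlap
NEMA_LUNG_DIAMETER <- 50       # mm
AXIAL_FOV_MM <- 157            # mm, scanner axial field of view
SLICES_PER_BED_DEFAULT <- 47L
OVERLAP_SLICES_DEFAULT <- 11L

# Printed fill concentrations (kBq/ml) per contrast case: c(sphere, background)
RATIO_CASE_FILLS <- list(
  "10:1" = c(sphere = 10.0, background = 1.0),
  "4:1"  = c(sphere = 6.5,  background = 1.6),
  "2:1"  = c(sphere = 4.8,  background = 2.6)
)

.normalize_ratio_case <- function(ratio_case) {
  key <- gsub("-to-", ":", tolower(as.character(ratio_case)[1]), fixed = TRUE)
  key <- gsub("\\s", "", key)
  if (!key %in% names(RATIO_CASE_FILLS)) {
    stop("unknown ratio_case '", ratio_case, "'; expected one of ",
         paste(names(RATIO_CASE_FILLS), collapse = ", "), call. = FALSE)
  }
  key
}

#' Sphere specification
#'
#' A hot (or cold) sphere within a phantom: position of its centre, inner
#' diameter and activity concentration. Shell walls are ignored; the inner
#' diameter defines the active volume.
#'
#' @param center numeric length-3, centre in mm (x, y, z).
#' @param inner_diameter sphere inner diameter in mm, > 0.
#' @param activity_concentration activity concentration in kBq/ml, >= 0.
#' @return an object of class `sphere_spec`.
#' @export
sphere_spec <- function(center, inner_diameter, activity_concentration) {
  stopifnot(length(center) == 3, is.finite(center))
  if (!is.finite(inner_diameter) || inner_diameter <= 0)
    stop("inner_diameter must be > 0", call. = FALSE)
  if (!is.finite(activity_concentration) || activity_concentration < 0)
    stop("activity_concentration must be >= 0", call. = FALSE)
  structure(
    list(center = as.numeric(center),
         inner_diameter = as.numeric(inner_diameter),
         activity_concentration = as.numeric(activity_concentration)),
    class = "sphere_spec")
}

# Axial body sections. A phantom is a stack of sections along z, each with a
# 2D outline that is constant over the section's z-range.
body_section <- function(z_range, outline, attenuation_scale = 1) {
  stopifnot(length(z_range) == 2, z_range[2] > z_range[1],
            attenuation_scale > 0)
  list(z_range = as.numeric(z_range), outline = outline,
       attenuation_scale = as.numeric(attenuation_scale))
}

# outline: list(shape = "rounded_rect"|"ellipse"|"cylinder", <params in mm>)
outline_inside <- function(outline, x, y) {
  switch(outline$shape,
    rounded_rect = {
      hw <- outline$width / 2 - outline$corner_radius
      hh <- outline$height / 2 - outline$corner_radius
      dx <- pmax(abs(x) - hw, 0)
      dy <- pmax(abs(y) - hh, 0)
      sqrt(dx^2 + dy^2) <= outline$corner_radius
    },
    ellipse = (2 * x / outline$width)^2 + (2 * y / outline$height)^2 <= 1,
    cylinder = x^2 + y^2 <= (outline$diameter / 2)^2,
    stop("unknown outline shape '", outline$shape, "'", call. = FALSE)
  )
}

#' Phantom specification
#'
#' Geometric and activity description of a phantom or patient-like object:
#' one or more axial body sections, a list of spheres, an optional cylindrical
#' lung insert, and the background activity concentration.
#'
#' @param sections list of body sections (internal constructor output).
#' @param spheres list of [sphere_spec()] objects.
#' @param lung_insert optional list(center = xy mm, diameter = mm,
#'   activity_concentration = kBq/ml).
#' @param background_concentration background activity, kBq/ml.
#' @param name label used in reports.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(sections, spheres = list(), lung_insert = NULL,
                         background_concentration = 0, name = "phantom") {
  stopifnot(length(sections) >= 1, background_concentration >= 0)
  ph <- structure(
    list(sections = sections, spheres = spheres, lung_insert = lung_insert,
         background_concentration = as.numeric(background_concentration),
         name = name),
    class = "phantom_spec")
  # placement check: every sphere centre must fall inside its section outline
  for (s in spheres) {
    sec <- .section_at(ph, s$center[3])
    if (is.null(sec))
      stop("sphere at z=", s$center[3], " mm lies outside the phantom's ",
           "axial extent", call. = FALSE)
    r <- s$inner_diameter / 2
    if (!outline_inside(sec$outline, s$center[1], s$center[2]))
      stop("sphere centred at (", paste(round(s$center, 1), collapse = ", "),
           ") mm lies outside the body outline", call. = FALSE)
    if (s$center[3] - r < .axial_range(ph)[1] ||
        s$center[3] + r > .axial_range(ph)[2])
      stop("sphere protrudes axially out of the phantom", call. = FALSE)
  }
  ph
}

.axial_range <- function(phantom) {
  zr <- vapply(phantom$sections, function(s) s$z_range, numeric(2))
  c(min(zr[1, ]), max(zr[2, ]))
}

.section_at <- function(phantom, z) {
  for (sec in phantom$sections)
    if (z >= sec$z_range[1] && z <= sec$z_range[2]) return(sec)
  NULL
}

#' Axial length of a phantom in mm
#' @param phantom a `phantom_spec`.
#' @export
axial_length <- function(phantom) diff(.axial_range(phantom))

#' Build the NEMA NU2 image-quality phantom
#'
#' Six fillable spheres (10-37 mm inner diameter) on a 57.2 mm ring around a
#' 50 mm cold cylindrical lung insert, inside a torso-shaped background
#' compartment, filled at one of the three studied sphere-to-background
#' contrast cases with the corresponding start concentrations.
#'
#' @param ratio_case one of `"10:1"`, `"4:1"`, `"2:1"` (aliases "10-to-1"
#'   etc. accepted).
#' @param axial_length_mm phantom length along the scanner axis; defaults to
#'   one bed's axial field of view.
#' @param sphere_plane_z z position (mm) of the sphere-centre plane; defaults
#'   to the axial centre (peak bed sensitivity).
#' @return a `phantom_spec` named `"nema"`.
#' @export
build_nema_iq <- function(ratio_case, axial_length_mm = AXIAL_FOV_MM,
                          sphere_plane_z = axial_length_mm / 2) {
  key <- .normalize_ratio_case(ratio_case)
  fill <- RATIO_CASE_FILLS[[key]]
  outline <- list(shape = "rounded_rect", width = 300, height = 230,
                  corner_radius = 77)
  ang <- (0:5) * pi / 3    # six spheres, 60 deg apart
  spheres <- Map(function(d, a) {
    sphere_spec(center = c(NEMA_RING_RADIUS * cos(a),
                           NEMA_RING_RADIUS * sin(a), sphere_plane_z),
                inner_diameter = d, activity_concentration = fill[["sphere"]])
  }, NEMA_SPHERE_DIAMS, as.list(ang))
  phantom_spec(
    sections = list(body_section(c(0, axial_length_mm), outline)),
    spheres = spheres,
    lung_insert = list(center = c(0, 0), diameter = NEMA_LUNG_DIAMETER,
                       activity_concentration = 0),
    background_concentration = fill[["background"]],
    name = paste0("nema_", gsub(":", "to", key)))
}

#' Build the modified micro hollow-sphere phantom
#'
#' Five spheres of 4, 5, 6, 8 and 10 mm inner diameter: the 10 mm sphere at
#' the centre and the four smaller ones equiradially around it (90 degrees
#' apart), filled at the same contrast cases as the NEMA phantom.
#'
#' @inheritParams build_nema_iq
#' @param body_diameter_mm diameter of the cylindrical background
#'   compartment, mm.
#' @return a `phantom_spec` named `"micro"`.
#' @export
build_micro_sphere <- function(ratio_case, axial_length_mm = AXIAL_FOV_MM,
                               sphere_plane_z = axial_length_mm / 2,
                               body_diameter_mm = 100) {
  key <- .normalize_ratio_case(ratio_case)
  fill <- RATIO_CASE_FILLS[[key]]
  outline <- list(shape = "cylinder", diameter = body_diameter_mm)
  ang <- (0:3) * pi / 2    # four outer spheres, equiradial, 90 deg apart
  outer <- Map(function(d, a) {
    sphere_spec(center = c(MICRO_RING_RADIUS * cos(a),
                           MICRO_RING_RADIUS * sin(a), sphere_plane_z),
                inner_diameter = d, activity_concentration = fill[["sphere"]])
  }, MICRO_SPHERE_DIAMS[1:4], as.list(ang))
  central <- sphere_spec(center = c(0, 0, sphere_plane_z),
                         inner_diameter = MICRO_SPHERE_DIAMS[5],
                         activity_concentration = fill[["sphere"]])
  phantom_spec(
    sections = list(body_section(c(0, axial_length_mm), outline)),
    spheres = c(outer, list(central)),
    background_concentration = fill[["background"]],
    name = paste0("micro_", gsub(":", "to", key)))
}

#' Build a patient-like multi-bed phantom
#'
#' An elongated object spanning `n_beds` bed positions with uniform
#' muscle-like background activity and optional embedded lesions. The last
#' bed is a torso-sized ellipse; earlier beds are leg-sized (smaller
#' cross-section, hence shorter attenuation paths), emulating a whole-body
#' leg-to-torso scan.
#'
#' @param n_beds number of bed positions, >= 2.
#' @param lesion_specs list of [sphere_spec()] lesions (absolute mm coords).
#' @param section_attenuation optional per-bed attenuation scale factors.
#' @param background_concentration muscle background, kBq/ml.
#' @param slices_per_bed,overlap_slices,dz_mm bed geometry used to size the
#'   object axially.
#' @param n_torso_beds how many trailing beds use the torso cross-section.
#' @return a `phantom_spec` named `"patient"`.
#' @export
build_patient_like <- function(n_beds, lesion_specs = list(),
                               section_attenuation = NULL,
                               background_concentration = 1.5,
                               slices_per_bed = SLICES_PER_BED_DEFAULT,
                               overlap_slices = OVERLAP_SLICES_DEFAULT,
                               dz_mm = AXIAL_FOV_MM / SLICES_PER_BED_DEFAULT,
                               n_torso_beds = 1) {
  if (n_beds < 2) stop("n_beds must be >= 2 (at least one overlap)",
                       call. = FALSE)
  if (is.null(section_attenuation)) section_attenuation <- rep(1, n_beds)
  stopifnot(length(section_attenuation) == n_beds)
  pitch <- slices_per_bed - overlap_slices
  n_slices <- slices_per_bed + (n_beds - 1) * pitch
  total_len <- n_slices * dz_mm
  leg <- list(shape = "ellipse", width = 140, height = 100)
  torso <- list(shape = "ellipse", width = 300, height = 200)
  # sections partition z at bed-pitch boundaries; last section runs to the end
  sections <- lapply(seq_len(n_beds), function(b) {
    z0 <- (b - 1) * pitch * dz_mm
    z1 <- if (b == n_beds) total_len else b * pitch * dz_mm
    shape <- if (b > n_beds - n_torso_beds) torso else leg
    body_section(c(z0, z1), shape, attenuation_scale = section_attenuation[b])
  })
  phantom_spec(sections = sections, spheres = lesion_specs,
               background_concentration = background_concentration,
               name = "patient")
}

#' Build a uniform cylindrical phantom
#'
#' A sphere-free cylinder of uniform activity, used for noise (COV) studies
#' where structure would contaminate the background ROI.
#'
#' @param diameter_mm cylinder diameter.
#' @param axial_length_mm cylinder length.
#' @param concentration activity, kBq/ml.
#' @return a `phantom_spec` named `"cylinder"`.
#' @export
build_uniform_cylinder <- function(diameter_mm = 200,
                                   axial_length_mm = AXIAL_FOV_MM,
                                   concentration = 1) {
  phantom_spec(
    sections = list(body_section(c(0, axial_length_mm),
                                 list(shape = "cylinder",
                                      diameter = diameter_mm))),
    background_concentration = concentration, name = "cylinder")
}

#' Sphere-to-background activity-concentration ratio
#'
#' @param phantom a `phantom_spec` with background_concentration > 0.
#' @return the dimensionless ratio (scalar when all spheres share one
#'   concentration, otherwise one value per sphere).
#' @export
sphere_to_background_ratio <- function(phantom) {
  if (phantom$background_concentration <= 0)
    stop("sphere-to-background ratio undefined: background concentration ",
         "is zero", call. = FALSE)
  if (length(phantom$spheres) == 0)
    stop("phantom has no spheres", call. = FALSE)
  conc <- vapply(phantom$spheres, `[[`, numeric(1), "activity_concentration")
  r <- conc / phantom$background_concentration
  if (length(unique(r)) == 1) r[1] else r
}

#' Voxel grid
#'
#' @param shape integer length-3 (nx, ny, nz) voxel counts.
#' @param spacing numeric length-3 (dx, dy, dz) in mm, all > 0.
#' @param origin world position (mm) of the centre of voxel (1,1,1). Default
#'   centres the grid in-plane on (0,0) and starts z at half a slice.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, spacing, origin = NULL) {
  shape <- as.integer(shape); stopifnot(length(shape) == 3, shape >= 1)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(length(spacing) == 3, spacing > 0)
  if (is.null(origin))
    origin <- c(-(shape[1] - 1) / 2 * spacing[1],
                -(shape[2] - 1) / 2 * spacing[2],
                spacing[3] / 2)
  structure(list(shape = shape, spacing = spacing,
                 origin = as.numeric(origin)), class = "voxel_grid")
}

#' Default scanner-like grid: 2 mm in-plane, 157/47 mm slice pitch
#' @param nx,ny in-plane voxel counts.
#' @param nz slice count (47 per bed by default).
#' @param dx_mm in-plane voxel size.
#' @export
scanner_grid <- function(nx = 168, ny = 168, nz = SLICES_PER_BED_DEFAULT,
                         dx_mm = 2) {
  voxel_grid(c(nx, ny, nz),
             c(dx_mm, dx_mm, AXIAL_FOV_MM / SLICES_PER_BED_DEFAULT))
}

grid_axis <- function(grid, d) grid$origin[d] + (seq_len(grid$shape[d]) - 1) *
  grid$spacing[d]

#' @export
print.voxel_grid <- function(x, ...) {
  cat("voxel_grid:", paste(x$shape, collapse = " x "), "voxels,",
      paste(signif(x$spacing, 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("phantom_spec '", x$name, "': ", length(x$spheres), " spheres, ",
      "background ", x$background_concentration, " kBq/ml, axial length ",
      round(axial_length(x), 1), " mm\n", sep = "")
  invisible(x)
}
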