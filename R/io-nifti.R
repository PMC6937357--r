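# Minimal NIfTI-1 volume IO (float32, little-endian, single file .nii) with
# a JSON provenance sidecar. No NIfTI reader/writer is available in the
# supported dependency set, so the 348-byte header is written directly.

.pad_char <- function(s, n) {
  r <- charToRaw(substr(s, 1, n))
  c(r, raw(n - length(r)))
}

.fnv1a <- function(r) {
  # 32-bit FNV-1a over a raw vector, returned as 8 hex chars; the state is
  # held as a double < 2^32, with the multiply split into 16-bit halves so
  # no intermediate exceeds the exact-double range
  h <- 2166136261
  m <- 16777619
  for (b in as.integer(r)) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * m + ((h1 * m) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

values_digest_n <- 4096L   # hash at most this many bytes (speed)

values_hash <- function(values) {
  r <- writeBin(as.numeric(values), raw(), size = 4, endian = "little")
  if (length(r) > values_digest_n)   # strided subsample keeps hashing O(1)
    r <- c(r[seq(1L, length(r),
                 length.out = values_digest_n)],
           writeBin(length(r), raw()))
  .fnv1a(r)
}

#' Write an image volume as NIfTI-1 (+ JSON sidecar)
#'
#' Writes a single-file `.nii` (float32, little-endian) with the voxel
#' spacings in the header, and a `.json` sidecar next to it carrying the
#' provenance (algorithm, seed, config hash) and a hash of the voxel data.
#'
#' @param volume an `image_volume` with complete grid metadata.
#' @param path output path ending in `.nii`.
#' @return the path, invisibly.
#' @export
write_volume <- function(volume, path) {
  grid <- volume$grid
  if (is.null(grid) || any(!is.finite(grid$spacing)) ||
      any(grid$spacing <= 0))
    stop("refusing to write: voxel spacing missing or invalid",
         call. = FALSE)
  dims <- dim(volume$values)
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, size, type = "integer")
    writeBin(if (type == "integer") as.integer(x) else as.numeric(x), con,
             size = size, endian = "little")
  w(348L, 4)                                    # sizeof_hdr
  writeBin(raw(36 - 1), con); writeBin(as.raw(0L), con)  # filler to 40
  w(c(3L, dims, 1L, 1L, 1L, 1L), 2)             # dim[8]
  w(c(0, 0, 0), 4, "double")                    # intent_p1..p3
  w(c(0L, 16L, 32L, 0L), 2)                     # intent_code, FLOAT32, bitpix
  w(c(1, grid$spacing, 0, 0, 0, 0), 4, "double")   # pixdim
  w(352, 4, "double")                           # vox_offset
  w(c(1, 0), 4, "double")                       # scl_slope, scl_inter
  w(0L, 2); writeBin(as.raw(c(0L, 2L)), con)    # slice_end, code, units=mm
  w(c(0, 0, 0, 0), 4, "double")                 # cal_max/min, slice_dur, toff
  w(c(0L, 0L), 4)                               # glmax, glmin
  writeBin(.pad_char("petiq reconstructed volume", 80), con)
  writeBin(raw(24), con)                        # aux_file
  w(c(0L, 1L), 2)                               # qform=0, sform=1
  w(c(0, 0, 0), 4, "double")                    # quatern b,c,d
  w(grid$origin, 4, "double")                   # qoffset x,y,z
  w(c(grid$spacing[1], 0, 0, grid$origin[1]), 4, "double")   # srow_x
  w(c(0, grid$spacing[2], 0, grid$origin[2]), 4, "double")   # srow_y
  w(c(0, 0, grid$spacing[3], grid$origin[3]), 4, "double")   # srow_z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  writeBin(raw(4), con)                         # no extensions
  w(volume$values, 4, "double")                 # data as float32
  side <- sub("\\.nii$", ".json", path)
  meta <- list(provenance = volume$provenance,
               seed = volume$provenance$seed,
               config_hash = .fnv1a(serialize(volume$provenance$config,
                                              NULL)),
               values_hash = values_hash(volume$values),
               shape = dims, spacing = grid$spacing, origin = grid$origin)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_volume()]
#'
#' @param path `.nii` path; the `.json` sidecar is read when present and a
#'   mismatching stored data hash raises a warning.
#' @return an `image_volume`.
#' @export
read_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, "integer", 1, 4, endian = "little")
  if (!identical(hdr_size, 348L))
    stop("not a little-endian NIfTI-1 file (sizeof_hdr = ", hdr_size, ")",
         call. = FALSE)
  invisible(readBin(con, "raw", 36))
  dim8 <- readBin(con, "integer", 8, 2, endian = "little")
  invisible(readBin(con, "double", 3, 4, endian = "little"))
  ints <- readBin(con, "integer", 4, 2, endian = "little")
  datatype <- ints[2]
  pixdim <- readBin(con, "double", 8, 4, endian = "little")
  vox_offset <- readBin(con, "double", 1, 4, endian = "little")
  seek(con, 254)
  sform <- readBin(con, "integer", 1, 2, endian = "little")
  invisible(readBin(con, "double", 3, 4, endian = "little"))  # quatern b,c,d
  qoff <- readBin(con, "double", 3, 4, endian = "little")
  srow <- matrix(readBin(con, "double", 12, 4, endian = "little"), 4, 3)
  origin <- if (sform >= 1) srow[4, ] else qoff
  dims <- dim8[2:(dim8[1] + 1)]
  if (length(dims) < 3) dims <- c(dims, rep(1L, 3 - length(dims)))
  seek(con, vox_offset)
  n <- prod(dims)
  vals <- switch(as.character(datatype),
    "16" = readBin(con, "double", n, 4, endian = "little"),
    "64" = readBin(con, "double", n, 8, endian = "little"),
    stop("unsupported NIfTI datatype ", datatype, call. = FALSE))
  values <- array(vals, dims[1:3])
  prov <- list()
  side <- sub("\\.nii$", ".json", path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    prov <- meta$provenance
    if (!is.null(meta$values_hash) &&
        !identical(meta$values_hash, values_hash(values)))
      warning("sidecar hash does not match the voxel data in ", path,
              call. = FALSE)
  }
  image_volume(values, voxel_grid(dims[1:3], pixdim[2:4], origin),
               provenance = prov)
}

#' Persist a sinogram set (gzipped counts + JSON metadata sidecar)
#' @param sinos a `sinogram_set`.
#' @param path output path (`.bin.gz` recommended); sidecar at `path.json`.
#' @export
write_sinograms <- function(sinos, path) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  for (b in seq_len(sinos$geometry$n_beds)) {
    writeBin(as.integer(sinos$counts[[b]]), con, size = 4,
             endian = "little")
    writeBin(as.numeric(sinos$expected[[b]]), con, size = 8,
             endian = "little")
    writeBin(as.numeric(sinos$attenuation_factors[[b]]), con, size = 8,
             endian = "little")
  }
  meta <- list(dims = dim(sinos$counts[[1]]),
               geometry = unclass(sinos$geometry),
               config = unclass(sinos$config), dx = sinos$dx,
               times_s = sinos$times_s, bed_start_min = sinos$bed_start_min,
               grid = unclass(sinos$grid), seed = sinos$config$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a sinogram set written by [write_sinograms()]
#' @param path the `.bin.gz` path.
#' @export
read_sinograms <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dims <- as.integer(meta$dims)
  geom <- bed_geometry(meta$geometry$slices_per_bed,
                       meta$geometry$overlap_slices, meta$geometry$n_beds)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  n <- prod(dims)
  counts <- expected <- attf <- vector("list", geom$n_beds)
  for (b in seq_len(geom$n_beds)) {
    counts[[b]] <- array(readBin(con, "integer", n, 4, endian = "little"),
                         dims)
    expected[[b]] <- array(readBin(con, "double", n, 8, endian = "little"),
                           dims)
    attf[[b]] <- array(readBin(con, "double", n, 8, endian = "little"),
                       dims)
  }
  cfg <- meta$config
  config <- acquisition_config(time_per_bed = cfg$time_per_bed,
                               seed = cfg$seed, angles = cfg$angles,
                               radial_bins = cfg$radial_bins,
                               psf_fwhm = cfg$psf_fwhm,
                               calibration = cfg$calibration,
                               half_life = cfg$half_life,
                               start_time_offset = cfg$start_time_offset)
  grid <- voxel_grid(meta$grid$shape, meta$grid$spacing, meta$grid$origin)
  structure(list(counts = counts, expected = expected,
                 attenuation_factors = attf, geometry = geom,
                 profile = axial_sensitivity(geom$slices_per_bed),
                 config = config, dx = meta$dx, times_s = meta$times_s,
                 bed_start_min = meta$bed_start_min, grid = grid),
            class = "sinogram_set")
}
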