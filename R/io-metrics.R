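# Tidy CSV export of metric tables, one file per metric family, with a
# run-manifest id carried as a header comment.

#' Write metric tables as CSV
#'
#' Writes one CSV per table in `report` (a named list of data.frames) with
#' a `# manifest: <id>` header comment and stable column order. Output is
#' deterministic: identical inputs give byte-identical files.
#'
#' @param report named list of non-empty data.frames.
#' @param dir output directory (created if missing).
#' @param manifest_id identifier recorded in each file header.
#' @return character vector of written paths.
#' @export
write_metrics <- function(report, dir, manifest_id = "unspecified") {
  if (!length(report)) stop("empty report", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(report)) {
    tab <- report[[nm]]
    if (!is.data.frame(tab) || nrow(tab) == 0)
      stop("metric table '", nm, "' is empty", call. = FALSE)
    path <- file.path(dir, paste0(nm, ".csv"))
    con <- file(path, "wb")   # binary mode: byte-identical across platforms
    writeLines(paste0("# manifest: ", manifest_id), con)
    write.csv(tab, con, row.names = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  paths
}

#' Read a metrics CSV written by [write_metrics()]
#' @param path CSV path.
#' @return the data.frame, with the manifest id as attribute `"manifest"`.
#' @export
read_metrics <- function(path) {
  first <- readLines(path, n = 1)
  tab <- read.csv(path, comment.char = "#")
  attr(tab, "manifest") <- sub("^# manifest: ", "", first)
  tab
}

#' Pivot a recovery table into the published wide layout
#'
#' One row per (phantom, sphere diameter), one recovery-coefficient column
#' per reconstruction setting, within one contrast case.
#'
#' @param recovery long table from [run_contrast_series()].
#' @param ratio_case which contrast case to lay out.
#' @export
recovery_wide <- function(recovery, ratio_case = "10:1") {
  df <- recovery[recovery$ratio_case == ratio_case, ]
  recons <- unique(df$recon)
  key <- unique(df[, c("phantom", "diameter_mm")])
  key <- key[order(key$phantom, -key$diameter_mm), ]
  out <- key
  for (rn in recons) {
    sub <- df[df$recon == rn, ]
    out[[rn]] <- sub$recovery_coefficient[
      match(paste(key$phantom, key$diameter_mm),
            paste(sub$phantom, sub$diameter_mm))]
  }
  out
}
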