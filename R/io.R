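#' Save a tomogram as multi-page 32-bit float TIFF with a JSON sidecar
#'
#' Each z-slice becomes one TIFF page; voxel pitch, medium RI and optional
#' metadata go to `<path>.json`.
#'
#' @param tomo `odt_tomogram`.
#' @param path Output TIFF path (`.tif`).
#' @param metadata Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
save_tomogram <- function(tomo, path, metadata = list()) {
  # float TIFF stores [0, 1) faithfully; shift by a recorded offset
  offset <- floor(min(tomo$values))
  if (max(tomo$values) - offset >= 1)
    stop_labeled("io", "RI range exceeds 1 unit; cannot store as TIFF")
  slices <- lapply(seq_len(dim(tomo$values)[3]),
                   function(z) tomo$values[, , z] - offset)
  tiff::writeTIFF(slices, path, bits.per.sample = 32L)
  side <- c(list(voxel_pitch_um = tomo$grid$voxel_pitch,
                 shape = tomo$grid$shape,
                 n_medium = tomo$n_medium,
                 ri_offset = offset), metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a tomogram from TIFF + JSON sidecar
#'
#' @param path TIFF path written by [save_tomogram()].
#' @return `odt_tomogram` (metadata other than grid/medium as attribute
#'   `"metadata"`).
#' @export
load_tomogram <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop_labeled("io", "missing JSON sidecar with fields ",
                 "voxel_pitch_um, n_medium: ", sidecar)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (fld in c("voxel_pitch_um", "n_medium"))
    if (is.null(side[[fld]]))
      stop_labeled("io", "sidecar lacks required field '", fld, "'")
  slices <- tiff::readTIFF(path, all = TRUE)
  offset <- side$ri_offset %||% 0
  vals <- array(0, dim = c(dim(slices[[1]]), length(slices)))
  for (z in seq_along(slices)) vals[, , z] <- slices[[z]] + offset
  grid <- grid_spec(dim(vals), side$voxel_pitch_um)
  out <- tomogram(vals, grid, side$n_medium)
  attr(out, "metadata") <- side[setdiff(names(side),
                                        c("voxel_pitch_um", "shape",
                                          "n_medium", "ri_offset"))]
  out
}

#' Write / read a feature table as CSV
#'
#' @param features Feature `data.frame`.
#' @param path CSV path.
#' @return `path` / the `data.frame`.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
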