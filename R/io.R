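#' @include AllClasses.R
NULL

.trackCols <- c("particle_id", "channel", "frame", "time_s", "position_um")
.dwellCols <- c("particle_id", "channel", "start_s", "end_s", "duration_s",
                "censored")

.checkColumns <- function(df, mandatory, known, what) {
  missing <- setdiff(mandatory, names(df))
  if (length(missing))
    stop(sprintf("%s is missing mandatory column(s): %s", what,
                 paste(missing, collapse = ", ")))
  extra <- setdiff(names(df), known)
  if (length(extra))
    warning(sprintf("%s has unknown column(s): %s", what,
                    paste(extra, collapse = ", ")))
  invisible(df)
}

#' Read and write pipeline tables as CSV
#'
#' UTF-8 comma-separated files with a mandatory header row and '.' decimal
#' separator. Mandatory columns are validated on read (a missing one is a
#' format error naming the column; unknown columns give a warning).
#' Track tables carry particle_id, channel, frame, time_s, position_um and
#' optionally amplitude, sigma_px, censored_end, merged_gaps; dwell tables
#' carry particle_id, channel, start_s, end_s, duration_s, censored and
#' optionally on_target.
#'
#' @param path file path.
#' @param tracks,dwells tables to write.
#' @return the table (readers), invisibly the path (writers).
#' @name table_io
NULL

#' @rdname table_io
#' @export
readTracksCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .checkColumns(df, .trackCols,
                c(.trackCols, "amplitude", "sigma_px", "censored_end",
                  "merged_gaps", "position_kb"),
                sprintf("track table '%s'", basename(path)))
  df
}

#' @rdname table_io
#' @export
writeTracksCsv <- function(tracks, path) {
  .checkColumns(tracks, .trackCols,
                c(.trackCols, "amplitude", "sigma_px", "censored_end",
                  "merged_gaps", "position_kb"), "track table")
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
readDwellsCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .checkColumns(df, .dwellCols, c(.dwellCols, "on_target"),
                sprintf("dwell table '%s'", basename(path)))
  df
}

#' @rdname table_io
#' @export
writeDwellsCsv <- function(dwells, path) {
  .checkColumns(dwells, .dwellCols, c(.dwellCols, "on_target"), "dwell table")
  utils::write.csv(dwells, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a kymograph as TIFF plus JSON sidecar
#'
#' The image is stored as a 32-bit float grayscale TIFF (intensities scaled
#' to [0, 1] by the maximum); the sidecar \code{<path>.json} records
#' pixel_size_um, frame_interval_s, channel and the intensity scale so the
#' round-trip restores physical units to full float32 precision.
#'
#' @param kymograph a \linkS4class{Kymograph}.
#' @param path TIFF file path (sidecar written next to it).
#' @return the path (write, invisibly) or a \linkS4class{Kymograph} (read).
#' @export
writeKymographTiff <- function(kymograph, path) {
  validObject(kymograph)
  img <- kymograph@image
  scale <- max(img, 1e-12)
  tiff::writeTIFF(img / scale, path, bits.per.sample = 32L)
  meta <- list(pixel_size_um = kymograph@pixelSize,
               frame_interval_s = kymograph@frameInterval,
               channel = kymograph@channel, intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeKymographTiff
#' @export
readKymographTiff <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop(sprintf("missing sidecar metadata '%s'", basename(sidecar)))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (k in c("pixel_size_um", "frame_interval_s", "intensity_scale"))
    if (is.null(meta[[k]]) || !is.numeric(meta[[k]]) || meta[[k]] <= 0)
      stop(sprintf("sidecar field '%s' missing or invalid", k))
  img <- tiff::readTIFF(path)
  Kymograph(img * meta$intensity_scale, pixelSize = meta$pixel_size_um,
            frameInterval = meta$frame_interval_s,
            channel = if (is.null(meta$channel)) "A" else meta$channel)
}
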