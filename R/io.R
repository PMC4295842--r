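#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' The z planes are written as 16-bit grayscale TIFF pages; voxel values are
#' rounded to integers and clamped to \[0, 65535\], so integer-valued photon
#' counts round-trip losslessly. The pixel size, z spacing, stack id and
#' optional autofluorescence reference go into \code{<path>.json}.
#'
#' @param stack An \code{\link{image_stack}}.
#' @param path Output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  v <- round(stack$voxels)
  v[v < 0] <- 0
  v[v > 65535] <- 65535
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  meta <- list(pixel_size_nm = stack$pixel_size,
               z_spacing_nm = stack$z_spacing,
               stack_id = stack$stack_id,
               autofluorescence = stack$autofluorescence)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Read an image stack written by \code{\link{write_stack_tiff}}
#'
#' @param path TIFF path; calibration is read from \code{<path>.json} when
#'   present, otherwise defaults (101.3 nm/px, 150 nm) are used with a
#'   warning.
#' @return An \code{\link{image_stack}}.
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  vox <- array(0, dim = c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) vox[z, , ] <- round(pages[[z]] * 65535)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    image_stack(vox, meta$pixel_size_nm, meta$z_spacing_nm,
                stack_id = meta$stack_id,
                autofluorescence = meta$autofluorescence)
  } else {
    warning("no sidecar metadata for ", path, "; using default calibration")
    image_stack(vox, 304 / 3, 150, stack_id = basename(path))
  }
}

#' Write a FRAP trace as CSV with a JSON sidecar
#'
#' Columns \code{time_s}, \code{I_spot}, \code{I_cell}, \code{I_bg}; the
#' bleach index, trace id and condition go into \code{<path>.json}.
#'
#' @param trace A \code{\link{frap_trace}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_frap_trace <- function(trace, path) {
  stopifnot(inherits(trace, "frap_trace"))
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  jsonlite::write_json(
    list(bleach_index = attr(trace, "bleach_index"),
         trace_id = attr(trace, "trace_id"),
         condition = attr(trace, "condition")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a FRAP trace written by \code{\link{write_frap_trace}}
#'
#' @param path CSV path with a \code{<path>.json} sidecar.
#' @return A \code{\link{frap_trace}}.
#' @export
read_frap_trace <- function(path) {
  df <- read.csv(path)
  need <- c("time_s", "I_spot", "I_cell", "I_bg")
  if (!all(need %in% names(df)))
    stop(path, " lacks required columns ", paste(need, collapse = ", "))
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing sidecar ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  frap_trace(df$time_s, df$I_spot, df$I_cell, df$I_bg,
             bleach_index = meta$bleach_index, trace_id = meta$trace_id,
             condition = meta$condition)
}

#' Write / read single-molecule localization tables
#'
#' CSV with columns \code{frame}, \code{x_um}, \code{y_um}; a
#' \code{molecule_id} column, when present in the input, is written too but
#' ignored by the analysis reader unless \code{keep_molecule_id = TRUE}.
#'
#' @param localizations Data frame of localizations.
#' @param path CSV path.
#' @return \code{path} (writer) or the data frame (reader), invisibly for
#'   the writer.
#' @export
write_localizations <- function(localizations, path) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(localizations)))
  write.csv(localizations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @param keep_molecule_id Keep a ground-truth \code{molecule_id} column if
#'   present (default drops it, since real data carry no identity).
#' @export
read_localizations <- function(path, keep_molecule_id = FALSE) {
  df <- read.csv(path)
  need <- c("frame", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop(path, " lacks required columns ", paste(need, collapse = ", "))
  if (!keep_molecule_id) df <- df[need]
  df[order(df$frame), , drop = FALSE]
}

#' Write a simulation ground-truth manifest
#'
#' Stores the per-entity ground truth as CSV and the generating
#' configuration (including the seed) as JSON, so a simulation can be
#' reproduced and its analysis output checked against truth.
#'
#' @param ground_truth Data frame of per-entity true values.
#' @param config The simulation config object.
#' @param path_prefix Files are written to \code{<path_prefix>.csv} and
#'   \code{<path_prefix>.json}.
#' @return Character vector of the two paths, invisibly.
#' @export
write_ground_truth <- function(ground_truth, config, path_prefix) {
  csv <- paste0(path_prefix, ".csv")
  js <- paste0(path_prefix, ".json")
  write.csv(ground_truth, csv, row.names = FALSE)
  cfg <- unclass(config)
  jsonlite::write_json(list(config_class = class(config)[1], config = cfg),
                       js, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(csv, js))
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path_prefix) {
  gt <- read.csv(paste0(path_prefix, ".csv"))
  meta <- jsonlite::read_json(paste0(path_prefix, ".json"),
                              simplifyVector = TRUE)
  list(ground_truth = gt, config = meta$config,
       config_class = meta$config_class)
}
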