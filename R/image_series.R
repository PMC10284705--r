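#' Multi-channel time-lapse image series
#'
#' Container for a (time x channel x y x x) intensity stack with channel
#' roles, physical pixel size and acquisition-day stamps.
#'
#' @param data 4-D numeric array, dimensions time x channel x y x x.
#' @param channels named integer vector mapping channel roles (e.g. `tumour`,
#'   `tcell`, `gcamp`, `pi`) to channel indices; roles must be unique.
#' @param pixel_size_um physical pixel size (micrometres, > 0).
#' @param days acquisition day per frame; length must equal the time extent.
#' @param labels optional time x y x x integer array of ground-truth tumour
#'   labels (synthetic renders).
#' @return object of class `image_series`.
#' @export
image_series <- function(data, channels, pixel_size_um, days, labels = NULL) {
  if (length(dim(data)) != 4L) stop("data must be a 4-D array (t, c, y, x)")
  if (length(days) != dim(data)[1]) stop("length(days) must equal the time extent")
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (anyDuplicated(channels) || anyDuplicated(names(channels)))
    stop("channel roles must be unique")
  if (any(channels < 1 | channels > dim(data)[2])) stop("channel index out of range")
  x <- list(data = data, channels = channels, pixel_size_um = pixel_size_um,
            days = days, labels = labels)
  class(x) <- "image_series"
  x
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_series: %d frames x %d channels, %d x %d px @ %g um/px\n",
              d[1], d[2], d[3], d[4], x$pixel_size_um))
  cat("channels:", paste(names(x$channels), x$channels, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Extract one frame of one channel
#'
#' @param series an [image_series()].
#' @param frame frame index (1-based).
#' @param channel channel role name or index.
#' @return y x x numeric matrix.
#' @export
get_frame <- function(series, frame, channel) {
  ch <- if (is.character(channel)) {
    if (!channel %in% names(series$channels))
      stop("missing channel role: ", channel)
    series$channels[[channel]]
  } else channel
  series$data[frame, ch, , ]
}

#' Write / read an image series as multi-page TIFFs plus a JSON sidecar
#'
#' One 16-bit multi-page TIFF per channel (`<prefix>_<role>.tif`; intensities
#' are scaled to the 16-bit range, the scale factor is recorded in the
#' sidecar), a label TIFF when ground-truth labels are present, and
#' `<prefix>.json` with pixel size, channel roles, day stamps and scale.
#'
#' @param series an [image_series()].
#' @param prefix output path prefix.
#' @return `read_image_series()` returns an [image_series()].
#' @export
write_image_series <- function(series, prefix) {
  d <- dim(series$data)
  scale <- max(series$data, 1e-12)
  for (role in names(series$channels)) {
    ch <- series$channels[[role]]
    pages <- lapply(seq_len(d[1]), function(t) series$data[t, ch, , ] / scale)
    tiff::writeTIFF(pages, paste0(prefix, "_", role, ".tif"), bits.per.sample = 16L)
  }
  if (!is.null(series$labels)) {
    lmax <- max(series$labels, 1L)
    pages <- lapply(seq_len(d[1]), function(t) series$labels[t, , ] / lmax)
    tiff::writeTIFF(pages, paste0(prefix, "_labels.tif"), bits.per.sample = 16L)
  }
  sidecar <- list(pixel_size_um = series$pixel_size_um, days = series$days,
                  channels = as.list(series$channels), intensity_scale = scale,
                  label_scale = if (is.null(series$labels)) NULL else max(series$labels, 1L))
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_image_series
#' @export
read_image_series <- function(prefix) {
  sidecar <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  roles <- names(sidecar$channels)
  first <- tiff::readTIFF(paste0(prefix, "_", roles[1], ".tif"), all = TRUE)
  nt <- length(first); ny <- nrow(first[[1]]); nx <- ncol(first[[1]])
  data <- array(0, c(nt, length(roles), ny, nx))
  for (role in roles) {
    pages <- tiff::readTIFF(paste0(prefix, "_", role, ".tif"), all = TRUE)
    ch <- sidecar$channels[[role]]
    for (t in seq_len(nt)) data[t, ch, , ] <- pages[[t]] * sidecar$intensity_scale
  }
  labels <- NULL
  lab_path <- paste0(prefix, "_labels.tif")
  if (file.exists(lab_path)) {
    pages <- tiff::readTIFF(lab_path, all = TRUE)
    labels <- array(0L, c(nt, ny, nx))
    for (t in seq_len(nt))
      labels[t, , ] <- as.integer(round(pages[[t]] * sidecar$label_scale))
  }
  image_series(data, unlist(sidecar$channels), sidecar$pixel_size_um,
               sidecar$days, labels)
}
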