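#' Link segmented tumours across timepoints
#'
#' Greedy mutual-nearest-centroid linking from each frame to the next: a
#' track and an object are linked only if each is the other's nearest
#' neighbour and the displacement is within `max_displacement_um`. Tracks
#' with no match are carried forward as "not detected" (they may re-match
#' later at their last known centroid); unmatched objects open new tracks.
#' Every labelled object belongs to exactly one track.
#'
#' @param labels list of integer label matrices, one per frame, or an
#'   [image_series()] with ground-truth labels.
#' @param days acquisition day per frame.
#' @param pixel_size_um physical pixel size.
#' @param max_displacement_um maximum allowed centroid displacement between
#'   consecutive frames.
#' @return object of class `stamp_tracks`: `table` (one row per track x day:
#'   `tumour_id`, `day`, `detected`, `label`, `area_mm2`, `centroid_y`,
#'   `centroid_x`, `feret_um`), plus the label matrices for mask lookup.
#' @export
link_tracks <- function(labels, days = NULL, pixel_size_um = NULL,
                        max_displacement_um = 250) {
  if (inherits(labels, "image_series")) {
    series <- labels
    if (is.null(series$labels)) stop("image series carries no label images")
    labels <- lapply(seq_along(series$days), function(t) series$labels[t, , ])
    if (is.null(days)) days <- series$days
    pixel_size_um <- series$pixel_size_um
  }
  if (length(labels) < 1) stop("need at least one frame")
  if (is.null(days)) days <- seq_along(labels)
  if (is.null(pixel_size_um)) stop("pixel_size_um required")
  max_px <- max_displacement_um / pixel_size_um

  props <- lapply(labels, region_props)
  n_frames <- length(labels)

  ## track state: last known centroid per track; assignment matrix of labels
  track_cy <- track_cx <- numeric(0)
  assign <- matrix(0L, nrow = 0, ncol = n_frames)

  for (t in seq_len(n_frames)) {
    pr <- props[[t]]
    matched_obj <- rep(FALSE, nrow(pr))
    if (length(track_cy) > 0 && nrow(pr) > 0) {
      D <- sqrt(outer(track_cy, pr$cy, "-")^2 + outer(track_cx, pr$cx, "-")^2)
      nn_of_track <- apply(D, 1, which.min)
      nn_of_obj <- apply(D, 2, which.min)
      for (i in seq_along(track_cy)) {
        j <- nn_of_track[i]
        if (nn_of_obj[j] == i && D[i, j] <= max_px) {
          assign[i, t] <- pr$label[j]
          track_cy[i] <- pr$cy[j]; track_cx[i] <- pr$cx[j]
          matched_obj[j] <- TRUE
        }
      }
    }
    for (j in which(!matched_obj)) {
      track_cy <- c(track_cy, pr$cy[j]); track_cx <- c(track_cx, pr$cx[j])
      assign <- rbind(assign, 0L)
      assign[nrow(assign), t] <- pr$label[j]
    }
  }

  rows <- list()
  for (i in seq_len(nrow(assign))) {
    for (t in seq_len(n_frames)) {
      lab <- assign[i, t]
      if (lab > 0L) {
        m <- measure_mask(labels[[t]] == lab, pixel_size_um)
        rows[[length(rows) + 1L]] <- data.frame(
          tumour_id = i, day = days[t], detected = TRUE, label = lab,
          area_mm2 = m$area_mm2, centroid_y = m$centroid[1],
          centroid_x = m$centroid[2], feret_um = m$feret_um)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          tumour_id = i, day = days[t], detected = FALSE, label = 0L,
          area_mm2 = 0, centroid_y = NA_real_, centroid_x = NA_real_,
          feret_um = NA_real_)
      }
    }
  }
  structure(list(table = do.call(rbind, rows), labels = labels, days = days,
                 assign = assign, pixel_size_um = pixel_size_um),
            class = "stamp_tracks")
}

#' @export
print.stamp_tracks <- function(x, ...) {
  cat("stamp_tracks:", nrow(x$assign), "tracks over", length(x$days), "frames\n")
  invisible(x)
}

#' Measure a single tumour mask
#'
#' Area in mm^2 (pixel count x (pixel_size/1000)^2), centroid (row, col, pixel
#' centres) and Feret diameter (maximum pairwise distance between boundary
#' pixel centres, in um; 0 for a single pixel).
#'
#' @param mask logical matrix.
#' @param pixel_size_um pixel size.
#' @return list(area_mm2, centroid, feret_um). An empty mask gives area 0 and
#'   NA geometry.
#' @export
measure_mask <- function(mask, pixel_size_um) {
  n_px <- sum(mask)
  if (n_px == 0)
    return(list(area_mm2 = 0, centroid = c(NA_real_, NA_real_), feret_um = NA_real_))
  idx <- which(mask, arr.ind = TRUE)
  list(area_mm2 = n_px * (pixel_size_um / 1000)^2,
       centroid = c(mean(idx[, 1]), mean(idx[, 2])),
       feret_um = feret_diameter(mask) * pixel_size_um)
}

# Max pairwise distance between boundary pixel centres (in pixels).
feret_diameter <- function(mask) {
  b <- boundary_pixels(mask)
  if (nrow(b) <= 1) return(0)
  hull <- tryCatch(grDevices::chull(b[, 2], b[, 1]), error = function(e) seq_len(nrow(b)))
  pts <- b[hull, , drop = FALSE]
  max(stats::dist(pts))
}

# Pixels of the mask with at least one 4-neighbour outside the mask (or on the
# image border).
boundary_pixels <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  pad <- matrix(FALSE, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- mask
  core <- pad[2:(ny + 1), 2:(nx + 1)]
  interior <- core & pad[1:ny, 2:(nx + 1)] & pad[3:(ny + 2), 2:(nx + 1)] &
    pad[2:(ny + 1), 1:nx] & pad[2:(ny + 1), 3:(nx + 2)]
  which(core & !interior, arr.ind = TRUE)
}

#' Classify a tumour's response from its area series
#'
#' Complete responder (CR) if the tumour is no longer detectable: at least two
#' consecutive undetected frames at the end of the series (a single missing
#' frame is treated as a tracking dropout). Otherwise partial responder (PR)
#' if the last observed area shrank from the maximum by `pr_drop` (default
#' 20%) or more. The remainder are stable vs progressing disease, split at
#' +/- `sd_band` of the initial area; set `merge_sd_pd = TRUE` to report the
#' combined "SD/PD" class.
#'
#' @param area_mm2 per-day areas.
#' @param detected per-day detectability flags (default: all detected).
#' @param pr_drop fractional shrinkage from maximum that defines PR.
#' @param sd_band fractional band around the initial area separating SD from PD.
#' @param merge_sd_pd report "SD/PD" instead of the split labels.
#' @return one of "CR", "PR", "SD", "PD" (or "SD/PD").
#' @export
classify_response <- function(area_mm2, detected = rep(TRUE, length(area_mm2)),
                              pr_drop = 0.2, sd_band = 0.2,
                              merge_sd_pd = FALSE) {
  if (length(area_mm2) < 2) stop("need at least 2 timepoints")
  if (!any(detected)) stop("tumour never detected")
  n <- length(detected)
  trail <- 0L
  while (trail < n && !detected[n - trail]) trail <- trail + 1L
  if (trail >= 2L) return("CR")
  obs <- area_mm2[detected]
  final <- obs[length(obs)]
  if (final <= (1 - pr_drop) * max(obs)) return("PR")
  if (merge_sd_pd) return("SD/PD")
  if (final > (1 + sd_band) * obs[1]) "PD" else "SD"
}
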