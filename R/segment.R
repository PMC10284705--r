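#' Segmentation parameters
#'
#' The segmenter is a classical pluggable stage: Gaussian smoothing, a global
#' threshold (Otsu by default, or a fixed intensity), hole filling, connected
#' components, and removal of objects below an area floor. It is deterministic
#' for fixed input and parameters.
#'
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_threshold absolute intensity threshold for `method = "fixed"`.
#' @param smooth_sigma Gaussian smoothing sigma in pixels.
#' @param min_area_mm2 objects smaller than this are discarded.
#' @return list of class `stamp_segment_params`.
#' @export
segment_params <- function(method = c("otsu", "fixed"), fixed_threshold = NULL,
                           smooth_sigma = 1.5, min_area_mm2 = 0.005) {
  method <- match.arg(method)
  if (method == "fixed" && is.null(fixed_threshold))
    stop("fixed_threshold required for method = 'fixed'")
  structure(list(method = method, fixed_threshold = fixed_threshold,
                 smooth_sigma = smooth_sigma, min_area_mm2 = min_area_mm2),
            class = "stamp_segment_params")
}

#' Segment tumours in one frame
#'
#' @param x an [image_series()] (the `tumour` channel is segmented) or a
#'   plain intensity matrix.
#' @param frame frame index when `x` is an image series.
#' @param params a [segment_params()].
#' @param pixel_size_um pixel size; taken from the series when available.
#' @return integer label matrix, background 0, objects labelled 1..n.
#' @export
segment_frame <- function(x, frame = 1L, params = segment_params(),
                          pixel_size_um = NULL) {
  if (inherits(x, "image_series")) {
    if (!"tumour" %in% names(x$channels)) stop("missing channel role: tumour")
    img <- get_frame(x, frame, "tumour")
    pixel_size_um <- x$pixel_size_um
  } else img <- x
  if (is.null(pixel_size_um)) stop("pixel_size_um required for the area floor")

  sm <- img
  if (params$smooth_sigma > 0)
    sm <- EBImage::imageData(EBImage::gblur(img, sigma = params$smooth_sigma))
  rng <- range(sm)
  if (diff(rng) < 1e-9) return(matrix(0L, nrow(img), ncol(img)))

  thr <- if (params$method == "otsu") {
    norm <- (sm - rng[1]) / diff(rng)
    EBImage::otsu(EBImage::Image(norm), range = c(0, 1)) * diff(rng) + rng[1]
  } else params$fixed_threshold
  mask <- sm > thr
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask))) > 0
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))

  min_px <- params$min_area_mm2 / (pixel_size_um / 1000)^2
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_px)
  out <- matrix(0L, nrow(img), ncol(img))
  for (j in seq_along(keep)) out[lab == keep[j]] <- j
  out
}

# Per-object area (px) and centroid (row, col of pixel centres) of a label
# image; label ids need not be contiguous (absent ids are skipped).
region_props <- function(labels) {
  n <- max(labels)
  if (n == 0) return(data.frame(label = integer(), area_px = integer(),
                                cy = numeric(), cx = numeric()))
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  area <- tabulate(lab, n)
  present <- which(area > 0)
  sy <- rowsum(as.numeric(idx[, 1]), lab)[, 1]
  sx <- rowsum(as.numeric(idx[, 2]), lab)[, 1]
  data.frame(label = present, area_px = area[present],
             cy = sy / area[present], cx = sx / area[present])
}
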