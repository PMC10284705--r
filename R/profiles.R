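#' Median radial fluorescence profile of a tumour
#'
#' Every in-mask pixel is assigned a normalized radius: distance to the mask
#' centroid divided by the equivalent radius sqrt(area/pi), clipped to
#' \[0, 1\]. The radius axis is split into `n_bins` equal-width bins and the
#' per-bin median of the T-cell channel intensities is returned.
#'
#' @param img intensity matrix (T-cell channel).
#' @param mask logical tumour mask, same dimensions, non-empty.
#' @param n_bins number of radial bins.
#' @return object of class `radial_profile`: list(bin_edges, median_intensity,
#'   n_px). Empty bins hold NA medians.
#' @export
radial_profile <- function(img, mask, n_bins = 20) {
  rn <- normalized_radius(mask)
  if (is.null(rn)) stop("empty mask")
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- findInterval(rn$r, edges, rightmost.closed = TRUE, all.inside = TRUE)
  vals <- img[rn$idx]
  med <- rep(NA_real_, n_bins)
  npx <- integer(n_bins)
  for (b in unique(bin)) {
    med[b] <- stats::median(vals[bin == b])
    npx[b] <- sum(bin == b)
  }
  structure(list(bin_edges = edges, median_intensity = med, n_px = npx),
            class = "radial_profile")
}

# normalized radius of each in-mask pixel: distance to centroid / sqrt(A/pi),
# clipped to [0,1]; returns NULL on an empty mask.
normalized_radius <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  r_eq <- sqrt(nrow(idx) / pi)
  r <- pmin(sqrt((idx[, 1] - cy)^2 + (idx[, 2] - cx)^2) / r_eq, 1)
  list(r = r, idx = which(mask), arr = idx)
}

#' Median T-cell intensity in the tumour core
#'
#' Median over in-mask pixels with normalized radius at most `core_fraction`
#' (the "inner 25%" of the radius by default).
#'
#' @inheritParams radial_profile
#' @param core_fraction normalized-radius cut-off defining the core.
#' @return numeric median intensity.
#' @export
core_median <- function(img, mask, core_fraction = 0.25) {
  rn <- normalized_radius(mask)
  if (is.null(rn)) stop("empty mask")
  sel <- rn$r <= core_fraction
  if (!any(sel)) return(NA_real_)
  stats::median(img[rn$idx][sel])
}

#' T cell abundance index
#'
#' Per-day MFI = mean T-cell intensity within the tumour mask; the index is
#' the median of those MFIs across timepoints.
#'
#' @param imgs list of per-day T-cell intensity matrices.
#' @param masks list of per-day logical masks (empty masks are skipped).
#' @return numeric index.
#' @export
abundance_index <- function(imgs, masks) {
  stopifnot(length(imgs) == length(masks))
  mfi <- mapply(function(im, m) if (sum(m) == 0) NA_real_ else mean(im[m]),
                imgs, masks)
  mfi <- mfi[!is.na(mfi)]
  if (length(mfi) == 0) stop("no day with a non-empty mask")
  stats::median(mfi)
}

#' T cell infiltration index (centre / periphery)
#'
#' The tumour centre holds the central 50% of the mask area (in-mask pixels
#' with normalized radius <= sqrt(0.5)); the periphery holds out-of-mask
#' pixels within `max_dist_um` of the mask border, excluding pixels belonging
#' to any other tumour. Per-day MFIs are computed in each region and the index
#' is the ratio of their across-day medians (centre / periphery).
#'
#' @param imgs list of per-day T-cell intensity matrices.
#' @param masks list of per-day logical tumour masks.
#' @param pixel_size_um pixel size.
#' @param other_masks optional list of logical masks of all other tumours,
#'   excluded from the periphery.
#' @param max_dist_um periphery reach beyond the tumour border (um).
#' @return numeric index; NA with a warning when the periphery median is 0.
#' @export
infiltration_index <- function(imgs, masks, pixel_size_um, other_masks = NULL,
                               max_dist_um = 50) {
  stopifnot(length(imgs) == length(masks))
  centre_mfi <- peri_mfi <- rep(NA_real_, length(imgs))
  for (t in seq_along(imgs)) {
    m <- masks[[t]]
    if (sum(m) == 0) next
    rn <- normalized_radius(m)
    centre_sel <- rn$r <= sqrt(0.5)
    if (!any(centre_sel)) next
    centre_mfi[t] <- mean(imgs[[t]][rn$idx][centre_sel])
    dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(!m)))
    peri <- !m & dm * pixel_size_um <= max_dist_um
    if (!is.null(other_masks)) peri <- peri & !other_masks[[t]]
    if (any(peri)) peri_mfi[t] <- mean(imgs[[t]][peri])
  }
  if (all(is.na(centre_mfi))) stop("centre region empty on all days")
  num <- stats::median(centre_mfi, na.rm = TRUE)
  den <- stats::median(peri_mfi, na.rm = TRUE)
  if (is.na(den) || den == 0) {
    warning("periphery median is 0; infiltration index undefined")
    return(NA_real_)
  }
  num / den
}

#' T cell infiltration ratio (core / profile maximum)
#'
#' Numerator: median T-cell intensity over in-mask pixels with normalized
#' radius <= `core_fraction`. Denominator: maximum of the median radial
#' profile. By construction the ratio lies in \[0, ~1\].
#'
#' @inheritParams radial_profile
#' @param core_fraction core cut-off on the normalized radius.
#' @return numeric ratio; 0 (with a warning) when the profile maximum is 0.
#' @export
infiltration_ratio <- function(img, mask, n_bins = 20, core_fraction = 0.25) {
  prof <- radial_profile(img, mask, n_bins)
  num <- core_median(img, mask, core_fraction)
  den <- max(prof$median_intensity, na.rm = TRUE)
  if (is.na(den) || den == 0) {
    warning("profile maximum is 0; infiltration ratio set to 0")
    return(0)
  }
  num / den
}
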