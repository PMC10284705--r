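#' Calcium influx index, in vivo epifluorescence
#'
#' For each channel, S(t) is the sum of in-mask pixel intensities per frame;
#' the average absolute delta D = mean |S(t+1) - S(t)| is normalized by the
#' channel's mean in-mask MFI across frames (N = D / MFI). The index is the
#' ratio N_gcamp / N_reference, quantifying calcium-sensor dynamics relative
#' to the stable tumour reporter.
#'
#' @param gcamp pixels x frames matrix of in-mask calcium-sensor intensities.
#' @param reference pixels x frames matrix of the tumour reporter channel
#'   over the same mask support.
#' @return numeric index (>= 0); NA with a warning when the reference channel
#'   is degenerate (zero normalized delta).
#' @export
ca_index_epifluorescence <- function(gcamp, reference) {
  n_g <- normalized_delta_sum(gcamp)
  n_r <- normalized_delta_sum(reference)
  if (is.na(n_r) || n_r == 0) {
    warning("reference channel degenerate; index undefined")
    return(NA_real_)
  }
  n_g / n_r
}

# mean |consecutive difference| of per-frame intensity sums, divided by the
# across-frame mean MFI of the channel
normalized_delta_sum <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 frames")
  s <- colSums(x)
  d <- mean(abs(diff(s)))
  mfi <- mean(colMeans(x))
  if (mfi == 0) return(NA_real_)
  d / mfi
}

#' Calcium influx index, in vivo two-photon
#'
#' value1 is the epifluorescence-style ratio of normalized average delta sums;
#' value2 is the mean (over pixels) temporal standard deviation of the calcium
#' channel divided by that of the reference channel. The two-photon index is
#' value1 x value2.
#'
#' @inheritParams ca_index_epifluorescence
#' @return numeric index; NA with a warning when the reference temporal SD
#'   is 0.
#' @export
ca_index_two_photon <- function(gcamp, reference) {
  v1 <- ca_index_epifluorescence(gcamp, reference)
  sd_g <- mean(apply(as.matrix(gcamp), 1, stats::sd))
  sd_r <- mean(apply(as.matrix(reference), 1, stats::sd))
  if (sd_r == 0) {
    warning("reference temporal SD is 0; index undefined")
    return(NA_real_)
  }
  v1 * (sd_g / sd_r)
}

#' Calcium influx index, in vitro spinning-disk confocal
#'
#' M(t) is the median over cell isosurfaces of per-cell calcium MFIs at frame
#' t. The index is the mean absolute consecutive delta of M divided by the
#' mean of M across frames.
#'
#' @param mfi cells x frames matrix of per-cell MFIs, or a numeric vector
#'   already reduced to the per-frame median M(t).
#' @return numeric index; NA with a warning when mean M is 0.
#' @export
ca_index_confocal <- function(mfi) {
  delta_median_index(mfi)
}

#' Propidium-iodide influx index, in vitro spinning-disk confocal
#'
#' Identical construction to [ca_index_confocal()] applied to the PI channel:
#' average absolute delta of the per-frame median PI MFI, divided by the mean
#' PI MFI across frames.
#'
#' @param mfi cells x frames matrix of per-cell PI MFIs, or the per-frame
#'   median vector.
#' @return numeric index; NA with a warning when the mean MFI is 0.
#' @export
pi_influx_index <- function(mfi) {
  delta_median_index(mfi)
}

delta_median_index <- function(mfi) {
  m <- if (is.matrix(mfi)) apply(mfi, 2, stats::median) else as.numeric(mfi)
  if (length(m) < 2) stop("need at least 2 frames")
  denom <- mean(m)
  if (denom == 0) {
    warning("mean MFI is 0; index undefined")
    return(NA_real_)
  }
  mean(abs(diff(m))) / denom
}

#' Extract in-mask pixel series from an image series
#'
#' Builds the pixels x frames matrices the influx indices consume. The mask is
#' held fixed across the movie (the acquisition-time segmentation); per-frame
#' re-segmentation can be performed upstream and passed as separate calls.
#'
#' @param series an [image_series()].
#' @param mask logical matrix selecting the tumour isosurface.
#' @param channel channel role (e.g. `"gcamp"`, `"tumour"`, `"tcell"`).
#' @return pixels x frames numeric matrix.
#' @export
calcium_series <- function(series, mask, channel) {
  if (sum(mask) == 0) stop("empty mask")
  nt <- dim(series$data)[1]
  out <- matrix(0, sum(mask), nt)
  for (t in seq_len(nt)) out[, t] <- get_frame(series, t, channel)[mask]
  out
}
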