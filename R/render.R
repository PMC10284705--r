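#' Regular array layout for rendered microtumour cohorts
#'
#' Tumour centres on an n_rows x n_cols grid with spacing `pitch_um`,
#' optionally jittered. The pitch must leave room for the largest rendered
#' tumour plus its peritumoral annulus; [render_timelapse()] enforces this.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param pitch_um centre-to-centre spacing (um).
#' @param jitter_um uniform positional jitter (um, applied per tumour).
#' @param seed seed for the jitter draws.
#' @return object of class `stamp_layout` with a `positions` matrix (y, x in um).
#' @export
array_layout <- function(n_rows, n_cols, pitch_um = 2500, jitter_um = 0, seed = 1L) {
  if (n_rows < 1 || n_cols < 1 || pitch_um <= 0 || jitter_um < 0)
    stop("invalid layout parameters")
  g <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  pos <- cbind(y = (g$row - 0.5) * pitch_um, x = (g$col - 0.5) * pitch_um)
  if (jitter_um > 0) {
    set.seed(as.integer(seed))
    pos <- pos + matrix(stats::runif(length(pos), -jitter_um, jitter_um), ncol = 2)
  }
  structure(list(n_rows = n_rows, n_cols = n_cols, pitch_um = pitch_um,
                 jitter_um = jitter_um, positions = pos),
            class = "stamp_layout")
}

#' Imaging parameters for the synthetic renderer
#'
#' @param pixel_size_um physical pixel size.
#' @param tumour_amp peak tumour-reporter intensity.
#' @param tumour_background camera background added to the tumour channel.
#' @param tcell_amp peak T-cell channel intensity at emission abundance 100.
#' @param tcell_diffuse_frac fraction of `tcell_amp` rendered as diffuse
#'   in-mask signal for excluded tumours (T cells bleeding past the rim).
#' @param gcamp_baseline baseline calcium-sensor intensity inside tumours.
#' @param gcamp_flash_amp peak intensity of a calcium flash event.
#' @param flash_sigma_frac flash spot Gaussian sigma as a fraction of the
#'   tumour equivalent radius.
#' @param rim_width_frac half-width of the excluded T-cell annulus as a
#'   fraction of the equivalent radius (annulus spans (1-w)..(1+w) r).
#' @param edge_exponent steepness q of the tumour radial falloff
#'   exp(-log(2) (d/r)^q); intensity is half-maximal at the true radius so
#'   thresholded area tracks ground-truth area.
#' @return list of class `stamp_imaging`.
#' @export
imaging_params <- function(pixel_size_um = 25, tumour_amp = 3000,
                           tumour_background = 50, tcell_amp = 2000,
                           tcell_diffuse_frac = 0.08, gcamp_baseline = 300,
                           gcamp_flash_amp = 4000, flash_sigma_frac = 0.15,
                           rim_width_frac = 0.2, edge_exponent = 12) {
  structure(as.list(environment()), class = "stamp_imaging")
}

#' Render a synthetic cohort as a multi-channel time-lapse stack
#'
#' Produces an [image_series()] with tumour-reporter, T-cell and calcium
#' channels plus a ground-truth label image per frame. Tumours are radially
#' symmetric blobs whose half-maximum contour matches the true area. The
#' T-cell channel encodes the phenotype: desert tumours get no T-cell signal,
#' excluded tumours an annulus centred on the mask boundary (with a faint
#' diffuse in-mask component), inflamed tumours a uniformly filled disc;
#' resolved tumours leave a residual T-cell cluster. The calcium channel is
#' baseline plus Poisson-count transient flash events. Detector noise
#' (Gaussian and/or scaled-Poisson) is applied last.
#'
#' @param cohort a `stamp_cohort` or trajectory data.frame with columns
#'   `tumour_id`, `day`, `area_mm2`, `phenotype_code` and optionally
#'   `abundance` (scales T-cell intensity) and `detected`.
#' @param layout an [array_layout()]; must accommodate all tumours without
#'   overlap of rendered masks.
#' @param imaging an [imaging_params()].
#' @param flash_rate named expected flash events per frame per state; taken
#'   from the cohort's scenario when available.
#' @param noise list(gaussian_sd, poisson_gain); taken from the scenario when
#'   available.
#' @param seed seed for flash and noise draws.
#' @return an [image_series()] with channels `tumour`, `tcell`, `gcamp` and a
#'   `labels` array.
#' @export
render_timelapse <- function(cohort, layout, imaging = imaging_params(),
                             flash_rate = NULL, noise = NULL, seed = 1L) {
  traj <- if (inherits(cohort, "stamp_cohort")) cohort$trajectories else cohort
  cfg <- if (inherits(cohort, "stamp_cohort")) cohort$config else NULL
  if (is.null(flash_rate))
    flash_rate <- if (!is.null(cfg)) cfg$flash_rate else
      c(desert = 0, excluded = 0, inflamed = 0, resolved = 0, death = 0)
  if (is.null(noise))
    noise <- if (!is.null(cfg)) cfg$noise else list(gaussian_sd = 0, poisson_gain = 0)

  ids <- sort(unique(traj$tumour_id))
  if (length(ids) > nrow(layout$positions))
    stop("layout error: layout holds ", nrow(layout$positions),
         " positions for ", length(ids), " tumours")
  px <- imaging$pixel_size_um
  days <- sort(unique(traj$day))
  ny <- ceiling(layout$n_rows * layout$pitch_um / px)
  nx <- ceiling(layout$n_cols * layout$pitch_um / px)

  ## layout precondition: no two rendered masks may touch
  r_max_um <- sqrt(max(traj$area_mm2) / pi) * 1000
  pos <- layout$positions[seq_along(ids), , drop = FALSE]
  if (length(ids) > 1) {
    dmin <- min(stats::dist(pos))
    if (dmin <= 2 * r_max_um * (1 + imaging$rim_width_frac))
      stop("layout error: minimum centre distance ", round(dmin),
           " um cannot accommodate tumours of radius ", round(r_max_um), " um")
  }

  data <- array(0, c(length(days), 3L, ny, nx))
  labels <- array(0L, c(length(days), ny, nx))
  states_by_code <- stats::setNames(tip_states(), as.character(tip_codes()))
  rmax_px <- vapply(ids, function(id)
    sqrt(max(traj$area_mm2[traj$tumour_id == id]) / pi) * 1000 / px, 0)

  set.seed(as.integer(seed))
  for (ti in seq_along(days)) {
    tum <- matrix(imaging$tumour_background, ny, nx)
    tcell <- matrix(0, ny, nx)
    gcamp <- matrix(0, ny, nx)
    lab <- matrix(0L, ny, nx)
    rows_t <- traj[traj$day == days[ti], , drop = FALSE]
    for (k in seq_len(nrow(rows_t))) {
      row <- rows_t[k, ]
      i <- match(row$tumour_id, ids)
      state <- states_by_code[[as.character(row$phenotype_code)]]
      if (state == "death") next
      cy <- pos[i, "y"] / px
      cx <- pos[i, "x"] / px
      r_px <- sqrt(row$area_mm2 / pi) * 1000 / px
      ab_scale <- if (!is.null(row$abundance) && !is.na(row$abundance))
        row$abundance / 100 else 1

      half <- ceiling(max(r_px, 0.6 * rmax_px[i]) * (1 + imaging$rim_width_frac)) + 2L
      ys <- max(1L, floor(cy - half)):min(ny, ceiling(cy + half))
      xs <- max(1L, floor(cx - half)):min(nx, ceiling(cx + half))
      d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))

      if (r_px >= 0.5) {
        prof <- exp(-log(2) * (d / r_px)^imaging$edge_exponent)
        tum[ys, xs] <- tum[ys, xs] + imaging$tumour_amp * prof
        gcamp[ys, xs] <- gcamp[ys, xs] + imaging$gcamp_baseline * prof
        inside <- d <= r_px
        if (any(lab[ys, xs][inside] != 0L))
          stop("layout error: rendered tumour masks overlap")
        lab[ys, xs][inside] <- i
      }

      tc <- matrix(0, length(ys), length(xs))
      amp_i <- imaging$tcell_amp * ab_scale
      w <- imaging$rim_width_frac
      if (state == "excluded" && r_px >= 0.5) {
        tc[d >= (1 - w) * r_px & d <= (1 + w) * r_px] <- amp_i
        tc[d < (1 - w) * r_px] <- imaging$tcell_diffuse_frac * amp_i
      } else if (state == "inflamed" && r_px >= 0.5) {
        tc[d <= r_px] <- amp_i
      } else if (state == "resolved") {
        tc[d <= 0.6 * rmax_px[i]] <- amp_i
      }
      tcell[ys, xs] <- tcell[ys, xs] + tc

      ## calcium flash events: Poisson count per frame
      lambda <- flash_rate[[state]]
      n_fl <- stats::rpois(1, lambda)
      if (n_fl > 0 && r_px >= 1) {
        for (f in seq_len(n_fl)) {
          theta <- stats::runif(1, 0, 2 * pi)
          rr <- sqrt(stats::runif(1)) * 0.8 * r_px
          fy <- cy + rr * sin(theta); fx <- cx + rr * cos(theta)
          sig <- imaging$flash_sigma_frac * r_px
          dd <- outer((ys - fy)^2, (xs - fx)^2, "+")
          gcamp[ys, xs] <- gcamp[ys, xs] +
            imaging$gcamp_flash_amp * exp(-dd / (2 * sig^2))
        }
      }
    }
    chans <- list(tum, tcell, gcamp)
    for (ci in 1:3) {
      x <- chans[[ci]]
      if (noise$poisson_gain > 0)
        x <- matrix(stats::rpois(length(x), x / noise$poisson_gain) *
                      noise$poisson_gain, ny, nx)
      if (noise$gaussian_sd > 0)
        x <- x + matrix(stats::rnorm(length(x), 0, noise$gaussian_sd), ny, nx)
      data[ti, ci, , ] <- pmax(x, 0)
    }
    labels[ti, , ] <- lab
  }
  image_series(data, c(tumour = 1L, tcell = 2L, gcamp = 3L),
               pixel_size_um = px, days = days, labels = labels)
}
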