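#' Ratiometric inflamed / excluded call from a radial profile
#'
#' A tumour is called inflamed when the radial profile within the inner
#' `core_fraction` of the normalized radius is consistently greater than
#' `hi` (60%) of the profile maximum, and excluded when it is consistently
#' less than `lo` (40%) of the maximum. "Consistently" is read strictly: every
#' non-empty inner bin must satisfy the cut-off (`consistent = "all"`); the
#' laxer reading requiring 80% of inner bins is available. Profiles with a
#' non-positive maximum are indeterminate.
#'
#' @param profile a [radial_profile()].
#' @param core_fraction inner-radius fraction defining the core bins.
#' @param hi,lo inflamed / excluded cut-offs as fractions of the maximum.
#' @param consistent `"all"` (strict) or `"frac80"`.
#' @return one of `"inflamed"`, `"excluded"`, `"indeterminate"`.
#' @export
ratiometric_call <- function(profile, core_fraction = 0.25, hi = 0.6, lo = 0.4,
                             consistent = c("all", "frac80")) {
  consistent <- match.arg(consistent)
  med <- profile$median_intensity
  mx <- suppressWarnings(max(med, na.rm = TRUE))
  if (!is.finite(mx) || mx <= 0) return("indeterminate")
  inner <- med[profile$bin_edges[-1] <= core_fraction + 1e-9]
  inner <- inner[!is.na(inner)]
  if (length(inner) == 0) return("indeterminate")
  ok <- function(flags) if (consistent == "all") all(flags) else mean(flags) >= 0.8
  if (ok(inner > hi * mx)) return("inflamed")
  if (ok(inner < lo * mx)) return("excluded")
  "indeterminate"
}

#' Cohort-referenced classification thresholds
#'
#' The desert threshold is the 25th percentile (linear interpolation,
#' `quantile` type 7) of the per-tumour median T-cell intensities on the
#' first imaging day; it is computed once and frozen. The inflamed core
#' reference is the median core intensity of all tumours whose ratiometric
#' call is inflamed, recomputed each day; when a day has no inflamed tumour
#' the reclassification rule is disabled for that day (`NA` reference).
#'
#' @param first_day_medians per-tumour median T-cell intensities on the first
#'   imaging day.
#' @param core_medians per-tumour core intensities for the day under
#'   consideration (optional).
#' @param calls the corresponding ratiometric calls (optional).
#' @return list(desert_threshold, inflamed_core_median,
#'   reclassification_enabled).
#' @export
compute_cohort_refs <- function(first_day_medians, core_medians = NULL,
                                calls = NULL) {
  if (length(first_day_medians) == 0) stop("no first-day medians")
  thr <- unname(stats::quantile(first_day_medians, 0.25, type = 7, names = FALSE))
  ref <- NA_real_
  if (!is.null(core_medians) && !is.null(calls)) {
    infl <- calls == "inflamed" & !is.na(core_medians)
    if (any(infl)) ref <- stats::median(core_medians[infl])
  }
  list(desert_threshold = thr, inflamed_core_median = ref,
       reclassification_enabled = !is.na(ref))
}

#' Classify one tumour-day
#'
#' Applies the full rule precedence: (i) ratiometric inflamed; (ii)
#' ratiometric excluded but core intensity above the inflamed core reference,
#' reclassified as inflamed; (iii) ratiometric excluded; (iv) indeterminate
#' with median intensity below the cohort desert threshold, desert; (v)
#' otherwise the previous day's phenotype is propagated forward (on the first
#' day, with no previous phenotype, an indeterminate non-desert tumour
#' defaults to excluded, the modal early state).
#'
#' @param call ratiometric call for the day ([ratiometric_call()]).
#' @param tumour_median the tumour's median T-cell intensity.
#' @param core_med the tumour's core (inner 25%) median T-cell intensity.
#' @param refs a [compute_cohort_refs()] list for the day.
#' @param prev_code previous day's integer code, or NA on the first day.
#' @return list(code, tag); tags are one of `inflamed-rule`, `reclassified`,
#'   `excluded-rule`, `desert-rule`, `propagated`, `default-excluded`.
#' @export
classify_day <- function(call, tumour_median, core_med, refs, prev_code = NA) {
  if (call == "inflamed")
    return(list(code = 3L, tag = "inflamed-rule"))
  if (call == "excluded") {
    if (!is.na(refs$inflamed_core_median) && !is.na(core_med) &&
        core_med > refs$inflamed_core_median)
      return(list(code = 3L, tag = "reclassified"))
    return(list(code = 2L, tag = "excluded-rule"))
  }
  if (!is.na(tumour_median) && tumour_median < refs$desert_threshold)
    return(list(code = 1L, tag = "desert-rule"))
  if (!is.na(prev_code))
    return(list(code = as.integer(prev_code), tag = "propagated"))
  list(code = 2L, tag = "default-excluded")
}

#' Pad a per-day code sequence with resolution and death codes
#'
#' From `resolved_day` onward codes become 5; from `death_day` onward codes
#' become 0. When both apply, death wins from its own day onward (it
#' overrides resolution only if it occurs first or the same day).
#'
#' @param codes integer codes for the classified days (may be shorter than
#'   `horizon`; missing trailing days are filled by the padding rules, or by
#'   the last code when no event applies).
#' @param horizon total number of days.
#' @param resolved_day first day the tumour counts as resolved (NA if never).
#' @param death_day first day the mouse is dead (NA if never).
#' @return integer vector of length `horizon`.
#' @export
encode_timeline <- function(codes, horizon = length(codes),
                            resolved_day = NA, death_day = NA) {
  out <- rep(NA_integer_, horizon)
  out[seq_along(codes)] <- as.integer(codes)
  if (anyNA(out)) {
    last <- max(which(!is.na(out)))
    out[is.na(out)] <- out[last]
  }
  if (!is.na(resolved_day) && !is.na(death_day)) {
    if (death_day <= resolved_day) resolved_day <- NA else death_day <- NA
  }
  if (!is.na(resolved_day) && resolved_day <= horizon)
    out[resolved_day:horizon] <- 5L
  if (!is.na(death_day) && death_day <= horizon)
    out[death_day:horizon] <- 0L
  out
}

#' Phenotype timelines container
#'
#' @param codes n_tumours x n_days integer code matrix.
#' @param days day stamps (default 1..n_days).
#' @param provenance optional character matrix of per-day rule tags.
#' @param tumour_ids tumour identifiers.
#' @param refs optional list of cohort references used during classification.
#' @return object of class `stamp_timelines`.
#' @export
phenotype_timelines <- function(codes, days = seq_len(ncol(codes)),
                                provenance = NULL,
                                tumour_ids = seq_len(nrow(codes)),
                                refs = NULL) {
  codes <- matrix(as.integer(codes), nrow(codes), ncol(codes))
  bad <- !codes %in% c(0L, 1L, 2L, 3L, 5L)
  if (any(bad)) stop("phenotype code outside alphabet {0,1,2,3,5}")
  for (i in seq_len(nrow(codes))) {
    for (a in absorbing_codes()) {
      first <- which(codes[i, ] == a)[1]
      if (!is.na(first) && first < ncol(codes) &&
          any(codes[i, (first + 1):ncol(codes)] != a))
        stop("absorbing-state closure violated in tumour ", tumour_ids[i])
    }
  }
  structure(list(codes = codes, days = days, provenance = provenance,
                 tumour_ids = tumour_ids, refs = refs),
            class = "stamp_timelines")
}

#' @export
print.stamp_timelines <- function(x, ...) {
  cat("stamp_timelines:", nrow(x$codes), "tumours x", ncol(x$codes), "days\n")
  print(table(factor(x$codes, levels = tip_codes(), labels = tip_states())))
  invisible(x)
}

#' Classify tumour immune phenotypes from an imaged, tracked cohort
#'
#' Full classification pipeline over an image series and its tracks: per
#' tumour-day median radial profiles and median/core intensities of the
#' T-cell channel; the frozen first-day desert threshold; two passes per day
#' (ratiometric calls, then reclassification against that day's inflamed core
#' reference); rule precedence as in [classify_day()]; propagation across
#' undetected days; and resolution padding for tumours that disappear for at
#' least `cr_min_undetected` trailing frames.
#'
#' @param series an [image_series()] with a `tcell` channel.
#' @param tracks a [link_tracks()] result on the same series.
#' @param n_bins radial profile bins.
#' @param core_fraction inner-radius core fraction.
#' @param cr_min_undetected trailing undetected frames required to call a
#'   resolution (guards against single-frame dropouts).
#' @param death_day optional per-tumour first day of mouse death.
#' @param ... passed to [ratiometric_call()].
#' @return a [phenotype_timelines()] with provenance tags and the cohort
#'   references in `$refs`.
#' @export
classify_tip <- function(series, tracks, n_bins = 20, core_fraction = 0.25,
                         cr_min_undetected = 2L, death_day = NULL, ...) {
  if (!"tcell" %in% names(series$channels)) stop("missing channel role: tcell")
  n_tum <- nrow(tracks$assign)
  n_day <- length(tracks$days)
  if (is.null(death_day)) death_day <- rep(NA_integer_, n_tum)

  prof <- vector("list", n_tum * n_day)
  dim(prof) <- c(n_tum, n_day)
  med <- core <- matrix(NA_real_, n_tum, n_day)
  for (t in seq_len(n_day)) {
    img <- get_frame(series, t, "tcell")
    for (i in seq_len(n_tum)) {
      lab <- tracks$assign[i, t]
      if (lab == 0L) next
      mask <- tracks$labels[[t]] == lab
      prof[[i, t]] <- radial_profile(img, mask, n_bins)
      med[i, t] <- stats::median(img[mask])
      core[i, t] <- core_median(img, mask, core_fraction)
    }
  }

  first_day_medians <- med[, 1][!is.na(med[, 1])]
  if (length(first_day_medians) == 0)
    stop("no tumour detected on the first imaging day")
  thr <- compute_cohort_refs(first_day_medians)$desert_threshold

  codes <- matrix(NA_integer_, n_tum, n_day)
  tags <- matrix(NA_character_, n_tum, n_day)
  inflamed_ref_by_day <- rep(NA_real_, n_day)
  for (t in seq_len(n_day)) {
    calls <- rep(NA_character_, n_tum)
    for (i in seq_len(n_tum))
      if (!is.null(prof[[i, t]]))
        calls[i] <- ratiometric_call(prof[[i, t]], core_fraction, ...)
    refs <- compute_cohort_refs(first_day_medians, core[, t], calls)
    refs$desert_threshold <- thr
    inflamed_ref_by_day[t] <- refs$inflamed_core_median
    for (i in seq_len(n_tum)) {
      prev <- if (t > 1) codes[i, t - 1] else NA_integer_
      if (is.na(calls[i])) {   # undetected this frame
        if (!is.na(prev)) { codes[i, t] <- prev; tags[i, t] <- "propagated" }
        next
      }
      res <- classify_day(calls[i], med[i, t], core[i, t], refs, prev)
      codes[i, t] <- res$code
      tags[i, t] <- res$tag
    }
  }

  ## resolution: trailing undetected run of sufficient length => code 5 onward
  for (i in seq_len(n_tum)) {
    det <- tracks$assign[i, ] > 0L
    trail <- 0L
    while (trail < n_day && !det[n_day - trail]) trail <- trail + 1L
    resolved_day <- if (trail >= cr_min_undetected && trail < n_day)
      n_day - trail + 1L else NA_integer_
    dd <- death_day[i]
    if (!is.na(resolved_day) && !is.na(dd)) {
      if (dd <= resolved_day) resolved_day <- NA_integer_ else dd <- NA_integer_
    }
    codes[i, ] <- encode_timeline(codes[i, ], n_day, resolved_day, dd)
    if (!is.na(resolved_day))
      tags[i, resolved_day:n_day] <- "resolved"
    if (!is.na(dd) && dd <= n_day)
      tags[i, dd:n_day] <- "death"
  }
  ## leading undetected frames (tumour not yet seen): no code can be assigned
  if (anyNA(codes)) {
    for (i in seq_len(n_tum)) {
      nas <- which(is.na(codes[i, ]))
      if (length(nas) > 0) {
        first_obs <- which(!is.na(codes[i, ]))[1]
        codes[i, nas] <- codes[i, first_obs]
        tags[i, nas] <- "propagated"
      }
    }
  }
  phenotype_timelines(codes, tracks$days, tags,
                      refs = list(desert_threshold = thr,
                                  inflamed_core_median = inflamed_ref_by_day))
}

#' Write timelines as CSV (tumour_id, day, code, rule_tag)
#'
#' @param timelines a [phenotype_timelines()].
#' @param path CSV path.
#' @export
write_timelines <- function(timelines, path) {
  n <- nrow(timelines$codes)
  df <- data.frame(
    tumour_id = rep(timelines$tumour_ids, each = ncol(timelines$codes)),
    day = rep(timelines$days, n),
    code = as.vector(t(timelines$codes)),
    rule_tag = if (is.null(timelines$provenance)) NA_character_ else
      as.vector(t(timelines$provenance)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
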