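#' Default daily transition matrix for the immunocompetent control scenario
#'
#' Row-stochastic matrix of daily transition probabilities between the five
#' phenotype states (order `tip_states()`). The default is calibrated so that,
#' together with [default_start_probs()], the first-passage probability into
#' the resolved state by day 14 is ~30% — the spontaneous rejection fraction
#' observed in immunocompetent hosts. Resolved and death rows are absorbing.
#'
#' @return 5x5 numeric matrix with dimnames `tip_states()`.
#' @export
default_transition_matrix <- function() {
  s <- tip_states()
  m <- rbind(
    desert   = c(0.88, 0.080, 0.020, 0.005, 0.015),
    excluded = c(0.05, 0.835, 0.080, 0.015, 0.020),
    inflamed = c(0.02, 0.100, 0.770, 0.090, 0.020),
    resolved = c(0.00, 0.000, 0.000, 1.000, 0.000),
    death    = c(0.00, 0.000, 0.000, 0.000, 1.000)
  )
  dimnames(m) <- list(s, s)
  m
}

#' @rdname default_transition_matrix
#' @export
default_start_probs <- function() {
  c(desert = 0.15, excluded = 0.60, inflamed = 0.25, resolved = 0, death = 0)
}

#' Per-phenotype emission parameters
#'
#' Mean T-cell abundance (arbitrary fluorescence units) and mean core
#' infiltration fraction emitted for each phenotype state by the synthetic
#' cohort generator. Values are chosen so that the downstream classifier's
#' decision regions are realizable (deserts far below the cohort 25th
#' percentile; excluded cores well under the 40% ratiometric cut-off;
#' inflamed cores above 60%); they are not calibrated to real MFIs.
#'
#' @return data.frame with columns `state`, `abundance_mean`, `core_fraction`.
#' @export
default_emission <- function() {
  data.frame(
    state          = tip_states(),
    abundance_mean = c(15, 90, 160, 120, NA),
    core_fraction  = c(0.50, 0.15, 0.85, 0.90, NA),
    stringsAsFactors = FALSE
  )
}

#' Scenario configuration for the synthetic cohort generator
#'
#' Bundles everything the generator needs: the daily phenotype transition
#' matrix, the day-1 state distribution, logistic growth parameters, the
#' post-rejection decay rate, per-phenotype emissions, calcium flash rates,
#' detector noise, and the imaging horizon.
#'
#' @param transition_matrix row-stochastic 5x5 matrix over `tip_states()`;
#'   resolved and death rows must be absorbing.
#' @param start_probs day-1 distribution over the five states.
#' @param growth list with `r` (median intrinsic growth rate, 1/day),
#'   `r_sdlog` (lognormal spread of per-tumour rates), `K` (carrying
#'   capacity, mm^2), `a0` (seeded area, mm^2).
#' @param rejection_decay exponential area decay rate (1/day) once a tumour
#'   enters the resolved state.
#' @param detect_floor_mm2 area below which a tumour is no longer detectable.
#' @param emission per-phenotype emission table, see [default_emission()].
#' @param abundance_sdlog lognormal sdlog of per-day abundance draws.
#' @param core_ratio_sd Gaussian sd of per-day core-fraction draws (clamped
#'   to \[0, 1\]).
#' @param flash_rate named expected calcium flash events per rendered frame,
#'   one entry per state.
#' @param noise list with `gaussian_sd` (additive detector noise, intensity
#'   units) and `poisson_gain` (shot-noise gain; 0 disables).
#' @param n_timepoints number of daily timepoints (days 1..n).
#' @return object of class `stamp_scenario`.
#' @export
scenario_config <- function(transition_matrix = default_transition_matrix(),
                            start_probs = default_start_probs(),
                            growth = list(r = 0.45, r_sdlog = 0.25, K = 3, a0 = 0.05),
                            rejection_decay = 2.0,
                            detect_floor_mm2 = 0.01,
                            emission = default_emission(),
                            abundance_sdlog = 0.25,
                            core_ratio_sd = 0.05,
                            flash_rate = c(desert = 0.02, excluded = 0.1,
                                           inflamed = 1.5, resolved = 0.5, death = 0),
                            noise = list(gaussian_sd = 0, poisson_gain = 0),
                            n_timepoints = 21L) {
  cfg <- list(
    transition_matrix = transition_matrix, start_probs = start_probs,
    growth = growth, rejection_decay = rejection_decay,
    detect_floor_mm2 = detect_floor_mm2, emission = emission,
    abundance_sdlog = abundance_sdlog, core_ratio_sd = core_ratio_sd,
    flash_rate = flash_rate, noise = noise,
    n_timepoints = as.integer(n_timepoints)
  )
  class(cfg) <- "stamp_scenario"
  validate_scenario(cfg)
  cfg
}

validate_scenario <- function(cfg) {
  s <- tip_states()
  P <- cfg$transition_matrix
  if (!is.matrix(P) || any(dim(P) != 5L))
    stop("transition_matrix must be 5x5 over states ", paste(s, collapse = ", "))
  if (is.null(dimnames(P))) dimnames(P) <- list(s, s)
  if (any(P < 0)) stop("transition_matrix has negative entries")
  if (any(abs(rowSums(P) - 1) > 1e-9))
    stop("transition_matrix rows must sum to 1 (tolerance 1e-9)")
  for (abs_state in c("resolved", "death")) {
    if (abs(P[abs_state, abs_state] - 1) > 1e-9)
      stop("'", abs_state, "' row must be absorbing (self-probability 1)")
  }
  p0 <- cfg$start_probs
  if (length(p0) != 5L || any(p0 < 0) || abs(sum(p0) - 1) > 1e-9)
    stop("start_probs must be a length-5 distribution over the states")
  g <- cfg$growth
  if (any(unlist(g[c("r", "K", "a0")]) <= 0)) stop("growth parameters must be positive")
  if (cfg$rejection_decay < 0 || cfg$detect_floor_mm2 < 0)
    stop("rates must be non-negative")
  if (any(cfg$flash_rate < 0)) stop("flash rates must be non-negative")
  if (cfg$noise$gaussian_sd < 0 || cfg$noise$poisson_gain < 0)
    stop("noise parameters must be non-negative")
  if (cfg$n_timepoints < 2L) stop("need at least 2 timepoints")
  invisible(cfg)
}

#' Default imaging-scale study conditions
#'
#' The render-scale counterpart of the tabular defaults: an 8x8 array of
#' sub-millimetre microtumours (carrying capacity 0.8 mm^2, seeded at
#' 0.05 mm^2) at 1.3 mm pitch, imaged at 10 um/px over 15 daily frames.
#' The pixel size is chosen so that a tumour at the detectability floor still
#' spans enough pixels for contour pixelization to stay well below the
#' segmentation accuracy of interest.
#'
#' @param n_tumours how many array positions are used (<= 64).
#' @param n_timepoints daily frames.
#' @return list(config, layout, imaging) ready for [simulate_cohort()] and
#'   [render_timelapse()].
#' @export
imaging_scenario <- function(n_tumours = 64, n_timepoints = 15) {
  if (n_tumours > 64) stop("the default 8x8 layout holds at most 64 tumours")
  list(
    config = scenario_config(
      growth = list(r = 0.45, r_sdlog = 0.25, K = 0.8, a0 = 0.05),
      n_timepoints = n_timepoints),
    layout = array_layout(8, 8, pitch_um = 1300),
    imaging = imaging_params(pixel_size_um = 10)
  )
}

#' Read or write a scenario configuration as YAML
#'
#' @param path file path.
#' @param cfg a `stamp_scenario`.
#' @return `read_scenario()` returns a validated `stamp_scenario`.
#' @export
write_scenario <- function(cfg, path) {
  x <- unclass(cfg)
  x$transition_matrix <- apply(x$transition_matrix, 1, as.list, simplify = FALSE)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  P <- do.call(rbind, lapply(x$transition_matrix, unlist))
  dimnames(P) <- list(tip_states(), tip_states())
  scenario_config(
    transition_matrix = P,
    start_probs = unlist(x$start_probs),
    growth = x$growth,
    rejection_decay = x$rejection_decay,
    detect_floor_mm2 = x$detect_floor_mm2,
    emission = as.data.frame(x$emission),
    abundance_sdlog = x$abundance_sdlog,
    core_ratio_sd = x$core_ratio_sd,
    flash_rate = unlist(x$flash_rate),
    noise = x$noise,
    n_timepoints = x$n_timepoints
  )
}
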