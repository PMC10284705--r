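#' Simulate a ground-truthed synthetic microtumour cohort
#'
#' Each tumour's phenotype sequence is a realization of the scenario Markov
#' chain; area follows logistic growth until the chain enters the resolved
#' state, then decays exponentially below the detectability floor; per-day
#' T-cell abundance and core-ratio emissions are drawn conditional on the
#' phenotype. One global stream is split into per-tumour substreams (a vector
#' of per-tumour seeds drawn up front), so enlarging the cohort does not
#' perturb existing tumours.
#'
#' @param config a [scenario_config()].
#' @param n_tumours number of tumours (>= 1).
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @return object of class `stamp_cohort`: list with
#'   \describe{
#'     \item{truth}{per-tumour data.frame: `tumour_id`, `archetype_class`
#'       (I = never inflamed, II = inflamed after day 7, III = inflamed by
#'       day 7), `rejection_day` (first resolved day or NA), `death_day`,
#'       growth parameters `r`, `K`, `a0`.}
#'     \item{trajectories}{long data.frame: `tumour_id`, `day`, `area_mm2`,
#'       `phenotype_code`, `abundance`, `core_ratio`, `detected`.}
#'     \item{codes}{n_tumours x n_timepoints integer matrix of phenotype codes.}
#'   }
#' @export
simulate_cohort <- function(config = scenario_config(), n_tumours, seed = 1L) {
  validate_scenario(config)
  if (n_tumours < 1) stop("n_tumours must be >= 1")
  n_t <- config$n_timepoints
  states <- tip_states()
  codes_of <- tip_codes()
  P <- config$transition_matrix

  set.seed(as.integer(seed))
  tumour_seeds <- sample.int(2147483646L, n_tumours, replace = TRUE)

  em <- config$emission
  em_ab <- stats::setNames(em$abundance_mean, em$state)
  em_cf <- stats::setNames(em$core_fraction, em$state)

  codes <- matrix(NA_integer_, n_tumours, n_t)
  truth <- vector("list", n_tumours)
  traj <- vector("list", n_tumours)

  for (i in seq_len(n_tumours)) {
    set.seed(tumour_seeds[i])
    ## phenotype chain
    st <- character(n_t)
    st[1] <- sample(states, 1, prob = config$start_probs)
    for (t in 2:n_t) {
      prev <- st[t - 1]
      st[t] <- if (prev %in% c("resolved", "death")) prev else
        sample(states, 1, prob = P[prev, ])
    }
    code_i <- state_to_code(st)
    rejection_day <- if (any(st == "resolved")) which(st == "resolved")[1] else NA_integer_
    death_day <- if (any(st == "death")) which(st == "death")[1] else NA_integer_

    ## logistic growth until rejection, exponential decay after
    g <- config$growth
    r_i <- stats::rlnorm(1, log(g$r), g$r_sdlog)
    days <- seq_len(n_t)
    area <- g$K * g$a0 / (g$a0 + (g$K - g$a0) * exp(-r_i * (days - 1)))
    if (!is.na(rejection_day)) {
      a_rej <- if (rejection_day > 1) area[rejection_day - 1] else g$a0
      idx <- days >= rejection_day
      area[idx] <- a_rej * exp(-config$rejection_decay * (days[idx] - rejection_day + 1))
    }
    detected <- area >= config$detect_floor_mm2 & code_i != 0L

    ## per-day emissions conditional on phenotype
    ab <- cf <- rep(NA_real_, n_t)
    live <- st != "death"
    ab[live] <- stats::rlnorm(sum(live), log(em_ab[st[live]]), config$abundance_sdlog)
    cf[live] <- pmin(1, pmax(0, stats::rnorm(sum(live), em_cf[st[live]],
                                             config$core_ratio_sd)))

    codes[i, ] <- code_i
    truth[[i]] <- data.frame(
      tumour_id = i,
      archetype_class = archetype_from_codes(code_i),
      rejection_day = rejection_day, death_day = death_day,
      r = r_i, K = g$K, a0 = g$a0
    )
    traj[[i]] <- data.frame(
      tumour_id = i, day = days, area_mm2 = area, phenotype_code = code_i,
      abundance = ab, core_ratio = cf, detected = detected
    )
  }

  out <- list(
    truth = do.call(rbind, truth),
    trajectories = do.call(rbind, traj),
    codes = codes,
    config = config, seed = as.integer(seed)
  )
  class(out) <- "stamp_cohort"
  out
}

# Trajectory-class label derived from a realized phenotype sequence:
# III = inflamed by early_day, II = inflamed later, I = never inflamed.
archetype_from_codes <- function(code, early_day = 7L) {
  inf_day <- which(code == 3L)[1]
  if (is.na(inf_day)) "I" else if (inf_day <= early_day) "III" else "II"
}

#' Simulate a control-arm cohort from the default archetype mixture
#'
#' Generates tumours from three trajectory archetypes: class I tumours gain
#' T-cell abundance over time but remain immune excluded; class II pass
#' through an excluded state and reach an inflamed phenotype late; class III
#' convert early to an inflamed phenotype with high abundance and
#' infiltration ratio and are then mostly rejected. This is the generator
#' used for trajectory-class recovery studies; phenotype emissions reuse the
#' scenario emission table.
#'
#' @param n_tumours cohort size.
#' @param weights mixture weights over classes I, II, III.
#' @param n_timepoints daily horizon.
#' @param emission per-state emission table ([default_emission()]).
#' @param abundance_sdlog,core_ratio_sd emission spreads.
#' @param seed integer seed.
#' @return a `stamp_cohort` whose `truth$archetype_class` holds the generating
#'   class; `trajectories` carries per-day `abundance` and `core_ratio`.
#' @export
simulate_archetype_cohort <- function(n_tumours,
                                      weights = c(I = 0.40, II = 0.35, III = 0.25),
                                      n_timepoints = 21L,
                                      emission = default_emission(),
                                      abundance_sdlog = 0.20,
                                      core_ratio_sd = 0.05,
                                      seed = 1L) {
  if (n_tumours < 1) stop("n_tumours must be >= 1")
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid mixture weights")
  n_t <- as.integer(n_timepoints)
  em_ab <- stats::setNames(emission$abundance_mean, emission$state)
  em_cf <- stats::setNames(emission$core_fraction, emission$state)

  set.seed(as.integer(seed))
  tumour_seeds <- sample.int(2147483646L, n_tumours, replace = TRUE)

  codes <- matrix(NA_integer_, n_tumours, n_t)
  truth <- traj <- vector("list", n_tumours)
  for (i in seq_len(n_tumours)) {
    set.seed(tumour_seeds[i])
    cls <- sample(c("I", "II", "III"), 1, prob = weights / sum(weights))
    st <- rep("excluded", n_t)
    if (cls == "II") {
      sw <- sample(11:14, 1)
      st[sw:n_t] <- "inflamed"
      if (stats::runif(1) < 0.15) {
        rs <- min(n_t, sw + 3L + stats::rgeom(1, 0.3))
        st[rs:n_t] <- "resolved"
      }
    } else if (cls == "III") {
      sw <- sample(3:5, 1)
      st[sw:n_t] <- "inflamed"
      if (stats::runif(1) < 0.85) {
        rs <- min(n_t, sw + 2L + stats::rgeom(1, 0.35))
        st[rs:n_t] <- "resolved"
      }
    }
    code_i <- state_to_code(st)
    rejection_day <- if (any(st == "resolved")) which(st == "resolved")[1] else NA_integer_

    ab <- stats::rlnorm(n_t, log(em_ab[st]), abundance_sdlog)
    if (cls == "I") ab <- ab * seq(0.5, 1.5, length.out = n_t)  # rising abundance
    cf <- pmin(1, pmax(0, stats::rnorm(n_t, em_cf[st], core_ratio_sd)))

    codes[i, ] <- code_i
    truth[[i]] <- data.frame(tumour_id = i, archetype_class = cls,
                             rejection_day = rejection_day, death_day = NA_integer_)
    traj[[i]] <- data.frame(tumour_id = i, day = seq_len(n_t),
                            phenotype_code = code_i, abundance = ab,
                            core_ratio = cf)
  }
  out <- list(truth = do.call(rbind, truth),
              trajectories = do.call(rbind, traj),
              codes = codes, seed = as.integer(seed))
  class(out) <- "stamp_cohort"
  out
}

#' @export
print.stamp_cohort <- function(x, ...) {
  cat("stamp_cohort:", nrow(x$truth), "tumours x", ncol(x$codes), "days\n")
  cat("archetype classes:\n")
  print(table(x$truth$archetype_class))
  invisible(x)
}

#' Write or read a trajectory table as CSV
#'
#' Columns: tumour_id, day, area_mm2 (if present), phenotype_code, abundance,
#' core_ratio, detected (if present).
#'
#' @param cohort a `stamp_cohort` (or plain trajectory data.frame).
#' @param path CSV path.
#' @return `read_trajectories()` returns the trajectory data.frame.
#' @export
write_trajectories <- function(cohort, path) {
  df <- if (inherits(cohort, "stamp_cohort")) cohort$trajectories else cohort
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) utils::read.csv(path)
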