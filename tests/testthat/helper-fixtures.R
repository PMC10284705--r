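# Shared fixtures and naive oracles. Oracles are deliberate brute-force
# re-implementations, independent of the package internals.

disc_mask <- function(n, r, cy = (n + 1) / 2, cx = (n + 1) / 2) {
  d <- sqrt(outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, "+"))
  d <= r
}

# naive radial profile: explicit per-pixel loop and per-bin median
oracle_radial_profile <- function(img, mask, n_bins) {
  idx <- which(mask, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  r_eq <- sqrt(nrow(idx) / pi)
  edges <- seq(0, 1, length.out = n_bins + 1)
  med <- rep(NA_real_, n_bins)
  rn <- pmin(sqrt((idx[, 1] - cy)^2 + (idx[, 2] - cx)^2) / r_eq, 1)
  for (b in seq_len(n_bins)) {   # bins left-closed, last bin closed at 1
    lo <- edges[b]; hi <- edges[b + 1]
    sel <- if (b == n_bins) rn >= lo & rn <= hi else rn >= lo & rn < hi
    if (any(sel)) med[b] <- median(img[mask][sel])
  }
  med
}

# naive transition counts: explicit pairwise enumeration with absorbing stop
oracle_transition_counts <- function(codes) {
  states <- c(1L, 2L, 3L, 5L, 0L)
  cm <- matrix(0L, 5, 5)
  for (i in seq_len(nrow(codes))) {
    x <- codes[i, ]
    for (t in seq_len(length(x) - 1)) {
      cm[match(x[t], states), match(x[t + 1], states)] <-
        cm[match(x[t], states), match(x[t + 1], states)] + 1L
      if (x[t + 1] %in% c(5L, 0L)) break
    }
  }
  cm
}

# naive product-limit estimator, term by term
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (k in seq_along(ts)) {
    at_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event == 1)
    s <- s * (1 - d / at_risk)
    out[k] <- s
  }
  data.frame(time = ts, surv = out)
}

# naive log-rank: explicit 2x2 per event time, group 1 observed vs expected
oracle_logrank <- function(time, event, group) {
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (tk in ts) {
    n <- sum(time >= tk)
    n1 <- sum(time >= tk & group == 1)
    d <- sum(time == tk & event == 1)
    d1 <- sum(time == tk & event == 1 & group == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# trajectory table for a constant-phenotype, constant-area cohort
constant_trajectories <- function(codes_by_tumour, n_days, area = 0.5,
                                  abundance = 100) {
  do.call(rbind, lapply(seq_along(codes_by_tumour), function(i)
    data.frame(tumour_id = i, day = seq_len(n_days), area_mm2 = area,
               phenotype_code = codes_by_tumour[i], abundance = abundance,
               core_ratio = NA_real_, detected = TRUE)))
}

# accuracy of cluster labels against truth, maximized over label permutations
perm_accuracy <- function(labels, truth) {
  lt <- sort(unique(truth))
  stopifnot(length(unique(labels)) <= length(lt))
  perms <- function(v) if (length(v) == 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  best <- 0
  for (p in perms(seq_along(lt))) {
    acc <- mean(lt[p][labels] == truth)
    best <- max(best, acc)
  }
  best
}
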