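#' Transition counts over phenotype timelines
#'
#' Counts code(t) -> code(t+1) over consecutive observed days for every
#' tumour. Counting stops after the first entry into an absorbing state
#' (resolved or death): the entry transition is counted, the trailing padding
#' is bookkeeping, not dynamics. Set `count_absorbing_self = TRUE` to count
#' the padding self-loops instead.
#'
#' @param timelines a [phenotype_timelines()] or an integer code matrix
#'   (tumours x days; NA marks unobserved days, transitions across NA are
#'   skipped).
#' @param count_absorbing_self count absorbing self-loops after entry.
#' @return object of class `transition_matrix` with `states` and integer
#'   `counts` (state x state).
#' @export
transition_counts <- function(timelines, count_absorbing_self = FALSE) {
  codes <- if (inherits(timelines, "stamp_timelines")) timelines$codes else
    as.matrix(timelines)
  if (any(!codes[!is.na(codes)] %in% c(0L, 1L, 2L, 3L, 5L)))
    stop("phenotype code outside alphabet {0,1,2,3,5}")
  s <- tip_states()
  cd <- tip_codes()
  counts <- matrix(0L, 5, 5, dimnames = list(s, s))
  for (i in seq_len(nrow(codes))) {
    x <- codes[i, ]
    stop_at <- length(x)
    if (!count_absorbing_self) {
      first_abs <- which(x %in% absorbing_codes())[1]
      if (!is.na(first_abs)) stop_at <- first_abs
    }
    for (t in seq_len(stop_at - 1)) {
      a <- x[t]; b <- x[t + 1]
      if (is.na(a) || is.na(b)) next
      ai <- match(a, cd); bi <- match(b, cd)
      counts[ai, bi] <- counts[ai, bi] + 1L
    }
  }
  structure(list(states = s, counts = counts, probs = NULL),
            class = "transition_matrix")
}

#' Row-stochastic transition probabilities from counts
#'
#' Rows are normalized by their totals. Zero-count absorbing rows get the
#' conventional self-loop probability 1; zero-count transient rows are
#' undefined (NA).
#'
#' @param counts a `transition_matrix` (from [transition_counts()]) or a
#'   plain count matrix over the state alphabet.
#' @return the `transition_matrix` with `probs` filled in.
#' @export
transition_probabilities <- function(counts) {
  tm <- if (inherits(counts, "transition_matrix")) counts else
    structure(list(states = tip_states(), counts = counts, probs = NULL),
              class = "transition_matrix")
  cm <- tm$counts
  probs <- matrix(NA_real_, 5, 5, dimnames = dimnames(cm))
  rs <- rowSums(cm)
  for (i in seq_len(5)) {
    if (rs[i] > 0) probs[i, ] <- cm[i, ] / rs[i]
    else if (tm$states[i] %in% c("resolved", "death")) {
      probs[i, ] <- 0; probs[i, i] <- 1
    }
  }
  tm$probs <- probs
  tm
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("transition_matrix over", paste(x$states, collapse = ", "), "\n")
  cat("counts:\n"); print(x$counts)
  if (!is.null(x$probs)) { cat("probabilities:\n"); print(round(x$probs, 3)) }
  invisible(x)
}

#' Fold difference between two transition-probability matrices
#'
#' Element-wise P_treat / P_control. Entries with control probability 0 (or
#' undefined rows) are NA. Values > 1 mark increased, < 1 decreased
#' transitions under treatment.
#'
#' @param p_treat,p_control `transition_matrix` objects with probabilities,
#'   or plain probability matrices with the same state order.
#' @return numeric matrix of fold differences.
#' @export
fold_difference <- function(p_treat, p_control) {
  pt <- if (inherits(p_treat, "transition_matrix")) p_treat$probs else p_treat
  pc <- if (inherits(p_control, "transition_matrix")) p_control$probs else p_control
  if (is.null(pt) || is.null(pc)) stop("probabilities missing; run transition_probabilities()")
  if (!all(dim(pt) == dim(pc))) stop("shape mismatch between treatment and control")
  out <- pt / pc
  out[is.na(pc) | pc == 0] <- NA_real_
  out
}

#' Shuffle null for transition matrices
#'
#' Each permutation independently shuffles every tumour's pre-absorbing code
#' sequence (preserving its state multiset; the absorbing tail stays in
#' place), then recomputes the transition matrix. Per-cell empirical
#' two-sided p-values compare the observed probabilities with the null
#' distribution using (1 + #extreme) / (1 + n_perm).
#'
#' @param timelines a [phenotype_timelines()] or code matrix.
#' @param n_perm number of permutations (default 10).
#' @param seed integer seed.
#' @param keep_codes also return the permuted code matrices (for auditing the
#'   multiset-preservation invariant).
#' @return list(observed `transition_matrix`, `null` array
#'   (state x state x n_perm) of null probabilities, `p` matrix; `codes`
#'   list when `keep_codes`).
#' @export
shuffle_null <- function(timelines, n_perm = 10, seed = 1L, keep_codes = FALSE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  codes <- if (inherits(timelines, "stamp_timelines")) timelines$codes else
    as.matrix(timelines)
  obs <- transition_probabilities(transition_counts(codes))
  set.seed(as.integer(seed))
  null_probs <- array(NA_real_, c(5, 5, n_perm),
                      dimnames = c(dimnames(obs$counts), NULL))
  kept <- if (keep_codes) vector("list", n_perm) else NULL
  for (p in seq_len(n_perm)) {
    shuffled <- codes
    for (i in seq_len(nrow(codes))) {
      x <- codes[i, ]
      first_abs <- which(x %in% absorbing_codes())[1]
      upto <- if (is.na(first_abs)) length(x) else first_abs - 1L
      if (upto >= 2) shuffled[i, 1:upto] <- sample(x[1:upto])
    }
    if (keep_codes) kept[[p]] <- shuffled
    null_probs[, , p] <-
      transition_probabilities(transition_counts(shuffled))$probs
  }
  pobs <- obs$probs
  pmat <- matrix(NA_real_, 5, 5, dimnames = dimnames(obs$counts))
  for (i in 1:5) for (j in 1:5) {
    if (is.na(pobs[i, j])) next
    nn <- null_probs[i, j, ]
    nn <- nn[!is.na(nn)]
    if (length(nn) == 0) next
    hi <- (1 + sum(nn >= pobs[i, j])) / (1 + length(nn))
    lo <- (1 + sum(nn <= pobs[i, j])) / (1 + length(nn))
    pmat[i, j] <- min(1, 2 * min(hi, lo))
  }
  out <- list(observed = obs, null = null_probs, p = pmat)
  if (keep_codes) out$codes <- kept
  out
}

#' Order timelines for heat-map display
#'
#' Deterministic leaf order from agglomerative clustering of the padded code
#' vectors (Hamming distance, average linkage).
#'
#' @param timelines a [phenotype_timelines()] or code matrix.
#' @return integer permutation of tumour indices.
#' @export
order_timelines <- function(timelines) {
  codes <- if (inherits(timelines, "stamp_timelines")) timelines$codes else
    as.matrix(timelines)
  n <- nrow(codes)
  if (n <= 2) return(seq_len(n))
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- mean(codes[i, ] != codes[j, ])
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  hc$order
}

#' Cluster tumour trajectories in immune-state space
#'
#' Feature vector per tumour: the concatenated per-day T-cell abundance and
#' infiltration-ratio series, each day/feature column standardized. Ward
#' agglomerative clustering; when `k = "auto"` the class count is chosen by
#' the mean silhouette width over 2..`k_max`, with a minimum-separation guard:
#' if the best silhouette is below `min_silhouette` the cohort is reported as
#' a single effective class (flagged). Missing days inside a series are
#' linearly interpolated; leading/trailing gaps are edge-held. Class labels
#' are canonicalized by increasing mean infiltration ratio, so the labelling
#' is invariant to tumour input order.
#'
#' @param abundance tumours x days matrix of abundance values (or a
#'   `stamp_cohort`, in which case `ratio` is ignored and both series are
#'   pulled from its trajectories).
#' @param ratio tumours x days matrix of infiltration ratios.
#' @param k number of classes, or `"auto"`.
#' @param k_max largest k tried under `"auto"`.
#' @param min_silhouette minimum-separation guard for `"auto"`.
#' @return object of class `trajectory_classes`: list(k, labels, silhouette,
#'   medians (per-class list of per-day median abundance / ratio),
#'   degenerate flag).
#' @export
cluster_trajectories <- function(abundance, ratio = NULL, k = "auto",
                                 k_max = 6, min_silhouette = 0.25) {
  if (inherits(abundance, "stamp_cohort")) {
    traj <- abundance$trajectories
    ids <- sort(unique(traj$tumour_id))
    days <- sort(unique(traj$day))
    abundance <- matrix(NA_real_, length(ids), length(days))
    ratio <- matrix(NA_real_, length(ids), length(days))
    for (i in seq_along(ids)) {
      rows <- traj[traj$tumour_id == ids[i], ]
      abundance[i, match(rows$day, days)] <- rows$abundance
      ratio[i, match(rows$day, days)] <- rows$core_ratio
    }
  }
  if (is.null(ratio) || !all(dim(abundance) == dim(ratio)))
    stop("abundance and ratio must be matrices of equal shape")
  n <- nrow(abundance)
  if (!identical(k, "auto") && n < k) stop("fewer tumours than classes")

  fill <- function(m) t(apply(m, 1, interp_series))
  feats <- cbind(fill(abundance), fill(ratio))
  feats <- scale(feats)
  feats[, !is.finite(colSums(feats))] <- 0  # constant columns

  D <- stats::dist(feats)
  hc <- stats::hclust(D, method = "ward.D2")

  degenerate <- FALSE
  sil <- NA_real_
  if (identical(k, "auto")) {
    ks <- 2:min(k_max, n - 1)
    sil_k <- vapply(ks, function(kk) {
      cl <- stats::cutree(hc, kk)
      if (length(unique(cl)) < 2) return(-1)
      mean(cluster::silhouette(cl, D)[, "sil_width"])
    }, 0)
    best <- which.max(sil_k)
    sil <- sil_k[best]
    if (!is.finite(sil) || sil < min_silhouette) {
      k <- 1L; degenerate <- TRUE
      warning("no well-separated class structure; reporting 1 effective class")
    } else k <- ks[best]
  }
  labels <- if (k == 1L) rep(1L, n) else stats::cutree(hc, k)

  ## canonical label order: ascending mean infiltration ratio
  mr <- vapply(seq_len(k), function(c) mean(fill(ratio)[labels == c, , drop = FALSE]), 0)
  relabel <- match(seq_len(k), order(mr))
  labels <- relabel[labels]

  medians <- lapply(seq_len(k), function(c) list(
    abundance = apply(abundance[labels == c, , drop = FALSE], 2, stats::median, na.rm = TRUE),
    ratio = apply(ratio[labels == c, , drop = FALSE], 2, stats::median, na.rm = TRUE)))
  structure(list(k = as.integer(k), labels = labels, silhouette = sil,
                 medians = medians, degenerate = degenerate),
            class = "trajectory_classes")
}

#' @export
print.trajectory_classes <- function(x, ...) {
  cat("trajectory_classes: k =", x$k,
      if (x$degenerate) "(degenerate)" else "", "\n")
  print(table(x$labels))
  invisible(x)
}

# linear interpolation of interior NAs; edge-hold for leading/trailing NAs
interp_series <- function(x) {
  if (!anyNA(x)) return(x)
  obs <- which(!is.na(x))
  if (length(obs) == 0) return(rep(0, length(x)))
  stats::approx(obs, x[obs], xout = seq_along(x), rule = 2)$y
}
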