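test_that("transition counts follow hand counting with the absorbing stop rule", {
  tm <- transition_counts(matrix(c(1, 1, 2, 2, 3), 1))
  expect_equal(tm$counts["desert", "desert"], 1L)
  expect_equal(tm$counts["desert", "excluded"], 1L)
  expect_equal(tm$counts["excluded", "excluded"], 1L)
  expect_equal(tm$counts["excluded", "inflamed"], 1L)
  expect_equal(sum(tm$counts), 4L)

  tm2 <- transition_counts(matrix(c(2, 5, 5, 5), 1))
  expect_equal(sum(tm2$counts), 1L)
  expect_equal(tm2$counts["excluded", "resolved"], 1L)
  ## optional padding self-loops
  tm3 <- transition_counts(matrix(c(2, 5, 5, 5), 1), count_absorbing_self = TRUE)
  expect_equal(tm3$counts["resolved", "resolved"], 2L)

  expect_error(transition_counts(matrix(c(1, 4), 1)), "alphabet")
})

test_that("cohort transition counts equal the naive enumeration oracle", {
  co <- simulate_cohort(scenario_config(n_timepoints = 15), 120, seed = 23)
  tm <- transition_counts(co$codes)
  expect_identical(unname(tm$counts), oracle_transition_counts(co$codes))
})

test_that("row normalization handles empty and absorbing rows", {
  cm <- matrix(0L, 5, 5, dimnames = list(tip_states(), tip_states()))
  cm["desert", "desert"] <- 1L; cm["desert", "excluded"] <- 1L
  tm <- transition_probabilities(
    structure(list(states = tip_states(), counts = cm, probs = NULL),
              class = "transition_matrix"))
  expect_equal(tm$probs["desert", c("desert", "excluded")], c(desert = 0.5, excluded = 0.5))
  expect_true(all(is.na(tm$probs["inflamed", ])))      # empty transient row
  expect_equal(tm$probs["resolved", "resolved"], 1)    # absorbing convention
  expect_equal(tm$probs["death", "death"], 1)
  rs <- rowSums(tm$probs, na.rm = TRUE)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-9))
})

test_that("fold differences are element-wise ratios with missing zero cells", {
  co <- simulate_cohort(scenario_config(), 150, seed = 29)
  p <- transition_probabilities(transition_counts(co$codes))
  expect_equal(unname(fold_difference(p, p)[!is.na(fold_difference(p, p))]),
               rep(1, sum(!is.na(fold_difference(p, p)))))
  a <- matrix(0.4, 5, 5); b <- matrix(0.2, 5, 5)
  expect_equal(unname(fold_difference(a, b)[1, 1]), 2.0)
  b[2, 3] <- 0
  expect_true(is.na(fold_difference(a, b)[2, 3]))
  ## randomized pair equals the element-wise oracle
  set.seed(5)
  x <- matrix(runif(25, 0.1, 1), 5); y <- matrix(runif(25, 0.1, 1), 5)
  expect_equal(fold_difference(x, y), x / y, tolerance = 1e-12)
  expect_error(fold_difference(x, matrix(1, 4, 4)), "shape mismatch")
})

test_that("the shuffle null preserves per-tumour state multisets", {
  co <- simulate_cohort(scenario_config(n_timepoints = 12), 40, seed = 31)
  sn <- shuffle_null(co$codes, n_perm = 10, seed = 7, keep_codes = TRUE)
  expect_equal(dim(sn$null)[3], 10)
  for (p in seq_len(10)) {
    shuf <- sn$codes[[p]]
    for (i in seq_len(nrow(shuf)))
      expect_equal(sort(shuf[i, ]), sort(co$codes[i, ]))
  }
  ## timelines with nothing to shuffle give a null identical to the observed
  short <- matrix(c(2L, 5L), 1)
  sn2 <- shuffle_null(short, n_perm = 5, seed = 1)
  for (p in 1:5) expect_identical(sn2$null[, , p], sn2$observed$probs)
  ## determinism
  sn3 <- shuffle_null(co$codes, n_perm = 10, seed = 7)
  expect_identical(sn3$null, sn$null)
})

test_that("timeline ordering groups identical and well-separated profiles", {
  block_a <- matrix(rep(c(1L, 1L, 2L, 2L, 3L), each = 4), 4, byrow = FALSE)
  block_b <- matrix(rep(c(3L, 3L, 3L, 5L, 5L), each = 4), 4, byrow = FALSE)
  codes <- rbind(block_a[1, , drop = FALSE], block_b,
                 block_a[2:4, , drop = FALSE])
  ord <- order_timelines(codes)
  pos_a <- match(c(1, 6, 7, 8), ord)
  pos_b <- match(2:5, ord)
  expect_true(max(pos_a) < min(pos_b) || max(pos_b) < min(pos_a))
  ## permuting input order preserves the grouping
  perm <- c(3, 1, 8, 2, 5, 7, 4, 6)
  ord2 <- order_timelines(codes[perm, ])
  grp <- ifelse(perm %in% c(1, 6, 7, 8), "a", "b")
  expect_equal(length(rle(grp[ord2])$values), 2)
})

test_that("trajectory clustering recovers archetypes and handles degeneracy", {
  co <- simulate_archetype_cohort(75, seed = 37)
  cl <- cluster_trajectories(co)
  expect_equal(cl$k, 3L)
  expect_gte(perm_accuracy(cl$labels, co$truth$archetype_class), 0.9)

  ## cluster medians equal componentwise medians of members
  ids <- sort(unique(co$trajectories$tumour_id))
  days <- sort(unique(co$trajectories$day))
  ab <- matrix(NA_real_, length(ids), length(days))
  rt <- matrix(NA_real_, length(ids), length(days))
  for (i in seq_along(ids)) {
    rows <- co$trajectories[co$trajectories$tumour_id == ids[i], ]
    ab[i, ] <- rows$abundance; rt[i, ] <- rows$core_ratio
  }
  for (c in seq_len(cl$k)) {
    expect_equal(cl$medians[[c]]$abundance,
                 apply(ab[cl$labels == c, , drop = FALSE], 2, median),
                 tolerance = 1e-12)
    expect_equal(cl$medians[[c]]$ratio,
                 apply(rt[cl$labels == c, , drop = FALSE], 2, median),
                 tolerance = 1e-12)
  }

  ## label assignment invariant to tumour input order (canonical relabelling)
  set.seed(2)
  perm <- sample(length(ids))
  cl2 <- cluster_trajectories(ab[perm, ], rt[perm, ])
  expect_equal(cl2$labels, cl$labels[perm])

  ## a single duplicated archetype reports one effective class, flagged
  dup_ab <- matrix(rep(ab[1, ], 12), 12, byrow = TRUE)
  dup_rt <- matrix(rep(rt[1, ], 12), 12, byrow = TRUE)
  expect_warning(cl3 <- cluster_trajectories(dup_ab, dup_rt), "1 effective class")
  expect_equal(cl3$k, 1L)
  expect_true(cl3$degenerate)

  expect_error(cluster_trajectories(ab[1:2, ], rt[1:2, ], k = 5),
               "fewer tumours than classes")
})
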