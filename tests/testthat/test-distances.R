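# Distance algorithms: reduction rules, flat-interval approximation, greedy
# merge heuristic, unit-event DP, Euclidean, symmetrization, lower bounds,
# and the exact search oracle.

test_that("null-position reduction applies the three rules to a fixed point", {
  r <- reduce_null_positions(c(3, 5, 2, 4), c(1, 0, 0, 2))
  expect_equal(r$u, c(3L, 5L, 4L))
  expect_equal(r$v, c(1L, 0L, 2L))
  expect_equal(r$removed$position, 3L)
  expect_equal(r$removed$rule, "adjacent-null")

  r2 <- reduce_null_positions(c(3, 2, 4), c(1, 0, 2))
  expect_equal(r2$u, c(3L, 4L))
  expect_equal(r2$v, c(1L, 2L))
  expect_equal(r2$removed$rule, "dominated-null")

  r3 <- reduce_null_positions(c(2, 3), c(1, 2))
  expect_equal(r3$u, c(2L, 3L))
  expect_equal(nrow(r3$removed), 0L)

  expect_error(reduce_null_positions(c(0, 1), c(1, 1)), "untransformable")
  r4 <- reduce_null_positions(c(0, 2), c(1, 1), drop_source_nulls = TRUE)
  expect_equal(r4$u, 2L)
  expect_equal(r4$removed$rule, "source-null")
})

test_that("reduction output always satisfies the sandwich condition", {
  set.seed(7001)
  for (rep in 1:60) {
    pr <- random_pair(sample(3:10, 1))
    r <- reduce_null_positions(pr$u, pr$v)
    w <- r$u - r$v
    n <- length(w)
    for (p in which(r$v == 0L)) {
      wl <- if (p > 1L) w[p - 1L] else 0L
      wr <- if (p < n) w[p + 1L] else 0L
      expect_lt(wl, w[p])
      expect_lt(wr, w[p])
    }
    expect_true(all(r$u > 0L | r$v == 0L))
  }
})

test_that("reduction preserves the exact distance on small null instances", {
  fam <- null_family()
  cnt <- 0L
  for (i in seq_len(nrow(fam$src))) {
    u <- fam$src[i, ]
    for (j in seq_len(nrow(fam$tgt))) {
      v <- fam$tgt[j, ]
      if (all(v > 0L)) next
      r <- reduce_null_positions(u, v)
      if (length(r$u) == 0L || length(r$u) == 3L) next
      cnt <- cnt + 1L
      if (cnt %% 3L != 0L) next   # subsample: oracle calls are the slow part
      expect_equal(exact_distance_oracle(r$u, r$v, "any"),
                   exact_distance_oracle(u, v, "any"))
    }
  }
  expect_gt(cnt, 100L)
})

test_that("flat-interval count gives |F_w| - 2 with a realizing sequence", {
  d <- flat_count_distance(c(4, 8, 15, 23, 14), rep(1, 5))
  expect_equal(d$cost, 5L)
  expect_equal(apply_sequence(c(4, 8, 15, 23, 14), d$events), rep(1L, 5))
  expect_equal(flat_count_distance(c(2, 2), c(2, 2))$cost, 0L)
  expect_equal(flat_count_distance(c(3, 1), c(1, 2))$cost, 2L)
  # interior zero-valued flat interval: fewer events than the counted cost
  d2 <- flat_count_distance(c(3, 1, 4), c(1, 1, 2))
  expect_equal(d2$cost, 3L)
  expect_equal(nrow(d2$events), 2L)
  expect_equal(apply_sequence(c(3, 1, 4), d2$events), c(1L, 1L, 2L))
})

test_that("merge-event search honours the boundary condition and tie-breaks", {
  e <- find_merge_event(c(1, 2, 1), c(2, 3, 2), c(1, 1, 1))
  expect_equal(unlist(e), c(s = 1L, t = 2L, delta = -1L))
  expect_null(find_merge_event(c(3, 7, 14, 22, 13), c(4, 8, 15, 23, 14), rep(1L, 5)))
  e2 <- find_merge_event(5L, 6L, 1L)
  expect_equal(unlist(e2), c(s = 1L, t = 1L, delta = -5L))
  # the only condition-matching merge would kill position 2 (target > 0)
  expect_null(find_merge_event(c(5, 1, 2, 5), c(6, 2, 3, 6), c(1, 1, 1, 1)))
})

test_that("greedy heuristic realizes its cost and solves mirrored staircases", {
  h <- heuristic_distance(c(2, 3, 2), c(1, 1, 1))
  expect_equal(h$cost, 2L)
  expect_equal(apply_sequence(c(2, 3, 2), h$events), c(1L, 1L, 1L))
  expect_equal(heuristic_distance(c(4, 8, 15, 23, 14), rep(1, 5))$cost, 5L)
  # w = (1, 2, ..., k, ..., 2, 1) is solvable in exactly k merge events
  for (k in 1:6) {
    w <- c(seq_len(k), rev(seq_len(k - 1)))
    u <- w + 1L
    v <- rep(1L, length(w))
    expect_equal(heuristic_distance(u, v)$cost, k)
  }
})

test_that("heuristic event sequences transform reduced pairs with nulls", {
  set.seed(2024)
  for (rep in 1:40) {
    pr <- random_pair(sample(4:14, 1))
    r <- reduce_null_positions(pr$u, pr$v)
    if (length(r$u) == 0L) next
    h <- heuristic_distance(r$u, r$v, reduce = FALSE)
    expect_equal(nrow(h$events), h$cost)
    expect_equal(apply_sequence(r$u, h$events), r$v)
    expect_lte(h$cost, flat_count_distance(r$u, r$v, reduce = FALSE)$cost)
  }
})

test_that("unit-event distance reproduces worked small cases", {
  expect_equal(zzs_distance(c(1, 1), c(0, 0))$cost, 1)
  expect_equal(zzs_distance(c(2, 1, 3), c(1, 1, 1))$cost, 3)
  expect_equal(zzs_distance(c(3, 1), c(1, 2))$cost, 3)
  expect_error(zzs_distance(c(0, 1), c(1, 1)), "untransformable")
})

test_that("unit-event skyline fast path equals the dynamic program", {
  fam <- zero_free_family()
  prof <- fam$profiles
  for (i in seq_len(nrow(prof))) {
    for (j in seq_len(nrow(prof))) {
      if (i == j) next
      fast <- zzs_distance(prof[i, ], prof[j, ], fast_path = TRUE)$cost
      slow <- zzs_distance(prof[i, ], prof[j, ], fast_path = FALSE)$cost
      expect_identical(fast, slow)
    }
  }
})

test_that("Euclidean distance is the plain L2 norm of the difference", {
  expect_equal(euclidean_distance(c(1, 1), c(0, 0)), sqrt(2))
  expect_equal(euclidean_distance(c(5, 2), c(5, 2)), 0)
  expect_equal(euclidean_distance(c(4, 8, 15, 23, 14), rep(1, 5)), sqrt(907))
})

test_that("symmetrized distance takes the defined-direction minimum", {
  expect_equal(symmetric_distance(c(1, 1), c(0, 0), "zzs"), 1)
  expect_equal(symmetric_distance(c(2, 3, 2), c(1, 1, 1), "heuristic"), 2)
  # symmetry on random pairs, all methods
  set.seed(31)
  for (rep in 1:20) {
    pr <- random_pair(sample(3:10, 1))
    for (m in c("heuristic", "flat", "zzs", "euclidean")) {
      d1 <- symmetric_distance(pr$u, pr$v, m)
      d2 <- symmetric_distance(pr$v, pr$u, m)
      expect_equal(d1, d2)
      expect_true(is.finite(d1))
    }
  }
})

test_that("lower bound reproduces worked values and stays admissible", {
  expect_equal(lower_bound(c(3, 7, 14, 22, 13)), 4L)
  expect_equal(lower_bound(c(0, 0)), 0L)
  expect_equal(lower_bound(c(1, 2, 3, 2, 1)), 3L)
  fam <- zero_free_family()
  prof <- fam$profiles
  for (i in seq_len(nrow(prof)))
    for (j in seq_len(nrow(prof))) {
      if (i == j) next
      expect_lte(lower_bound(prof[i, ] - prof[j, ]), fam$d_any[i, j])
    }
})

test_that("exact oracle agrees with worked values and is cap-robust", {
  expect_equal(exact_distance_oracle(c(2, 3, 2), c(1, 1, 1), "any"), 2L)
  expect_equal(exact_distance_oracle(c(3, 3), c(3, 3), "any"), 0L)
  expect_equal(exact_distance_oracle(c(1, 1), c(0, 0), "mdc"), 1L)
  expect_error(exact_distance_oracle(c(0, 1), c(1, 1), "any"), "unreachable")
  expect_error(exact_distances_from(c(2, 2, 2, 2, 2, 2, 2),
                                    c(1, 1, 1, 1, 1, 1, 1), "any",
                                    max_states = 10000),
               "state space too large")
  # widening the cap must not change any distance (overshoot head-room)
  prof <- family_profiles(1:3)
  set.seed(17)
  for (i in sample(nrow(prof), 6)) {
    a <- exact_distances_from(prof[i, ], prof, "any")
    b <- exact_distances_from(prof[i, ], prof, "any", value_cap = 10)
    expect_equal(a, b)
  }
  # the doubling cost restricts amplifications but not deletions
  expect_equal(exact_distance_oracle(c(1, 1), c(3, 3), "dbl"), 2L)
  expect_equal(exact_distance_oracle(c(1, 1), c(4, 4), "dbl"), 2L)
  expect_equal(exact_distance_oracle(c(1, 1), c(5, 5), "dbl"), 3L)
  expect_equal(exact_distance_oracle(c(7, 7), c(1, 1), "dbl"), 1L)
})

test_that("removing a shared position never increases the exact distance", {
  set.seed(55)
  for (rep in 1:25) {
    u <- sample(1:4, 3, replace = TRUE)
    v <- sample(1:4, 3, replace = TRUE)
    d <- exact_distance_oracle(u, v, "any")
    for (i in 1:3)
      expect_lte(exact_distance_oracle(u[-i], v[-i], "any"), d)
  }
})
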