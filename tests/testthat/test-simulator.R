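# Clone-tree simulator: uniform topology sampling, branch event counts,
# chromosome evolution, profile extraction, and measurement noise.

test_that("tree sampling is uniform over labeled topologies", {
  expect_error(sample_tree(1), ">= 2")
  tr <- sample_tree(2)
  expect_equal(sort(tr$tip.label), c("1", "2"))
  expect_equal(tr$Nnode, 1L)
  set.seed(88)
  # l = 3: the three labeled topologies should be equifrequent
  keys3 <- replicate(3000, canonical_topology(sample_tree(3)))
  tab3 <- table(keys3)
  expect_equal(length(tab3), 3L)
  expect_gt(stats::chisq.test(tab3)$p.value, 0.01)
  # l = 5: all 105 labeled topologies, uniform by chi-square
  keys5 <- replicate(8400, canonical_topology(sample_tree(5)))
  tab5 <- table(keys5)
  expect_equal(length(tab5), 105L)
  expect_gt(stats::chisq.test(tab5)$p.value, 0.001)
})

test_that("branch event counts follow the pinned and full distributions", {
  cfg <- sim_config(e_min = 5, e_max = 10)
  set.seed(11)
  ks <- replicate(6000, sample_branch_event_count(cfg, multiplier = 1))
  expect_setequal(unique(ks), 5:10)
  expect_gt(stats::chisq.test(table(ks))$p.value, 0.01)
  cfg2 <- sim_config(e_min = 2, e_max = 2)
  expect_true(all(replicate(50, sample_branch_event_count(cfg2, multiplier = 1)) == 2L))
  # full model: mean of k*max(m, 0) with m ~ U(1 - sqrt(3), 1 + sqrt(3));
  # E[max(m, 0)] = (1 + sqrt(3))^2 / (4 * sqrt(3)) by integrating the
  # positive part of the density
  emax <- (1 + sqrt(3))^2 / (4 * sqrt(3))
  draws <- replicate(40000, sample_branch_event_count(cfg))
  mu <- 7.5 * emax
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mu), 3 * se + 0.25)  # 0.25 covers rounding bias
  expect_true(all(draws >= 0L))
})

test_that("chromosome evolution respects length and copy accounting", {
  cfg <- sim_config(n = 10)
  expect_identical(evolve_chromosome(1:10, 0, cfg), 1:10)
  # r = 1 stops extension immediately: every event has length exactly 1
  cfg1 <- sim_config(n = 10, r = 1, dup_prob = 1)
  set.seed(5)
  out <- evolve_chromosome(1:10, 7, cfg1)
  expect_equal(length(out), 17L)
  # a duplication adds its own length and bumps each duplicated gene by one
  set.seed(9)
  cfgd <- sim_config(n = 12, dup_prob = 1)
  s0 <- 1:12
  s1 <- evolve_chromosome(s0, 1, cfgd)
  added <- length(s1) - length(s0)
  expect_gt(added, 0L)
  diffcnp <- cnp_of(s1, 12) - cnp_of(s0, 12)
  expect_equal(sum(diffcnp), added)
  expect_true(all(diffcnp %in% c(0L, 1L)))
  # deletions never increase a count; duplications never shrink the gene set
  set.seed(33)
  cfgx <- sim_config(n = 15, dup_prob = 0)
  s2 <- evolve_chromosome(1:15, 5, cfgx)
  expect_true(all(cnp_of(s2, 15) <= 1L))
  expect_gt(length(s2), 0L)
})

test_that("profiles count gene occurrences", {
  expect_equal(cnp_of(1:5, 5), rep(1L, 5))
  expect_equal(cnp_of(c(1, 2, 2, 4), 4), c(1L, 2L, 0L, 1L))
  expect_equal(cnp_of(integer(), 4), rep(0L, 4))
  expect_error(cnp_of(c(1, 9), 4), "1..n")
})

test_that("simulated instances are reproducible and conserve gene counts", {
  cfg <- sim_config(l = 12, n = 30, seed = 77)
  a <- simulate_instance(cfg)
  b <- simulate_instance(cfg)
  expect_identical(a$profiles, b$profiles)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$event_counts, b$event_counts)
  expect_equal(dim(a$profiles), c(12L, 30L))
  expect_true(all(a$profiles >= 0L))
  # profile entries sum to the sequence length at every leaf
  for (i in 1:12)
    expect_equal(sum(a$profiles[i, ]), length(a$sequences[[i]]))
  # no evolution: every leaf keeps the exemplar profile
  z <- simulate_instance(sim_config(l = 6, n = 9, e_min = 0, e_max = 0, seed = 1))
  expect_true(all(z$profiles == 1L))
})

test_that("relaxing the last-copy guard inflates the null proportion", {
  p_strict <- mean(simulate_instance(sim_config(l = 25, q = 0, seed = 5))$profiles == 0)
  p_loose <- mean(simulate_instance(sim_config(l = 25, q = 1, seed = 5))$profiles == 0)
  expect_equal(p_strict, 0)   # q = 0 forbids losing any last copy entirely
  expect_gt(p_loose, 0.2)
})

test_that("measurement noise has the stated moments and fixes nulls", {
  u <- c(10L, 0L, 3L)
  expect_identical(add_noise(u, 0), u)
  set.seed(61)
  draws <- t(replicate(20000, add_noise(u, 0.1)))
  expect_true(all(draws[, 2] == 0L))
  expect_lt(abs(mean(draws[, 1]) - 10), 0.05)
  expect_lt(abs(stats::sd(draws[, 1]) - 1), 0.05)
  expect_true(all(draws >= 0L))
})
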