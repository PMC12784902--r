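test_that("summarize_flies computes proportions, rates and exclusions", {
  ev <- tiny_events()
  fl <- summarize_flies(ev, observation_minutes = 120, min_turns = 1)
  f1 <- fl[fl$fly_id == "f1", ]
  expect_equal(f1$prop_right, 0.75)
  expect_equal(f1$n_turns, 4L)
  expect_equal(fl[fl$fly_id == "f2", ]$prop_right, 1 / 3)

  # 144 events over 120 min -> 1.2 turns/min
  many <- tibble::tibble(fly_id = "f3", treatment = "ctrl",
                         time_s = seq_len(144),
                         direction = rep(c("L", "R"), 72))
  fm <- summarize_flies(many, observation_minutes = 120, min_turns = 1)
  expect_equal(fm$turns_per_min, 1.2)

  # a zero-event fly from the roster is excluded with a reason
  roster <- tibble::tibble(fly_id = c("f1", "f2", "f9"),
                           treatment = "ctrl")
  fl2 <- summarize_flies(ev, min_turns = 1, roster = roster)
  exc <- excluded_flies(fl2)
  expect_equal(exc$fly_id, "f9")
  expect_equal(exc$reason, "insufficient_turns")

  # the min_turns filter excludes low-count flies
  fl3 <- summarize_flies(ev, min_turns = 4)
  expect_equal(fl3$fly_id, "f1")
  expect_equal(excluded_flies(fl3)$fly_id, "f2")
})

test_that("summarize_flies rejects bad directions and duplicate timestamps", {
  ev <- tiny_events()
  ev$direction[2] <- "left"
  expect_error(summarize_flies(ev), "left")
  ev2 <- tiny_events()
  ev2$time_s[2] <- ev2$time_s[1]
  expect_error(summarize_flies(ev2), "duplicate")
})

test_that("group_mad matches direct enumeration and its invariances", {
  expect_equal(group_mad(c(0.5, 0.5, 0.5)), 0)
  expect_equal(group_mad(c(0.2, 0.5, 0.5, 0.8, 0.9)), 0.3)
  expect_error(group_mad(numeric(0)), "at least one")
  expect_error(group_mad(c(1, NA)), "finite")

  set.seed(31)
  for (i in 1:200) {
    n <- sample(1:40, 1)
    x <- if (runif(1) < 0.5) round(runif(n), 1) else rnorm(n)  # heavy ties half the time
    expect_equal(group_mad(x), oracle_mad(x))
    c0 <- runif(1, -5, 5)
    k <- runif(1, 0.1, 4)
    expect_equal(group_mad(x + c0), group_mad(x))
    expect_equal(group_mad(k * x), k * group_mad(x))
    expect_equal(group_mad(sample(x)), group_mad(x))
  }
})

test_that("perm_test_mad is deterministic, valid under exchange, and matches enumeration", {
  a <- sample_bias(0.5, 30, 20, seed = 1)
  r1 <- perm_test_mad(a, a, n_iter = 500, seed = 9)
  r2 <- perm_test_mad(a, a, n_iter = 500, seed = 9)
  expect_identical(r1[names(r1) != "fit"], r2[names(r2) != "fit"])
  expect_equal(r1$stat_observed, 0)
  expect_gt(r1$p_value, 0.5)
  expect_true(r1$p_value > 0 && r1$p_value <= 1)

  # Monte-Carlo p within 3 binomial SEs of the exhaustive p on tiny groups
  set.seed(77)
  for (sizes in list(c(3, 3), c(4, 3))) {
    x <- rnorm(sizes[1])
    y <- rnorm(sizes[2], sd = 3)
    p_exact <- exhaustive_perm_p(x, y)
    mc <- perm_test_mad(x, y, n_iter = 4000, seed = 5)
    se <- sqrt(p_exact * (1 - p_exact) / 4000)
    expect_lt(abs(mc$p_value - p_exact), 3 * se + 2 / 4000)
  }
  expect_error(perm_test_mad(1, c(1, 2)), "at least 2")
})

test_that("bootstrap_mad propagates degeneracy and brackets the point estimate", {
  z <- bootstrap_mad(rep(0.4, 10), n_boot = 200, seed = 1)
  expect_equal(z$boot_se, 0)
  expect_equal(c(z$ci_low, z$ci_high), c(0, 0))

  b <- bootstrap_mad(c(0.2, 0.5, 0.5, 0.8, 0.9), n_boot = 4000, seed = 2)
  expect_lte(b$ci_low, 0.3)
  expect_gte(b$ci_high, 0.3)
  expect_equal(b$mad, 0.3)

  # determinism under seed
  b2 <- bootstrap_mad(c(0.2, 0.5, 0.5, 0.8, 0.9), n_boot = 4000, seed = 2)
  expect_identical(b, b2)
})

test_that("bootstrap percentile CI covers the population MAD at nominal-ish rate", {
  # population MAD of Beta(5,5) by large-sample brute force
  set.seed(123)
  pop <- rbeta(2e5, 5, 5)
  pop_mad <- oracle_mad(pop)
  cover <- 0L
  reps <- 60
  for (r in seq_len(reps)) {
    x <- sample_bias(0.5, 10, 120, seed = 3000 + r)
    ci <- bootstrap_mad(x, n_boot = 400, seed = r)
    if (ci$ci_low <= pop_mad && pop_mad <= ci$ci_high) cover <- cover + 1L
  }
  expect_gte(cover / reps, 0.85)
})

test_that("group_variability returns one seeded row per treatment", {
  fl <- two_group_flies(n = 40)
  gv <- group_variability(fl, n_boot = 300, seed = 4)
  expect_equal(nrow(gv), 2)
  expect_equal(gv$n_flies, c(40L, 40L))
  expect_true(all(gv$ci_low <= gv$mad & gv$mad <= gv$ci_high))
  expect_gt(gv$mad[gv$treatment == "b"], gv$mad[gv$treatment == "a"])
  # per-fly variant runs on the choice_mad column
  gv2 <- group_variability(fl, n_boot = 300, seed = 4, per_fly = TRUE)
  expect_equal(gv2$mad, c(0, 0))
})

test_that("pairwise_mad_tests reports raw and BH-adjusted p-values per pair", {
  fl <- dplyr::bind_rows(
    two_group_flies(n = 30, k_a = 50, k_b = 50, seed = 2),
    dplyr::mutate(two_group_flies(n = 30, k_a = 8, k_b = 8, seed = 5),
                  treatment = ifelse(treatment == "a", "c", "d"),
                  fly_id = paste0("x", fly_id)))
  res <- pairwise_mad_tests(fl, n_iter = 300, seed = 1)
  expect_equal(nrow(res), choose(4, 2))
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  # deterministic under the master seed
  res2 <- pairwise_mad_tests(fl, n_iter = 300, seed = 1)
  expect_identical(res, res2)
})

test_that("tidy and glance summarize a permutation test", {
  a <- sample_bias(0.5, 40, 30, seed = 1)
  b <- sample_bias(0.5, 8, 30, seed = 2)
  t <- perm_test_mad(a, b, n_iter = 200, seed = 3,
                     group_a = "tight", group_b = "loose")
  td <- generics::tidy(t)
  expect_equal(td$group, c("tight", "loose"))
  expect_equal(td$mad, c(oracle_mad(a), oracle_mad(b)))
  gl <- generics::glance(t)
  expect_equal(gl$stat_observed, oracle_mad(a) - oracle_mad(b))
  expect_equal(gl$n_iter, 200L)
})
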