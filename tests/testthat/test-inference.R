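make_flies <- function(groups) {
  tibble::tibble(
    fly_id = sprintf("f%02d", seq_len(sum(lengths(groups)))),
    treatment = rep(names(groups), lengths(groups)),
    n_turns = 50L,
    prop_right = unlist(groups, use.names = FALSE),
    choice_mad = 0,
    turns_per_min = unlist(groups, use.names = FALSE)
  )
}

test_that("anova_bias reproduces hand-computed F and label invariance", {
  fl <- make_flies(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  res <- anova_bias(fl)
  expect_equal(res$statistic, 13.5)
  expect_equal(c(res$df1, res$df2), c(1, 4))

  # identical groups: zero between-group variance
  fl0 <- make_flies(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_equal(anova_bias(fl0)$statistic, 0)

  # relabeling groups jointly with values leaves F unchanged
  set.seed(4)
  vals <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8))
  f1 <- anova_bias(make_flies(vals))$statistic
  f2 <- anova_bias(make_flies(setNames(vals, c("c", "a", "b"))))$statistic
  expect_equal(f1, f2)

  expect_error(anova_bias(make_flies(list(a = 1, b = c(1, 2)))), ">= 2")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(12)
    y <- rnorm(10, mean = 0.3)
    fl <- make_flies(list(a = x, b = y))
    f <- anova_bias(fl)$statistic
    t2 <- unname(t.test(x, y, var.equal = TRUE)$statistic^2)
    expect_equal(f, t2)
  }
})

test_that("anova_bias attaches Shapiro-Wilk and Brown-Forsythe diagnostics", {
  set.seed(2)
  fl <- make_flies(list(a = rnorm(30), b = rnorm(30), c = rnorm(30, sd = 2)))
  d <- anova_bias(fl)$diagnostics
  expect_true(all(is.finite(unlist(d))))
  # cross-check Levene against an independent median-centered one-way F
  z <- abs(fl$prop_right - ave(fl$prop_right, fl$treatment, FUN = median))
  ref <- anova(lm(z ~ factor(fl$treatment)))
  expect_equal(d$levene_stat, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(d$levene_p, ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("kruskal_activity matches the rank formula and handles degeneracy", {
  fl <- make_flies(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)))
  res <- kruskal_activity(fl)
  expect_equal(res$statistic, 32 / 7, tolerance = 1e-10)  # 4.571
  expect_equal(res$df1, 2)

  # identical multisets across two groups: H = 0
  fl0 <- make_flies(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(kruskal_activity(fl0)$statistic, 0, tolerance = 1e-12)

  # all observations identical: defined as H = 0, p = 1
  flc <- make_flies(list(a = c(2, 2), b = c(2, 2)))
  r0 <- kruskal_activity(flc)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # invariance under strictly monotone transforms
  set.seed(8)
  vals <- list(a = runif(7), b = runif(9), c = runif(5))
  h1 <- kruskal_activity(make_flies(vals))$statistic
  h2 <- kruskal_activity(make_flies(lapply(vals, function(v) exp(3 * v))))$statistic
  expect_equal(h1, h2)
})

test_that("tie-corrected H matches a brute-force rank computation with ties", {
  # direct tie-corrected rank formula, independent implementation
  kw_oracle <- function(groups) {
    y <- unlist(groups, use.names = FALSE)
    g <- rep(seq_along(groups), lengths(groups))
    N <- length(y)
    r <- rank(y)
    rbar <- tapply(r, g, mean)
    n <- lengths(groups)
    h <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
    tt <- table(y)
    h / (1 - sum(tt^3 - tt) / (N^3 - N))
  }
  set.seed(13)
  for (i in 1:20) {
    groups <- list(a = sample(1:4, 3, TRUE), b = sample(1:4, 3, TRUE),
                   c = sample(1:4, 2, TRUE))
    if (length(unique(unlist(groups))) == 1) next
    expect_equal(kruskal_activity(make_flies(groups))$statistic,
                 kw_oracle(groups), tolerance = 1e-10)
  }
})

test_that("mann_whitney_u: exact branch, symmetry and antisymmetry", {
  m <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(m$u_statistic, 0)
  expect_equal(m$p_raw, 0.1)
  expect_equal(m$method, "exact")

  # identical lists: U sits at the midpoint n_a * n_b / 2
  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$u_statistic, 8)

  m3 <- mann_whitney_u(c(1, 2, 3, 4), c(1.5, 2.5, 3.5, 0.5))
  swap <- mann_whitney_u(c(1.5, 2.5, 3.5, 0.5), c(1, 2, 3, 4))
  expect_equal(swap$u_statistic, 16 - m3$u_statistic)
  expect_equal(swap$p_raw, m3$p_raw)

  # exact branch agrees with exhaustive enumeration, tie-free n <= 6
  exact_oracle <- function(a, b) {
    pooled <- c(a, b)
    N <- length(pooled)
    u_of <- function(ix) sum(rank(pooled)[ix]) - length(ix) * (length(ix) + 1) / 2
    obs <- u_of(seq_along(a))
    all_u <- vapply(utils::combn(N, length(a), simplify = FALSE), u_of,
                    numeric(1))
    mu <- length(a) * length(b) / 2
    mean(abs(all_u - mu) >= abs(obs - mu))
  }
  set.seed(3)
  for (i in 1:15) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    v <- sample(seq(0.01, 0.99, by = 0.01), na + nb)  # tie-free
    a <- v[1:na]; b <- v[-(1:na)]
    m <- mann_whitney_u(a, b)
    expect_equal(m$method, "exact")
    expect_equal(m$p_raw, exact_oracle(a, b), tolerance = 1e-10)
  }
})

test_that("MWU normal-approximation branch stays near the exact branch at n = 8", {
  set.seed(21)
  for (i in 1:10) {
    v <- sample(seq_len(500), 16) / 500
    a <- v[1:8]; b <- v[9:16]
    p_exact <- mann_whitney_u(a, b, exact_max = 8)$p_raw
    p_norm <- mann_whitney_u(a, b, exact_max = 0)$p_raw
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("bh_adjust reproduces the step-up computation and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  # independent hand implementation of the step-up rule
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
    out <- numeric(m)
    out[o] <- q
    out
  }
  set.seed(6)
  for (i in 1:50) {
    p <- runif(sample(1:10, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
  }
})

test_that("bh_adjust controls FDR under independent uniform nulls", {
  # m = 3 independent true nulls: P(any adjusted p < alpha) should be ~ alpha
  set.seed(99)
  alpha <- 0.05
  reps <- 1000
  fp <- 0L
  for (r in seq_len(reps)) {
    if (any(bh_adjust(runif(3)) < alpha)) fp <- fp + 1L
  }
  se <- sqrt(alpha * (1 - alpha) / reps)
  expect_lt(abs(fp / reps - alpha), 3.5 * se)
})

test_that("pairwise_activity adjusts the three comparisons as one family", {
  set.seed(44)
  fl <- make_flies(list(a = rlnorm(40, 0, 0.5), b = rlnorm(40, 0.6, 0.5),
                        c = rlnorm(40, 0, 0.5)))
  res <- pairwise_activity(fl)
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_adjusted >= res$p_raw))
  expect_equal(res$p_adjusted, bh_adjust(res$p_raw))
  expect_equal(unique(res$method), "mann_whitney_bh")
})

test_that("significance letters separate only significantly different groups", {
  pw <- tibble::tibble(group_a = c("a", "a", "b"),
                       group_b = c("b", "c", "c"),
                       p_adjusted = c(0.01, 0.80, 0.03))
  lt <- significance_letters(pw)
  l <- setNames(lt$letters, lt$treatment)
  shares <- function(x, y) any(strsplit(l[[x]], "")[[1]] %in%
                               strsplit(l[[y]], "")[[1]])
  expect_false(shares("a", "b"))
  expect_true(shares("a", "c"))
  expect_false(shares("b", "c"))
})
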