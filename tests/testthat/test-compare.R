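# Independent oracles: exhaustive-window HDI search and O(n*m) pairwise
# AUC enumeration.
hdi_oracle <- function(draws, mass) {
  s <- sort(draws)
  n <- length(s)
  k <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - k + 1)) {
    if (s[i + k - 1] - s[i] < best[2] - best[1]) best <- c(s[i], s[i + k - 1])
  }
  best
}

auc_oracle <- function(e, r) {
  total <- 0
  for (x in e) total <- total + sum(x > r) + 0.5 * sum(x == r)
  total / (length(e) * length(r))
}

test_that("hdi equals the exhaustive shortest-window oracle", {
  expect_equal(unname(hdi(rep(3.5, 20))), c(3.5, 3.5))
  expect_equal(unname(hdi(1:20, 0.9)), hdi_oracle(1:20, 0.9))
  set.seed(42)
  for (i in 1:25) {
    draws <- switch(1 + i %% 3, rnorm(60), rexp(45), c(rnorm(30), rnorm(20, 6)))
    mass <- sample(c(0.5, 0.8, 0.9, 0.95), 1)
    expect_equal(unname(hdi(draws, mass)), hdi_oracle(draws, mass))
  }
  expect_error(hdi(1:5), ">= 10")
  expect_error(hdi(1:20, 1.2), "mass")
})

test_that("hdi matches analytic normal quantiles and widens with mass", {
  set.seed(1)
  z <- rnorm(1e5)
  h <- hdi(z, 0.95)
  expect_equal(unname(h), c(-1.96, 1.96), tolerance = 0.05 / 1.96)
  # width non-decreasing in mass; mass -> 1 approaches the full range
  masses <- c(0.5, 0.7, 0.9, 0.95, 0.999999)
  widths <- vapply(masses, function(m) diff(hdi(z, m)), numeric(1))
  expect_true(all(diff(widths) >= 0))
  expect_equal(unname(hdi(z, 0.999999)), range(z), tolerance = 1e-6)
})

test_that("kde_mode finds the most probable value", {
  expect_equal(kde_mode(rep(2.25, 50)), 2.25)
  set.seed(2)
  expect_lt(abs(kde_mode(rnorm(1e5))), 0.1)
  expect_lt(abs(kde_mode(stats::rchisq(1e5, df = 4)) - 2), 0.3)
  expect_error(kde_mode(1:5), ">= 10")
})

test_that("auc_superiority equals pairwise enumeration with midrank ties", {
  expect_equal(auc_superiority(c(3, 5), c(1, 4)), 0.75)
  expect_equal(auc_superiority(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(auc_superiority(c(10, 11), c(1, 2)), 1.0)
  set.seed(3)
  for (i in 1:30) {
    n <- sample(1:200, 1); m <- sample(1:200, 1)
    # duplicate-heavy draws exercise the tie correction
    e <- sample(round(rnorm(n, 0, 2)), n, replace = TRUE)
    r <- sample(round(rnorm(m, 1, 2)), m, replace = TRUE)
    expect_equal(auc_superiority(e, r), auc_oracle(e, r))
  }
  expect_error(auc_superiority(numeric(0), 1:3), "non-empty")
})

test_that("auc obeys symmetry and monotone-transform invariance", {
  set.seed(4)
  for (i in 1:10) {
    e <- rnorm(80); r <- rnorm(60, 0.5)
    expect_equal(auc_superiority(e, r) + auc_superiority(r, e), 1,
                 tolerance = 1e-12)
    tr <- function(x) exp(x) + x^3 # strictly increasing
    expect_equal(auc_superiority(tr(e), tr(r)), auc_superiority(e, r))
  }
})

test_that("overlap matches the analytic coefficient for shifted normals", {
  set.seed(5)
  a <- rnorm(1e5); b <- rnorm(1e5, 1)
  # two unit normals one apart: overlap = 2 * pnorm(-1/2) = 0.617
  expect_equal(overlap(a, b), 2 * pnorm(-0.5), tolerance = 0.02 / 0.617)
  expect_gte(overlap(a, a), 0.99)
  expect_lte(overlap(a, rnorm(1e4, 10)), 0.01)
  # invariance under a common location/scale shift
  expect_equal(overlap(3 + 2 * a[1:5000], 3 + 2 * b[1:5000]),
               overlap(a[1:5000], b[1:5000]), tolerance = 1e-8)
  expect_error(overlap(1:5, 1:20), ">= 10")
  expect_error(overlap(rep(1, 20), 1:20), "degenerate")
})

test_that("summarize_effect assembles all four statistics coherently", {
  set.seed(6)
  draws <- rnorm(2000, 15, 3)
  rope <- rope_distribution(draws, "subjective")
  s <- summarize_effect(draws, rope)
  expect_s3_class(s, "effect_summary")
  expect_equal(s$auc_vs_rope, 0.5)
  expect_gte(s$overlap_vs_rope, 0.99)
  expect_equal(s$mode, 15, tolerance = 0.5)

  # total separation: effect 10 ROPE SDs above the ROPE
  far <- rnorm(2000, mean(draws) + 10 * sd(draws), 3)
  s2 <- summarize_effect(far, rope)
  expect_gte(s2$auc_vs_rope, 0.999)
  expect_lte(s2$overlap_vs_rope, 0.01)
  expect_output(print(s2), "HDI")
})

test_that("rope_distribution validates its draws", {
  expect_error(rope_distribution(1:50), ">= 100")
  expect_error(rope_distribution(c(rep(1, 200), NA)), "finite")
  r <- rope_distribution(rnorm(200), "external")
  expect_identical(r$source, "external")
})
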