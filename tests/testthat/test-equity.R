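test_that("gap and equilibrium index follow their closed forms", {
  expect_equal(accessibility_gap(c(0.41, 0.45, 1.0)), 0.59)
  expect_equal(accessibility_gap(rep(0.7, 5)), 0)
  expect_equal(equilibrium_index(c(3, 1)), 0.5)
  expect_equal(equilibrium_index(rep(2, 4)), 0)
  expect_equal(equilibrium_index(c(0, 0, 0)), 0)
  expect_error(accessibility_gap(numeric(0)), "non-empty")
})

test_that("dispersion statistics behave under scaling and equalization", {
  set.seed(42)
  for (i in 1:10) {
    a <- runif(7, 0.05, 3)
    w <- runif(7, 100, 10000)
    c0 <- runif(1, 0.1, 10)
    expect_equal(equilibrium_index(c0 * a), equilibrium_index(a),
                 tolerance = 1e-12)
    expect_equal(accessibility_gap(c0 * a), c0 * accessibility_gap(a),
                 tolerance = 1e-12)
    expect_equal(gini_coefficient(c0 * a, w), gini_coefficient(a, w),
                 tolerance = 1e-12)
    # mean-preserving transfer from the max to the min never raises spread
    a2 <- a
    step <- (max(a) - min(a)) * 0.2
    a2[which.max(a)] <- max(a) - step
    a2[which.min(a)] <- min(a) + step
    expect_lte(accessibility_gap(a2), accessibility_gap(a))
    expect_lte(equilibrium_index(a2), equilibrium_index(a))
    expect_lte(gini_coefficient(a2), gini_coefficient(a) + 1e-12)
  }
})

test_that("weighted Gini agrees with the pairwise-difference oracle", {
  gini_pairwise <- function(a, w) {
    mu <- sum(w * a) / sum(w)
    sum(outer(w, w) * abs(outer(a, a, "-"))) / (2 * sum(w)^2 * mu)
  }
  expect_equal(gini_coefficient(rep(1.3, 6)), 0)
  expect_equal(gini_coefficient(c(0, 2)), 0.5)
  set.seed(7)
  for (i in 1:20) {
    n <- sample(2:9, 1)
    a <- runif(n, 0, 5)
    w <- runif(n, 1, 1000)
    expect_equal(gini_coefficient(a, w), gini_pairwise(a, w),
                 tolerance = 1e-12)
    expect_equal(gini_coefficient(a), gini_pairwise(a, rep(1, n)),
                 tolerance = 1e-12)
  }
  expect_error(gini_coefficient(numeric(0)), "empty")
  expect_error(gini_coefficient(c(1, 2), c(0, 0)), "positive")
})

test_that("equity report bundles consistent statistics", {
  a <- c(2.45, 1.05, 0.72, 0.37, 0.17, 0.09)
  w <- c(146, 3285, 3463, 1061, 5820, 9349)
  rep_ <- equity_report(a, w)
  expect_s3_class(rep_, "equity_report")
  expect_equal(rep_$gap, 2.36)
  expect_equal(rep_$equilibrium_index, 2.36 / 2.54)
  expect_true(rep_$a_min <= rep_$mean && rep_$mean <= rep_$a_max)
  expect_gte(rep_$gini, 0)
  expect_lte(rep_$gini, 1)
  df <- as.data.frame(rep_)
  expect_equal(df$gap, rep_$gap)
})
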