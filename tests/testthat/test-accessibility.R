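test_that("decay weight follows the power law with floor and threshold", {
  spec <- decay_spec(beta = 2)
  expect_equal(decay_weight(1, spec), 1)
  expect_equal(decay_weight(2, spec), 0.25)
  expect_equal(decay_weight(5, decay_spec(beta = 2, d0 = 3)), 0)
  # floor caps the divergence at zero distance
  expect_equal(decay_weight(0, spec), 0.1^-2)
  expect_equal(decay_weight(0.01, decay_spec(beta = 1, d_floor = 0.5)), 2)
  # beta = 0 gives unit weight inside the catchment
  expect_equal(decay_weight(c(0, 3, 100), decay_spec(beta = 0)),
               c(1, 1, 1))
  expect_error(decay_weight(-1, spec), "finite and >= 0")
})

test_that("site supply ratio divides resource by catchment population", {
  expect_equal(supply_ratio(10, c(1, 2), c(100, 100), d0 = 5), 0.05)
  expect_equal(supply_ratio(0, c(1, 2), c(100, 100), d0 = 5), 0)
  expect_equal(supply_ratio(12, c(1, 2, 3), c(100, 200, 300), d0 = 5), 0.02)
  # out-of-catchment divisions do not count
  expect_equal(supply_ratio(10, c(1, 9), c(100, 100), d0 = 5), 0.1)
  expect_warning(r <- supply_ratio(10, c(9, 9), c(100, 100), d0 = 5),
                 "empty catchment")
  expect_equal(r, 0)
})

test_that("gravity accessibility reproduces the hand-worked two-division case", {
  costs <- matrix(c(1, 2), 1, dimnames = list("j1", c("k1", "k2")))
  a <- offline_accessibility(12, costs, c(100, 200), decay_spec(beta = 2))
  expect_equal(unname(a), c(0.08, 0.02))
  # supply is fully distributed over demand
  expect_equal(sum(c(100, 200) * a), 12)
})

test_that("beta = 0 collapses the gravity form to the uniform ratio", {
  inst <- random_instance(11)
  M <- inst$divisions$pop_chronic
  is_c <- inst$sites$tier == "community"
  S <- inst$sites$resource_offline[is_c]
  a <- offline_accessibility(S, inst$costs[is_c, , drop = FALSE], M,
                             decay_spec(beta = 0))
  expect_equal(unname(a), rep(sum(S) / sum(M), length(M)))
})

test_that("hard-threshold two-step sums agree with the gravity form when decay is flat", {
  for (seed in 1:5) {
    inst <- random_instance(seed)
    M <- inst$divisions$pop_chronic
    is_c <- inst$sites$tier == "community"
    S <- inst$sites$resource_offline[is_c]
    costs <- inst$costs[is_c, , drop = FALSE]
    a_thresh <- catchment_accessibility(S, costs, M, d0 = Inf)
    a_decay <- offline_accessibility(S, costs, M, decay_spec(beta = 0))
    expect_equal(a_thresh, a_decay, tolerance = 1e-12)
  }
})

test_that("symmetric instances yield a constant profile", {
  fix <- make_fixture_suite(1)$uniform
  fit <- baseline_fit(fix)
  expect_equal(diff(range(fit$profile$a_total)), 0, tolerance = 1e-12)
})

test_that("offline supply is conserved and accessibility is homogeneous in supply", {
  for (seed in 1:20) {
    inst <- random_instance(seed)
    M <- inst$divisions$pop_chronic
    is_c <- inst$sites$tier == "community"
    S <- inst$sites$resource_offline[is_c]
    costs <- inst$costs[is_c, , drop = FALSE]
    a <- offline_accessibility(S, costs, M, decay_spec(beta = 2))
    expect_equal(sum(M * a), sum(S), tolerance = 1e-9)
    # scaling supply by c scales accessibility by exactly c
    a3 <- offline_accessibility(3 * S, costs, M, decay_spec(beta = 2))
    expect_equal(a3, 3 * a, tolerance = 1e-12)
  }
})

test_that("referral blend conserves total resource and hits its endpoints", {
  inst <- random_instance(3)
  M <- inst$divisions$pop_chronic
  is_c <- inst$sites$tier == "community"
  spec <- decay_spec(beta = 2)
  a_c <- offline_accessibility(inst$sites$resource_offline[is_c],
                               inst$costs[is_c, , drop = FALSE], M, spec)
  a_t <- offline_accessibility(inst$sites$resource_offline[!is_c],
                               inst$costs[!is_c, , drop = FALSE], M, spec)
  expect_equal(referral_accessibility(a_c, a_t, 0), a_c)
  expect_equal(referral_accessibility(a_c, a_t, 1), a_t)
  expect_equal(referral_accessibility(c(k1 = 0.08), c(k1 = 0.02), 0.5),
               c(k1 = 0.05))
  r <- 0.3
  blend <- referral_accessibility(a_c, a_t, r)
  expect_equal(sum(M * blend),
               (1 - r) * sum(inst$sites$resource_offline[is_c]) +
                 r * sum(inst$sites$resource_offline[!is_c]),
               tolerance = 1e-9)
  expect_error(referral_accessibility(a_c, a_t[-1], 0.2), "mismatched")
})

test_that("online accessibility matches the pooled-supply formula", {
  M <- c(k1 = 100, k2 = 200)
  Q <- c(k1 = 0.35, k2 = 0.1)
  a <- online_accessibility(c(4, 2), Q, M)
  expect_equal(unname(a), c(6 * 0.35 / 55, 6 * 0.1 / 55))
  # identical preference cancels out of the as-printed form
  aq <- online_accessibility(c(4, 2), c(k1 = 0.2, k2 = 0.2), M)
  expect_equal(unname(aq), rep(6 / 300, 2))
  expect_equal(unname(online_accessibility(c(0, 0), Q, M)), c(0, 0))
  # no online demand anywhere: defined zero
  expect_equal(unname(online_accessibility(c(4, 2), c(k1 = 0, k2 = 0), M)),
               c(0, 0))
})

test_that("online supply is conserved in conserving mode and monotone in V", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(3:8, 1)
    M <- runif(n, 100, 5000)
    Q <- runif(n)
    V <- runif(3, 0, 50)
    a <- online_accessibility(V, Q, M, mode = "conserving")
    expect_equal(sum(M * Q * a), sum(V), tolerance = 1e-9)
    # raising any V_i weakly increases a^v, strictly where Q_k > 0
    V2 <- V + c(5, 0, 0)
    a2 <- online_accessibility(V2, Q, M, mode = "as_printed")
    a1 <- online_accessibility(V, Q, M, mode = "as_printed")
    expect_true(all(a2 >= a1))
    expect_true(all(a2[Q > 0] > a1[Q > 0]))
  }
})

test_that("combined index reduces to its offline and online limits", {
  inst <- random_instance(5)
  M <- inst$divisions$pop_chronic
  is_c <- inst$sites$tier == "community"
  spec <- decay_spec(beta = 2)
  a_c <- offline_accessibility(inst$sites$resource_offline[is_c],
                               inst$costs[is_c, , drop = FALSE], M, spec)
  a_t <- offline_accessibility(inst$sites$resource_offline[!is_c],
                               inst$costs[!is_c, , drop = FALSE], M, spec)
  a_v <- online_accessibility(c(10, 20), rep(0.35, length(M)), M)
  r <- 0.2
  zero <- rep(0, length(M))
  expect_equal(combined_accessibility(a_c, a_t, a_v, Q = zero, r = r),
               referral_accessibility(a_c, a_t, r))
  one <- rep(1, length(M))
  expect_equal(unname(combined_accessibility(a_c, a_t, a_v, Q = one, r = r)),
               unname(a_v))
  expect_error(combined_accessibility(a_c, a_t, a_v, Q = one + 1, r = r),
               "Q outside")
})

test_that("combined index matches the hand-worked blended example", {
  # community 0.08/0.02, tertiary 0.02/0.08, r = 0.5, V sums to 6
  a_c <- c(k1 = 0.08, k2 = 0.02)
  a_t <- c(k1 = 0.02, k2 = 0.08)
  M <- c(k1 = 100, k2 = 200)
  Q <- c(k1 = 0.35, k2 = 0.1)
  a_v <- online_accessibility(6, Q, M)
  a <- combined_accessibility(a_c, a_t, a_v, Q, r = 0.5)
  expect_equal(a[["k1"]], 0.65 * 0.05 + 0.35 * 6 * 0.35 / 55,
               tolerance = 1e-12)
})

test_that("two-tier preference assignment splits at the regional mean", {
  a <- c(k1 = 0.1, k2 = 0.5, k3 = 1.5)   # mean 0.7
  expect_equal(unname(assign_online_preference(a)), c(0.35, 0.35, 0.1))
  # ties at the mean classify as good access
  expect_equal(unname(assign_online_preference(c(a = 1, b = 1, c = 1))),
               rep(0.1, 3))
  expect_equal(unname(assign_online_preference(a, q_poor = 0.2,
                                               q_good = 0.2)),
               rep(0.2, 3))
  expect_error(assign_online_preference(numeric(0)), "empty")
})

test_that("the model object carries a consistent per-division profile", {
  inst <- random_instance(9)
  fit <- i2sfca(inst)
  prof <- fit$profile
  expect_s3_class(fit, "i2sfca")
  expect_equal(nrow(prof), nrow(inst$divisions))
  expect_true(all(prof[, c("a_comm", "a_tert", "a_online", "a_total")] >= 0))
  with(prof, expect_equal(
    a_total,
    (1 - q_online) * ((1 - 0.2) * a_comm + 0.2 * a_tert) +
      q_online * a_online,
    tolerance = 1e-12))
  expect_equal(fit$mean, mean(prof$a_total))
  expect_equal(unname(coef(fit)), prof$a_total)
})
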