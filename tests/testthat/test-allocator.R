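test_that("program construction counts variables and validates inputs", {
  inst <- random_instance(1, n_tert = 2)
  prob <- allocation_problem(inst, G = 0.7)
  prog <- build_program(prob)
  expect_s3_class(prog, "th_program")
  expect_equal(prog$n_alloc, 2)
  expect_equal(prog$n_var, 4)  # V_1, V_2 + a_min, a_max
  expect_error(allocation_problem(inst, G = 0), "G must be in")
  expect_error(allocation_problem(inst, G = 1.2), "G must be in")
})

test_that("zero online capacity pins the optimum at the offline profile", {
  inst <- random_instance(2)
  res <- allocate_telehealth(inst, G = 1, rho = 0)
  expect_equal(unname(res$V), c(0, 0))
  fit0 <- i2sfca(inst, V = c(0, 0), Q = res$problem$Q)
  expect_equal(res$objective, fit0$mean, tolerance = 1e-9)
})

test_that("G = 1 leaves the equity constraint vacuous and Q = 0 degenerates to V = 0", {
  inst <- random_instance(4)
  # no online demand anywhere: objective independent of V, canonical V = 0
  zQ <- stats::setNames(rep(0, 5), inst$divisions$id)
  params <- th_params(offline_mode = "as_printed")
  res <- solve_allocation(allocation_problem(inst, params = params, G = 1,
                                             Q = zQ))
  expect_equal(res$status, "optimal")
  expect_equal(unname(res$V), c(0, 0))
  expect_equal(res$objective, baseline_fit(inst, params = params)$mean,
               tolerance = 1e-9)
})

test_that("with fixed tertiary offline supply the objective saturates the online cap", {
  # single tertiary site, as-printed offline mode: every unit of V adds
  # online accessibility and costs nothing, so V* = rho * T
  inst <- random_instance(6, n_tert = 1)
  params <- th_params(offline_mode = "as_printed")
  res <- solve_allocation(allocation_problem(inst, params = params, G = 1))
  is_t <- inst$sites$tier == "tertiary_A"
  expect_equal(unname(res$V),
               0.4 * inst$sites$resource_offline[is_t], tolerance = 1e-6)
  # verified by sweep: no coarser allocation beats it
  for (frac in c(0, 0.25, 0.5, 0.75)) {
    V <- frac * 0.4 * inst$sites$resource_offline[is_t]
    fit <- i2sfca(inst, params = params, V = V, Q = res$problem$Q)
    expect_lte(fit$mean, res$objective + 1e-9)
  }
})

test_that("LP optimum agrees with the brute-force grid oracle", {
  for (seed in 1:8) {
    inst <- random_instance(seed, n_div = 4, n_comm = 3, n_tert = 2)
    prob <- allocation_problem(inst, G = 0.9)
    lp <- solve_allocation(prob)
    bf <- brute_force_allocation(prob, grid_steps = 20)
    expect_equal(lp$status, "optimal")
    expect_equal(bf$status, "optimal")
    # grid optimum cannot beat the continuum optimum
    expect_lte(bf$objective, lp$objective + 1e-9)
    expect_lt(abs(lp$objective - bf$objective),
              1e-2 * max(abs(lp$objective), 1e-12))
  }
})

test_that("the grid oracle converges to the LP optimum as the grid refines", {
  inst <- random_instance(12, n_div = 4, n_comm = 3, n_tert = 2)
  prob <- allocation_problem(inst, G = 0.9)
  lp <- solve_allocation(prob)
  gaps <- sapply(c(5, 10, 20), function(steps) {
    lp$objective - brute_force_allocation(prob, steps)$objective
  })
  expect_true(all(gaps >= -1e-9))
  expect_true(all(diff(gaps) <= 1e-9))   # monotone refinement
})

test_that("the oracle guard rejects oversized enumerations", {
  inst <- random_instance(3, n_tert = 5)
  prob <- allocation_problem(inst, G = 0.9)
  expect_error(brute_force_allocation(prob), "guard")
  prob2 <- allocation_problem(random_instance(3, n_tert = 2), G = 0.9)
  expect_error(brute_force_allocation(prob2, grid_steps = 60), "guard")
})

test_that("feasible optima respect the equity bound and resource conservation", {
  city <- generate_city(city_config(seed = 1))
  for (G in c(0.7, 0.9)) {
    res <- allocate_telehealth(city, G = G)
    expect_equal(res$status, "optimal")
    expect_lte(res$achieved_equilibrium_index, G + 1e-6)
    # resource-shift mode conserves total physician time by construction
    is_t <- city$sites$tier == "tertiary_A"
    T_i <- city$sites$resource_offline[is_t]
    expect_equal(sum(T_i - res$V) + sum(res$V), sum(T_i),
                 tolerance = 1e-12)
    expect_true(all(res$V <= 0.4 * T_i + 1e-6))
  }
})

test_that("relaxing the equity bound weakly increases the optimum", {
  city <- generate_city(city_config(seed = 3))
  probs <- lapply(c(0.7, 0.8, 0.9, 1.0), function(G)
    allocate_telehealth(city, G = G))
  objs <- sapply(probs, function(r)
    if (r$status == "optimal") r$objective else NA_real_)
  objs <- objs[!is.na(objs)]
  expect_true(all(diff(objs) >= -1e-9))
})

test_that("an unreachable equity bound reports the minimal achievable index", {
  city <- generate_city(city_config(seed = 1))
  res <- allocate_telehealth(city, G = 0.05)
  expect_equal(res$status, "infeasible")
  g_min <- res$diagnostic$min_achievable_equilibrium_index
  expect_true(is.finite(g_min))
  expect_gt(g_min, 0.05)
  # just above the reported bound the problem solves
  res2 <- allocate_telehealth(city, G = min(1, g_min + 0.01))
  expect_equal(res2$status, "optimal")
})

test_that("integer allocations solve within the stated relative gap", {
  inst <- random_instance(8, n_div = 4, n_comm = 3, n_tert = 2)
  cont <- allocate_telehealth(inst, G = 0.9)
  int <- solve_allocation(allocation_problem(inst, G = 0.9,
                                             integrality = "integer"))
  expect_equal(int$status, "optimal")
  expect_equal(unname(int$V), round(unname(int$V)))
  expect_lte(int$objective, cont$objective + 1e-9)
  expect_lte(int$solver_gap, 0.01 + 1e-9)
})

test_that("the optimum is invariant to division relabeling when preferences collapse", {
  inst <- random_instance(15, n_div = 4, n_comm = 3, n_tert = 2)
  params <- th_params(q_poor = 0.2, q_good = 0.2)
  res1 <- solve_allocation(allocation_problem(inst, params = params, G = 0.9))
  # permute division order
  perm <- c(3, 1, 4, 2)
  inst2 <- th_instance(inst$divisions[perm, ], inst$sites,
                       costs = inst$costs[, perm])
  res2 <- solve_allocation(allocation_problem(inst2, params = params,
                                              G = 0.9))
  expect_equal(res1$objective, res2$objective, tolerance = 1e-8)
  expect_equal(res1$V, res2$V, tolerance = 1e-6)
})
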