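#' Define an online-resource allocation problem
#'
#' Packages an instance with the equity bound and solver options into an
#' allocation problem: choose online allocations \eqn{V_i} of tertiary-A
#' physician time (capped at \eqn{\rho_i T_i}) to maximize the mean combined
#' accessibility subject to the equilibrium-index bound
#' \eqn{(a_{max}-a_{min})/(a_{max}+a_{min}) \le G}.
#'
#' @param instance A [th_instance()].
#' @param decay A [decay_spec()].
#' @param params A [th_params()].
#' @param G Equity bound in (0, 1].
#' @param rho Optional override of the per-tertiary-site online cap fraction
#'   \eqn{\rho_i} (scalar or vector); default: the sites'
#'   \code{online_cap_fraction}.
#' @param Q Optional per-division online preference; default: the instance's
#'   \code{q_online} column if present, else the two-tier baseline rule.
#' @param bounds_mode \code{"variable_extremes"} (default): \eqn{a_{min}},
#'   \eqn{a_{max}} are auxiliary decision variables pinched onto the realized
#'   extremes; \code{"fixed_bounds"}: they are the fixed values in
#'   \code{fixed_bounds}.
#' @param fixed_bounds Length-2 numeric \code{c(a_min, a_max)}, used only in
#'   \code{"fixed_bounds"} mode.
#' @param integrality \code{"continuous"} (default; consultation time is
#'   divisible) or \code{"integer"} (headcount semantics, solved by branch
#'   and bound with a 0.01 relative gap).
#' @return An object of class \code{"allocation_problem"}.
#' @export
allocation_problem <- function(instance, decay = decay_spec(),
                               params = th_params(), G = 0.7, rho = NULL,
                               Q = NULL,
                               bounds_mode = c("variable_extremes",
                                               "fixed_bounds"),
                               fixed_bounds = NULL,
                               integrality = c("continuous", "integer")) {
  stopifnot(inherits(instance, "th_instance"))
  bounds_mode <- match.arg(bounds_mode)
  integrality <- match.arg(integrality)
  if (!is.numeric(G) || length(G) != 1L || G <= 0 || G > 1) {
    stop("allocation_problem: G must be in (0, 1]", call. = FALSE)
  }
  is_t <- instance$sites$tier == "tertiary_A"
  if (!any(is_t)) {
    stop("allocation_problem: no tertiary-A site in instance", call. = FALSE)
  }
  rho_full <- instance$sites$online_cap_fraction[is_t]
  if (!is.null(rho)) {
    stopifnot(all(rho >= 0), all(rho <= 1),
              length(rho) %in% c(1L, sum(is_t)))
    rho_full <- rep(rho, length.out = sum(is_t))
  }
  if (is.null(Q)) {
    base <- i2sfca(instance, decay, params)   # V = 0 baseline, two-tier rule
    Q <- base$Q
  }
  stopifnot(length(Q) == nrow(instance$divisions),
            all(Q >= 0), all(Q <= 1))
  if (bounds_mode == "fixed_bounds") {
    stopifnot(is.numeric(fixed_bounds), length(fixed_bounds) == 2L,
              fixed_bounds[1] >= 0, fixed_bounds[2] >= fixed_bounds[1])
  }
  structure(list(instance = instance, decay = decay, params = params,
                 G = G, rho = rho_full,
                 Q = stats::setNames(as.numeric(Q), instance$divisions$id),
                 bounds_mode = bounds_mode, fixed_bounds = fixed_bounds,
                 integrality = integrality),
            class = "allocation_problem")
}

# affine representation a_k(V) = const_k + grad[k, ] %*% V
affine_accessibility <- function(problem) {
  inst <- problem$instance
  p <- problem$params
  M <- demand_vector(inst, p$demand_stratum)
  is_t <- inst$sites$tier == "tertiary_A"
  S <- inst$sites$resource_offline[!is_t]
  T_i <- inst$sites$resource_offline[is_t]
  f_t <- decay_matrix(inst$costs[is_t, , drop = FALSE], problem$decay)
  denom_t <- as.vector(f_t %*% M)
  share_t <- f_t / ifelse(denom_t > 0, denom_t, Inf)  # w[i, k]
  a_comm <- offline_accessibility(S, inst$costs[!is_t, , drop = FALSE], M,
                                  problem$decay)
  a_tert0 <- as.vector(T_i %*% share_t)
  Q <- problem$Q
  r <- p$referral_rate
  qm <- sum(Q * M)
  c_k <- if (qm > 0) {
    if (p$online_mode == "as_printed") Q / qm else rep(1 / qm, length(Q))
  } else {
    rep(0, length(Q))
  }
  const <- (1 - Q) * ((1 - r) * a_comm + r * a_tert0)
  L <- length(T_i)
  P <- length(Q)
  grad <- matrix(0, P, L)
  for (i in seq_len(L)) {
    g <- Q * c_k                                    # online gain per unit V_i
    if (p$offline_mode == "resource_shift") {
      g <- g - (1 - Q) * r * share_t[i, ]           # offline tertiary loss
    }
    grad[, i] <- g
  }
  list(const = as.numeric(const), grad = grad,
       ub = problem$rho * T_i, L = L, P = P,
       division = inst$divisions$id,
       site = inst$sites$id[is_t])
}

#' Build the linear program of an allocation problem
#'
#' Expresses the allocation problem as a linear program: the combined index
#' is affine in \eqn{V}, the equity constraint is linearized exactly to
#' \eqn{(1-G)\,a_{max} \le (1+G)\,a_{min}} (equivalent for
#' \eqn{a_{max}+a_{min} > 0}), and in \code{"variable_extremes"} mode
#' \eqn{a_{min}, a_{max}} are auxiliary variables constrained to bracket
#' every \eqn{a_k}.
#'
#' @param problem An [allocation_problem()].
#' @return An object of class \code{"th_program"}: objective vector,
#'   inequality blocks (in \code{<=} / \code{>=} form with nonnegative right
#'   sides), constant objective offset, variable names, and the affine
#'   accessibility map.
#' @export
build_program <- function(problem) {
  stopifnot(inherits(problem, "allocation_problem"))
  if (any(problem$instance$sites$resource_offline < 0)) {
    stop("build_program: negative resources", call. = FALSE)
  }
  aff <- affine_accessibility(problem)
  L <- aff$L; P <- aff$P; G <- problem$G
  ve <- problem$bounds_mode == "variable_extremes"
  nv <- L + if (ve) 2L else 0L
  vn <- c(paste0("V_", aff$site), if (ve) c("a_min", "a_max"))

  obj <- c(colMeans(aff$grad), if (ve) c(0, 0))
  rows_le <- list(); rhs_le <- numeric(0)
  rows_ge <- list(); rhs_ge <- numeric(0)
  add <- function(coef, dir, rhs) {
    # boot::simplex wants nonnegative right-hand sides; flip when needed
    if (rhs < 0) { coef <- -coef; rhs <- -rhs; dir <- setdiff(c("<=", ">="), dir) }
    if (dir == "<=") { rows_le[[length(rows_le) + 1L]] <<- coef
                       rhs_le[length(rhs_le) + 1L] <<- rhs }
    else             { rows_ge[[length(rows_ge) + 1L]] <<- coef
                       rhs_ge[length(rhs_ge) + 1L] <<- rhs }
  }
  for (k in seq_len(P)) {
    g <- aff$grad[k, ]
    if (ve) {
      add(c(-g, 1, 0), "<=", aff$const[k])   # a_min <= a_k(V)
      add(c(-g, 0, 1), ">=", aff$const[k])   # a_max >= a_k(V)
    } else {
      add(c(g), ">=", problem$fixed_bounds[1] - aff$const[k])
      add(c(g), "<=", problem$fixed_bounds[2] - aff$const[k])
    }
  }
  if (ve) {
    add(c(rep(0, L), -(1 + G), 1 - G), "<=", 0)  # equity linearization
  } else if ((1 - G) * problem$fixed_bounds[2] >
             (1 + G) * problem$fixed_bounds[1] + 1e-12) {
    stop("build_program: fixed bounds violate the equity constraint",
         call. = FALSE)
  }
  for (i in seq_len(L)) {
    e <- rep(0, nv); e[i] <- 1
    add(e, "<=", aff$ub[i])                  # V_i <= rho_i T_i
  }
  structure(list(objective = obj, obj_const = mean(aff$const),
                 A1 = do.call(rbind, rows_le), b1 = rhs_le,
                 A2 = if (length(rows_ge)) do.call(rbind, rows_ge), b2 = rhs_ge,
                 n_var = nv, n_alloc = L, var_names = vn, affine = aff,
                 problem = problem),
            class = "th_program")
}

#' @export
print.th_program <- function(x, ...) {
  cat("Allocation LP: ", x$n_var, " variables (", x$n_alloc,
      " allocations), ", nrow(x$A1) + NROW(x$A2), " constraints\n", sep = "")
  invisible(x)
}

simplex_solve <- function(prog, extra_le = NULL, extra_le_rhs = NULL,
                          extra_ge = NULL, extra_ge_rhs = NULL,
                          objective = prog$objective) {
  A1 <- rbind(prog$A1, extra_le); b1 <- c(prog$b1, extra_le_rhs)
  A2 <- rbind(prog$A2, extra_ge); b2 <- c(prog$b2, extra_ge_rhs)
  if (!length(b1)) { A1 <- NULL; b1 <- NULL }
  if (!length(b2)) { A2 <- NULL; b2 <- NULL }
  s <- boot::simplex(a = objective, A1 = A1, b1 = b1,
                     A2 = A2, b2 = b2, maxi = TRUE,
                     n.iter = 50 * (prog$n_var + length(b1) + length(b2)))
  list(status = if (s$solved == 1) "optimal" else if (s$solved == -1)
         "infeasible" else "iteration_limit",
       x = as.numeric(s$soln), value = s$value)
}

#' Solve an allocation problem
#'
#' Solves the equity-constrained allocation program (continuous LP via the
#' simplex method, or branch and bound for integer allocations), then
#' recomputes the accessibility profile from the optimal \eqn{V} through
#' [i2sfca()] as a guard against drift between the program matrix and the
#' model equations. Feasibility tolerance 1e-6; integer mode stops at a 0.01
#' relative gap.
#'
#' When no feasible allocation satisfies the equity bound, the result has
#' status \code{"infeasible"} and a diagnostic reporting the minimal
#' achievable equilibrium index found by bisection on \eqn{G}.
#'
#' @param problem An [allocation_problem()].
#' @return An object of class \code{"th_allocation"}: named allocation
#'   vector \code{V}, the [i2sfca()] \code{profile} at the optimum, the
#'   \code{objective} (mean accessibility), \code{status},
#'   \code{solver_gap}, \code{achieved_equilibrium_index}, and the bound
#'   \code{G}.
#' @seealso [allocate_telehealth()] for the one-call interface,
#'   [brute_force_allocation()] for the verification oracle.
#' @export
solve_allocation <- function(problem) {
  prog <- build_program(problem)
  L <- prog$n_alloc
  if (max(abs(prog$affine$grad)) < 1e-12) {
    # accessibility independent of V: canonicalize to V = 0
    V <- stats::setNames(rep(0, L), prog$affine$site)
    fit <- refit(problem, V)
    ok <- equilibrium_index(fit) <= problem$G + 1e-6
    return(finish_allocation(problem, V, fit,
                             status = if (ok) "optimal" else "infeasible",
                             gap = 0))
  }
  if (problem$integrality == "integer") {
    return(solve_allocation_bb(problem, prog))
  }
  s <- simplex_solve(prog)
  if (s$status != "optimal") {
    return(infeasible_result(problem, prog, s$status))
  }
  V <- stats::setNames(pmin(pmax(s$x[seq_len(L)], 0), prog$affine$ub),
                       prog$affine$site)
  finish_allocation(problem, V, refit(problem, V), status = "optimal",
                    gap = 0)
}

refit <- function(problem, V) {
  i2sfca(problem$instance, problem$decay, problem$params, V = V,
         Q = problem$Q)
}

finish_allocation <- function(problem, V, fit, status, gap,
                              diagnostic = NULL) {
  structure(list(V = V, profile = fit, objective = fit$mean, status = status,
                 solver_gap = gap,
                 achieved_equilibrium_index = equilibrium_index(fit),
                 G = problem$G, problem = problem, diagnostic = diagnostic),
            class = "th_allocation")
}

infeasible_result <- function(problem, prog, status) {
  g_min <- minimal_equilibrium_bound(prog)
  V <- stats::setNames(rep(0, prog$n_alloc), prog$affine$site)
  fit <- refit(problem, V)
  finish_allocation(problem, V, fit, status = status, gap = NA_real_,
                    diagnostic = list(min_achievable_equilibrium_index = g_min))
}

# bisection on G for the smallest equity bound with a feasible program
minimal_equilibrium_bound <- function(prog, tol = 1e-3) {
  feasible_at <- function(G) {
    p2 <- prog$problem; p2$G <- G
    s <- simplex_solve(build_program(p2), objective = rep(0, prog$n_var))
    s$status == "optimal"
  }
  lo <- 0; hi <- 1
  if (!feasible_at(1)) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (feasible_at(mid)) hi <- mid else lo <- mid
  }
  hi
}

# branch & bound over integer V with LP relaxations
solve_allocation_bb <- function(problem, prog, rel_gap = 0.01,
                                max_nodes = 500L) {
  L <- prog$n_alloc
  best <- NULL; best_val <- -Inf
  ub_root <- NULL
  nodes <- list(list(lb = rep(0, L), ub = floor(prog$affine$ub + 1e-9)))
  n_done <- 0L
  while (length(nodes) && n_done < max_nodes) {
    nd <- nodes[[1L]]; nodes <- nodes[-1L]; n_done <- n_done + 1L
    nv <- prog$n_var
    ex_le <- diag(nv)[seq_len(L), , drop = FALSE]
    ex_ge <- ex_le[nd$lb > 0, , drop = FALSE]
    s <- simplex_solve(prog,
                       extra_le = ex_le, extra_le_rhs = nd$ub,
                       extra_ge = if (nrow(ex_ge)) ex_ge,
                       extra_ge_rhs = nd$lb[nd$lb > 0])
    if (s$status != "optimal") next
    val <- s$value + prog$obj_const
    if (is.null(ub_root)) ub_root <- val
    if (is.finite(best_val) &&
        val <= best_val + abs(best_val) * rel_gap) next  # pruned
    V <- s$x[seq_len(L)]
    frac <- abs(V - round(V))
    if (max(frac) < 1e-6) {
      if (val > best_val) { best_val <- val; best <- round(V) }
      next
    }
    i <- which.max(frac)
    dn <- nd; dn$ub[i] <- floor(V[i])
    up <- nd; up$lb[i] <- ceiling(V[i])
    nodes <- c(nodes, list(dn), list(up))
  }
  if (is.null(best)) return(infeasible_result(problem, prog, "infeasible"))
  gap <- if (is.null(ub_root) || ub_root == 0) 0 else
    max(0, (ub_root - best_val) / max(abs(ub_root), 1e-12))
  V <- stats::setNames(best, prog$affine$site)
  finish_allocation(problem, V, refit(problem, V), status = "optimal",
                    gap = gap)
}

#' Allocate tertiary physician time to tele-health
#'
#' One-call interface: builds an [allocation_problem()] from an instance and
#' solves it with [solve_allocation()].
#'
#' @inheritParams allocation_problem
#' @param ... Passed to [allocation_problem()].
#' @return A \code{"th_allocation"} result; see [solve_allocation()].
#' @examples
#' city <- generate_city(city_config(seed = 7))
#' res <- allocate_telehealth(city, G = 0.7)
#' res
#' @export
allocate_telehealth <- function(instance, decay = decay_spec(),
                                params = th_params(), G = 0.7, ...) {
  solve_allocation(allocation_problem(instance, decay, params, G = G, ...))
}

#' Brute-force grid oracle for the allocation problem
#'
#' Enumerates online allocations on a regular grid over
#' \eqn{\prod_i [0, \rho_i T_i]}, evaluates the combined accessibility for
#' each grid point through the model equations, keeps the points that
#' satisfy the equity bound, and returns the best mean accessibility. Used
#' to verify [solve_allocation()] on small instances; a combinatorial guard
#' restricts it to at most 4 tertiary sites and 50 grid steps.
#'
#' @param problem An [allocation_problem()].
#' @param grid_steps Number of grid intervals per site (grid has
#'   \code{grid_steps + 1} levels per site).
#' @return A \code{"th_allocation"} result (status \code{"optimal"} if any
#'   grid point is feasible, else \code{"infeasible"}). Ties are broken
#'   lexicographically by the allocation vector.
#' @export
brute_force_allocation <- function(problem, grid_steps = 20) {
  stopifnot(inherits(problem, "allocation_problem"))
  inst <- problem$instance
  p <- problem$params
  is_t <- inst$sites$tier == "tertiary_A"
  L <- sum(is_t)
  if (L > 4 || grid_steps > 50) {
    stop("brute_force_allocation: guard exceeded (L <= 4, grid_steps <= 50)",
         call. = FALSE)
  }
  M <- demand_vector(inst, p$demand_stratum)
  Q <- problem$Q
  S <- inst$sites$resource_offline[!is_t]
  T_i <- inst$sites$resource_offline[is_t]
  a_comm <- offline_accessibility(S, inst$costs[!is_t, , drop = FALSE], M,
                                  problem$decay)
  # per-unit tertiary share, from the public tier equation at unit supply
  share <- t(vapply(seq_len(L), function(i) {
    e <- rep(0, L); e[i] <- 1
    offline_accessibility(e, inst$costs[is_t, , drop = FALSE], M,
                          problem$decay)
  }, numeric(length(M))))
  ub <- problem$rho * T_i
  levels <- lapply(ub, function(u) seq(0, u, length.out = grid_steps + 1))
  Vs <- as.matrix(expand.grid(rev(levels)))[, L:1, drop = FALSE]
  T_off <- if (p$offline_mode == "resource_shift") {
    sweep(-Vs, 2, T_i, "+")
  } else {
    matrix(T_i, nrow(Vs), L, byrow = TRUE)
  }
  A_tert <- T_off %*% share                       # points x divisions
  qm <- sum(Q * M)
  a_v_unit <- if (qm > 0) {
    if (p$online_mode == "as_printed") Q / qm else rep(1 / qm, length(Q))
  } else {
    rep(0, length(Q))
  }
  A_online <- rowSums(Vs) %o% a_v_unit
  r <- p$referral_rate
  off <- sweep(r * A_tert, 2, (1 - r) * a_comm, "+")
  A <- sweep(off, 2, (1 - Q), "*") + sweep(A_online, 2, Q, "*")
  a_min <- do.call(pmin, as.data.frame(A))
  a_max <- do.call(pmax, as.data.frame(A))
  denom <- a_max + a_min
  eq <- ifelse(denom > 0, (a_max - a_min) / denom, 0)
  feas <- eq <= problem$G + 1e-9
  if (!any(feas)) {
    V0 <- stats::setNames(rep(0, L), inst$sites$id[is_t])
    return(finish_allocation(problem, V0, refit(problem, V0),
                             status = "infeasible", gap = NA_real_))
  }
  objs <- rowMeans(A)
  objs[!feas] <- -Inf
  best <- which(objs == max(objs))
  if (length(best) > 1L) {               # lexicographic tie-break
    ord <- do.call(order, as.data.frame(Vs[best, , drop = FALSE]))
    best <- best[ord[1L]]
  }
  V <- stats::setNames(Vs[best, ], inst$sites$id[is_t])
  finish_allocation(problem, V, refit(problem, V), status = "optimal",
                    gap = NA_real_)
}

#' @export
print.th_allocation <- function(x, digits = 4, ...) {
  cat("Tele-health allocation (", x$status, ")\n", sep = "")
  if (x$status == "optimal") {
    cat("  objective (mean accessibility): ",
        format(x$objective, digits = digits), "\n", sep = "")
    cat("  equilibrium index ",
        format(x$achieved_equilibrium_index, digits = digits),
        " (bound G = ", format(x$G), ")\n", sep = "")
    cat("  online allocation V:\n")
    print(round(x$V, digits))
  } else if (!is.null(x$diagnostic)) {
    cat("  minimal achievable equilibrium index: ",
        format(x$diagnostic$min_achievable_equilibrium_index,
               digits = digits), "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.th_allocation <- function(object, ...) object$V

#' @export
summary.th_allocation <- function(object, ...) {
  structure(list(res = object), class = "summary.th_allocation")
}

#' @export
print.summary.th_allocation <- function(x, digits = 4, ...) {
  print(x$res, digits = digits)
  if (x$res$status == "optimal") {
    cat("\nResulting profile:\n")
    print(summary(x$res$profile), digits = digits)
  }
  invisible(x)
}

#' Plot an allocation result
#'
#' Side-by-side bars of the baseline (no tele-health) and optimized
#' per-division accessibility.
#'
#' @param x A \code{"th_allocation"} result.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.th_allocation <- function(x, ...) {
  base <- refit(x$problem, stats::setNames(rep(0, length(x$V)), names(x$V)))
  m <- rbind(baseline = base$profile$a_total,
             optimized = x$profile$a_total)
  colnames(m) <- x$profile$profile$division
  graphics::barplot(m, beside = TRUE, las = 2,
                    legend.text = rownames(m),
                    ylab = "accessibility index", ...)
  invisible(x)
}
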