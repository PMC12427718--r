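#' Distance-decay weight
#'
#' Power-law decay \eqn{f(d) = \max(d, d_{floor})^{-\beta}}, zero beyond the
#' catchment threshold \code{d0} when one is set. With \code{beta = 0} the
#' weight is 1 for every in-catchment distance.
#'
#' @param d Nonnegative travel cost(s).
#' @param spec A [decay_spec()].
#' @return Numeric vector of nonnegative weights, same length as \code{d}.
#' @examples
#' decay_weight(c(1, 2), decay_spec(beta = 2))   # 1, 0.25
#' decay_weight(5, decay_spec(beta = 2, d0 = 3)) # 0
#' @export
decay_weight <- function(d, spec = decay_spec()) {
  stopifnot(inherits(spec, "decay_spec"), is.numeric(d))
  if (any(!is.finite(d) | d < 0)) {
    stop("decay_weight: travel costs must be finite and >= 0", call. = FALSE)
  }
  w <- pmax(d, spec$d_floor)^(-spec$beta)
  if (!is.null(spec$d0)) w[d > spec$d0] <- 0
  w
}

decay_matrix <- function(costs, spec) {
  w <- decay_weight(as.vector(costs), spec)
  matrix(w, nrow = nrow(costs), dimnames = dimnames(costs))
}

#' Physician-to-population ratio of one site (catchment step 1)
#'
#' The supply-to-demand ratio of a site over its hard catchment: offline
#' resource divided by the total demand population of all divisions within
#' travel cost \code{d0}. An empty catchment yields 0 with a warning so that
#' degenerate instances do not abort batch sweeps.
#'
#' @param resource Offline resource of the site (consultation-time units).
#' @param costs_to_divisions Travel costs from the site to every division.
#' @param populations Demand population of every division (same order).
#' @param d0 Catchment threshold.
#' @return The ratio, a single nonnegative number.
#' @export
supply_ratio <- function(resource, costs_to_divisions, populations, d0) {
  stopifnot(resource >= 0, d0 > 0,
            length(costs_to_divisions) == length(populations))
  inside <- costs_to_divisions <= d0
  pop <- sum(populations[inside])
  if (pop <= 0) {
    warning("supply_ratio: empty catchment, ratio defined as 0")
    return(0)
  }
  resource / pop
}

#' Catchment-sum accessibility (hard-threshold two-step form)
#'
#' The classical two-step floating catchment area measure: per-division sum
#' of [supply_ratio()]s of all sites within \code{d0}. Provided for
#' comparison with the decay-weighted form of [offline_accessibility()],
#' to which it reduces when \code{beta = 0} and \code{d0} covers all pairs.
#'
#' @param resources Offline resource per site.
#' @param costs Site-by-division cost matrix.
#' @param populations Demand population per division (column order).
#' @param d0 Catchment threshold.
#' @return Named per-division accessibility vector.
#' @export
catchment_accessibility <- function(resources, costs, populations, d0) {
  stopifnot(length(resources) == nrow(costs),
            length(populations) == ncol(costs))
  ratios <- vapply(seq_len(nrow(costs)), function(j) {
    suppressWarnings(supply_ratio(resources[j], costs[j, ], populations, d0))
  }, numeric(1))
  a <- vapply(seq_len(ncol(costs)), function(k) {
    sum(ratios[costs[, k] <= d0])
  }, numeric(1))
  stats::setNames(a, colnames(costs))
}

#' Decay-weighted offline accessibility (gravity two-step form)
#'
#' Per-division accessibility of one hospital tier:
#' \deqn{a_k = \sum_j S_j f(d_{jk}) / \sum_l M_l f(d_{jl}),}
#' where each site's supply is shared over all divisions in proportion to
#' decayed demand. Without a hard threshold this conserves supply exactly:
#' \eqn{\sum_k M_k a_k = \sum_j S_j}.
#'
#' @param resources Offline resource per site (rows of \code{costs}).
#' @param costs Site-by-division cost matrix.
#' @param populations Demand population per division (columns of
#'   \code{costs}).
#' @param spec A [decay_spec()].
#' @return Named per-division accessibility vector.
#' @examples
#' costs <- matrix(c(1, 2), 1, dimnames = list("j1", c("k1", "k2")))
#' offline_accessibility(12, costs, c(100, 200), decay_spec(beta = 2))
#' # 0.08 0.02
#' @export
offline_accessibility <- function(resources, costs, populations,
                                  spec = decay_spec()) {
  stopifnot(length(resources) == nrow(costs),
            length(populations) == ncol(costs),
            all(populations >= 0), all(resources >= 0))
  f <- decay_matrix(costs, spec)
  denom <- as.vector(f %*% populations)        # per-site decayed demand
  share <- f / ifelse(denom > 0, denom, Inf)   # 0/0 -> 0: no demand, no flow
  a <- as.vector(resources %*% share)
  stats::setNames(a, colnames(costs))
}

#' Referral-adjusted offline accessibility
#'
#' Blends community and tertiary offline accessibility by the referral rate
#' \eqn{r}: \eqn{a_k = (1-r) a_k^c + r a_k^a}. A fraction \eqn{r} of
#' chronic-disease patients visits a tertiary-A hospital in addition to the
#' community hospital.
#'
#' @param a_comm,a_tert Named per-division accessibility of the community and
#'   tertiary tiers, same division set.
#' @param r Referral rate in \[0, 1\].
#' @return Named per-division accessibility vector.
#' @export
referral_accessibility <- function(a_comm, a_tert, r) {
  stopifnot(is.numeric(r), length(r) == 1L, r >= 0, r <= 1)
  if (length(a_comm) != length(a_tert) ||
      !identical(names(a_comm), names(a_tert))) {
    stop("referral_accessibility: mismatched division sets", call. = FALSE)
  }
  (1 - r) * a_comm + r * a_tert
}

#' Online (tele-health) accessibility
#'
#' Distance-free accessibility of the pooled online resource
#' \eqn{\sum_i V_i}. In \code{"as_printed"} mode the division's own online
#' preference appears in the numerator,
#' \eqn{a_k^v = Q_k \sum_i V_i / \sum_l Q_l M_l}; in \code{"conserving"} mode
#' that factor is dropped so that \eqn{\sum_k M_k Q_k a_k^v = \sum_i V_i}.
#'
#' @param V Online resource per tertiary site (any nonnegative vector; only
#'   the sum enters).
#' @param Q Online preference per division, in \[0, 1\].
#' @param populations Demand population per division.
#' @param mode \code{"as_printed"} or \code{"conserving"}.
#' @return Named per-division online accessibility vector. All zero when no
#'   division has positive online demand.
#' @export
online_accessibility <- function(V, Q, populations,
                                 mode = c("as_printed", "conserving")) {
  mode <- match.arg(mode)
  stopifnot(all(V >= 0), all(Q >= 0), all(Q <= 1),
            length(Q) == length(populations))
  qm <- sum(Q * populations)
  if (qm <= 0) {
    return(stats::setNames(rep(0, length(Q)), names(Q)))
  }
  tot <- sum(V)
  if (mode == "as_printed") tot * Q / qm else
    stats::setNames(rep(tot / qm, length(Q)), names(Q))
}

#' Combined offline + online accessibility
#'
#' The overall regional accessibility index per division:
#' \deqn{a_k = (1-Q_k)\,[(1-r)a_k^c + r\,a_k^a] + Q_k\,a_k^v.}
#' A fraction \eqn{Q_k} of each division's chronic-disease demand shifts to
#' online service; the rest follows the community-plus-referral path.
#'
#' @param a_comm,a_tert,a_online Named per-division component vectors on the
#'   same division set.
#' @param Q Online preference per division, in \[0, 1\].
#' @param r Referral rate.
#' @return Named per-division combined accessibility vector.
#' @export
combined_accessibility <- function(a_comm, a_tert, a_online, Q, r) {
  if (any(Q < 0 | Q > 1)) {
    stop("combined_accessibility: Q outside [0,1]", call. = FALSE)
  }
  n <- length(a_comm)
  stopifnot(length(a_tert) == n, length(a_online) == n, length(Q) == n)
  (1 - Q) * referral_accessibility(a_comm, a_tert, r) + Q * a_online
}

#' Two-tier online-preference assignment
#'
#' Classifies divisions by their baseline (purely offline) accessibility:
#' divisions strictly below the regional mean are "poor-access" and get
#' \code{q_poor}; the rest (ties included) get \code{q_good}.
#'
#' @param a_baseline Named per-division baseline offline accessibility,
#'   computed with all online preferences at 0.
#' @param q_poor,q_good Preference levels for poor- and good-access
#'   divisions.
#' @return Named per-division preference vector \eqn{Q_k}.
#' @examples
#' assign_online_preference(c(k1 = 0.1, k2 = 0.5, k3 = 1.5))
#' # 0.35 0.35 0.10
#' @export
assign_online_preference <- function(a_baseline, q_poor = 0.35,
                                     q_good = 0.1) {
  if (length(a_baseline) == 0L) {
    stop("assign_online_preference: empty division set", call. = FALSE)
  }
  stopifnot(q_poor >= 0, q_poor <= 1, q_good >= 0, q_good <= 1)
  ifelse(a_baseline < mean(a_baseline), q_poor, q_good)
}

#' Fit the i2SFCA-TH accessibility model
#'
#' Computes the full accessibility profile of an instance: community-tier and
#' tertiary-tier offline components, the referral blend, the online
#' component for a given online allocation \code{V}, and the combined index,
#' together with equity summaries. This is the package's central model
#' function; [allocate_telehealth()] optimizes \code{V} on top of it.
#'
#' @param instance A [th_instance()].
#' @param decay A [decay_spec()].
#' @param params A [th_params()].
#' @param V Online resource per tertiary site, a named or ordered vector over
#'   the instance's tertiary sites; default all zero (no tele-health).
#' @param Q Online preference per division. Default \code{NULL}: the
#'   instance's \code{q_online} column is used if present, otherwise the
#'   two-tier rule of [assign_online_preference()] is applied to the offline
#'   baseline.
#' @return An object of class \code{"i2sfca"}: a list with a per-division
#'   data frame \code{profile} (columns \code{division}, \code{demand},
#'   \code{q_online}, \code{a_comm}, \code{a_tert}, \code{a_offline},
#'   \code{a_online}, \code{a_total}), the summary statistics \code{mean},
#'   \code{min}, \code{max}, the inputs, and the [equity_report()].
#' @examples
#' city <- generate_city(city_config(seed = 1))
#' fit <- i2sfca(city)
#' summary(fit)
#' @export
i2sfca <- function(instance, decay = decay_spec(), params = th_params(),
                   V = NULL, Q = NULL) {
  stopifnot(inherits(instance, "th_instance"))
  div <- instance$divisions
  if (nrow(div) == 0L) stop("i2sfca: empty division set", call. = FALSE)
  M <- demand_vector(instance, params$demand_stratum)
  is_t <- instance$sites$tier == "tertiary_A"
  costs_c <- instance$costs[!is_t, , drop = FALSE]
  costs_t <- instance$costs[is_t, , drop = FALSE]
  S <- instance$sites$resource_offline[!is_t]
  T_i <- instance$sites$resource_offline[is_t]

  if (is.null(V)) V <- rep(0, sum(is_t))
  stopifnot(length(V) == sum(is_t), all(V >= 0))
  T_off <- if (params$offline_mode == "resource_shift") T_i - V else T_i
  if (any(T_off < -1e-9)) {
    stop("i2sfca: online allocation exceeds tertiary offline resource",
         call. = FALSE)
  }
  T_off <- pmax(T_off, 0)

  a_comm <- offline_accessibility(S, costs_c, M, decay)
  a_tert <- offline_accessibility(T_off, costs_t, M, decay)

  if (is.null(Q)) {
    if ("q_online" %in% names(div)) {
      Q <- stats::setNames(div$q_online, div$id)
    } else {
      base_tert <- offline_accessibility(T_i, costs_t, M, decay)
      base_comm <- offline_accessibility(S, costs_c, M, decay)
      a0 <- referral_accessibility(base_comm, base_tert, params$referral_rate)
      Q <- assign_online_preference(a0, params$q_poor, params$q_good)
    }
  }
  stopifnot(length(Q) == nrow(div))

  a_online <- online_accessibility(V, Q, M, params$online_mode)
  a_off <- referral_accessibility(a_comm, a_tert, params$referral_rate)
  a_tot <- combined_accessibility(a_comm, a_tert, a_online, Q,
                                  params$referral_rate)

  profile <- data.frame(division = div$id, demand = as.numeric(M),
                        q_online = as.numeric(Q),
                        a_comm = as.numeric(a_comm),
                        a_tert = as.numeric(a_tert),
                        a_offline = as.numeric(a_off),
                        a_online = as.numeric(a_online),
                        a_total = as.numeric(a_tot),
                        stringsAsFactors = FALSE)
  structure(list(profile = profile,
                 mean = mean(a_tot), min = min(a_tot), max = max(a_tot),
                 V = V, Q = stats::setNames(as.numeric(Q), div$id),
                 decay = decay, params = params,
                 equity = equity_report(a_tot, weights = M),
                 call = match.call()),
            class = "i2sfca")
}

#' Per-division accessibility of a fitted model
#'
#' @param object An \code{"i2sfca"} fit.
#' @param ... Unused.
#' @return The combined per-division accessibility vector \eqn{a_k}.
#' @export
coef.i2sfca <- function(object, ...) {
  stats::setNames(object$profile$a_total, object$profile$division)
}

#' @export
as.data.frame.i2sfca <- function(x, ...) x$profile

#' @export
print.i2sfca <- function(x, digits = 4, ...) {
  cat("i2SFCA-TH accessibility profile (", nrow(x$profile),
      " divisions)\n", sep = "")
  cat("  mean ", format(x$mean, digits = digits),
      ", min ", format(x$min, digits = digits),
      ", max ", format(x$max, digits = digits),
      ", gap ", format(x$max - x$min, digits = digits),
      ", equilibrium index ",
      format(x$equity$equilibrium_index, digits = digits), "\n", sep = "")
  invisible(x)
}

#' @export
summary.i2sfca <- function(object, ...) {
  structure(list(fit = object), class = "summary.i2sfca")
}

#' @export
print.summary.i2sfca <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat("\nPer-division components:\n")
  print(format(f$profile, digits = digits), row.names = FALSE)
  cat("\nEquity:\n")
  print(f$equity, digits = digits)
  invisible(x)
}

#' Plot a fitted accessibility profile
#'
#' Bar chart of the combined per-division accessibility with the regional
#' mean as a dashed reference line.
#'
#' @param x An \code{"i2sfca"} fit.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.i2sfca <- function(x, ...) {
  a <- stats::setNames(x$profile$a_total, x$profile$division)
  graphics::barplot(a, las = 2, ylab = "accessibility index",
                    main = "i2SFCA-TH accessibility by division", ...)
  graphics::abline(h = x$mean, lty = 2)
  invisible(x)
}
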