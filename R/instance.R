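#' Distance-decay specification
#'
#' Parameters of the power-law distance-decay weight used by the catchment
#' model, \eqn{f(d) = d^{-\beta}}, optionally truncated at a hard catchment
#' threshold \code{d0}.
#'
#' @param beta Nonnegative decay exponent. \code{beta = 2} is the customary
#'   value for intra-urban hospital access in Chinese cities and the default.
#' @param d0 Optional catchment threshold (same unit as the cost matrix,
#'   typically km): beyond \code{d0} the weight is 0. \code{NULL} (default)
#'   means pure decay with no hard cutoff.
#' @param d_floor Minimum effective distance (> 0). \eqn{d^{-\beta}} diverges
#'   at 0, so distances are floored at \code{d_floor} before decay.
#' @return An object of class \code{"decay_spec"}.
#' @examples
#' decay_spec(beta = 2)
#' decay_spec(beta = 1.5, d0 = 10)
#' @export
decay_spec <- function(beta = 2, d0 = NULL, d_floor = 0.1) {
  stopifnot(is.numeric(beta), length(beta) == 1L, beta >= 0)
  stopifnot(is.numeric(d_floor), length(d_floor) == 1L, d_floor > 0)
  if (!is.null(d0)) stopifnot(is.numeric(d0), length(d0) == 1L, d0 > 0)
  structure(list(beta = beta, d0 = d0, d_floor = d_floor),
            class = "decay_spec")
}

#' Behavioural model parameters
#'
#' Parameters governing patient flows between community care, tertiary
#' referral and online consultation.
#'
#' @param referral_rate Fraction \eqn{r \in [0,1]} of chronic-disease patients
#'   who, after a community-hospital visit, make an additional visit to a
#'   tertiary-A hospital. Default 0.2.
#' @param q_poor,q_good Online-consultation preference assigned to divisions
#'   with below-mean (strictly) and at-or-above-mean baseline offline
#'   accessibility, respectively. Defaults 0.35 and 0.1.
#' @param online_mode How the online component enters the combined index:
#'   \code{"as_printed"} keeps the preference factor inside the online term
#'   so the combined index carries it twice; \code{"conserving"} keeps it
#'   once, which makes total online supply conserved across divisions.
#' @param offline_mode \code{"resource_shift"} (default) deducts online
#'   allocations from tertiary offline capacity, conserving total physician
#'   time; \code{"as_printed"} leaves tertiary offline capacity untouched.
#' @param demand_stratum Which population column is the demand mass:
#'   \code{"chronic"} (default), \code{"elderly"} or \code{"total"}.
#' @return An object of class \code{"th_params"}.
#' @export
th_params <- function(referral_rate = 0.2, q_poor = 0.35, q_good = 0.1,
                      online_mode = c("as_printed", "conserving"),
                      offline_mode = c("resource_shift", "as_printed"),
                      demand_stratum = c("chronic", "elderly", "total")) {
  online_mode <- match.arg(online_mode)
  offline_mode <- match.arg(offline_mode)
  demand_stratum <- match.arg(demand_stratum)
  for (v in c(referral_rate, q_poor, q_good)) {
    stopifnot(is.numeric(v), length(v) == 1L, v >= 0, v <= 1)
  }
  structure(list(referral_rate = referral_rate, q_poor = q_poor,
                 q_good = q_good, online_mode = online_mode,
                 offline_mode = offline_mode,
                 demand_stratum = demand_stratum),
            class = "th_params")
}

#' Assemble and validate a study instance
#'
#' Bundles the demand divisions, supply sites, and a site-by-division travel
#' cost matrix into a validated instance. When \code{costs} is missing it is
#' computed from coordinates: haversine kilometres for lon/lat, Euclidean
#' distance for planar coordinates.
#'
#' @param divisions Data frame with columns \code{id}, \code{pop_total},
#'   \code{pop_elderly}, \code{pop_chronic}, optionally \code{q_online} and
#'   coordinates (\code{lon}/\code{lat} or \code{x}/\code{y}).
#' @param sites Data frame with columns \code{id}, \code{tier}
#'   (\code{"tertiary_A"} or \code{"community"}), \code{resource_offline}
#'   (physician consultation-time units/day), optionally
#'   \code{online_cap_fraction} (tertiary only) and coordinates.
#' @param costs Optional numeric matrix, rows = site ids, columns = division
#'   ids, of nonnegative finite travel costs. Overrides coordinates.
#' @param cost_unit Unit label recorded in metadata (default "km").
#' @return An object of class \code{"th_instance"}: a list with elements
#'   \code{divisions}, \code{sites}, \code{costs}, \code{cost_unit}.
#' @examples
#' div <- data.frame(id = c("k1", "k2"), x = c(0, 3), y = c(0, 0),
#'                   pop_total = c(1000, 2000), pop_elderly = c(300, 600),
#'                   pop_chronic = c(100, 200))
#' sit <- data.frame(id = "j1", tier = "community", x = 1, y = 0,
#'                   resource_offline = 12)
#' th_instance(div, sit)
#' @export
th_instance <- function(divisions, sites, costs = NULL, cost_unit = "km") {
  divisions <- validate_divisions(divisions)
  sites <- validate_sites(sites)
  if (is.null(costs)) {
    costs <- cost_matrix_from_coords(sites, divisions)
  } else {
    costs <- validate_costs(costs, sites$id, divisions$id)
  }
  structure(list(divisions = divisions, sites = sites, costs = costs,
                 cost_unit = cost_unit),
            class = "th_instance")
}

validate_divisions <- function(d) {
  stopifnot(is.data.frame(d))
  need <- c("id", "pop_total", "pop_elderly", "pop_chronic")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("divisions: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d$id <- as.character(d$id)
  if (anyDuplicated(d$id)) {
    stop("divisions: duplicate id: ", d$id[duplicated(d$id)][1L],
         call. = FALSE)
  }
  for (col in c("pop_total", "pop_elderly", "pop_chronic")) {
    bad <- which(!is.finite(d[[col]]) | d[[col]] < 0)
    if (length(bad)) {
      stop("divisions: negative or non-finite ", col, " for id '",
           d$id[bad[1L]], "'", call. = FALSE)
    }
  }
  if ("q_online" %in% names(d)) {
    bad <- which(!is.finite(d$q_online) | d$q_online < 0 | d$q_online > 1)
    if (length(bad)) {
      stop("divisions: q_online outside [0,1] for id '", d$id[bad[1L]], "'",
           call. = FALSE)
    }
  }
  rownames(d) <- NULL
  d
}

validate_sites <- function(s) {
  stopifnot(is.data.frame(s))
  need <- c("id", "tier", "resource_offline")
  miss <- setdiff(need, names(s))
  if (length(miss)) {
    stop("sites: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  s$id <- as.character(s$id)
  s$tier <- as.character(s$tier)
  if (anyDuplicated(s$id)) {
    stop("sites: duplicate id: ", s$id[duplicated(s$id)][1L], call. = FALSE)
  }
  bad <- which(!s$tier %in% c("tertiary_A", "community"))
  if (length(bad)) {
    stop("sites: unknown tier '", s$tier[bad[1L]], "' for id '",
         s$id[bad[1L]], "'", call. = FALSE)
  }
  bad <- which(!is.finite(s$resource_offline) | s$resource_offline < 0)
  if (length(bad)) {
    stop("sites: negative or non-finite resource_offline for id '",
         s$id[bad[1L]], "'", call. = FALSE)
  }
  if (!"online_cap_fraction" %in% names(s)) {
    s$online_cap_fraction <- ifelse(s$tier == "tertiary_A", 0.4, 0)
  }
  s$online_cap_fraction[is.na(s$online_cap_fraction)] <- 0
  bad <- which(s$online_cap_fraction < 0 | s$online_cap_fraction > 1)
  if (length(bad)) {
    stop("sites: online_cap_fraction outside [0,1] for id '", s$id[bad[1L]],
         "'", call. = FALSE)
  }
  # online consultation is a tertiary-A service only
  bad <- which(s$tier == "community" & s$online_cap_fraction != 0)
  if (length(bad)) {
    stop("sites: community site '", s$id[bad[1L]],
         "' has nonzero online_cap_fraction", call. = FALSE)
  }
  rownames(s) <- NULL
  s
}

validate_costs <- function(costs, site_ids, division_ids) {
  costs <- as.matrix(costs)
  if (is.null(rownames(costs)) || is.null(colnames(costs))) {
    stop("costs: matrix must carry site row names and division column names",
         call. = FALSE)
  }
  miss_r <- setdiff(site_ids, rownames(costs))
  miss_c <- setdiff(division_ids, colnames(costs))
  if (length(miss_r)) {
    stop("costs: missing row for site '", miss_r[1L], "'", call. = FALSE)
  }
  if (length(miss_c)) {
    stop("costs: missing column for division '", miss_c[1L], "'",
         call. = FALSE)
  }
  costs <- costs[site_ids, division_ids, drop = FALSE]
  bad <- which(!is.finite(costs) | costs < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("costs: negative or non-finite cost for pair (",
         site_ids[bad[1L, 1L]], ", ", division_ids[bad[1L, 2L]], ")",
         call. = FALSE)
  }
  costs
}

coords_of <- function(df, what) {
  if (all(c("lon", "lat") %in% names(df))) {
    list(type = "lonlat", xy = cbind(df$lon, df$lat))
  } else if (all(c("x", "y") %in% names(df))) {
    list(type = "planar", xy = cbind(df$x, df$y))
  } else {
    stop(what, ": need lon/lat or x/y coordinates when no cost matrix is ",
         "supplied", call. = FALSE)
  }
}

cost_matrix_from_coords <- function(sites, divisions) {
  cs <- coords_of(sites, "sites")
  cd <- coords_of(divisions, "divisions")
  if (cs$type != cd$type) {
    stop("sites and divisions use different coordinate systems",
         call. = FALSE)
  }
  if (cs$type == "lonlat") {
    m <- outer(seq_len(nrow(sites)), seq_len(nrow(divisions)),
               Vectorize(function(i, k) {
                 geosphere::distHaversine(cs$xy[i, ], cd$xy[k, ]) / 1000
               }))
  } else {
    m <- outer(seq_len(nrow(sites)), seq_len(nrow(divisions)),
               Vectorize(function(i, k) {
                 sqrt(sum((cs$xy[i, ] - cd$xy[k, ])^2))
               }))
  }
  dimnames(m) <- list(sites$id, divisions$id)
  m
}

demand_vector <- function(instance, stratum) {
  col <- switch(stratum,
                chronic = "pop_chronic",
                elderly = "pop_elderly",
                total = "pop_total",
                stop("unknown demand stratum: ", stratum, call. = FALSE))
  stats::setNames(instance$divisions[[col]], instance$divisions$id)
}

#' @export
print.th_instance <- function(x, ...) {
  nt <- sum(x$sites$tier == "tertiary_A")
  nc <- sum(x$sites$tier == "community")
  cat("i2SFCA-TH instance: ", nrow(x$divisions), " divisions, ",
      nt, " tertiary-A + ", nc, " community sites; costs in ",
      x$cost_unit, "\n", sep = "")
  invisible(x)
}
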