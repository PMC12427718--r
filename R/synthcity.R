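#' Configuration of a synthetic metropolitan district
#'
#' Parameters of the seeded generator in [generate_city()]. The defaults
#' emulate a central district of a Chinese metropolitan city: 13 residential
#' divisions, 6 tertiary-A and 56 community hospitals, chronic-disease
#' populations spanning two orders of magnitude, and supply concentrated at
#' the geographic center so that baseline accessibility is strongly unequal.
#'
#' @param n_divisions,n_tertiary,n_community Counts (defaults 13, 6, 56).
#' @param pop_range Range of chronic-disease population per division;
#'   draws are log-uniform so the spread covers both magnitudes.
#' @param centralization Fraction in \[0, 1\] controlling how tightly supply
#'   clusters at the center (0 = fully dispersed). Default 0.9.
#' @param extent_km Side length of the square study region in km.
#' @param tier_ratio Ratio of a typical tertiary site's resource to a typical
#'   community site's. Default 40, reflecting the large physician staff of a
#'   tertiary-A hospital relative to a community health service center.
#' @param resource_base Median community-site resource; default \code{NULL}
#'   scales total supply to about 0.72 consultation-time units per
#'   chronic-disease resident.
#' @param seed Integer RNG seed; the instance is fully reproducible from it.
#' @return An object of class \code{"city_config"}.
#' @export
city_config <- function(n_divisions = 13, n_tertiary = 6, n_community = 56,
                        pop_range = c(100, 10000), centralization = 0.9,
                        extent_km = 15, tier_ratio = 40, resource_base = NULL,
                        seed = 1L) {
  stopifnot(n_divisions >= 1, n_tertiary >= 1, n_community >= 1,
            length(pop_range) == 2L, all(pop_range > 0),
            pop_range[2] >= pop_range[1],
            centralization >= 0, centralization <= 1,
            extent_km >= 0, tier_ratio > 0)
  if (extent_km == 0 && n_divisions > 1) {
    stop("city_config: zero extent with more than one division",
         call. = FALSE)
  }
  structure(list(n_divisions = n_divisions, n_tertiary = n_tertiary,
                 n_community = n_community, pop_range = pop_range,
                 centralization = centralization, extent_km = extent_km,
                 tier_ratio = tier_ratio, resource_base = resource_base,
                 seed = as.integer(seed)),
            class = "city_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit(if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# anchor of the synthetic region (study-region latitude band, North China)
.city_center <- c(lon = 118.18, lat = 39.63)

km_to_lon <- function(km, lat) km / (111.320 * cos(lat * pi / 180))
km_to_lat <- function(km) km / 110.574

#' Generate a synthetic metropolitan instance
#'
#' Draws a reproducible center-periphery instance with the structural
#' features of a central urban district:
#' \itemize{
#'   \item divisions sit on a jittered grid over the square region, with
#'     chronic-disease populations following a log-scale center-periphery
#'     density gradient (dense center, sparse periphery) plus noise;
#'   \item hospitals cluster around an "old-town" supply center offset from
#'     the demographic center by 15\% of the extent, with a spread that
#'     shrinks as \code{centralization} grows; every division additionally
#'     hosts one local community health service center, emulating the
#'     sub-district service mandate;
#'   \item resources are lognormal around tier-specific levels, scaled to
#'     about 0.72 consultation-time units per chronic-disease resident;
#'   \item the cost matrix is pairwise haversine kilometres.
#' }
#' These structural constants were fixed by a one-off Monte-Carlo
#' calibration so that default instances lie in the regime of strong but
#' repairable baseline inequality (see the package vignette).
#'
#' @param config A [city_config()].
#' @return A [th_instance()].
#' @examples
#' city <- generate_city(city_config(seed = 42))
#' city
#' @export
generate_city <- function(config = city_config()) {
  stopifnot(inherits(config, "city_config"))
  with_seed(config$seed, {
    ext <- config$extent_km
    nd <- config$n_divisions
    nside <- ceiling(sqrt(nd))
    cell <- if (nside > 1) ext / nside else ext
    gx <- rep(seq_len(nside), nside)[seq_len(nd)]
    gy <- rep(seq_len(nside), each = nside)[seq_len(nd)]
    dx <- (gx - (nside + 1) / 2) * cell + stats::runif(nd, -0.35, 0.35) * cell
    dy <- (gy - (nside + 1) / 2) * cell + stats::runif(nd, -0.35, 0.35) * cell
    # chronic population: log-scale center-periphery gradient plus noise
    centrality <- exp(-0.5 * ((dx^2 + dy^2) / (0.3 * ext)^2))
    u <- pmin(pmax(0.6 * centrality + 0.4 * stats::runif(nd), 0), 1)
    lo <- config$pop_range[1]; hi <- config$pop_range[2]
    chronic <- round(lo * (hi / lo)^u)
    elderly <- round(chronic * stats::runif(nd, 1.5, 4))
    divisions <- data.frame(
      id = sprintf("div%02d", seq_len(nd)),
      lon = .city_center["lon"] + km_to_lon(dx, .city_center["lat"]),
      lat = .city_center["lat"] + km_to_lat(dy),
      pop_total = round(elderly / 0.24),
      pop_elderly = elderly,
      pop_chronic = chronic)

    # hospitals cluster at the historical town center, offset from the
    # demographic center
    ang <- stats::runif(1, 0, 2 * pi)
    off <- 0.15 * ext * c(cos(ang), sin(ang))
    draw_sites <- function(n, sd_km) {
      cbind(pmin(pmax(off[1] + stats::rnorm(n, 0, sd_km), -ext / 2), ext / 2),
            pmin(pmax(off[2] + stats::rnorm(n, 0, sd_km), -ext / 2), ext / 2))
    }
    sd_t <- ext / 2 * (1 - config$centralization) + 0.02 * ext
    sd_c <- ext / 2 * (1 - config$centralization) + 0.015 * ext
    xy_t <- draw_sites(config$n_tertiary, sd_t)
    n_local <- min(nd, config$n_community)
    xy_local <- cbind(dx[seq_len(n_local)] + stats::rnorm(n_local, 0, 0.8),
                      dy[seq_len(n_local)] + stats::rnorm(n_local, 0, 0.8))
    xy_c <- rbind(xy_local,
                  draw_sites(config$n_community - n_local, sd_c))

    base <- config$resource_base
    if (is.null(base)) {
      base <- 0.72 * sum(chronic) /
        (config$n_community + config$tier_ratio * config$n_tertiary)
    }
    res_c <- base * stats::rlnorm(config$n_community, 0, 0.4)
    res_t <- base * config$tier_ratio *
      stats::rlnorm(config$n_tertiary, 0, 0.4)

    sites <- data.frame(
      id = c(sprintf("tert%02d", seq_len(config$n_tertiary)),
             sprintf("comm%02d", seq_len(config$n_community))),
      tier = c(rep("tertiary_A", config$n_tertiary),
               rep("community", config$n_community)),
      lon = .city_center["lon"] +
        km_to_lon(c(xy_t[, 1], xy_c[, 1]), .city_center["lat"]),
      lat = .city_center["lat"] + km_to_lat(c(xy_t[, 2], xy_c[, 2])),
      resource_offline = c(res_t, res_c),
      online_cap_fraction = c(rep(0.4, config$n_tertiary),
                              rep(0, config$n_community)))
    th_instance(divisions, sites, cost_unit = "km")
  })
}

#' Canonical test fixtures
#'
#' A small suite of named instances with known properties:
#' \describe{
#'   \item{\code{uniform}}{four equal divisions and a fully symmetric supply
#'     layout, so every division has identical accessibility;}
#'   \item{\code{two_division_toy}}{a hand-calculable two-division instance
#'     (one community site, S = 12, at distances 1 and 2 km from divisions
#'     with chronic populations 100 and 200, plus a mirrored tertiary site
#'     with T = 18) whose community-tier accessibility is exactly
#'     (0.08, 0.02) at \eqn{\beta = 2};}
#'   \item{\code{lubei_like}}{a full 13-division, 6 + 56 site instance from
#'     [generate_city()] with strongly unequal baseline accessibility.}
#' }
#'
#' @param seed Seed for the \code{lubei_like} instance.
#' @return Named list of [th_instance()] objects; each carries an
#'   \code{"expected"} attribute describing the property it exhibits.
#' @export
make_fixture_suite <- function(seed = 1L) {
  h <- 4   # half-side of the symmetric square, km
  uniform_div <- data.frame(
    id = paste0("k", 1:4), x = c(-h, h, -h, h), y = c(-h, -h, h, h),
    pop_total = 5000, pop_elderly = 1500, pop_chronic = 1000)
  uniform_sites <- data.frame(
    id = c(paste0("c", 1:4), "t1"),
    tier = c(rep("community", 4), "tertiary_A"),
    x = c(-h, h, -h, h, 0), y = c(-h, -h, h, h, 0),
    resource_offline = c(rep(100, 4), 500),
    online_cap_fraction = c(rep(0, 4), 0.4))
  uniform <- th_instance(uniform_div, uniform_sites)
  attr(uniform, "expected") <- list(constant_profile = TRUE)

  toy_div <- data.frame(id = c("k1", "k2"),
                        pop_total = c(1000, 2000),
                        pop_elderly = c(300, 600),
                        pop_chronic = c(100, 200))
  toy_sites <- data.frame(id = c("j1", "i1"),
                          tier = c("community", "tertiary_A"),
                          resource_offline = c(12, 18),
                          online_cap_fraction = c(0, 0.4))
  toy_costs <- matrix(c(1, 2,
                        2, 1), 2, 2, byrow = TRUE,
                      dimnames = list(c("j1", "i1"), c("k1", "k2")))
  toy <- th_instance(toy_div, toy_sites, costs = toy_costs)
  attr(toy, "expected") <- list(a_comm = c(k1 = 0.08, k2 = 0.02),
                                a_tert = c(k1 = 0.02, k2 = 0.08))

  lubei <- generate_city(city_config(seed = seed))
  attr(lubei, "expected") <- list(gap_over_mean_min = 3,
                                  equilibrium_index_min = 0.7)

  list(uniform = uniform, two_division_toy = toy, lubei_like = lubei)
}
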