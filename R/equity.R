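#' Accessibility gap
#'
#' Spread of the combined accessibility index across divisions:
#' \eqn{a_{max} - a_{min}}.
#'
#' @param a A per-division accessibility vector, or an \code{"i2sfca"} fit.
#' @return A single nonnegative number.
#' @export
accessibility_gap <- function(a) {
  a <- as_access_vector(a)
  max(a) - min(a)
}

#' Equilibrium index
#'
#' A Gini-like spread measure of an accessibility profile,
#' \eqn{(a_{max}-a_{min})/(a_{max}+a_{min})}, in \[0, 1\] for nonnegative
#' profiles; 0 for a perfectly even one. The allocation optimizer bounds this
#' index by the equity parameter \eqn{G}.
#'
#' @inheritParams accessibility_gap
#' @return A single number; defined as 0 for an all-zero profile.
#' @export
equilibrium_index <- function(a) {
  a <- as_access_vector(a)
  s <- max(a) + min(a)
  if (s <= 0) return(0)
  (max(a) - min(a)) / s
}

#' Gini coefficient of accessibility
#'
#' Population-weighted Gini coefficient of the per-division accessibility
#' distribution, computed by the sorted cumulative-share (Lorenz) formula.
#' Equal weights recover the ordinary Gini.
#'
#' @inheritParams accessibility_gap
#' @param weights Per-division population weights; default equal.
#' @return Gini coefficient in \[0, 1\].
#' @export
gini_coefficient <- function(a, weights = NULL) {
  a <- as_access_vector(a)
  if (length(a) == 0L) stop("gini_coefficient: empty input", call. = FALSE)
  if (any(a < 0)) {
    stop("gini_coefficient: negative accessibility", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(a))
  stopifnot(length(weights) == length(a), all(weights >= 0))
  if (sum(weights) <= 0) {
    stop("gini_coefficient: total weight must be positive", call. = FALSE)
  }
  mu <- sum(weights * a) / sum(weights)
  if (mu == 0) return(0)
  o <- order(a)
  a <- a[o]; w <- weights[o] / sum(weights)
  # trapezoid area under the Lorenz curve: Y = cumulative value share
  yc <- cumsum(w * a) / mu
  1 - sum(w * (yc + c(0, yc[-length(yc)])))
}

as_access_vector <- function(a) {
  if (inherits(a, "i2sfca")) {
    a <- stats::setNames(a$profile$a_total, a$profile$division)
  }
  if (!is.numeric(a) || length(a) == 0L) {
    stop("expected a non-empty accessibility vector or an i2sfca fit",
         call. = FALSE)
  }
  a
}

#' Equity report for an accessibility profile
#'
#' Bundles the dispersion statistics of a per-division accessibility
#' distribution: mean, extremes, gap, equilibrium index and population-
#' weighted Gini coefficient.
#'
#' @inheritParams gini_coefficient
#' @return An object of class \code{"equity_report"}: a list with elements
#'   \code{mean}, \code{a_min}, \code{a_max}, \code{gap},
#'   \code{equilibrium_index}, \code{gini}.
#' @examples
#' equity_report(c(2.45, 0.72, 0.17, 0.09))
#' @export
equity_report <- function(a, weights = NULL) {
  a <- as_access_vector(a)
  structure(list(mean = mean(a), a_min = min(a), a_max = max(a),
                 gap = accessibility_gap(a),
                 equilibrium_index = equilibrium_index(a),
                 gini = gini_coefficient(a, weights)),
            class = "equity_report")
}

#' @export
print.equity_report <- function(x, digits = 4, ...) {
  cat("Equity report: mean ", format(x$mean, digits = digits),
      ", min ", format(x$a_min, digits = digits),
      ", max ", format(x$a_max, digits = digits), "\n  gap ",
      format(x$gap, digits = digits), ", equilibrium index ",
      format(x$equilibrium_index, digits = digits), ", Gini ",
      format(x$gini, digits = digits), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.equity_report <- function(x, ...) {
  data.frame(mean = x$mean, a_min = x$a_min, a_max = x$a_max, gap = x$gap,
             equilibrium_index = x$equilibrium_index, gini = x$gini)
}
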