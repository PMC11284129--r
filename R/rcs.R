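#' Knot locations for a restricted cubic spline
#'
#' Default epidemiological placement: 4 knots at the 5th/35th/65th/95th
#' percentiles of the observed exposure. Both the count and locations are
#' overridable wherever a spline is used.
#'
#' @param x Numeric exposure vector.
#' @param n_knots Number of knots (>= 3).
#' @param probs Quantile probabilities; default depends on `n_knots` and
#'   follows the usual percentile conventions for 3--5 knots.
#' @return Numeric vector of strictly increasing knots.
#' @export
rcs_knots <- function(x, n_knots = 4, probs = NULL) {
  if (n_knots < 3) stop("need at least 3 knots", call. = FALSE)
  if (is.null(probs)) {
    probs <- switch(as.character(n_knots),
      "3" = c(0.10, 0.50, 0.90),
      "4" = c(0.05, 0.35, 0.65, 0.95),
      "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
      seq(0.05, 0.95, length.out = n_knots)
    )
  }
  k <- unname(quantile(x[is.finite(x)], probs, type = 7))
  if (any(diff(k) <= 0)) {
    stop("knots are not strictly increasing; exposure too discrete for ",
         n_knots, " knots at these percentiles", call. = FALSE)
  }
  k
}

#' Restricted (natural) cubic spline basis
#'
#' Truncated-power natural cubic spline basis in the Harrell convention:
#' `k` strictly increasing knots give `k - 1` columns, the first being `x`
#' itself (named `lin`) and the rest the nonlinear terms (`nl1`, `nl2`, ...),
#' each scaled by the squared boundary-knot span. The fitted function has
#' continuous first and second derivatives everywhere and is exactly linear
#' beyond the boundary knots (zero second derivative outside them).
#'
#' @param x Numeric vector where the basis is evaluated.
#' @param knots Strictly increasing numeric vector of at least 3 knots.
#' @return An `length(x)` by `length(knots) - 1` matrix with a `knots`
#'   attribute. Usable directly inside model formulas, e.g.
#'   `y ~ rcs_basis(obs_total, knots = c(10, 17, 23, 30))`.
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  if (k < 3) stop("need at least 3 knots", call. = FALSE)
  if (any(diff(knots) <= 0)) {
    stop("knots must be strictly increasing", call. = FALSE)
  }
  cube <- function(u) pmax(u, 0)^3
  tk <- knots[k]
  tk1 <- knots[k - 1]
  scale2 <- (tk - knots[1])^2
  out <- matrix(0, nrow = length(x), ncol = k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    out[, j + 1] <- (cube(x - tj) -
                       cube(x - tk1) * (tk - tj) / (tk - tk1) +
                       cube(x - tk) * (tk1 - tj) / (tk - tk1)) / scale2
  }
  colnames(out) <- c("lin", if (k > 2) paste0("nl", seq_len(k - 2)))
  attr(out, "knots") <- knots
  out
}

#' Exposure-response curve from a spline fit
#'
#' Evaluates the exponentiated effect (OR or HR) of an exposure modelled
#' through [rcs_basis()] over a grid, relative to a reference exposure
#' value, with a pointwise normal-approximation confidence band from the
#' design-based covariance.
#'
#' @param fit A fit from [fit_weighted_logistic()] or [fit_weighted_cox()]
#'   whose formula contains an `rcs_basis(<exposure>, ...)` term.
#' @param exposure Name of the exposure column.
#' @param knots The knot vector used in the fit.
#' @param grid Exposure values at which to evaluate; default an even grid
#'   over the observed range.
#' @param ref Reference exposure value (effect fixed at 1 there); default
#'   the observed median.
#' @param conf_level Confidence level for the band.
#' @return A tibble of class `oxb_rcs_curve` with columns `exposure`,
#'   `value`, `estimate`, `conf.low`, `conf.high` (exponentiated scale).
#' @export
rcs_curve <- function(fit, exposure, knots, grid = NULL, ref = NULL,
                      conf_level = 0.95) {
  stopifnot(inherits(fit, "oxb_svy_fit"))
  x_obs <- fit$data[[exposure]]
  if (is.null(grid)) {
    grid <- seq(min(x_obs, na.rm = TRUE), max(x_obs, na.rm = TRUE),
                length.out = 101)
  }
  if (is.null(ref)) ref <- median(x_obs, na.rm = TRUE)
  idx <- grep(paste0("rcs_basis(", exposure), names(coef(fit)), fixed = TRUE)
  if (!length(idx)) {
    stop("fit has no rcs_basis() term in '", exposure, "'", call. = FALSE)
  }
  beta <- coef(fit)[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  B <- rcs_basis(c(ref, grid), knots)
  D <- sweep(B[-1, , drop = FALSE], 2, B[1, ])
  est <- drop(D %*% beta)
  se <- sqrt(rowSums((D %*% V) * D))
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- tibble::tibble(
    exposure = exposure, value = grid,
    estimate = exp(est), conf.low = exp(est - z * se),
    conf.high = exp(est + z * se)
  )
  class(out) <- c("oxb_rcs_curve", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.oxb_rcs_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = unique(object$exposure),
                  y = "Exponentiated effect (95% CI)") +
    ggplot2::theme_minimal()
}
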