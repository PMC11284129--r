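#' Weighted Kaplan-Meier (product-limit) survival curves
#'
#' Weighted product-limit estimator per group: at each distinct event time
#' the hazard increment is the weighted number of events over the weighted
#' number at risk, and the survival curve is the cumulative product of the
#' complements. The estimate is a right-continuous step function starting
#' at 1. With unit weights it reduces to the textbook Kaplan-Meier
#' estimator.
#'
#' @param data Data frame with the survival columns.
#' @param time Name of the positive follow-up time column.
#' @param event Name of the event indicator column (logical or 0/1; 0 =
#'   censored).
#' @param group Optional name of a grouping column (e.g. OBS quartile);
#'   `NULL` for a single pooled curve.
#' @param weights Optional name of a positive weight column; `NULL` for
#'   unit weights.
#' @return A tibble of class `oxb_km` with columns `group`, `time`,
#'   `n_risk`, `n_event` (weighted totals) and `survival`, including the
#'   `time = 0, survival = 1` anchor per group.
#' @examples
#' d <- data.frame(t = c(1, 2, 3), ev = c(1, 0, 1))
#' km_estimate(d, "t", "ev")
#' @export
km_estimate <- function(data, time, event, group = NULL, weights = NULL) {
  for (col in c(time, event, group, weights)) {
    if (!col %in% names(data)) {
      stop("column '", col, "' not found in data", call. = FALSE)
    }
  }
  t <- data[[time]]
  ev <- as.numeric(data[[event]])
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("follow-up times must be positive and finite", call. = FALSE)
  }
  if (!all(ev %in% c(0, 1))) {
    stop("event indicator must be logical or 0/1", call. = FALSE)
  }
  w <- if (is.null(weights)) rep(1, nrow(data)) else data[[weights]]
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("weights must be positive and finite", call. = FALSE)
  }
  g <- if (is.null(group)) rep("all", nrow(data)) else as.character(data[[group]])
  out <- lapply(unique(g), function(gi) {
    sel <- which(g == gi)
    if (!length(sel)) stop("empty group: ", gi, call. = FALSE)
    ti <- t[sel]; ei <- ev[sel]; wi <- w[sel]
    te <- sort(unique(ti[ei == 1]))
    surv <- numeric(length(te))
    n_risk <- numeric(length(te))
    n_event <- numeric(length(te))
    s <- 1
    for (j in seq_along(te)) {
      n_risk[j] <- sum(wi[ti >= te[j]])
      n_event[j] <- sum(wi[ti == te[j] & ei == 1])
      s <- s * (1 - n_event[j] / n_risk[j])
      surv[j] <- s
    }
    tibble::tibble(group = gi, time = c(0, te),
                   n_risk = c(sum(wi), n_risk),
                   n_event = c(0, n_event), survival = c(1, surv))
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("oxb_km", class(out))
  out
}

# Evaluate a fitted product-limit curve at arbitrary times
# (right-continuous step interpolation).
km_survival_at <- function(km, times, group = NULL) {
  if (!is.null(group)) km <- km[km$group == group, ]
  vapply(times, function(tt) {
    idx <- which(km$time <= tt)
    km$survival[max(idx)]
  }, numeric(1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.oxb_km <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Follow-up time (months)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Weighted k-sample log-rank test
#'
#' Classic log-rank (Mantel-Haenszel) statistic with weighted risk and
#' event totals: at each distinct event time the observed weighted events
#' per group are compared with their expectation under a common hazard, and
#' a hypergeometric-form covariance accumulates across event times. Weights
#' are normalized to mean 1 first so the finite-population tie correction
#' keeps its usual scale; with unit weights the statistic equals the
#' unweighted log-rank exactly.
#'
#' @inheritParams km_estimate
#' @param group Name of the grouping column; at least two non-empty groups.
#' @return One-row tibble with `statistic` (chi-squared), `df`
#'   (`groups - 1`) and `p.value`.
#' @export
logrank_test <- function(data, time, event, group, weights = NULL) {
  for (col in c(time, event, group, weights)) {
    if (!col %in% names(data)) {
      stop("column '", col, "' not found in data", call. = FALSE)
    }
  }
  t <- data[[time]]
  ev <- as.numeric(data[[event]])
  g <- factor(data[[group]])
  g <- droplevels(g)
  if (nlevels(g) < 2) {
    stop("log-rank test needs at least 2 non-empty groups", call. = FALSE)
  }
  w <- if (is.null(weights)) rep(1, nrow(data)) else data[[weights]]
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  w <- w / mean(w)
  k <- nlevels(g)
  te <- sort(unique(t[ev == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (tt in te) {
    at_risk <- t >= tt
    Y <- sum(w[at_risk])
    d <- sum(w[at_risk & t == tt & ev == 1])
    if (d == 0 || Y <= 0) next
    Yg <- vapply(levels(g), function(l) sum(w[at_risk & g == l]), numeric(1))
    dg <- vapply(levels(g),
                 function(l) sum(w[at_risk & t == tt & ev == 1 & g == l]),
                 numeric(1))
    O <- O + dg
    E <- E + Yg * d / Y
    if (Y > 1) {
      p <- Yg / Y
      V <- V + d * (Y - d) / (Y - 1) * (diag(p) - tcrossprod(p))
    }
  }
  i <- seq_len(k - 1)
  delta <- (O - E)[i]
  Vi <- V[i, i, drop = FALSE]
  stat <- if (all(abs(delta) < .Machine$double.eps^0.5)) {
    0
  } else {
    drop(t(delta) %*% solve(Vi, delta))
  }
  tibble::tibble(statistic = stat, df = k - 1,
                 p.value = pchisq(stat, k - 1, lower.tail = FALSE))
}
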