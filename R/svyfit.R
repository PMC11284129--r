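#' @importFrom survival Surv
#' @export
survival::Surv

#' Survey-weighted logistic regression with Taylor-linearized variance
#'
#' Point estimates solve the weight-multiplied score equations (iteratively
#' reweighted least squares via [stats::glm()] with a quasibinomial family,
#' so estimates are invariant to the weight scale). The design-based
#' covariance is obtained by Taylor linearization: influence contributions
#' `I^-1 u_i` (score residuals premultiplied by the inverse information) are
#' summed to PSU totals and their between-PSU covariance is accumulated
#' within strata. Confidence intervals use the normal approximation on the
#' log-odds scale.
#'
#' Rows with missing values in any model or design variable are dropped
#' (complete-case). Non-convergence and separation raise explicit errors.
#'
#' @param data Participant data frame including the design columns.
#' @param formula Model formula with a binary (0/1 or logical) outcome.
#' @param strata,psu,weights Names of the design columns: stratum
#'   identifier, primary sampling unit within stratum, and analysis weight
#'   (e.g. the MEC examination weight).
#' @return An object of class `oxb_svy_logit` / `oxb_svy_fit` with
#'   [tidy()], [glance()], `coef()` and `vcov()` methods.
#' @examples
#' cohort <- compute_obs(generate_cohort(cohort_config(n = 1500, seed = 7)))
#' fit <- fit_weighted_logistic(cohort, high_risk ~ obs_total)
#' tidy(fit, exponentiate = TRUE)
#' @export
fit_weighted_logistic <- function(data, formula, strata = "stratum",
                                  psu = "psu", weights = "weight") {
  prep <- svy_prepare(data, formula, strata, psu, weights)
  d <- prep$data
  y_chk <- stats::model.response(stats::model.frame(formula, d))
  if (!all(as.numeric(y_chk) %in% c(0, 1))) {
    stop("outcome must be binary (0/1 or logical)", call. = FALSE)
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(formula, family = quasibinomial(), data = d, weights = .svy_w,
        control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  # (quasi-)separation: boundary fitted probabilities, a vanishing deviance
  # or a non-converged path, together with diverging coefficients
  if ((sep_warn || !fit$converged || fit$deviance < 1e-6) &&
      max(abs(coef(fit)), na.rm = TRUE) > 10) {
    stop("separation detected in weighted logistic fit (fitted ",
         "probabilities of 0/1 with diverging coefficients)", call. = FALSE)
  }
  if (!fit$converged) {
    stop("weighted logistic fit did not converge after ", fit$iter,
         " IRLS iterations", call. = FALSE)
  }
  if (anyNA(coef(fit))) {
    stop("aliased (collinear) terms in weighted logistic fit: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  X <- model.matrix(fit)
  mu <- fitted(fit)
  w <- d$.svy_w
  u <- X * (w * (fit$y - mu))
  A <- crossprod(X, X * (w * mu * (1 - mu)))
  infl <- tryCatch(u %*% solve(A), error = function(e) {
    stop("singular information matrix in weighted logistic fit ",
         "(collinear or unsupported terms)", call. = FALSE)
  })
  colnames(infl) <- colnames(X)
  V <- svy_linearized_vcov(infl, d[[strata]], d[[psu]])
  new_svy_fit("oxb_svy_logit", fit, formula, d,
              list(strata = strata, psu = psu, weights = weights),
              V, prep$n_dropped)
}

#' Survey-weighted Cox regression with design-based sandwich variance
#'
#' Weighted partial-likelihood estimation via [survival::coxph()] with the
#' Breslow approximation for ties. The design-based covariance aggregates
#' weighted dfbeta residuals (per-subject influences on the coefficient
#' vector) to PSU totals and accumulates their between-PSU covariance
#' within strata, as in the weighted logistic fitter.
#'
#' @inheritParams fit_weighted_logistic
#' @param formula Formula with a `Surv(time, event)` left-hand side;
#'   follow-up times must be positive and at least one event present.
#' @return An object of class `oxb_svy_cox` / `oxb_svy_fit`.
#' @export
fit_weighted_cox <- function(data, formula, strata = "stratum",
                             psu = "psu", weights = "weight") {
  prep <- svy_prepare(data, formula, strata, psu, weights)
  d <- prep$data
  y <- stats::model.response(stats::model.frame(formula, d))
  if (!inherits(y, "Surv")) {
    stop("formula must have a Surv(time, event) response", call. = FALSE)
  }
  if (any(y[, "time"] <= 0)) {
    stop("follow-up times must be strictly positive", call. = FALSE)
  }
  if (sum(y[, "status"]) == 0) {
    stop("zero events: Cox model is not estimable", call. = FALSE)
  }
  fit <- survival::coxph(formula, data = d, weights = .svy_w,
                         ties = "breslow", robust = FALSE,
                         x = TRUE, y = TRUE, model = TRUE)
  if (!is.null(fit$info) && any(is.na(coef(fit)))) {
    stop("weighted Cox fit produced undefined coefficients", call. = FALSE)
  }
  infl <- stats::residuals(fit, type = "dfbeta", weighted = TRUE)
  infl <- as.matrix(infl)
  colnames(infl) <- names(coef(fit))
  V <- svy_linearized_vcov(infl, d[[strata]], d[[psu]])
  out <- new_svy_fit("oxb_svy_cox", fit, formula, d,
                     list(strata = strata, psu = psu, weights = weights),
                     V, prep$n_dropped)
  out$n_events <- fit$nevent
  out
}

svy_refit <- function(fit, formula) {
  fitter <- if (inherits(fit, "oxb_svy_logit")) {
    fit_weighted_logistic
  } else {
    fit_weighted_cox
  }
  fitter(fit$data, formula, strata = fit$design$strata,
         psu = fit$design$psu, weights = fit$design$weights)
}

#' @exportS3Method generics::tidy
tidy.oxb_svy_fit <- function(x, exponentiate = FALSE, conf.level = 0.95,
                             ...) {
  est <- coef(x)
  se <- sqrt(diag(x$vcov))
  z <- est / se
  zc <- qnorm(1 - (1 - conf.level) / 2)
  out <- tibble::tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(z),
    p.value = 2 * pnorm(-abs(unname(z))),
    conf.low = unname(est - zc * se), conf.high = unname(est + zc * se)
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' @exportS3Method generics::glance
glance.oxb_svy_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_dropped = x$n_dropped, n_strata = x$n_strata,
    n_psu = x$n_psu, n_events = x$n_events %||% NA_integer_,
    lonely_strata = length(x$lonely_strata %||% character(0)),
    converged = x$converged
  )
}

#' Wald test for nonlinearity of a spline-coded exposure
#'
#' Tests that all nonlinear restricted-cubic-spline coefficients are jointly
#' zero, using the design-based covariance. Under the null the exposure
#' effect is linear on the link scale.
#'
#' @param fit A survey fit whose formula contains an [rcs_basis()] term.
#' @return One-row tibble with `statistic` (chi-squared), `df` and
#'   `p.value`.
#' @export
test_nonlinearity <- function(fit) {
  stopifnot(inherits(fit, "oxb_svy_fit"))
  nm <- names(coef(fit))
  idx <- grep("rcs_basis\\(.*\\)nl[0-9]+$", nm)
  if (!length(idx)) {
    stop("fit has no nonlinear spline columns; use an rcs_basis() exposure ",
         "with at least 3 knots", call. = FALSE)
  }
  svy_wald(fit, idx)
}

#' Trend test across ordered quartiles
#'
#' Refits the model with the quartile factor replaced by a single ordinal
#' term (1, 2, 3, 4); the p-trend is that term's Wald p-value under the
#' design-based covariance. The result is invariant to affine recoding of
#' the ordinal scores.
#'
#' @param fit A survey fit whose formula contains the quartile factor.
#' @param quartile Name of the quartile factor column.
#' @return One-row tibble with the ordinal slope `estimate`, `std.error`,
#'   `statistic` and `p.value` (the p-trend).
#' @export
trend_test <- function(fit, quartile) {
  stopifnot(inherits(fit, "oxb_svy_fit"))
  if (!quartile %in% names(fit$data)) {
    stop("quartile column '", quartile, "' not in fit data", call. = FALSE)
  }
  q <- droplevels(factor(fit$data[[quartile]]))
  if (nlevels(q) < 2) {
    stop("fewer than 2 quartile levels represented", call. = FALSE)
  }
  ord_term <- paste0("as.numeric(", quartile, ")")
  f2 <- update(fit$formula,
               paste(". ~ . -", quartile, "+", ord_term))
  refit <- svy_refit(fit, f2)
  td <- tidy(refit)
  td[td$term == ord_term, c("estimate", "std.error", "statistic", "p.value")]
}

#' Interaction (effect-modification) test
#'
#' Adds exposure-by-modifier product term(s) to the fitted model and
#' jointly tests them with a design-based Wald test.
#'
#' @param fit A survey fit containing the exposure.
#' @param exposure Name of the exposure term.
#' @param modifier Name of a binary or categorical modifier column.
#' @return One-row tibble with `statistic`, `df` and `p.value`.
#' @export
interaction_test <- function(fit, exposure, modifier) {
  stopifnot(inherits(fit, "oxb_svy_fit"))
  if (!modifier %in% names(fit$data)) {
    stop("modifier column '", modifier, "' not in fit data", call. = FALSE)
  }
  m <- fit$data[[modifier]]
  if (length(unique(stats::na.omit(m))) < 2) {
    stop("modifier '", modifier, "' is constant", call. = FALSE)
  }
  f2 <- update(fit$formula,
               paste0(". ~ . + ", modifier, " + ", exposure, ":", modifier))
  refit <- svy_refit(fit, f2)
  nm <- names(coef(refit))
  idx <- which(grepl(":", nm, fixed = TRUE) &
                 grepl(exposure, nm, fixed = TRUE) &
                 grepl(modifier, nm, fixed = TRUE))
  if (!length(idx)) {
    stop("no interaction terms were estimable", call. = FALSE)
  }
  svy_wald(refit, idx)
}
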