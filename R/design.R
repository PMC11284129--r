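# Design-based variance machinery shared by the weighted logistic and Cox
# fitters. Taylor linearization: per-row influence contributions are summed
# to PSU totals, and the between-PSU covariance of those totals within each
# stratum (with the usual n_h/(n_h - 1) finite-sample factor) estimates the
# sampling covariance of the estimator. Strata with a single PSU cannot
# contribute a within-stratum variance; their total is centered at the grand
# mean of all PSU totals instead (and the stratum is reported), which avoids
# silently underestimating the variance.

svy_check_design <- function(data, strata, psu, weights) {
  for (col in c(strata, psu, weights)) {
    if (!col %in% names(data)) {
      stop("design column '", col, "' not found in data", call. = FALSE)
    }
  }
  w <- data[[weights]]
  if (any(!is.na(w) & w <= 0)) {
    stop("survey weights must be strictly positive", call. = FALSE)
  }
  invisible(TRUE)
}

# infl: n x p matrix of influence contributions (already premultiplied by
# the inverse information), aligned with strata/psu vectors.
svy_linearized_vcov <- function(infl, strata, psu) {
  infl <- as.matrix(infl)
  p <- ncol(infl)
  key <- paste0(strata, "\r", psu)
  tot <- rowsum(infl, key)
  tot_stratum <- strata[match(rownames(tot), key)]
  grand <- colMeans(tot)
  V <- matrix(0, p, p)
  lonely <- character(0)
  for (h in unique(tot_stratum)) {
    z <- tot[tot_stratum == h, , drop = FALSE]
    nh <- nrow(z)
    if (nh == 1L) {
      lonely <- c(lonely, as.character(h))
      d <- z[1, ] - grand
      V <- V + tcrossprod(d)
    } else {
      d <- sweep(z, 2, colMeans(z))
      V <- V + crossprod(d) * nh / (nh - 1)
    }
  }
  if (length(lonely)) {
    warning("lonely PSU in stratum(s) ", paste(lonely, collapse = ", "),
            ": contribution centered at the grand PSU mean", call. = FALSE)
  }
  dimnames(V) <- list(colnames(infl), colnames(infl))
  attr(V, "lonely") <- lonely
  V
}

# Complete-case preparation on the model variables plus design columns.
svy_prepare <- function(data, formula, strata, psu, weights) {
  data <- tibble::as_tibble(data)
  svy_check_design(data, strata, psu, weights)
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    stop("model variable(s) not in data: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  keep <- complete.cases(data[, c(vars, strata, psu, weights)])
  d <- data[keep, , drop = FALSE]
  if (!nrow(d)) stop("no complete cases for this model", call. = FALSE)
  # point estimates and the linearized variance are invariant to the weight
  # scale; normalizing keeps IRLS well-conditioned with population-scale
  # weights
  d$.svy_w <- d[[weights]] / mean(d[[weights]])
  list(data = d, n_dropped = sum(!keep))
}

new_svy_fit <- function(subclass, engine, formula, data, design, vcov,
                        n_dropped) {
  strata <- data[[design$strata]]
  psu <- paste0(strata, "\r", data[[design$psu]])
  structure(
    list(
      coefficients = coef(engine),
      vcov = vcov,
      engine = engine,
      formula = formula,
      data = data,
      design = design,
      n = nrow(data),
      n_dropped = n_dropped,
      n_strata = length(unique(strata)),
      n_psu = length(unique(psu)),
      lonely_strata = attr(vcov, "lonely"),
      converged = TRUE
    ),
    class = c(subclass, "oxb_svy_fit")
  )
}

#' @export
coef.oxb_svy_fit <- function(object, ...) object$coefficients

#' @export
vcov.oxb_svy_fit <- function(object, ...) object$vcov

#' @export
print.oxb_svy_fit <- function(x, ...) {
  kind <- if (inherits(x, "oxb_svy_logit")) "logistic" else "Cox"
  cat("Survey-weighted", kind, "fit (Taylor-linearized variance)\n")
  cat("  n =", x$n, " strata =", x$n_strata, " PSUs =", x$n_psu, "\n")
  print(tidy(x, exponentiate = TRUE), n = Inf)
  invisible(x)
}

# Wald test of H0: selected coefficients are all zero, using the
# design-based covariance.
svy_wald <- function(fit, idx) {
  b <- coef(fit)[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  qr_V <- qr(V)
  if (qr_V$rank < length(b)) {
    stop("singular design-based covariance in Wald test", call. = FALSE)
  }
  stat <- drop(t(b) %*% solve(qr_V, b))
  df <- length(b)
  tibble::tibble(statistic = stat, df = df,
                 p.value = pchisq(stat, df, lower.tail = FALSE))
}
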