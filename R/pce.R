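# Pooled Cohort Equations (PCE): race- and sex-specific proportional-hazards
# risk equations for a first hard ASCVD event within 10 years.
# risk = 1 - S10 ^ exp(LP - group mean LP), with the linear predictor LP a
# sum of log-transformed risk factors, treatment-specific SBP terms, flags
# and age interactions. Coefficients live in a versioned data file, not in
# code, so the transcription from the source guideline stays auditable.

.pce_terms <- c(
  "ln_age", "ln_age_sq", "ln_tc", "ln_age_ln_tc", "ln_hdl", "ln_age_ln_hdl",
  "ln_sbp_treated", "ln_age_ln_sbp_treated", "ln_sbp_untreated",
  "ln_age_ln_sbp_untreated", "smoker", "ln_age_smoker", "diabetes"
)
.pce_groups <- c("white_female", "black_female", "white_male", "black_male")

#' Load and validate a Pooled Cohort Equations coefficient set
#'
#' Reads a coefficient file (default: the set packaged with the package,
#' transcribed from the 2013 ACC/AHA risk-assessment guideline) and checks
#' its schema: all four sex-by-race groups present, every term name known,
#' one `mean_lp` and one `s10` row per group, and `s10` strictly inside
#' (0, 1).
#'
#' @param path Path to a CSV file with columns `group`, `term`, `value` (and
#'   optionally `source`); `NULL` for the packaged default.
#' @return A tibble of class `oxb_pce` with a `checksum` attribute (sum of
#'   the coefficient values, logged so a transcription edit is detectable).
#' @examples
#' coefs <- pce_coefficients()
#' attr(coefs, "checksum")
#' @export
pce_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pce_coefficients.csv",
                        package = "oxbalance", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("coefficient file not found: ", path,
                               call. = FALSE)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("group", "term", "value") %in% names(tab))) {
    stop("coefficient file needs columns group, term, value", call. = FALSE)
  }
  missing_groups <- setdiff(.pce_groups, unique(tab$group))
  if (length(missing_groups)) {
    stop("coefficient file is missing group(s): ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  }
  bad_group <- setdiff(unique(tab$group), .pce_groups)
  if (length(bad_group)) {
    stop("unknown group(s) in coefficient file: ",
         paste(bad_group, collapse = ", "), call. = FALSE)
  }
  bad_term <- setdiff(unique(tab$term), c(.pce_terms, "mean_lp", "s10"))
  if (length(bad_term)) {
    stop("unknown term(s) in coefficient file: ",
         paste(bad_term, collapse = ", "), call. = FALSE)
  }
  for (g in .pce_groups) {
    sub <- tab[tab$group == g, ]
    if (sum(sub$term == "mean_lp") != 1L || sum(sub$term == "s10") != 1L) {
      stop("group '", g, "' must have exactly one mean_lp and one s10 row",
           call. = FALSE)
    }
    s10 <- sub$value[sub$term == "s10"]
    if (!is.finite(s10) || s10 <= 0 || s10 >= 1) {
      stop("group '", g, "': s10 must lie strictly in (0, 1), got ", s10,
           call. = FALSE)
    }
    if (anyDuplicated(sub$term)) {
      stop("group '", g, "' has duplicated term(s)", call. = FALSE)
    }
  }
  attr(tab, "checksum") <- sum(tab$value)
  class(tab) <- c("oxb_pce", class(tab))
  tab
}

# Evaluate one PCE design term for a profile table.
pce_term_value <- function(term, d) {
  la <- log(d$age)
  trt <- as.numeric(d$bp_treated)
  switch(term,
    ln_age = la,
    ln_age_sq = la^2,
    ln_tc = log(d$total_chol),
    ln_age_ln_tc = la * log(d$total_chol),
    ln_hdl = log(d$hdl),
    ln_age_ln_hdl = la * log(d$hdl),
    ln_sbp_treated = trt * log(d$sbp),
    ln_age_ln_sbp_treated = trt * la * log(d$sbp),
    ln_sbp_untreated = (1 - trt) * log(d$sbp),
    ln_age_ln_sbp_untreated = (1 - trt) * la * log(d$sbp),
    smoker = as.numeric(d$smoker),
    ln_age_smoker = la * as.numeric(d$smoker),
    diabetes = as.numeric(d$diabetes),
    stop("unknown PCE term: ", term, call. = FALSE)
  )
}

#' Compute 10-year ASCVD risk with the Pooled Cohort Equations
#'
#' Vectorized over the rows of `data`. Each participant is assigned one of
#' four equation groups by sex and race: `ethnicity == "black"` maps to the
#' African-American equations and all other categories to the white
#' equations (the guideline's stated practice for groups without their own
#' equations). Ages outside the PCE-valid range 20--79 produce a warning and
#' are flagged, never clamped: the pipeline excludes them.
#'
#' @param data Data frame with columns `age` (years), `sex`
#'   (`"male"`/`"female"`), `ethnicity`, `total_chol` (mg/dL), `hdl`
#'   (mg/dL), `sbp` (mmHg), `bp_treated`, `diabetes`, `smoker`
#'   (logical/0-1 flags).
#' @param coefs A coefficient set from [pce_coefficients()].
#' @return Numeric vector of 10-year risks in (0, 1), with attribute
#'   `valid_age` (logical vector).
#' @export
pce_risk <- function(data, coefs = pce_coefficients()) {
  need <- c("age", "sex", "ethnicity", "total_chol", "hdl", "sbp",
            "bp_treated", "diabetes", "smoker")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("missing risk-factor column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!inherits(coefs, "oxb_pce")) {
    stop("`coefs` must come from pce_coefficients()", call. = FALSE)
  }
  if (any(data$total_chol <= 0 | data$hdl <= 0 | data$sbp <= 0,
          na.rm = TRUE)) {
    stop("cholesterol and SBP values must be strictly positive",
         call. = FALSE)
  }
  race_group <- ifelse(data$ethnicity == "black", "black", "white")
  group <- paste(race_group, data$sex, sep = "_")
  if (!all(stats::na.omit(unique(group)) %in% .pce_groups)) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  valid_age <- !is.na(data$age) & data$age >= 20 & data$age <= 79
  if (any(!valid_age)) {
    warning(sum(!valid_age), " row(s) outside the PCE-valid age range ",
            "[20, 79]; risks are flagged via attr(., 'valid_age')",
            call. = FALSE)
  }
  risk <- rep(NA_real_, nrow(data))
  for (g in .pce_groups) {
    idx <- which(!is.na(group) & group == g)
    if (!length(idx)) next
    sub <- coefs[coefs$group == g, ]
    d <- data[idx, , drop = FALSE]
    lp <- numeric(length(idx))
    for (k in seq_len(nrow(sub))) {
      if (sub$term[k] %in% c("mean_lp", "s10")) next
      lp <- lp + sub$value[k] * pce_term_value(sub$term[k], d)
    }
    mean_lp <- sub$value[sub$term == "mean_lp"]
    s10 <- sub$value[sub$term == "s10"]
    risk[idx] <- 1 - s10^exp(lp - mean_lp)
  }
  attr(risk, "valid_age") <- valid_age
  risk
}

#' Dichotomize 10-year ASCVD risk at a threshold
#'
#' High risk is right-closed at the threshold: a predicted risk exactly
#' equal to the threshold (default 7.5%) is classified high.
#'
#' @param risk Numeric vector of probabilities in `[0, 1]`.
#' @param threshold Classification threshold, default `0.075`.
#' @return Factor with levels `low`, `high` (`NA` propagates).
#' @examples
#' classify_high_risk(c(0.0749, 0.075))
#' @export
classify_high_risk <- function(risk, threshold = 0.075) {
  if (any(risk < 0 | risk > 1, na.rm = TRUE)) {
    stop("risk values must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop("threshold must be a probability", call. = FALSE)
  }
  factor(ifelse(risk >= threshold, "high", "low"), levels = c("low", "high"))
}

#' Add ASCVD risk and high-risk classification columns
#'
#' Convenience wrapper around [pce_risk()] and [classify_high_risk()] for
#' pipeline use.
#'
#' @inheritParams pce_risk
#' @inheritParams classify_high_risk
#' @return `data` with added columns `ascvd_risk` (probability),
#'   `ascvd_high` (logical, `risk >= threshold`) and `pce_valid_age`
#'   (logical flag used by the exclusion cascade).
#' @export
add_ascvd_risk <- function(data, coefs = pce_coefficients(),
                           threshold = 0.075) {
  risk <- pce_risk(data, coefs)
  data <- tibble::as_tibble(data)
  data$ascvd_risk <- as.numeric(risk)
  data$ascvd_high <- classify_high_risk(as.numeric(risk), threshold) == "high"
  data$pce_valid_age <- attr(risk, "valid_age")
  data
}
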