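#' Adjustment covariate sets for Models 1-3
#'
#' Model 1 is unadjusted (exposure only); Model 2 adds sex, age, ethnicity
#' and education; Model 3 adds creatinine, lymphocyte percentage, white
#' blood cell count, ALT, alcohol-user category, diabetes, hypertension,
#' hyperlipidemia, anemia and total energy intake.
#'
#' @param model Integer 1, 2 or 3.
#' @return Character vector of covariate column names.
#' @export
model_covariates <- function(model) {
  if (!model %in% 1:3) stop("model must be 1, 2 or 3", call. = FALSE)
  m2 <- c("sex", "age", "ethnicity", "education")
  m3 <- c("creatinine", "lymphocyte_pct", "wbc", "alt", "alcohol_user",
          "diabetes", "hypertension", "hyperlipidemia", "anemia",
          "energy_kcal")
  switch(model, character(0), m2, c(m2, m3))
}

#' Default exclusion cascade
#'
#' Ordered rules mirroring the study's participant flow: missing OBS
#' components, missing ASCVD risk inputs, age outside the PCE-valid range,
#' prevalent ASCVD, missing adjustment covariates, missing mortality
#' linkage. Each removed row is attributed to the first rule it violates.
#'
#' @param components Component table whose columns define OBS missingness.
#' @return A tibble with columns `rule`, `type` and a `columns` list
#'   column; `type` is one of `missing_any`, `outside_range`, `flag_true`.
#' @export
default_exclusion_rules <- function(components = obs_components()) {
  tibble::tibble(
    rule = c("missing_obs_component", "missing_ascvd_input",
             "age_outside_pce_range", "prevalent_ascvd",
             "missing_covariate", "missing_mortality"),
    type = c("missing_any", "missing_any", "outside_range", "flag_true",
             "missing_any", "missing_any"),
    columns = list(
      components$component,
      c("age", "sex", "ethnicity", "total_chol", "hdl", "sbp",
        "bp_treated", "diabetes", "smoker"),
      "age",
      "prevalent_ascvd",
      model_covariates(3),
      c("follow_months", "death")
    ),
    lower = c(NA, NA, 20, NA, NA, NA),
    upper = c(NA, NA, 79, NA, NA, NA)
  )
}

#' Apply the exclusion cascade
#'
#' Rules are applied in declared order; the ledger records, for each rule,
#' how many of the still-remaining rows it removed and how many remain
#' after it, so every removed row is counted by exactly one rule and the
#' final count reconciles with the input.
#'
#' @param data Raw participant table.
#' @param rules Rule table as from [default_exclusion_rules()].
#' @return A list with `cohort` (the analytic tibble) and `ledger` (tibble
#'   with `rule`, `n_removed`, `n_remaining`).
#' @export
apply_exclusions <- function(data, rules = default_exclusion_rules()) {
  data <- tibble::as_tibble(data)
  keep <- rep(TRUE, nrow(data))
  ledger <- vector("list", nrow(rules))
  for (i in seq_len(nrow(rules))) {
    cols <- rules$columns[[i]]
    missing_cols <- setdiff(cols, names(data))
    if (length(missing_cols)) {
      stop("exclusion rule '", rules$rule[i], "' references unknown ",
           "column(s): ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    viol <- switch(rules$type[i],
      missing_any = {
        if (nrow(data)) {
          rowSums(is.na(data[, cols, drop = FALSE])) > 0
        } else logical(0)
      },
      outside_range = {
        v <- data[[cols[1]]]
        !is.na(v) & (v < rules$lower[i] | v > rules$upper[i])
      },
      flag_true = {
        v <- data[[cols[1]]]
        !is.na(v) & as.logical(v)
      },
      stop("unknown rule type: ", rules$type[i], call. = FALSE)
    )
    removed <- keep & viol
    keep <- keep & !removed
    ledger[[i]] <- tibble::tibble(rule = rules$rule[i],
                                  n_removed = sum(removed),
                                  n_remaining = sum(keep))
  }
  list(cohort = data[keep, , drop = FALSE],
       ledger = dplyr::bind_rows(ledger))
}

# One (exposure x form x model) fit; returns result rows plus details.
fit_one_spec <- function(data, outcome, exposure, form, model, engine,
                         strata, psu, weights, surv_time = NULL) {
  covs <- model_covariates(model)
  rhs_cov <- if (length(covs)) paste("+", paste(covs, collapse = " + ")) else ""
  lhs <- if (engine == "logistic") {
    outcome
  } else {
    sprintf("Surv(%s, %s)", surv_time, outcome)
  }
  fitter <- if (engine == "logistic") fit_weighted_logistic else fit_weighted_cox
  env <- environment()
  res <- tryCatch({
    if (form == "continuous") {
      f <- as.formula(paste(lhs, "~", exposure, rhs_cov), env = env)
      fit <- fitter(data, f, strata, psu, weights)
      td <- tidy(fit, exponentiate = TRUE)
      td <- td[td$term == exposure, ]
      tibble::tibble(term = exposure, level = NA_character_,
                     estimate = td$estimate, conf.low = td$conf.low,
                     conf.high = td$conf.high, p.value = td$p.value,
                     p_trend = NA_real_, p_nonlinearity = NA_real_,
                     n = fit$n)
    } else if (form == "quartile") {
      qcol <- paste0(exposure, "_q")
      d <- data
      d[[qcol]] <- assign_quartiles(d[[exposure]])
      f <- as.formula(paste(lhs, "~", qcol, rhs_cov), env = env)
      fit <- fitter(d, f, strata, psu, weights)
      td <- tidy(fit, exponentiate = TRUE)
      td <- td[grepl(paste0("^", qcol), td$term), ]
      ptr <- trend_test(fit, qcol)$p.value
      dplyr::bind_rows(
        tibble::tibble(term = qcol, level = "Q1", estimate = 1,
                       conf.low = NA_real_, conf.high = NA_real_,
                       p.value = NA_real_),
        tibble::tibble(term = qcol, level = sub(qcol, "", td$term),
                       estimate = td$estimate, conf.low = td$conf.low,
                       conf.high = td$conf.high, p.value = td$p.value)
      ) |>
        dplyr::mutate(p_trend = ptr, p_nonlinearity = NA_real_, n = fit$n)
    } else if (form == "spline") {
      ks <- rcs_knots(data[[exposure]])
      f <- as.formula(
        sprintf("%s ~ rcs_basis(%s, knots = c(%s)) %s", lhs, exposure,
                paste(format(ks, digits = 15), collapse = ", "), rhs_cov),
        env = env
      )
      fit <- fitter(data, f, strata, psu, weights)
      pnl <- test_nonlinearity(fit)$p.value
      lin_term <- grep("rcs_basis\\(.*\\)lin$", names(coef(fit)), value = TRUE)
      td <- tidy(fit, exponentiate = TRUE)
      td <- td[td$term == lin_term, ]
      tibble::tibble(term = exposure, level = NA_character_,
                     estimate = td$estimate, conf.low = td$conf.low,
                     conf.high = td$conf.high, p.value = td$p.value,
                     p_trend = NA_real_, p_nonlinearity = pnl, n = fit$n)
    } else {
      stop("unknown exposure form: ", form, call. = FALSE)
    }
  }, error = function(e) {
    stop(sprintf("fit failed for exposure '%s', form '%s', model %d: %s",
                 exposure, form, model, conditionMessage(e)), call. = FALSE)
  })
  res$exposure <- exposure
  res$form <- form
  res$model <- model
  res
}

#' Cross-sectional analysis of OBS and high ASCVD risk
#'
#' For every combination of exposure (total, dietary, lifestyle OBS), form
#' (continuous, quartile, spline) and adjustment model (1--3): a
#' survey-weighted logistic fit, with a p-trend for the quartile form and a
#' nonlinearity p-value for the spline form. Q1 is always the reference
#' level with effect exactly 1.
#'
#' @param data Analytic table with the OBS columns (see [compute_obs()])
#'   and the binary outcome already present.
#' @param outcome Name of the binary outcome column.
#' @param exposures,forms,models Which combinations to run.
#' @inheritParams fit_weighted_logistic
#' @return A tibble of results (one row per reported effect), ordered by
#'   exposure, form, model.
#' @export
run_cross_sectional <- function(data, outcome = "high_risk",
                                exposures = c("obs_total", "obs_dietary",
                                              "obs_lifestyle"),
                                forms = c("continuous", "quartile", "spline"),
                                models = 1:3, strata = "stratum",
                                psu = "psu", weights = "weight") {
  need <- c(outcome, exposures)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("column(s) must be computed upstream: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  grid <- expand.grid(exposure = exposures, form = forms, model = models,
                      stringsAsFactors = FALSE)
  out <- purrr::pmap(grid, function(exposure, form, model) {
    fit_one_spec(data, outcome, exposure, form, model, "logistic",
                 strata, psu, weights)
  })
  dplyr::bind_rows(out) |>
    dplyr::select("exposure", "form", "model", "term", "level", "estimate",
                  "conf.low", "conf.high", "p.value", "p_trend",
                  "p_nonlinearity", "n")
}

#' Cohort (mortality) analysis among high-risk participants
#'
#' Survey-weighted Cox models for all-cause and CVD mortality across the
#' same exposure/form/model grid as the cross-sectional analysis, plus
#' weighted Kaplan-Meier curves by OBS quartile with a log-rank test and a
#' two-segment (turning-point) Cox model for the lifestyle OBS against
#' all-cause mortality.
#'
#' @param data Analytic table restricted to high-risk rows (every row must
#'   have `ascvd_high == TRUE` when that column is present), with OBS and
#'   survival columns.
#' @param outcomes Which mortality outcomes to model: `"all_cause"` uses
#'   the `death` indicator, `"cvd"` the `cvd_death` indicator.
#' @inheritParams run_cross_sectional
#' @param time Name of the follow-up time column (months).
#' @return A list of class `oxb_cohort_report`: `fits` (result tibble with
#'   an `outcome` column), `km` (quartile curves), `logrank`, `segmented`.
#' @export
run_cohort <- function(data, outcomes = c("all_cause", "cvd"),
                       exposures = c("obs_total", "obs_dietary",
                                     "obs_lifestyle"),
                       forms = c("continuous", "quartile", "spline"),
                       models = 1:3, time = "follow_months",
                       strata = "stratum", psu = "psu", weights = "weight") {
  if ("ascvd_high" %in% names(data) && !all(data$ascvd_high)) {
    stop("run_cohort expects a table restricted to high-risk rows ",
         "(ascvd_high TRUE)", call. = FALSE)
  }
  event_col <- c(all_cause = "death", cvd = "cvd_death")
  fits <- list()
  for (oc in outcomes) {
    ev <- event_col[[oc]]
    if (!ev %in% names(data)) {
      stop("event column '", ev, "' not found", call. = FALSE)
    }
    if (sum(data[[ev]], na.rm = TRUE) == 0) {
      stop("zero events for outcome '", oc, "': model not estimable",
           call. = FALSE)
    }
    grid <- expand.grid(exposure = exposures, form = forms, model = models,
                        stringsAsFactors = FALSE)
    res <- purrr::pmap(grid, function(exposure, form, model) {
      fit_one_spec(data, ev, exposure, form, model, "cox",
                   strata, psu, weights, surv_time = time)
    })
    fits[[oc]] <- dplyr::bind_rows(res) |> dplyr::mutate(outcome = oc)
  }
  d <- add_obs_quartile(data)
  km <- km_estimate(d, time, "death", group = "obs_total_q",
                    weights = weights)
  lr <- logrank_test(d, time, "death", group = "obs_total_q",
                     weights = weights)
  seg <- segmented_cox(data, time, "death", "obs_lifestyle",
                       strata = strata, psu = psu, weights = weights)
  structure(
    list(fits = dplyr::bind_rows(fits), km = km, logrank = lr,
         segmented = seg),
    class = "oxb_cohort_report"
  )
}

#' Subgroup analyses with interaction tests
#'
#' Refits the Model-3 continuous-exposure model within each level of each
#' modifier (age dichotomized at 60 years, sex, GFR at 60 mL/min/1.73m2,
#' hyperlipidemia, hypertension by default) and reports the per-level
#' exponentiated effect plus a design-based interaction p-value per
#' modifier. Modifier variables are removed from the adjustment set of
#' their own subgroup models. Levels where the model is not estimable are
#' reported as such, not dropped.
#'
#' @inheritParams run_cross_sectional
#' @param exposure Single exposure column.
#' @param modifiers Character vector of modifier columns; `age_group` and
#'   `gfr_group` are derived automatically when requested.
#' @return A tibble with one row per modifier level.
#' @export
run_subgroups <- function(data, outcome = "high_risk",
                          exposure = "obs_total",
                          modifiers = c("age_group", "sex", "gfr_group",
                                        "hyperlipidemia", "hypertension"),
                          strata = "stratum", psu = "psu",
                          weights = "weight") {
  data <- tibble::as_tibble(data)
  if ("age_group" %in% modifiers && !"age_group" %in% names(data)) {
    data$age_group <- ifelse(data$age < 60, "under60", "60plus")
  }
  if ("gfr_group" %in% modifiers && !"gfr_group" %in% names(data)) {
    data$gfr_group <- ifelse(data$gfr < 60, "gfr_low", "gfr_normal")
  }
  out <- list()
  for (mod in modifiers) {
    if (!mod %in% names(data)) {
      stop("modifier column '", mod, "' not found", call. = FALSE)
    }
    lv <- unique(stats::na.omit(data[[mod]]))
    if (length(lv) < 2) {
      stop("modifier '", mod, "' is constant", call. = FALSE)
    }
    # the modifier (and its source variable) must leave the adjustment set
    covs <- setdiff(model_covariates(3),
                    c(mod, if (mod == "age_group") "age",
                      if (mod == "gfr_group") "gfr"))
    rhs <- paste(c(exposure, covs), collapse = " + ")
    full <- fit_weighted_logistic(
      data, as.formula(paste(outcome, "~", rhs)), strata, psu, weights
    )
    p_int <- interaction_test(full, exposure, mod)$p.value
    for (l in sort(as.character(lv))) {
      sub <- data[!is.na(data[[mod]]) & data[[mod]] == l, , drop = FALSE]
      row <- tryCatch({
        fit <- fit_weighted_logistic(
          sub, as.formula(paste(outcome, "~", rhs)), strata, psu, weights
        )
        td <- tidy(fit, exponentiate = TRUE)
        td <- td[td$term == exposure, ]
        tibble::tibble(modifier = mod, level = l, n = fit$n,
                       estimate = td$estimate, conf.low = td$conf.low,
                       conf.high = td$conf.high, p.value = td$p.value,
                       p_interaction = p_int, note = NA_character_)
      }, error = function(e) {
        tibble::tibble(modifier = mod, level = l, n = nrow(sub),
                       estimate = NA_real_, conf.low = NA_real_,
                       conf.high = NA_real_, p.value = NA_real_,
                       p_interaction = p_int,
                       note = paste("not estimable:", conditionMessage(e)))
      })
      out[[length(out) + 1L]] <- row
    }
  }
  dplyr::bind_rows(out)
}

#' Write an analysis report to disk
#'
#' Serializes the pipeline outputs: machine-readable result tables (CSV),
#' the exclusion ledger, run metadata (seed, package version, PCE
#' coefficient checksum, timestamp) as JSON, a formatted text table of the
#' regression results, and KM / spline figures when present.
#'
#' @param report A list with elements `cross_sectional` (tibble from
#'   [run_cross_sectional()]), `cohort` (from [run_cohort()]), and `ledger`
#'   (from [apply_exclusions()]); all three must be present.
#' @param dir Output directory (created if needed).
#' @param seed Seed to record in the metadata.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, seed = NA) {
  need <- c("cross_sectional", "cohort", "ledger")
  missing_parts <- setdiff(need, names(report))
  if (length(missing_parts)) {
    stop("report is missing section(s): ",
         paste(missing_parts, collapse = ", "), call. = FALSE)
  }
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  }
  paths <- c(
    cross_sectional = file.path(dir, "cross_sectional.csv"),
    cohort = file.path(dir, "cohort_mortality.csv"),
    ledger = file.path(dir, "exclusion_ledger.csv"),
    segmented = file.path(dir, "segmented_fit.csv"),
    metadata = file.path(dir, "run_metadata.json"),
    tables = file.path(dir, "tables.txt"),
    km_plot = file.path(dir, "km_curves.pdf")
  )
  readr::write_csv(report$cross_sectional, paths[["cross_sectional"]])
  readr::write_csv(report$cohort$fits, paths[["cohort"]])
  readr::write_csv(report$ledger, paths[["ledger"]])
  seg <- report$cohort$segmented
  readr::write_csv(
    dplyr::mutate(tidy(seg), breakpoint = seg$breakpoint,
                  identifiable = seg$identifiable),
    paths[["segmented"]]
  )
  meta <- list(
    seed = seed,
    package_version = as.character(packageVersion("oxbalance")),
    pce_checksum = attr(pce_coefficients(), "checksum"),
    written_at = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(meta, paths[["metadata"]], auto_unbox = TRUE)
  fmt_row <- function(r) {
    sprintf("%-14s %-10s M%d %-4s OR/HR %5.2f (%s) p=%s",
            r$exposure, r$form, r$model,
            ifelse(is.na(r$level), "", r$level), r$estimate,
            ifelse(is.na(r$conf.low), "ref",
                   sprintf("%.2f, %.2f", r$conf.low, r$conf.high)),
            format.pval(r$p.value, digits = 2))
  }
  lines <- c(
    "Cross-sectional: OBS vs high 10-year ASCVD risk",
    vapply(seq_len(nrow(report$cross_sectional)),
           function(i) fmt_row(report$cross_sectional[i, ]), character(1)),
    "", "Cohort: OBS vs mortality among high-risk participants",
    vapply(seq_len(nrow(report$cohort$fits)),
           function(i) fmt_row(report$cohort$fits[i, ]), character(1))
  )
  writeLines(lines, paths[["tables"]])
  p <- autoplot(report$cohort$km)
  ggplot2::ggsave(paths[["km_plot"]], p, width = 7, height = 5)
  invisible(paths)
}
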