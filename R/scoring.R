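#' Score alcohol intake for the oxidative balance score
#'
#' Alcohol is the one OBS component not scored by tertiles. Intake is
#' classified as abstainer (exactly 0 g/day on the recall), non-heavy
#' (between 0 and the sex-specific heavy-drinking threshold) or heavy
#' (at or above the threshold: 15 g/day for women, 30 g/day for men), and
#' scored 2, 1 and 0 respectively. The threshold itself counts as heavy,
#' which makes the three categories exhaustive and mutually exclusive.
#'
#' @param intake_g_per_day Non-negative alcohol intake in grams per day.
#'   `NA` propagates (a missing-data signal for upstream exclusion).
#' @param sex Character vector, `"male"` or `"female"`, recycled against
#'   `intake_g_per_day`.
#' @param thresholds Named numeric vector of heavy-drinking thresholds in
#'   g/day, with elements `female` and `male`.
#' @return Integer vector of scores in `{0, 1, 2}`.
#' @examples
#' score_alcohol(c(0, 20, 20), c("male", "male", "female"))
#' @export
score_alcohol <- function(intake_g_per_day, sex,
                          thresholds = c(female = 15, male = 30)) {
  if (!all(c("female", "male") %in% names(thresholds))) {
    stop("`thresholds` must have elements 'female' and 'male'", call. = FALSE)
  }
  bad_sex <- !is.na(sex) & !(sex %in% c("male", "female"))
  if (any(bad_sex)) {
    stop("unknown sex value(s): ",
         paste(unique(sex[bad_sex]), collapse = ", "), call. = FALSE)
  }
  if (any(intake_g_per_day < 0, na.rm = TRUE)) {
    stop("alcohol intake must be non-negative", call. = FALSE)
  }
  n <- max(length(intake_g_per_day), length(sex))
  intake <- rep_len(intake_g_per_day, n)
  sex <- rep_len(sex, n)
  thr <- unname(thresholds[sex])
  out <- ifelse(intake == 0, 2L, ifelse(intake < thr, 1L, 0L))
  as.integer(out)
}

#' Fit sex-stratified tertile cutpoints for tertile-scored components
#'
#' Cutpoints are the 1/3 and 2/3 empirical quantiles (inverse-ECDF quantile,
#' `type = 1`) of each component within each sex stratum, computed unweighted
#' on the supplied (analytic) sample. Scoring then uses right-closed
#' intervals: `value <= t1` is tertile 1, `t1 < value <= t2` tertile 2,
#' `value > t2` tertile 3. The alcohol-rule component gets no cutpoints.
#'
#' @param data Participant data frame with one column per tertile-rule
#'   component and a sex column.
#' @param components Component table, defaults to [obs_components()].
#' @param sex Name of the sex column (values `"male"`/`"female"`).
#' @return A tibble of class `oxb_scoring_table` with columns `component`,
#'   `sex`, `t1`, `t2` and a `provenance` attribute (sample size, fit time).
#' @export
fit_scoring_table <- function(data, components = obs_components(),
                              sex = "sex") {
  components <- validate_components(components)
  if (!sex %in% names(data)) {
    stop("sex column '", sex, "' not found in data", call. = FALSE)
  }
  sexes <- unique(stats::na.omit(data[[sex]]))
  if (!length(sexes) || !all(sexes %in% c("male", "female"))) {
    stop("sex column must contain 'male'/'female' values", call. = FALSE)
  }
  tert <- components$component[components$rule == "tertile"]
  missing_cols <- setdiff(tert, names(data))
  if (length(missing_cols)) {
    stop("missing component column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (comp in tert) {
    for (sx in sort(as.character(sexes))) {
      v <- data[[comp]][data[[sex]] == sx]
      v <- v[is.finite(v)]
      if (length(unique(v)) < 3L) {
        stop("degenerate component '", comp, "' in ", sx,
             " stratum: fewer than 3 distinct finite values", call. = FALSE)
      }
      q <- unname(quantile(v, c(1, 2) / 3, type = 1))
      rows[[length(rows) + 1L]] <-
        tibble::tibble(component = comp, sex = sx, t1 = q[1], t2 = q[2])
    }
  }
  out <- dplyr::bind_rows(rows)
  stopifnot(all(out$t1 <= out$t2))
  attr(out, "provenance") <- list(
    n = nrow(data),
    sexes = sort(as.character(sexes)),
    fitted_at = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  class(out) <- c("oxb_scoring_table", class(out))
  out
}

#' Score a component value against tertile cutpoints
#'
#' Tertile membership uses right-closed intervals (`value <= t1` is the
#' bottom tertile). Antioxidants score `tertile - 1` (0, 1, 2 ascending);
#' pro-oxidants score `3 - tertile` (2, 1, 0 descending), so for any value
#' the two polarities always sum to 2.
#'
#' @param value Numeric vector of component values; `NA` propagates.
#' @param t1,t2 Lower and upper cutpoints (recycled), from
#'   [fit_scoring_table()] for the matching sex.
#' @param polarity `"antioxidant"` or `"prooxidant"` (recycled).
#' @return Integer scores in `{0, 1, 2}` (`NA` where `value` is missing).
#' @export
score_component <- function(value, t1, t2, polarity) {
  if (!all(polarity %in% c("antioxidant", "prooxidant"))) {
    stop("polarity must be 'antioxidant' or 'prooxidant'", call. = FALSE)
  }
  if (any(t1 > t2)) stop("t1 must be <= t2", call. = FALSE)
  g <- 1L + (value > t1) + (value > t2)
  pol <- rep_len(polarity, length(g))
  as.integer(ifelse(pol == "antioxidant", g - 1L, 3L - g))
}

#' Compute oxidative balance scores for a participant table
#'
#' Applies the per-component scoring rules and sums them into the dietary
#' sub-score (16 components, range 0--32), the lifestyle sub-score (4
#' components, range 0--8) and the total OBS (range 0--40). Rows with any
#' missing component value get `NA` scores (complete-case exclusion happens
#' upstream; nothing is imputed here).
#'
#' @param data Participant data frame with the 20 component columns and a
#'   sex column.
#' @param scoring A fitted [fit_scoring_table()] result, or `NULL` to fit
#'   one on `data` itself.
#' @param components Component table, defaults to [obs_components()].
#' @param sex Name of the sex column.
#' @param keep_scores If `TRUE`, also return the per-component 0/1/2 scores
#'   as `score_<component>` columns.
#' @return `data` as a tibble with added columns `obs_dietary`,
#'   `obs_lifestyle` and `obs_total` (and per-component scores when
#'   requested).
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 200, seed = 1))
#' scored <- compute_obs(cohort)
#' summary(scored$obs_total)
#' @export
compute_obs <- function(data, scoring = NULL, components = obs_components(),
                        sex = "sex", keep_scores = FALSE) {
  components <- validate_components(components)
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(components$component, names(data))
  if (length(missing_cols)) {
    stop("missing component column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(scoring)) {
    scoring <- fit_scoring_table(data, components, sex = sex)
  }
  n <- nrow(data)
  score_mat <- matrix(NA_integer_, nrow = n, ncol = nrow(components),
                      dimnames = list(NULL, components$component))
  for (i in seq_len(nrow(components))) {
    comp <- components$component[i]
    if (components$rule[i] == "alcohol") {
      score_mat[, i] <- score_alcohol(data[[comp]], data[[sex]])
    } else {
      cuts <- scoring[scoring$component == comp, ]
      idx <- match(data[[sex]], cuts$sex)
      score_mat[, i] <- score_component(
        data[[comp]], cuts$t1[idx], cuts$t2[idx], components$polarity[i]
      )
    }
  }
  dietary <- components$class == "dietary"
  data$obs_dietary <- as.integer(rowSums(score_mat[, dietary, drop = FALSE]))
  data$obs_lifestyle <- as.integer(rowSums(score_mat[, !dietary, drop = FALSE]))
  data$obs_total <- data$obs_dietary + data$obs_lifestyle
  if (keep_scores) {
    sc <- tibble::as_tibble(as.data.frame(score_mat))
    names(sc) <- paste0("score_", names(sc))
    data <- dplyr::bind_cols(data, sc)
  }
  data
}

#' Assign score quartiles
#'
#' Boundaries are the 25th/50th/75th empirical percentiles (inverse-ECDF,
#' `type = 1`) of the supplied scores, with right-closed intervals so ties
#' at a boundary fall in the lower quartile.
#'
#' @param scores Numeric vector with at least 4 distinct finite values.
#' @return A factor with levels `Q1`--`Q4` and attribute `boundaries` (the
#'   three cut values). `NA` scores give `NA` labels.
#' @export
assign_quartiles <- function(scores) {
  v <- scores[is.finite(scores)]
  if (length(unique(v)) < 4L) {
    stop("degenerate quartiles: fewer than 4 distinct score values",
         call. = FALSE)
  }
  b <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 1))
  lab <- cut(scores, breaks = c(-Inf, b, Inf), labels = paste0("Q", 1:4),
             right = TRUE)
  attr(lab, "boundaries") <- b
  lab
}

#' Add an OBS quartile column to a data frame
#'
#' @param data Data frame containing the score column.
#' @param score Name of the score column (default `"obs_total"`).
#' @param name Name of the new quartile column.
#' @return `data` with the added quartile factor column; the quartile
#'   boundaries are stored in that column's `boundaries` attribute.
#' @export
add_obs_quartile <- function(data, score = "obs_total",
                             name = paste0(score, "_q")) {
  if (!score %in% names(data)) {
    stop("score column '", score, "' not found", call. = FALSE)
  }
  data[[name]] <- assign_quartiles(data[[score]])
  data
}

#' Write / read a fitted scoring table
#'
#' Serializes sex-stratified tertile cutpoints to a tab-separated file
#' (columns `component`, `sex`, `t1`, `t2`) for audit and reuse.
#'
#' @param table An `oxb_scoring_table`.
#' @param path Output (or input) file path.
#' @return `write_scoring_table()` returns `path` invisibly;
#'   `read_scoring_table()` returns the scoring tibble.
#' @export
write_scoring_table <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path)
  invisible(path)
}

#' @rdname write_scoring_table
#' @export
read_scoring_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("component", "sex", "t1", "t2") %in% names(out)),
            all(out$t1 <= out$t2))
  class(out) <- c("oxb_scoring_table", class(out))
  out
}
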