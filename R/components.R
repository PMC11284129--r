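#' Default oxidative balance score component table
#'
#' The oxidative balance score (OBS) sums 0--2 points over 20 diet and
#' lifestyle components: 16 dietary nutrient intakes and 4 lifestyle
#' variables, of which 5 are pro-oxidants and 15 antioxidants. Antioxidant
#' components score ascending with their sex-specific tertile (0, 1, 2) and
#' pro-oxidants descending (2, 1, 0); alcohol uses a dedicated three-category
#' rule (see [score_alcohol()]) instead of tertiles.
#'
#' The default table can be replaced by an edited copy (see
#' [read_components()]), e.g. to substitute alpha- or beta-carotene for total
#' carotene, as long as it still validates.
#'
#' @return A tibble with one row per component and columns `component`,
#'   `class` (`"dietary"` or `"lifestyle"`), `polarity` (`"antioxidant"` or
#'   `"prooxidant"`) and `rule` (`"tertile"` or `"alcohol"`).
#' @examples
#' obs_components()
#' @export
obs_components <- function() {
  spec <- tibble::tribble(
    ~component,          ~class,      ~polarity,     ~rule,
    "fiber",             "dietary",   "antioxidant", "tertile",
    "carotene",          "dietary",   "antioxidant", "tertile",
    "riboflavin",        "dietary",   "antioxidant", "tertile",
    "niacin",            "dietary",   "antioxidant", "tertile",
    "vitamin_b6",        "dietary",   "antioxidant", "tertile",
    "folate",            "dietary",   "antioxidant", "tertile",
    "vitamin_b12",       "dietary",   "antioxidant", "tertile",
    "vitamin_c",         "dietary",   "antioxidant", "tertile",
    "vitamin_e",         "dietary",   "antioxidant", "tertile",
    "calcium",           "dietary",   "antioxidant", "tertile",
    "magnesium",         "dietary",   "antioxidant", "tertile",
    "zinc",              "dietary",   "antioxidant", "tertile",
    "copper",            "dietary",   "antioxidant", "tertile",
    "selenium",          "dietary",   "antioxidant", "tertile",
    "total_fat",         "dietary",   "prooxidant",  "tertile",
    "iron",              "dietary",   "prooxidant",  "tertile",
    "physical_activity", "lifestyle", "antioxidant", "tertile",
    "bmi",               "lifestyle", "prooxidant",  "tertile",
    "cotinine",          "lifestyle", "prooxidant",  "tertile",
    "alcohol",           "lifestyle", "prooxidant",  "alcohol"
  )
  validate_components(spec)
}

#' Validate a component table
#'
#' Checks the structural invariants of an OBS component table: 20 uniquely
#' named components split 16 dietary / 4 lifestyle, 5 pro-oxidants versus 15
#' antioxidants, and exactly one alcohol-rule component which must be a
#' lifestyle pro-oxidant.
#'
#' @param spec A data frame with columns `component`, `class`, `polarity`,
#'   `rule`.
#' @return The validated table, invisibly coerced to a tibble.
#' @export
validate_components <- function(spec) {
  spec <- tibble::as_tibble(spec)
  need <- c("component", "class", "polarity", "rule")
  if (!all(need %in% names(spec))) {
    stop("component table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(spec$component)) {
    stop("component names must be unique", call. = FALSE)
  }
  if (!all(spec$class %in% c("dietary", "lifestyle"))) {
    stop("component class must be 'dietary' or 'lifestyle'", call. = FALSE)
  }
  if (!all(spec$polarity %in% c("antioxidant", "prooxidant"))) {
    stop("component polarity must be 'antioxidant' or 'prooxidant'",
         call. = FALSE)
  }
  if (!all(spec$rule %in% c("tertile", "alcohol"))) {
    stop("component rule must be 'tertile' or 'alcohol'", call. = FALSE)
  }
  if (nrow(spec) != 20L || sum(spec$class == "dietary") != 16L ||
      sum(spec$class == "lifestyle") != 4L) {
    stop("component table must have 20 components: 16 dietary, 4 lifestyle",
         call. = FALSE)
  }
  if (sum(spec$polarity == "prooxidant") != 5L) {
    stop("component table must have exactly 5 pro-oxidants (and 15 antioxidants)",
         call. = FALSE)
  }
  alc <- spec[spec$rule == "alcohol", ]
  if (nrow(alc) != 1L || alc$class != "lifestyle" ||
      alc$polarity != "prooxidant") {
    stop("exactly one component must use the alcohol rule, and it must be a ",
         "lifestyle pro-oxidant", call. = FALSE)
  }
  spec
}

#' Read a component table from a delimited file
#'
#' @param path Path to a CSV file with columns `component`, `class`,
#'   `polarity`, `rule`.
#' @return A validated component tibble.
#' @export
read_components <- function(path) {
  spec <- readr::read_csv(path, show_col_types = FALSE)
  validate_components(spec)
}
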