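#' Read an NHANES SAS transport (XPT) file with column mapping
#'
#' Thin adapter over [foreign::read.xport()] for use with real NHANES
#' release files: reads the transport file and renames survey variables to
#' the column names the rest of the package expects (e.g. `RIAGENDR` to
#' `sex`). The mapping is a named character vector
#' `c(new_name = "XPT_NAME")`; unmapped columns are kept with lower-cased
#' names. Value recodings (such as numeric sex codes to
#' `"male"`/`"female"`) are the caller's responsibility since NHANES code
#' books vary by cycle.
#'
#' @param path Path to a `.xpt` SAS transport file.
#' @param mapping Named character vector mapping package column names to
#'   XPT variable names; `NULL` keeps lower-cased originals.
#' @return A tibble.
#' @export
read_nhanes_xpt <- function(path, mapping = NULL) {
  if (!requireNamespace("foreign", quietly = TRUE)) {
    stop("the 'foreign' package is required to read XPT files",
         call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- foreign::read.xport(path)
  apply_column_mapping(raw, mapping)
}

# Rename columns per a c(new = "OLD") mapping; error on unknown sources.
apply_column_mapping <- function(data, mapping = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(mapping)) {
    names(data) <- tolower(names(data))
    return(data)
  }
  if (is.null(names(mapping)) || any(names(mapping) == "")) {
    stop("mapping must be a fully named character vector c(new = 'OLD')",
         call. = FALSE)
  }
  missing_src <- setdiff(unname(mapping), names(data))
  if (length(missing_src)) {
    stop("mapped variable(s) absent from file: ",
         paste(missing_src, collapse = ", "), call. = FALSE)
  }
  idx <- match(unname(mapping), names(data))
  names(data)[idx] <- names(mapping)
  names(data)[-idx] <- tolower(names(data)[-idx])
  data
}
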