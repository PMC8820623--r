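#' @importFrom rlang .data abort warn .env
#' @importFrom stats sd median quantile rnorm runif rlnorm rbinom rpois rgamma
#'   rbeta pnorm qnorm setNames complete.cases
NULL

# Season levels, in within-year order used throughout the package.
SEASONS <- c("autumn", "winter", "spring", "summer")

# The ten scorable MDD-W food-group codes (stable order).
MDDW_GROUPS <- c(
  "GRAINS_ROOTS_TUBERS", "PULSES", "NUTS_SEEDS", "DAIRY",
  "MEAT_POULTRY_FISH", "EGGS", "DARK_GREEN_LEAFY", "VITA_FRUITS_VEG",
  "OTHER_VEG", "OTHER_FRUITS"
)

# Column names used for the group indicators in recall tables (lowercase
# counterparts of MDDW_GROUPS, same order).
GROUP_COLS <- tolower(MDDW_GROUPS)

ZONES <- c("cool_semiarid_N", "upper_arid_temperate", "upper_arid_mild_E",
           "lower_arid_mild_S")

EDUCATION_LEVELS <- c("none", "primary", "secondary", "superior")

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' The ten scorable MDD-W food groups
#'
#' Returns the codes of the ten food groups that enter the women's dietary
#' diversity score (WDDS-10) and the group-based production indices. Olive
#' oil and other unclassified products never count towards these scores.
#'
#' @return Character vector of length 10.
#' @export
#' @examples
#' mddw_food_groups()
mddw_food_groups <- function() MDDW_GROUPS

#' Agro-climatic zones of the study region
#'
#' The four zones used both by the synthetic generator and as excluded
#' instruments (three dummies against the modal temperate zone).
#'
#' @return Character vector of length 4.
#' @export
climate_zones <- function() ZONES
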