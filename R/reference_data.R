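#' Reference product catalogue
#'
#' The 29 crop and animal products recorded in the farm survey, with their
#' mapping onto the ten MDD-W food groups. Five products (garlic, honey, hot
#' pepper, olive oil, table olive) carry the sentinel group `UNCLASSIFIED`
#' and are excluded from group-based scores (GPDI, GSDI, WDDS-10), though
#' they do count towards the plain product count (PDI) and the nutritional
#' functional diversity score.
#'
#' @return A tibble with columns `product_id`, `name`, `group` (29 rows).
#' @export
#' @examples
#' product_catalogue()
product_catalogue <- function() {
  path <- system.file("extdata", "products.csv", package = "agridiet",
                      mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  valid <- c(MDDW_GROUPS, "UNCLASSIFIED")
  bad <- setdiff(unique(out$group), valid)
  if (length(bad) > 0) abort(paste("unknown food group in catalogue:", bad))
  out
}

#' Product-nutrient fixture and reference intakes
#'
#' Loads the bundled synthetic 29 x 18 product-nutrient matrix (per edible
#' portion; the composition values are synthetic stand-ins generated from
#' food-group archetypes, not measured values) together with the 18 daily
#' reference intakes for adult women used to rescale nutrient columns.
#'
#' @param nutrients_path,rni_path Optional paths overriding the bundled
#'   fixture files (same CSV layout).
#' @return A list with elements `nutrients` (numeric matrix, product ids as
#'   rownames) and `rni` (named numeric vector, same column order).
#' @export
#' @examples
#' fx <- load_nutrient_fixture()
#' dim(fx$nutrients)
load_nutrient_fixture <- function(nutrients_path = NULL, rni_path = NULL) {
  nutrients_path <- nutrients_path %||%
    system.file("extdata", "synthetic_nutrients.csv", package = "agridiet",
                mustWork = TRUE)
  rni_path <- rni_path %||%
    system.file("extdata", "who_rni.csv", package = "agridiet",
                mustWork = TRUE)

  nut <- readr::read_csv(nutrients_path, show_col_types = FALSE)
  rni <- readr::read_csv(rni_path, show_col_types = FALSE)
  assert_cols(nut, "product_id", "nutrient fixture")
  assert_cols(rni, c("nutrient", "rni"), "reference-intake fixture")

  catalogue <- product_catalogue()
  if (!setequal(nut$product_id, catalogue$product_id)) {
    abort("nutrient fixture rows do not match the 29-product catalogue")
  }
  nut <- nut[match(catalogue$product_id, nut$product_id), ]

  mat <- as.matrix(nut[, setdiff(names(nut), "product_id")])
  rownames(mat) <- nut$product_id
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1, ]
    abort(sprintf("nutrient fixture has a missing cell at row '%s', column '%s'",
                  rownames(mat)[idx[1]], colnames(mat)[idx[2]]))
  }
  if (any(mat < 0)) {
    idx <- which(mat < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("nutrient fixture has a negative cell at row '%s', column '%s'",
                  rownames(mat)[idx[1]], colnames(mat)[idx[2]]))
  }
  if (!identical(colnames(mat), rni$nutrient)) {
    abort("reference-intake rows must match nutrient columns (same names, same order)")
  }
  if (any(rni$rni <= 0)) {
    abort(sprintf("non-positive reference intake for nutrient '%s'",
                  rni$nutrient[which(rni$rni <= 0)[1]]))
  }
  list(nutrients = mat, rni = setNames(rni$rni, rni$nutrient))
}

#' Stock-Yogo weak-instrument critical values
#'
#' Critical values for the first-stage Cragg-Donald F statistic, transcribed
#' from the published Stock-Yogo tables for one endogenous regressor.
#' `stock_yogo_table()` returns the full embedded transcription;
#' `stock_yogo_critical_value()` looks up a single cell and signals a
#' condition of class `agridiet_not_tabulated` for cells outside the
#' published tables (no interpolation is ever attempted). Relative-bias
#' criteria require at least two overidentifying restrictions
#' (`n_excl >= n_endog + 2`), which is why TSLS bias cells below three
#' instruments are not tabulated.
#'
#' @param estimator `"LIML"` (default) or `"TSLS"`.
#' @param criterion One of `"size10"`, `"size15"`, `"size20"`, `"size25"`
#'   (maximal Wald-test size) or `"bias5"`, `"bias10"`, `"bias20"`,
#'   `"bias30"` (maximal relative bias, TSLS only).
#' @param n_endog Number of endogenous regressors (only 1 is tabulated here).
#' @param n_excl Number of excluded instruments.
#' @return A positive scalar critical value.
#' @export
#' @examples
#' stock_yogo_critical_value("LIML", "size10", 1, 4)
stock_yogo_critical_value <- function(estimator = c("LIML", "TSLS"),
                                      criterion = "size10",
                                      n_endog = 1, n_excl = 1) {
  estimator <- match.arg(estimator)
  tab <- stock_yogo_table()
  hit <- tab[tab$estimator == estimator & tab$criterion == criterion &
               tab$n_endog == n_endog & tab$n_excl == n_excl, ]
  if (nrow(hit) != 1) {
    abort(
      sprintf("Stock-Yogo critical value not tabulated for (%s, %s, n_endog=%d, n_excl=%d)",
              estimator, criterion, n_endog, n_excl),
      class = "agridiet_not_tabulated"
    )
  }
  hit$critical_value
}

#' @rdname stock_yogo_critical_value
#' @export
stock_yogo_table <- function() {
  path <- system.file("extdata", "stock_yogo.csv", package = "agridiet",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    estimator = "c", criterion = "c",
                    n_endog = "i", n_excl = "i", critical_value = "d"
                  ))
}
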