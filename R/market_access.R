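#' Market Diversity Index (Shannon entropy)
#'
#' `shannon_index()` computes `-sum(p * log(p))` (natural log, with
#' `0 * log(0) = 0`) for one proportion vector. `mdi()` applies it to a
#' market table: one row per market with `market_id`, `lat`, `lon` and one
#' numeric proportion column per crop or animal species sold (every column
#' other than those three is treated as a species share). Proportions must
#' be non-negative and sum to one per market.
#'
#' @param p Numeric vector of proportions.
#' @param markets Market table as described above.
#' @param tol Tolerance on the row sums (default `1e-9`).
#' @return `shannon_index()`: a scalar; `mdi()`: tibble `market_id`, `mdi`.
#' @export
#' @examples
#' shannon_index(rep(1 / 4, 4))  # log(4)
shannon_index <- function(p) {
  if (any(p < 0)) abort("proportions must be non-negative")
  p <- p[p > 0]
  -sum(p * log(p))
}

species_cols <- function(markets) {
  setdiff(names(markets), c("market_id", "lat", "lon"))
}

#' @rdname shannon_index
#' @export
mdi <- function(markets, tol = 1e-9) {
  assert_cols(markets, "market_id", "market table")
  sp <- species_cols(markets)
  if (length(sp) == 0) abort("market table has no species proportion columns")
  mat <- as.matrix(markets[, sp])
  sums <- rowSums(mat)
  bad <- abs(sums - 1) > tol
  if (any(bad)) {
    abort(sprintf("species proportions for market '%s' sum to %.12f, not 1",
                  markets$market_id[which(bad)[1]], sums[which(bad)[1]]))
  }
  tibble::tibble(market_id = markets$market_id,
                 mdi = apply(mat, 1, shannon_index))
}

#' Crow-flies distance between GPS points
#'
#' Great-circle (haversine) distance in kilometres; a planar
#' (equirectangular) mode is available for small-area checks, where it
#' agrees with the haversine to well under 0.1% at the ~100 km scale of a
#' governorate.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorized).
#' @param method `"haversine"` (default) or `"planar"`.
#' @return Numeric vector of distances in km.
#' @export
#' @examples
#' distance_km(35, 9.5, 36, 9.5)  # ~111.2 km per degree of latitude
distance_km <- function(lat1, lon1, lat2, lon2,
                        method = c("haversine", "planar")) {
  method <- match.arg(method)
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    abort("coordinates out of range (|lat| <= 90, |lon| <= 180)")
  }
  if (method == "haversine") {
    geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                             r = 6371000) / 1000
  } else {
    km_per_deg <- pi * 6371 / 180
    dx <- (lon2 - lon1) * km_per_deg * cos((lat1 + lat2) / 2 * pi / 180)
    dy <- (lat2 - lat1) * km_per_deg
    sqrt(dx^2 + dy^2)
  }
}

#' Household access to market diversity (HAMDI)
#'
#' Assigns each household its `k` (default two) crow-flies-nearest markets
#' under the exclusive-frequentation hypothesis, and returns the mean of
#' their market diversity indices plus the distance to the single nearest
#' market. Distance ties at the cut-off rank are broken by the lower
#' `market_id` so results are reproducible.
#'
#' @param households Table with `household_id`, `lat`, `lon`.
#' @param markets Market table (see [mdi()]).
#' @param k Number of nearest markets averaged (default 2).
#' @param method Distance method passed to [distance_km()].
#' @return Tibble `household_id`, `hamdi`, `nearest_market_id`,
#'   `second_market_id` (when `k >= 2`), `nearest_km`.
#' @export
hamdi <- function(households, markets, k = 2,
                  method = c("haversine", "planar")) {
  method <- match.arg(method)
  assert_cols(households, c("household_id", "lat", "lon"), "household table")
  assert_cols(markets, c("market_id", "lat", "lon"), "market table")
  if (nrow(markets) < k) {
    abort(sprintf("need at least %d markets, got %d", k, nrow(markets)))
  }
  mdis <- mdi(markets)

  n <- nrow(households)
  m <- nrow(markets)
  D <- matrix(distance_km(households$lat[rep(seq_len(n), m)],
                          households$lon[rep(seq_len(n), m)],
                          markets$lat[rep(seq_len(m), each = n)],
                          markets$lon[rep(seq_len(m), each = n)],
                          method = method),
              nrow = n, ncol = m)

  sel <- t(apply(D, 1, function(d) order(d, markets$market_id)[seq_len(k)]))
  ids1 <- markets$market_id[sel[, 1]]
  tibble::tibble(
    household_id = households$household_id,
    hamdi = rowMeans(matrix(mdis$mdi[sel], ncol = k)),
    nearest_market_id = ids1,
    second_market_id = if (k >= 2) markets$market_id[sel[, 2]] else NA,
    nearest_km = D[cbind(seq_len(nrow(D)), sel[, 1])]
  )
}
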