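#' Women's dietary diversity scoring
#'
#' These functions score 24-hour recall records on the ten MDD-W food
#' groups. A recall table has one row per woman and season with a 0/1
#' indicator column per scorable group (lowercase group codes, see
#' [mddw_food_groups()]) plus an `olive_oil` indicator. Olive oil never
#' counts towards the WDDS-10 because it carries no essential
#' micronutrients; it is tracked separately for the consumption score.
#'
#' `wdds10()` returns the seasonal score (count of groups consumed, 0-10).
#' `annual_wdds()` averages the four seasonal scores; women without exactly
#' one recall per season are rejected, mirroring the study design in which
#' women with fewer than the required interviews are excluded rather than
#' imputed. `mddw_flag()` flags women whose annual score reaches five
#' groups. `consumption_scores()` returns, per woman and food group (and
#' olive oil), the fraction of the four recalls in which the group was
#' consumed, taking values 0, 0.25, 0.5, 0.75 or 1.
#'
#' @param recalls A data frame of recall records: `woman_id`, `season`
#'   (one of `"autumn"`, `"winter"`, `"spring"`, `"summer"`), one 0/1
#'   column per scorable group, and `olive_oil`.
#' @return A tibble; see the individual descriptions.
#' @name diet_scores
NULL

validate_recalls <- function(recalls, require_complete = FALSE) {
  assert_cols(recalls, c("woman_id", "season", GROUP_COLS, "olive_oil"),
              "recall table")
  bad <- setdiff(unique(recalls$season), SEASONS)
  if (length(bad) > 0) {
    abort(paste("unknown season value(s):", paste(bad, collapse = ", ")))
  }
  vals <- as.matrix(recalls[, c(GROUP_COLS, "olive_oil")])
  if (!all(vals %in% c(0, 1))) {
    abort("group indicator columns must be 0/1")
  }
  dup <- recalls |>
    dplyr::count(.data$woman_id, .data$season) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("more than one recall for woman '%s' in season '%s'",
                  dup$woman_id[1], dup$season[1]))
  }
  if (require_complete) {
    per_woman <- recalls |> dplyr::count(.data$woman_id)
    incomplete <- per_woman$woman_id[per_woman$n != 4]
    if (length(incomplete) > 0) {
      abort(sprintf(
        "woman '%s' does not have exactly one recall per season (women with incomplete recall sets are excluded, not imputed)",
        incomplete[1]))
    }
  }
  invisible(recalls)
}

#' @rdname diet_scores
#' @export
#' @examples
#' r <- tibble::tibble(
#'   woman_id = "w1", season = c("autumn", "winter", "spring", "summer"),
#'   grains_roots_tubers = 1, pulses = c(1, 0, 1, 0), nuts_seeds = 0,
#'   dairy = 1, meat_poultry_fish = c(1, 1, 1, 0), eggs = 0,
#'   dark_green_leafy = 0, vita_fruits_veg = 1, other_veg = 1,
#'   other_fruits = c(0, 0, 1, 1), olive_oil = 1
#' )
#' wdds10(r)
#' annual_wdds(r)
wdds10 <- function(recalls) {
  validate_recalls(recalls)
  recalls |>
    dplyr::mutate(wdds10 = rowSums(dplyr::pick(dplyr::all_of(GROUP_COLS)))) |>
    dplyr::select("woman_id", "season", "wdds10") |>
    tibble::as_tibble()
}

#' @rdname diet_scores
#' @export
annual_wdds <- function(recalls) {
  validate_recalls(recalls, require_complete = TRUE)
  wdds10(recalls) |>
    dplyr::summarise(annual_wdds = mean(.data$wdds10), .by = "woman_id")
}

#' @rdname diet_scores
#' @param per_season If `TRUE`, `mddw_flag()` also returns a seasonal flag
#'   per recall (score of five or more groups in that recall).
#' @export
mddw_flag <- function(recalls, per_season = FALSE) {
  if (per_season) {
    return(wdds10(recalls) |> dplyr::mutate(mddw = .data$wdds10 >= 5))
  }
  annual_wdds(recalls) |> dplyr::mutate(mddw = .data$annual_wdds >= 5)
}

#' @rdname diet_scores
#' @export
consumption_scores <- function(recalls) {
  validate_recalls(recalls, require_complete = TRUE)
  recalls |>
    tidyr::pivot_longer(dplyr::all_of(c(GROUP_COLS, "olive_oil")),
                        names_to = "group", values_to = "consumed") |>
    dplyr::summarise(score = sum(.data$consumed) / 4,
                     .by = c("woman_id", "group")) |>
    dplyr::mutate(group = factor(.data$group,
                                 levels = c(GROUP_COLS, "olive_oil")))
}

#' Seasonal summaries of women's diets
#'
#' `seasonal_consumers()` gives the percentage of women consuming each food
#' group (and olive oil) in each season; `seasonal_wdds()` gives the mean
#' and SD of the seasonal WDDS-10; `seasonal_summary()` returns both.
#'
#' @inheritParams diet_scores
#' @return Tibbles (a list of the two for `seasonal_summary()`).
#' @export
seasonal_consumers <- function(recalls) {
  validate_recalls(recalls)
  recalls |>
    tidyr::pivot_longer(dplyr::all_of(c(GROUP_COLS, "olive_oil")),
                        names_to = "group", values_to = "consumed") |>
    dplyr::summarise(pct_consumers = 100 * mean(.data$consumed),
                     .by = c("season", "group")) |>
    dplyr::mutate(season = factor(.data$season, levels = SEASONS),
                  group = factor(.data$group,
                                 levels = c(GROUP_COLS, "olive_oil"))) |>
    dplyr::arrange(.data$season, .data$group)
}

#' @rdname seasonal_consumers
#' @export
seasonal_wdds <- function(recalls) {
  wdds10(recalls) |>
    dplyr::summarise(mean_wdds = mean(.data$wdds10),
                     sd_wdds = sd(.data$wdds10),
                     n = dplyr::n(), .by = "season") |>
    dplyr::mutate(season = factor(.data$season, levels = SEASONS)) |>
    dplyr::arrange(.data$season)
}

#' @rdname seasonal_consumers
#' @export
seasonal_summary <- function(recalls) {
  list(consumers = seasonal_consumers(recalls), wdds = seasonal_wdds(recalls))
}

#' Seasonal variation tests
#'
#' Tests whether food-group consumption and the WDDS-10 vary across the
#' four seasons. Per group, a generalized Cochran-Mantel-Haenszel test of
#' season x consumption association stratified by woman is run
#' ([stats::mantelhaen.test()]); women who consumed the group in all four
#' seasons or in none are uninformative strata and are dropped (their count
#' is reported). Seasonal WDDS-10 scores are compared pairwise with the
#' paired Wilcoxon signed-rank test.
#'
#' @inheritParams diet_scores
#' @return A list with tibbles `cmh` (one row per group: statistic, df,
#'   p_value, n_informative, n_dropped) and `wilcoxon` (one row per season
#'   pair).
#' @export
seasonal_tests <- function(recalls) {
  validate_recalls(recalls, require_complete = TRUE)

  cmh <- purrr::map_dfr(c(GROUP_COLS, "olive_oil"), function(g) {
    wide <- recalls |>
      dplyr::select("woman_id", "season", dplyr::all_of(g)) |>
      tidyr::pivot_wider(names_from = "season", values_from = dplyr::all_of(g))
    mat <- as.matrix(wide[, SEASONS])
    informative <- rowSums(mat) %in% 1:3
    n_drop <- sum(!informative)
    mat <- mat[informative, , drop = FALSE]
    if (nrow(mat) == 0) {
      return(tibble::tibble(group = g, statistic = 0, df = 3, p_value = 1,
                            n_informative = 0L, n_dropped = n_drop))
    }
    arr <- array(0, dim = c(2, 4, nrow(mat)),
                 dimnames = list(consumed = c("no", "yes"), season = SEASONS,
                                 woman = NULL))
    arr[2, , ] <- t(mat)
    arr[1, , ] <- 1 - t(mat)
    ht <- stats::mantelhaen.test(arr)
    tibble::tibble(group = g, statistic = unname(ht$statistic),
                   df = unname(ht$parameter), p_value = ht$p.value,
                   n_informative = nrow(mat), n_dropped = n_drop)
  })

  scores <- wdds10(recalls) |>
    tidyr::pivot_wider(names_from = "season", values_from = "wdds10")
  pairs <- utils::combn(SEASONS, 2, simplify = FALSE)
  wilcoxon <- purrr::map_dfr(pairs, function(p) {
    x <- scores[[p[1]]]
    y <- scores[[p[2]]]
    if (all(x == y)) {
      return(tibble::tibble(season1 = p[1], season2 = p[2],
                            statistic = NA_real_, p_value = 1))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
    tibble::tibble(season1 = p[1], season2 = p[2],
                   statistic = unname(wt$statistic), p_value = wt$p.value)
  })

  list(cmh = cmh, wilcoxon = wilcoxon)
}

#' Consumption scores by on-farm production of the group
#'
#' For each of the ten food groups and olive oil, compares the annual
#' consumption score of women whose farm produces the group against women
#' whose farm does not (the own-production / consumption link). Groups are
#' compared with the Mann-Whitney rank-sum test; because the source tables
#' for this kind of comparison are sometimes labelled "Wilcoxon
#' signed-rank" even for independent groups, the (unpaired) signed-rank
#' reading is not meaningful and the rank-sum p-value is the headline;
#' both column names make the choice explicit.
#'
#' @inheritParams diet_scores
#' @param production Long production table (`farm_id`, `product_id`, ...).
#' @param household_of_woman A two-column table `woman_id`, `farm_id`
#'   linking each woman to her farm.
#' @return A tibble with one row per group: percent of farms producing it,
#'   mean/SD consumption score in producing and non-producing groups, and
#'   the rank-sum p-value (`NA` when one side is empty).
#' @export
consumption_by_production <- function(recalls, production, household_of_woman) {
  assert_cols(household_of_woman, c("woman_id", "farm_id"), "woman-farm link")
  scores <- consumption_scores(recalls)
  catalogue <- product_catalogue()

  produced <- production |>
    dplyr::inner_join(catalogue, by = "product_id") |>
    dplyr::mutate(group = ifelse(.data$product_id == "olive_oil",
                                 "olive_oil", tolower(.data$group))) |>
    dplyr::filter(.data$group %in% c(GROUP_COLS, "olive_oil")) |>
    dplyr::distinct(.data$farm_id, .data$group) |>
    dplyr::mutate(produces = TRUE)

  scores |>
    dplyr::mutate(group = as.character(.data$group)) |>
    dplyr::inner_join(household_of_woman, by = "woman_id") |>
    dplyr::left_join(produced, by = c("farm_id", "group")) |>
    dplyr::mutate(produces = !is.na(.data$produces)) |>
    dplyr::summarise(
      pct_producing = 100 * mean(.data$produces),
      mean_producing = mean(.data$score[.data$produces]),
      sd_producing = sd(.data$score[.data$produces]),
      mean_not_producing = mean(.data$score[!.data$produces]),
      sd_not_producing = sd(.data$score[!.data$produces]),
      p_ranksum = if (any(.data$produces) && any(!.data$produces)) {
        suppressWarnings(stats::wilcox.test(
          .data$score[.data$produces],
          .data$score[!.data$produces])$p.value)
      } else NA_real_,
      .by = "group"
    ) |>
    dplyr::mutate(group = factor(.data$group,
                                 levels = c(GROUP_COLS, "olive_oil"))) |>
    dplyr::arrange(.data$group)
}
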