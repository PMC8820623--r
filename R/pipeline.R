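PD_INDICES <- c("pdi", "sdi", "gpdi", "gsdi", "nfd")

WOMAN_EXOG <- c("age", "educ_primary", "educ_secondary", "educ_superior",
                "domestic_hours", "responsibility", "nonfarm_income",
                "offfarm_ag_income", "onfarm_participation")
HH_EXOG <- c("head_age", "hh_size", "wealth_score")
MARKET_EXOG <- c("hamdi", "nearest_km")

#' Included exogenous regressors and excluded instruments of the IV design
#'
#' Column names used by [run_models()] in the full outcome equation:
#' woman block (age, three education dummies against no schooling,
#' domestic work-time, expenditure responsibility, income and on-farm
#' activity flags), household block (head age, household size, wealth
#' score) and market block (HAMDI, distance to the nearest market).
#' Excluded instruments are the three climate-zone dummies (reference:
#' the modal temperate zone) plus farm seniority.
#'
#' @return Character vectors.
#' @export
design_exogenous <- function() c(WOMAN_EXOG, HH_EXOG, MARKET_EXOG)

#' @rdname design_exogenous
#' @export
design_instruments <- function() {
  c(paste0("zone_", setdiff(ZONES, "upper_arid_temperate")), "seniority_years")
}

# Drop design columns that carry no usable variation in this sample:
# constants (they duplicate the intercept) and binary flags with a single
# minority observation (a singleton dummy absorbs its observation, hat
# value 1, which degenerates the robust covariance and Hansen J weights).
active_columns <- function(frame, cols) {
  keep <- vapply(cols, function(cl) {
    x <- frame[[cl]]
    if (sd(x) == 0) return(FALSE)
    if (all(x %in% c(0, 1))) return(min(sum(x == 1), sum(x == 0)) >= 2)
    TRUE
  }, logical(1))
  if (any(!keep)) {
    warn(paste("dropping constant or singleton column(s) from the design:",
               paste(cols[!keep], collapse = ", ")))
  }
  cols[keep]
}

#' Assemble the per-woman analysis frame
#'
#' Joins the scored outcome (annual WDDS-10), the requested
#' production-diversity indices, woman/household covariates, the market
#' access block and the instrument columns into one row per woman, ready
#' for [fit_ols()] / [fit_liml()].
#'
#' @param dataset An `agridiet_survey` (or list with the same tables).
#' @param indices Which production indices to compute (default all five).
#' @param dendro Dendrogram for the NFD score; bundled reference
#'   dendrogram by default (only built when `"nfd"` is requested).
#' @return A tibble with one row per woman.
#' @export
build_analysis_frame <- function(dataset, indices = PD_INDICES,
                                 dendro = NULL) {
  indices <- match.arg(indices, PD_INDICES, several.ok = TRUE)

  scores <- annual_wdds(dataset$recalls)

  idx <- pdi(dataset$production)
  if ("sdi" %in% indices) {
    idx <- dplyr::left_join(idx, sdi(dataset$production), by = "farm_id")
  }
  if ("gpdi" %in% indices) {
    idx <- dplyr::left_join(idx, gpdi(dataset$production), by = "farm_id")
  }
  if ("gsdi" %in% indices) {
    idx <- dplyr::left_join(idx, gsdi_safe(dataset$production), by = "farm_id")
  }
  if ("nfd" %in% indices) {
    dendro <- dendro %||% reference_dendrogram()
    idx <- dplyr::left_join(idx, nfd(dataset$production, dendro),
                            by = "farm_id")
  }

  access <- hamdi(dataset$households, dataset$markets)

  edu <- dataset$women |>
    dplyr::transmute(
      .data$woman_id,
      educ_primary = as.integer(.data$education == "primary"),
      educ_secondary = as.integer(.data$education == "secondary"),
      educ_superior = as.integer(.data$education == "superior"))

  zones <- dataset$farms |>
    dplyr::transmute(
      .data$household_id, .data$farm_id, .data$seniority_years,
      zone_cool_semiarid_N = as.integer(.data$climate_zone == "cool_semiarid_N"),
      zone_upper_arid_mild_E = as.integer(.data$climate_zone == "upper_arid_mild_E"),
      zone_lower_arid_mild_S = as.integer(.data$climate_zone == "lower_arid_mild_S"))

  dataset$women |>
    dplyr::select("woman_id", "household_id", "age", "domestic_hours",
                  "responsibility", "nonfarm_income", "offfarm_ag_income",
                  "onfarm_participation") |>
    dplyr::inner_join(scores, by = "woman_id") |>
    dplyr::inner_join(edu, by = "woman_id") |>
    dplyr::inner_join(
      dplyr::select(dataset$households, "household_id", "hh_size",
                    "head_age", "wealth_score"),
      by = "household_id") |>
    dplyr::inner_join(zones, by = "household_id") |>
    dplyr::inner_join(idx, by = "farm_id") |>
    dplyr::inner_join(
      dplyr::select(access, "household_id", "hamdi", "nearest_km"),
      by = "household_id")
}

#' Fit the descriptive and instrumental-variable model tables
#'
#' For each production-diversity index, fits (i) the simple OLS of the
#' annual WDDS-10 on the index alone and (ii) the full LIML model with
#' the woman, household and market covariate blocks, instrumenting the
#' index with the climate-zone dummies and farm seniority. Also returns
#' the descriptive consumption-by-production comparison and the
#' Kruskal-Wallis comparison of the annual WDDS-10 across farm
#' orientation classes.
#'
#' @param dataset An `agridiet_survey`.
#' @param indices Production indices to model (default all five).
#' @param dendro Optional dendrogram for NFD.
#' @param sy_criterion Stock-Yogo criterion reported with each IV fit.
#' @return List with tibbles `simple` (per-index OLS), `iv_coefficients`
#'   (long coefficient table), `diagnostics` (per-index kappa, F,
#'   under/over-identification tests, standardized slope), `fits` (the
#'   underlying `agridiet_liml` objects), `consumption` and
#'   `orientation`.
#' @export
run_models <- function(dataset, indices = PD_INDICES, dendro = NULL,
                       sy_criterion = "size10") {
  frame <- build_analysis_frame(dataset, indices = indices, dendro = dendro)
  frame <- frame[complete.cases(frame[, c("annual_wdds", indices)]), ]
  exog <- active_columns(frame, design_exogenous())
  instr <- active_columns(frame, design_instruments())

  simple <- purrr::map_dfr(indices, function(ix) {
    f <- stats::as.formula(paste("annual_wdds ~", ix))
    fit <- fit_ols(f, frame)
    b1 <- unname(fit$coefficients[ix])
    p1 <- unname(fit$p_value[ix])
    tibble::tibble(
      index = ix, beta1 = b1, se = unname(fit$se[ix]), p_value = p1,
      stars = significance_stars(p1),
      std_beta1 = standardized_coefficient(b1, sd(frame[[ix]]),
                                           sd(frame$annual_wdds)),
      beta0 = unname(fit$coefficients["(Intercept)"]),
      beta0_p = unname(fit$p_value["(Intercept)"]))
  })

  fits <- purrr::map(setNames(indices, indices), function(ix) {
    fit_liml(frame, outcome = "annual_wdds", endogenous = ix,
             exogenous = exog, instruments = instr,
             sy_criterion = sy_criterion)
  })

  iv_coefficients <- purrr::imap_dfr(fits, function(fit, ix) {
    tidy(fit) |> dplyr::mutate(index = ix, .before = 1)
  })

  diagnostics <- purrr::imap_dfr(fits, function(fit, ix) {
    tibble::tibble(
      index = ix,
      beta1 = unname(fit$coefficients[ix]),
      se = unname(fit$se[ix]),
      p_value = unname(fit$p_value[ix]),
      stars = significance_stars(unname(fit$p_value[ix])),
      std_beta1 = fit$std_beta1,
      kappa = fit$kappa,
      underid_stat = fit$underid$statistic,
      underid_p = fit$underid$p_value,
      cragg_donald_f = fit$cragg_donald_f,
      stock_yogo = fit$stock_yogo$critical_value,
      sargan_p = fit$overid$sargan_p,
      hansen_j = fit$overid$hansen_j,
      hansen_p = fit$overid$hansen_p,
      overid_df = fit$overid$df)
  })

  consumption <- consumption_by_production(
    dataset$recalls, dataset$production,
    dplyr::inner_join(
      dplyr::select(dataset$women, "woman_id", "household_id"),
      dplyr::select(dataset$farms, "farm_id", "household_id"),
      by = "household_id") |>
      dplyr::select("woman_id", "farm_id"))

  orient <- classify_orientation(dataset$production) |>
    dplyr::inner_join(
      dplyr::select(dataset$farms, "farm_id", "household_id"),
      by = "farm_id") |>
    dplyr::inner_join(
      dplyr::select(dataset$women, "woman_id", "household_id"),
      by = "household_id") |>
    dplyr::inner_join(annual_wdds(dataset$recalls), by = "woman_id")
  kw <- stats::kruskal.test(orient$annual_wdds, orient$orientation)
  orientation <- list(
    summary = orient |>
      dplyr::summarise(n = dplyr::n(), mean_wdds = mean(.data$annual_wdds),
                       sd_wdds = sd(.data$annual_wdds), .by = "orientation"),
    kruskal_statistic = unname(kw$statistic),
    kruskal_p = kw$p.value)

  list(simple = simple, iv_coefficients = iv_coefficients,
       diagnostics = diagnostics, fits = fits,
       consumption = consumption, orientation = orientation,
       frame = frame)
}

#' Descriptive summary of a dataset
#'
#' Long tibble of the headline descriptive statistics of the survey:
#' diet scores, household and farm characteristics, per-group production
#' prevalences and market access.
#'
#' @param dataset An `agridiet_survey`.
#' @param frame Optional precomputed [build_analysis_frame()] output.
#' @return Tibble `variable`, `statistic`, `value`.
#' @export
descriptives <- function(dataset, frame = NULL) {
  frame <- frame %||% build_analysis_frame(dataset)
  med3 <- function(v, x) {
    q <- quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE)
    tibble::tibble(variable = v, statistic = c("median", "q1", "q3"),
                   value = q)
  }
  msd <- function(v, x) {
    tibble::tibble(variable = v, statistic = c("mean", "sd"),
                   value = c(mean(x, na.rm = TRUE), sd(x)))
  }
  produced <- join_groups(dataset$production) |>
    dplyr::filter(.data$group != "UNCLASSIFIED") |>
    dplyr::distinct(.data$farm_id, .data$group)
  n_farms <- nrow(dataset$farms)
  prev <- produced |>
    dplyr::summarise(n = dplyr::n_distinct(.data$farm_id), .by = "group") |>
    dplyr::mutate(variable = paste0("produces_", tolower(.data$group)),
                  statistic = "pct", value = 100 * .data$n / n_farms) |>
    dplyr::select("variable", "statistic", "value")
  olive <- tibble::tibble(
    variable = "produces_olive_oil", statistic = "pct",
    value = 100 * dplyr::n_distinct(
      dataset$production$farm_id[dataset$production$product_id == "olive_oil"]) /
      n_farms)

  dplyr::bind_rows(
    msd("age", frame$age),
    msd("annual_wdds", frame$annual_wdds),
    tibble::tibble(variable = "mddw", statistic = "pct",
                   value = 100 * mean(frame$annual_wdds >= 5)),
    msd("head_age", frame$head_age),
    msd("hh_size", frame$hh_size),
    med3("wealth_score", frame$wealth_score),
    med3("seniority_years", frame$seniority_years),
    med3("pdi", frame$pdi),
    med3("sdi", frame$sdi),
    med3("gpdi", frame$gpdi),
    med3("gsdi", frame$gsdi),
    med3("nfd", frame$nfd),
    prev, olive,
    med3("hamdi", frame$hamdi),
    med3("nearest_km", frame$nearest_km))
}

#' Run the full pipeline and write a reproducible report bundle
#'
#' Simulates a dataset from `config`, scores diets, production and market
#' access, fits the model tables and writes everything (input tables,
#' scores, descriptive and regression tables, diagnostics, and a run
#' manifest with the seed and a config hash) as plain CSV/JSON under
#' `out_dir`. Re-running with the same config produces byte-identical
#' files.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param indices Production indices to model.
#' @return Invisibly, the list returned by [run_models()] plus the
#'   dataset, with `out_dir` attached.
#' @export
run_all <- function(config, out_dir, indices = PD_INDICES) {
  cfg <- validate_sim_config(config)
  dataset <- simulate_survey(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_dataset(dataset, file.path(out_dir, "data"))

  models <- run_models(dataset, indices = indices)
  frame <- models$frame

  readr::write_csv(frame, file.path(out_dir, "analysis_frame.csv"))
  readr::write_csv(descriptives(dataset, frame),
                   file.path(out_dir, "table1.csv"))
  readr::write_csv(models$consumption, file.path(out_dir, "table2.csv"))
  readr::write_csv(models$simple, file.path(out_dir, "table3.csv"))
  readr::write_csv(models$iv_coefficients, file.path(out_dir, "table4.csv"))
  readr::write_csv(models$diagnostics,
                   file.path(out_dir, "diagnostics.csv"))
  readr::write_csv(models$orientation$summary,
                   file.path(out_dir, "orientation.csv"))
  jsonlite::write_json(
    list(diagnostics = models$diagnostics,
         orientation_kruskal_p = models$orientation$kruskal_p),
    file.path(out_dir, "diagnostics.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", pretty = TRUE)
  jsonlite::write_json(
    list(seed = cfg$seed,
         config_hash = digest::digest(unclass(cfg)),
         package_version = as.character(utils::packageVersion("agridiet")),
         files = sort(list.files(out_dir, recursive = TRUE))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)

  out <- c(models, list(dataset = dataset, out_dir = out_dir))
  invisible(out)
}

#' Monte Carlo replication of the estimation study
#'
#' Repeatedly simulates datasets (per-replicate seeds drawn
#' deterministically from the master seed), fits the full-covariate OLS
#' and the LIML IV model for the requested indices, and summarises the
#' slope estimates across replicates with medians (LIML has no finite
#' moments under weak identification, so medians — not means — are the
#' meaningful recovery summary).
#'
#' @param config Base [sim_config()]; its seed is the master seed.
#' @param n_replicates Number of replicates (>= 2).
#' @param indices Production indices to track (default `"pdi"`, the index
#'   whose structural effect the generator controls directly).
#' @return List with `results` (one row per replicate x index x
#'   estimator) and `summary` (median and quartiles of the slope).
#' @export
replicate_study <- function(config, n_replicates, indices = "pdi") {
  if (n_replicates < 2) abort("n_replicates must be >= 2")
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_replicates)

  results <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- rep_seeds[r]
    dataset <- simulate_survey(cfg_r)
    frame <- build_analysis_frame(dataset, indices = indices)
    exog <- active_columns(frame, design_exogenous())
    instr <- active_columns(frame, design_instruments())
    purrr::map_dfr(indices, function(ix) {
      f_ols <- stats::as.formula(paste(
        "annual_wdds ~", ix, "+", paste(exog, collapse = " + ")))
      ols <- fit_ols(f_ols, frame)
      liml <- fit_liml(frame, "annual_wdds", ix, exog, instr)
      tibble::tibble(
        replicate = r, seed = rep_seeds[r], index = ix,
        estimator = c("ols", "liml"),
        beta1 = c(unname(ols$coefficients[ix]),
                  unname(liml$coefficients[ix])),
        se = c(unname(ols$se[ix]), unname(liml$se[ix])),
        cragg_donald_f = c(NA_real_, liml$cragg_donald_f),
        underid_p = c(NA_real_, liml$underid$p_value),
        hansen_p = c(NA_real_, liml$overid$hansen_p),
        kappa = c(NA_real_, liml$kappa))
    })
  })

  summary <- results |>
    dplyr::summarise(
      median_beta1 = median(.data$beta1),
      q1_beta1 = quantile(.data$beta1, 0.25, names = FALSE),
      q3_beta1 = quantile(.data$beta1, 0.75, names = FALSE),
      median_cd_f = median(.data$cragg_donald_f),
      n = dplyr::n(),
      .by = c("index", "estimator"))

  list(results = results, summary = summary,
       true_beta1 = cfg$true_beta1)
}
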