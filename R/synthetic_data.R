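#' Configuration for the synthetic survey generator
#'
#' Builds and validates the parameter list that fully determines a
#' synthetic dataset (given the seed). Defaults emulate the smallholder
#' setting the package targets: 290 one-woman farm households across four
#' agro-climatic zones, 29 candidate products whose per-group production
#' prevalences follow the survey's descriptive margins (livestock on ~81%
#' of farms, olive oil on ~54%, low crop diversification with a median of
#' three products), log-normal production values (median ~1,960 USD/yr)
#' with a U-shaped self-consumption share, four seasonal 24-hour recalls
#' per woman averaging to an annual WDDS-10 near 6.5 with a modest spring
#' peak, and 24 weekly markets whose Shannon diversity gives a household
#' HAMDI near 1.48.
#'
#' Production diversity is endogenous by construction: a latent household
#' confounder raises both the product-count intensity
#' (`loading_on_diversity`) and the diet score (`loading_on_diet`), so OLS
#' overstates the true effect `true_beta1` while instruments (climate
#' zone, farm seniority) identify it.
#'
#' @param seed Integer master seed.
#' @param n_households Number of households (= farms = women).
#' @param true_beta1 Structural effect of the product count (PDI) on the
#'   latent annual WDDS-10.
#' @param confounder_sd SD of the latent confounder.
#' @param loading_on_diversity,loading_on_diet Confounder loadings on the
#'   log production intensity and on the diet score.
#' @param zone_probs Named probabilities of the four climate zones.
#' @param zone_effects Log-intensity shifts of the zones (instrument
#'   strength), same order as [climate_zones()].
#' @param seniority_effect Log-intensity effect per unit of
#'   `log(seniority / 25)`.
#' @param seniority_meanlog,seniority_sdlog Log-normal farm seniority
#'   (median 25 years).
#' @param production_prevalences Named per-group production prevalence
#'   targets (the ten scorable groups) plus per-product prevalences for
#'   the five unclassified products.
#' @param prevalence_calibration Named multipliers on the per-group
#'   inclusion hazards, frozen from the package's one-off moment
#'   calibration (they absorb the gap between the raw thinning model and
#'   the realized prevalence under intensity heterogeneity and
#'   zero-truncation).
#' @param value_meanlog,value_sdlog,value_split_alpha Log-normal total
#'   production value and Dirichlet concentration of its split across
#'   products.
#' @param hh_size_p Success probability of the `1 + Binomial(10, p)`
#'   household size model (mean `1 + 10 p`).
#' @param education_probs Probabilities of the four education levels.
#' @param education_effects,wealth_effect,hh_size_effect Diet-score
#'   effects of education level, latent wealth (per SD) and household
#'   size (per member, centred).
#' @param diet_intercept,diet_noise_sd Intercept and residual SD of the
#'   latent annual diet score (intercept frozen by calibration so the
#'   mean annual WDDS-10 sits at its target).
#' @param spring_priority Probability that leftover quarter-points of the
#'   annual score are allocated in fixed spring-first order (controls the
#'   size of the spring seasonal peak).
#' @param diet_model `"LINEAR"` (annual score drawn, then decomposed into
#'   seasons) or `"BERNOULLI_GROUPS"` (per-group per-season indicators
#'   drawn from logistic propensities).
#' @param recall_correlation Within-woman correlation of seasonal recalls
#'   (`BERNOULLI_GROUPS` mode).
#' @param group_pick_weights Relative weights with which consumed groups
#'   are picked in a recall (LINEAR mode), reflecting which groups
#'   dominate local diets.
#' @param dairy_bonus Multiplier on the dairy pick weight when the farm
#'   itself produces milk (own-production consumption link).
#' @param olive_oil_p Probability a recall reports olive oil.
#' @param market_count,n_species,market_dirichlet Number of weekly
#'   markets, species per market proportion vector, and Dirichlet
#'   concentration of the proportions (controls the Shannon MDI level).
#' @param region_extent_km Side of the square region in which markets and
#'   households are placed uniformly (controls nearest-market distances).
#' @param region_center Named lat/lon of the region centre.
#' @param n_assets Number of binary household asset indicators.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1L,
    n_households = 290L,
    true_beta1 = 0.10,
    confounder_sd = 1,
    loading_on_diversity = 0.25,
    loading_on_diet = 0.35,
    zone_probs = c(cool_semiarid_N = 0.2, upper_arid_temperate = 0.5,
                   upper_arid_mild_E = 0.2, lower_arid_mild_S = 0.1),
    zone_effects = c(cool_semiarid_N = 0.6, upper_arid_temperate = 0,
                     upper_arid_mild_E = 0.4, lower_arid_mild_S = -0.6),
    seniority_effect = 0.7,
    seniority_meanlog = log(25),
    seniority_sdlog = 0.63,
    production_prevalences = c(
      GRAINS_ROOTS_TUBERS = 0.062, PULSES = 0.021, NUTS_SEEDS = 0.069,
      DAIRY = 0.197, MEAT_POULTRY_FISH = 0.814, EGGS = 0.317,
      DARK_GREEN_LEAFY = 0.007, VITA_FRUITS_VEG = 0.038, OTHER_VEG = 0.114,
      OTHER_FRUITS = 0.007, olive_oil = 0.535, table_olive = 0.10,
      garlic = 0.05, hot_pepper = 0.08, honey = 0.03),
    prevalence_calibration = c(
      GRAINS_ROOTS_TUBERS = 1, PULSES = 1, NUTS_SEEDS = 1,
      DAIRY = 1, MEAT_POULTRY_FISH = 1.093, EGGS = 1,
      DARK_GREEN_LEAFY = 1, VITA_FRUITS_VEG = 1, OTHER_VEG = 1,
      OTHER_FRUITS = 1, olive_oil = 1, table_olive = 1,
      garlic = 1, hot_pepper = 1, honey = 1),
    value_meanlog = log(1960),
    value_sdlog = 1.53,
    value_split_alpha = 0.4,
    hh_size_p = 0.431,
    education_probs = c(none = 0.231, primary = 0.348, secondary = 0.310,
                        superior = 0.111),
    education_effects = c(none = 0, primary = 0.33, secondary = 0.53,
                          superior = 0.96),
    wealth_effect = 0.30,
    hh_size_effect = 0.10,
    diet_intercept = 5.833,
    diet_noise_sd = 0.85,
    spring_priority = 0.45,
    diet_model = c("LINEAR", "BERNOULLI_GROUPS"),
    recall_correlation = 0.3,
    group_pick_weights = c(
      grains_roots_tubers = 200, pulses = 3.5, nuts_seeds = 0.07,
      dairy = 1.2, meat_poultry_fish = 6, eggs = 0.75,
      dark_green_leafy = 1.8, vita_fruits_veg = 5.5, other_veg = 12,
      other_fruits = 2),
    dairy_bonus = 2,
    olive_oil_p = 0.93,
    market_count = 24L,
    n_species = 12L,
    market_dirichlet = 0.244,
    region_extent_km = 110,
    region_center = c(lat = 35.0, lon = 9.5),
    n_assets = 8L) {
  diet_model <- match.arg(diet_model)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed: single integer")
  chk(cfg$n_households >= 2, "n_households: must be >= 2")
  chk(abs(sum(cfg$zone_probs) - 1) < 1e-8, "zone_probs: must sum to 1")
  chk(all(cfg$zone_probs >= 0), "zone_probs: must be non-negative")
  chk(identical(sort(names(cfg$zone_probs)), sort(ZONES)),
      "zone_probs: must be named by the four climate zones")
  chk(all(cfg$production_prevalences >= 0 & cfg$production_prevalences < 1),
      "production_prevalences: must be in [0, 1)")
  chk(abs(sum(cfg$education_probs) - 1) < 1e-8,
      "education_probs: must sum to 1")
  chk(cfg$market_count >= 2, "market_count: must be >= 2 (HAMDI needs two markets)")
  chk(cfg$n_species >= 2, "n_species: must be >= 2")
  chk(cfg$confounder_sd >= 0, "confounder_sd: must be >= 0")
  chk(cfg$diet_noise_sd >= 0, "diet_noise_sd: must be >= 0")
  chk(cfg$spring_priority >= 0 && cfg$spring_priority <= 1,
      "spring_priority: must be in [0, 1]")
  chk(cfg$region_extent_km > 0, "region_extent_km: must be positive")
  chk(cfg$recall_correlation >= 0 && cfg$recall_correlation < 1,
      "recall_correlation: must be in [0, 1)")
  if (length(problems) > 0) {
    abort(paste0("invalid sim_config:\n",
                 paste("-", problems, collapse = "\n")),
          class = "agridiet_config_error")
  }
  cfg
}

# Per-product inclusion hazards theta_i from the per-group prevalence
# targets: group prevalence p over m products -> per-product inclusion
# q = 1 - (1-p)^(1/m) -> hazard -log(1-q), times the frozen calibration
# multiplier for the group.
product_hazards <- function(cfg) {
  catalogue <- product_catalogue()
  prev <- cfg$production_prevalences
  calib <- cfg$prevalence_calibration
  vapply(seq_len(nrow(catalogue)), function(i) {
    pid <- catalogue$product_id[i]
    grp <- catalogue$group[i]
    if (grp == "UNCLASSIFIED") {
      p <- unname(prev[pid])
      k <- unname(calib[pid] %||% 1)
      if (is.na(p)) abort(paste("no prevalence for unclassified product", pid))
    } else {
      m <- sum(catalogue$group == grp)
      p <- 1 - (1 - unname(prev[grp]))^(1 / m)
      k <- unname(calib[grp] %||% 1)
      if (is.na(p)) abort(paste("no prevalence for group", grp))
    }
    -log(1 - p) * ifelse(is.na(k), 1, k)
  }, numeric(1))
}

#' Generate synthetic weekly markets
#'
#' Places `market_count` markets uniformly in the square study region and
#' draws each market's species-sale proportion vector from a symmetric
#' Dirichlet, whose concentration sets the Shannon market diversity level.
#'
#' @param config A [sim_config()].
#' @return Market tibble: `market_id`, `lat`, `lon`, `sp_1..sp_k`.
#' @export
generate_markets <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  generate_markets_internal(cfg)
}

km_to_gps <- function(xy, cfg) {
  km_per_deg <- pi * 6371 / 180
  lat <- cfg$region_center[["lat"]] +
    (xy[, 2] - cfg$region_extent_km / 2) / km_per_deg
  lon <- cfg$region_center[["lon"]] +
    (xy[, 1] - cfg$region_extent_km / 2) /
    (km_per_deg * cos(cfg$region_center[["lat"]] * pi / 180))
  cbind(lat, lon)
}

draw_zero_truncated_products <- function(theta, intensity) {
  # inclusion of product i with prob 1 - exp(-theta_i * m); farms are
  # surveyed only if they produced something, so empty draws are redrawn
  repeat {
    inc <- runif(length(theta)) < 1 - exp(-theta * intensity)
    if (any(inc)) return(which(inc))
  }
}

self_consumption_draw <- function(n) {
  # U-shaped mixture: most farms sell nearly everything, a fifth keep
  # nearly everything, the rest sit in between
  comp <- sample.int(3, n, replace = TRUE, prob = c(0.62, 0.21, 0.17))
  s <- numeric(n)
  s[comp == 1] <- rbeta(sum(comp == 1), 0.3, 1.8)
  s[comp == 2] <- rbeta(sum(comp == 2), 1.8, 0.3)
  s[comp == 3] <- rbeta(sum(comp == 3), 2, 2)
  s
}

# Allocate the annual score (multiple of 0.25) into four seasonal integers
# whose mean is exactly the annual score, with leftover points routed
# spring-first with probability spring_priority.
allocate_seasons <- function(annual_q, spring_priority) {
  total <- as.integer(round(annual_q * 4))
  base <- total %/% 4L
  r <- total %% 4L
  seasonal <- rep(base, 4)
  names(seasonal) <- SEASONS
  if (r > 0) {
    priority <- c("spring", "winter", "autumn", "summer")
    order_pick <- if (runif(1) < spring_priority) priority else sample(SEASONS)
    extra <- order_pick[seq_len(r)]
    seasonal[extra] <- seasonal[extra] + 1L
  }
  # cap at 10 by moving surplus points to the emptiest seasons
  while (any(seasonal > 10)) {
    hi <- which.max(seasonal)
    lo <- which.min(seasonal)
    seasonal[hi] <- seasonal[hi] - 1L
    seasonal[lo] <- seasonal[lo] + 1L
  }
  seasonal
}

#' Generate a complete synthetic survey dataset
#'
#' Draws farms, households, women, seasonal recalls and markets under the
#' configured generative model, with all randomness derived from the
#' master seed (identical config and seed give identical datasets).
#' Generation proceeds: climate zones and farm seniority; the latent
#' household confounder; products via zero-truncated thinning with
#' log-intensity linear in zone, log-seniority and the confounder;
#' monetary values and U-shaped self-consumption splits; household
#' covariates, assets and the PCA wealth score; woman covariates; the
#' diet (annual latent score decomposed into seasonal recalls in LINEAR
#' mode, or per-group logistic draws in BERNOULLI_GROUPS mode); and
#' uniformly placed markets with Dirichlet species proportions.
#'
#' @param config A [sim_config()].
#' @return A list of class `agridiet_survey` with tibbles `farms`,
#'   `production`, `households`, `women`, `recalls`, `markets` and a
#'   `ground_truth` list carrying the structural parameters and
#'   per-household latents.
#' @export
simulate_survey <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  n <- as.integer(cfg$n_households)
  catalogue <- product_catalogue()
  theta <- product_hazards(cfg)

  hh_id <- sprintf("h%04d", seq_len(n))
  farm_id <- sprintf("f%04d", seq_len(n))
  woman_id <- sprintf("w%04d", seq_len(n))

  # --- farms: zone, seniority, latent confounder, products -------------
  zone <- sample(ZONES, n, replace = TRUE, prob = cfg$zone_probs[ZONES])
  seniority <- rlnorm(n, cfg$seniority_meanlog, cfg$seniority_sdlog)
  u <- rnorm(n, 0, cfg$confounder_sd)

  eta <- cfg$zone_effects[zone] +
    cfg$seniority_effect * (log(seniority) - cfg$seniority_meanlog) +
    cfg$loading_on_diversity * u
  # normalize so the mean intensity multiplier is ~1 under the defaults
  log_norm <- log(sum(cfg$zone_probs[ZONES] * exp(cfg$zone_effects[ZONES]))) +
    (cfg$seniority_effect * cfg$seniority_sdlog)^2 / 2 +
    (cfg$loading_on_diversity * cfg$confounder_sd)^2 / 2
  intensity <- exp(eta - log_norm)

  products <- lapply(seq_len(n), function(i) {
    draw_zero_truncated_products(theta, intensity[i])
  })

  pdi_count <- vapply(products, length, integer(1))
  n_rows <- sum(pdi_count)
  farm_rep <- rep(seq_len(n), pdi_count)
  total_value <- rlnorm(n, cfg$value_meanlog, cfg$value_sdlog)
  g <- rgamma(n_rows, cfg$value_split_alpha)
  g <- pmax(g, 1e-12)
  shares <- g / stats::ave(g, farm_rep, FUN = sum)
  self_base <- self_consumption_draw(n)
  self <- pmin(pmax(self_base[farm_rep] + rnorm(n_rows, 0, 0.05), 0), 1)
  donated <- (1 - self) * rbeta(n_rows, 1, 19)
  production <- tibble::tibble(
    farm_id = farm_id[farm_rep],
    product_id = catalogue$product_id[unlist(products)],
    value_usd = total_value[farm_rep] * shares,
    frac_sold = 1 - self - donated,
    frac_donated = donated,
    frac_selfconsumed = self)

  farm_xy <- matrix(runif(n * 2, 0, cfg$region_extent_km), ncol = 2)
  farm_gps <- km_to_gps(farm_xy, cfg)
  farms <- tibble::tibble(
    farm_id = farm_id, household_id = hh_id, climate_zone = zone,
    seniority_years = seniority,
    size_ha = rlnorm(n, log(2), 1.0),
    lat = farm_gps[, 1], lon = farm_gps[, 2])

  # --- households: size, head age, assets, wealth ----------------------
  hh_size <- 1L + rbinom(n, 10, cfg$hh_size_p)
  head_age <- pmax(22, rnorm(n, 44.6, 12.3))
  w_latent <- rnorm(n)
  cuts <- qnorm(seq(0.88, 0.15, length.out = cfg$n_assets))
  assets <- vapply(seq_len(cfg$n_assets), function(j) {
    as.integer(0.8 * w_latent + 0.6 * rnorm(n) > cuts[j])
  }, integer(n))
  colnames(assets) <- paste0("asset_", seq_len(cfg$n_assets))
  households <- tibble::tibble(
    household_id = hh_id, hh_size = hh_size, head_age = head_age,
    lat = farm_gps[, 1], lon = farm_gps[, 2]) |>
    dplyr::bind_cols(tibble::as_tibble(assets))
  households <- households |>
    dplyr::left_join(wealth_index(dplyr::select(households, "household_id",
                                                dplyr::starts_with("asset_"))),
                     by = "household_id")

  # --- women ------------------------------------------------------------
  age <- round(truncated_normal(n, 35, 7.9, 20, 49))
  education <- sample(EDUCATION_LEVELS, n, replace = TRUE,
                      prob = cfg$education_probs[EDUCATION_LEVELS])
  women <- tibble::tibble(
    woman_id = woman_id, household_id = hh_id, age = age,
    education = factor(education, levels = EDUCATION_LEVELS),
    domestic_hours = rlnorm(n, log(25.3), 0.41),
    responsibility = as.integer(runif(n) < 0.041),
    nonfarm_income = as.integer(runif(n) < 0.093),
    offfarm_ag_income = as.integer(runif(n) < 0.228),
    onfarm_participation = as.integer(runif(n) < 0.855),
    bmi = rnorm(n, 25.7, 5.0))

  # --- diet ---------------------------------------------------------------
  latent <- cfg$diet_intercept + cfg$true_beta1 * pdi_count +
    unname(cfg$education_effects[education]) +
    cfg$wealth_effect * w_latent +
    cfg$hh_size_effect * (hh_size - (1 + 10 * cfg$hh_size_p)) +
    cfg$loading_on_diet * u +
    rnorm(n, 0, cfg$diet_noise_sd)
  latent <- pmin(pmax(latent, 0), 10)

  produces_dairy <- farm_id %in%
    production$farm_id[production$product_id == "milk"]

  ind <- matrix(0L, n * 4, 10, dimnames = list(NULL, GROUP_COLS))
  if (cfg$diet_model == "LINEAR") {
    annual_q <- round(latent * 4) / 4
    base_w <- cfg$group_pick_weights[GROUP_COLS]
    for (i in seq_len(n)) {
      seasonal <- allocate_seasons(annual_q[i], cfg$spring_priority)
      w <- base_w
      if (produces_dairy[i]) w["dairy"] <- w["dairy"] * cfg$dairy_bonus
      for (s in 1:4) {
        k <- seasonal[[s]]
        if (k > 0) ind[(i - 1) * 4 + s, sample.int(10, k, prob = w)] <- 1L
      }
    }
  } else {
    sigma_b <- sqrt(cfg$recall_correlation / (1 - cfg$recall_correlation) *
                      pi^2 / 3)
    b <- rnorm(n, 0, sigma_b)
    base_p <- c(grains_roots_tubers = 0.99, pulses = 0.77, nuts_seeds = 0.04,
                dairy = 0.50, meat_poultry_fish = 0.80, eggs = 0.33,
                dark_green_leafy = 0.53, vita_fruits_veg = 0.84,
                other_veg = 0.95, other_fruits = 0.61)
    base_lp <- stats::qlogis(base_p[GROUP_COLS])
    for (i in seq_len(n)) {
      for (s in 1:4) {
        lp <- base_lp + 0.35 * (latent[i] - 6.53) + b[i] +
          0.15 * (SEASONS[s] == "spring") +
          ifelse(GROUP_COLS == "dairy" & produces_dairy[i], 0.7, 0)
        ind[(i - 1) * 4 + s, ] <- as.integer(runif(10) < stats::plogis(lp))
      }
    }
  }
  recalls <- tibble::tibble(
    woman_id = rep(woman_id, each = 4),
    season = rep(SEASONS, n)) |>
    dplyr::bind_cols(tibble::as_tibble(ind)) |>
    dplyr::mutate(olive_oil = as.integer(runif(n * 4) < cfg$olive_oil_p))

  markets <- generate_markets_internal(cfg)

  dataset <- structure(
    list(farms = farms, production = production, households = households,
         women = women, recalls = recalls, markets = markets,
         ground_truth = list(
           config = unclass(cfg),
           true_beta1 = cfg$true_beta1,
           confounder = setNames(u, hh_id),
           latent_wealth = setNames(w_latent, hh_id),
           latent_diet = setNames(latent, woman_id),
           intensity = setNames(intensity, farm_id))),
    class = "agridiet_survey")
  dataset
}

truncated_normal <- function(n, mean, sd, lower, upper) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  stats::qnorm(runif(n, lo, hi), mean, sd)
}

# markets without re-seeding (simulate_survey already owns the RNG stream)
generate_markets_internal <- function(cfg) {
  xy <- matrix(runif(cfg$market_count * 2, 0, cfg$region_extent_km), ncol = 2)
  gps <- km_to_gps(xy, cfg)
  g <- matrix(rgamma(cfg$market_count * cfg$n_species,
                     shape = cfg$market_dirichlet), nrow = cfg$market_count)
  props <- g / rowSums(g)
  colnames(props) <- paste0("sp_", seq_len(cfg$n_species))
  tibble::tibble(market_id = sprintf("m%02d", seq_len(cfg$market_count)),
                 lat = gps[, 1], lon = gps[, 2]) |>
    dplyr::bind_cols(tibble::as_tibble(props))
}

#' @export
print.agridiet_survey <- function(x, ...) {
  cat("Synthetic farm-household survey\n")
  cat("  households/farms/women:", nrow(x$households), "\n")
  cat("  production rows:", nrow(x$production),
      " recalls:", nrow(x$recalls), " markets:", nrow(x$markets), "\n")
  cat("  true beta1:", x$ground_truth$true_beta1, "\n")
  invisible(x)
}

#' Write or read a synthetic dataset as plain CSV + JSON
#'
#' `write_dataset()` writes one CSV per table plus `ground_truth.json`;
#' `read_dataset()` reads them back, validating that every file and every
#' required column is present (errors name the offending file/column).
#' Reading a written dataset reproduces the original tables.
#'
#' @param dataset An `agridiet_survey` object.
#' @param dir Directory to write to / read from.
#' @return `read_dataset()` returns an `agridiet_survey` object;
#'   `write_dataset()` returns `dir` invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "agridiet_survey"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tb in dataset_tables()) {
    readr::write_csv(dataset[[tb]], file.path(dir, paste0(tb, ".csv")))
  }
  gt <- dataset$ground_truth
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

dataset_tables <- function() {
  c("farms", "production", "households", "women", "recalls", "markets")
}

dataset_required_cols <- function() {
  list(
    farms = c("farm_id", "household_id", "climate_zone", "seniority_years",
              "size_ha", "lat", "lon"),
    production = c("farm_id", "product_id", "value_usd", "frac_sold",
                   "frac_donated", "frac_selfconsumed"),
    households = c("household_id", "hh_size", "head_age", "lat", "lon",
                   "wealth_score"),
    women = c("woman_id", "household_id", "age", "education",
              "domestic_hours", "responsibility", "nonfarm_income",
              "offfarm_ag_income", "onfarm_participation"),
    recalls = c("woman_id", "season", GROUP_COLS, "olive_oil"),
    markets = c("market_id", "lat", "lon"))
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  req <- dataset_required_cols()
  out <- lapply(dataset_tables(), function(tb) {
    path <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(path)) {
      abort(sprintf("dataset file missing: %s.csv", tb))
    }
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    missing <- setdiff(req[[tb]], names(df))
    if (length(missing) > 0) {
      abort(sprintf("file %s.csv is missing column(s): %s", tb,
                    paste(missing, collapse = ", ")))
    }
    df
  })
  names(out) <- dataset_tables()
  out$women$education <- factor(out$women$education, levels = EDUCATION_LEVELS)
  gt_path <- file.path(dir, "ground_truth.json")
  out$ground_truth <- if (file.exists(gt_path)) {
    jsonlite::read_json(gt_path, simplifyVector = TRUE)
  } else NULL
  structure(out, class = "agridiet_survey")
}
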