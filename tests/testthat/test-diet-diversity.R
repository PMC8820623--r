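test_that("wdds10 counts scorable groups and never olive oil", {
  r <- make_recalls("w1", list(
    autumn = character(),
    winter = GROUPS10,
    spring = c("grains_roots_tubers", "dairy"),
    summer = c("grains_roots_tubers")), olive_oil = 1)
  s <- wdds10(r)
  expect_equal(s$wdds10[s$season == "autumn"], 0)
  expect_equal(s$wdds10[s$season == "winter"], 10)
  expect_equal(s$wdds10[s$season == "spring"], 2)  # olive oil ignored
  expect_equal(s$wdds10[s$season == "summer"], 1)
})

test_that("annual score is the mean of the four seasonal scores", {
  r <- make_recalls("w1", list(
    autumn = GROUPS10[1:6], winter = GROUPS10[1:7],
    spring = GROUPS10[1:6], summer = GROUPS10[1:7]))
  expect_equal(annual_wdds(r)$annual_wdds, 6.5)

  r0 <- make_recalls("w0", list())
  expect_equal(annual_wdds(r0)$annual_wdds, 0)
  r10 <- make_recalls("wX", list(autumn = GROUPS10, winter = GROUPS10,
                                 spring = GROUPS10, summer = GROUPS10))
  expect_equal(annual_wdds(r10)$annual_wdds, 10)
})

test_that("incomplete recall sets are rejected, not imputed", {
  r <- make_recalls("w1", list(autumn = GROUPS10[1:5]))
  r <- r[r$season != "summer", ]
  expect_error(annual_wdds(r), "exactly one recall per season")
  dup <- dplyr::bind_rows(recall_row("w1", "spring", GROUPS10[1:3]),
                          recall_row("w1", "spring", GROUPS10[1:2]))
  expect_error(wdds10(dup), "more than one recall")
})

test_that("the MDD-W flag switches exactly at five groups", {
  at5 <- make_recalls("w1", list(autumn = GROUPS10[1:5], winter = GROUPS10[1:5],
                                 spring = GROUPS10[1:5], summer = GROUPS10[1:5]))
  expect_true(mddw_flag(at5)$mddw)
  below <- make_recalls("w2", list(autumn = GROUPS10[1:5], winter = GROUPS10[1:5],
                                   spring = GROUPS10[1:5], summer = GROUPS10[1:4]))
  expect_equal(annual_wdds(below)$annual_wdds, 4.75)
  expect_false(mddw_flag(below)$mddw)
  per <- mddw_flag(at5, per_season = TRUE)
  expect_true(all(per$mddw))
})

test_that("consumption scores take the five quarter values", {
  r <- make_recalls("w1", list(
    autumn = c("dairy", "pulses"), winter = c("dairy"),
    spring = c("dairy", "pulses", "eggs"), summer = c("pulses")),
    olive_oil = 1)
  cs <- consumption_scores(r)
  get <- function(g) cs$score[cs$group == g]
  expect_equal(get("dairy"), 0.75)
  expect_equal(get("pulses"), 0.75)
  expect_equal(get("eggs"), 0.25)
  expect_equal(get("grains_roots_tubers"), 0)
  expect_equal(get("olive_oil"), 1)
  expect_true(all(cs$score %in% c(0, 0.25, 0.5, 0.75, 1)))
})

test_that("wdds10 is monotone under adding a consumed group", {
  set.seed(11)
  for (i in 1:25) {
    consumed <- sample(GROUPS10, sample(0:9, 1))
    r <- recall_row("w1", "spring", consumed)
    extra <- sample(setdiff(GROUPS10, consumed), 1)
    r2 <- recall_row("w1", "spring", c(consumed, extra))
    expect_equal(wdds10(r2)$wdds10, wdds10(r)$wdds10 + 1)
  }
})

test_that("seasonal summary matches a brute-force count on a small cohort", {
  set.seed(21)
  recs <- purrr::map_dfr(1:5, function(i) {
    make_recalls(paste0("w", i), list(
      autumn = sample(GROUPS10, 4), winter = sample(GROUPS10, 6),
      spring = sample(GROUPS10, 7), summer = sample(GROUPS10, 5)))
  })
  sc <- seasonal_consumers(recs)
  # brute force: loop over women and seasons
  for (s in c("autumn", "winter", "spring", "summer")) {
    for (g in GROUPS10) {
      hand <- 100 * mean(recs[[g]][recs$season == s])
      expect_equal(sc$pct_consumers[sc$season == s & sc$group == g], hand)
    }
  }
  expect_true(all(sc$pct_consumers >= 0 & sc$pct_consumers <= 100))
  sw <- seasonal_wdds(recs)
  expect_equal(sw$mean_wdds[sw$season == "spring"], 7)
})

test_that("seasonal tests are null on constant diets, powered on seasonal ones", {
  # identical across seasons: every stratum degenerate, CMH statistic 0
  recs <- purrr::map_dfr(1:20, function(i) {
    g <- if (i <= 12) GROUPS10[1:6] else GROUPS10[1:4]
    make_recalls(paste0("w", i),
                 list(autumn = g, winter = g, spring = g, summer = g))
  })
  out <- seasonal_tests(recs)
  expect_true(all(out$cmh$p_value == 1))
  expect_true(all(out$cmh$statistic == 0))
  expect_equal(sum(out$cmh$n_informative), 0)
  expect_true(all(out$wilcoxon$p_value == 1))

  # strong spring-only consumption of pulses
  recs2 <- purrr::map_dfr(1:40, function(i) {
    base <- GROUPS10[c(1, 4, 5)]
    make_recalls(paste0("w", i), list(
      autumn = base, winter = base,
      spring = if (i <= 30) c(base, "pulses") else base,
      summer = base))
  })
  out2 <- seasonal_tests(recs2)
  expect_lt(out2$cmh$p_value[out2$cmh$group == "pulses"], 0.01)
  expect_equal(out2$cmh$n_dropped[out2$cmh$group == "pulses"], 10)
  # spring vs summer WDDS differs for 30 of 40 women
  ws <- out2$wilcoxon
  expect_lt(ws$p_value[ws$season1 == "spring" & ws$season2 == "summer"], 0.01)
})

test_that("consumption-by-production table links own production to diets", {
  recs <- purrr::map_dfr(1:12, function(i) {
    milk_seasons <- if (i <= 6) c("autumn", "winter", "spring", "summer")
                    else c("autumn")
    make_recalls(paste0("w", i), setNames(
      lapply(c("autumn", "winter", "spring", "summer"), function(s) {
        c("grains_roots_tubers", if (s %in% milk_seasons) "dairy")
      }), c("autumn", "winter", "spring", "summer")))
  })
  production <- dplyr::bind_rows(
    purrr::map_dfr(1:6, ~ make_production(c("milk", "wheat"),
                                          farm = paste0("f", .x))),
    purrr::map_dfr(7:12, ~ make_production("wheat", farm = paste0("f", .x))))
  link <- tibble::tibble(woman_id = paste0("w", 1:12),
                         farm_id = paste0("f", 1:12))
  tab <- consumption_by_production(recs, production, link)
  dairy <- tab[tab$group == "dairy", ]
  expect_equal(dairy$pct_producing, 50)
  expect_equal(dairy$mean_producing, 1)
  expect_equal(dairy$mean_not_producing, 0.25)
  expect_lt(dairy$p_ranksum, 0.01)
  expect_equal(nrow(tab), 11)  # ten groups plus olive oil
})
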