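test_that("wealth index is a 0-100 monotone transform of the first PC", {
  set.seed(51)
  # two perfectly correlated assets: index is monotone in either
  a <- tibble::tibble(household_id = paste0("h", 1:20),
                      tv = rep(c(0, 1), 10), radio = rep(c(0, 1), 10))
  w <- wealth_index(a)
  expect_equal(sort(unique(w$wealth_score)), c(0, 100))
  expect_true(all(w$wealth_score[a$tv == 1] > w$wealth_score[a$tv == 0]))

  # four-household case against a direct eigen-decomposition oracle
  m <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 1, 1), c(0, 0, 1))
  colnames(m) <- c("a1", "a2", "a3")
  tab <- tibble::tibble(household_id = paste0("h", 1:4),
                        tibble::as_tibble(m))
  w4 <- wealth_index(tab)
  z <- scale(m)
  ev <- eigen(stats::cor(m))$vectors[, 1]
  pc1 <- drop(z %*% ev)
  if (stats::cor(pc1, rowSums(z)) < 0) pc1 <- -pc1
  oracle <- 100 * (pc1 - min(pc1)) / diff(range(pc1))
  expect_equal(w4$wealth_score, oracle, tolerance = 1e-10)
  expect_equal(range(w4$wealth_score), c(0, 100))

  # constant columns are dropped with a warning
  tab$flat <- 1
  expect_warning(wealth_index(tab), "constant asset column")
})

test_that("OLS matches the normal-equations oracle and flags collinearity", {
  set.seed(52)
  X <- cbind(1, matrix(rnorm(20 * 2), 20, 2))
  beta <- c(1.5, -2, 0.5)
  y <- drop(X %*% beta) + rnorm(20, 0, 0.3)
  d <- tibble::tibble(y = y, x1 = X[, 2], x2 = X[, 3])
  fit <- fit_ols(y ~ x1 + x2, d)
  oracle <- drop(solve(crossprod(X), crossprod(X, y)))
  expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-10)

  # exact linear data recovered exactly
  d2 <- tibble::tibble(x = 1:10, y = 3 + 2 * (1:10))
  fit2 <- fit_ols(y ~ x, d2)
  expect_equal(unname(fit2$coefficients), c(3, 2), tolerance = 1e-10)
  expect_equal(unname(stats::resid(fit2$lm)), rep(0, 10), tolerance = 1e-10)

  # intercept-only model returns the mean
  fit3 <- fit_ols(y ~ 1, d2)
  expect_equal(unname(fit3$coefficients), mean(d2$y))

  d$dup <- d$x1
  expect_error(fit_ols(y ~ x1 + dup, d), "collinear.*dup")
})

test_that("robust SEs agree with classical ones under homoskedasticity", {
  set.seed(53)
  n <- 1000
  d <- tibble::tibble(x = rnorm(n), y = 1 + 0.5 * rnorm(n))
  d$y <- 1 + 0.8 * d$x + rnorm(n)  # equal-variance residuals
  fit <- fit_ols(y ~ x, d)
  classical <- summary(fit$lm)$coefficients[, "Std. Error"]
  expect_equal(unname(fit$se), unname(classical), tolerance = 0.05)
})

test_that("standardized coefficients rescale as the closed form demands", {
  expect_equal(standardized_coefficient(2, 1.5, 3), 1)
  expect_equal(standardized_coefficient(0, 2, 5), 0)
  expect_error(standardized_coefficient(1, 1, 0), "positive")
  # rescaling x by c and refitting leaves the standardized slope unchanged
  set.seed(54)
  d <- tibble::tibble(x = rnorm(50), y = 2 + 0.7 * rnorm(50))
  d$y <- 2 + 0.7 * d$x + rnorm(50, 0, 0.4)
  f1 <- fit_ols(y ~ x, d)
  d2 <- dplyr::mutate(d, x = x * 13)
  f2 <- fit_ols(y ~ x, d2)
  s1 <- standardized_coefficient(f1$coefficients["x"], sd(d$x), sd(d$y))
  s2 <- standardized_coefficient(f2$coefficients["x"], sd(d2$x), sd(d2$y))
  expect_equal(unname(s1), unname(s2), tolerance = 1e-10)
})

test_that("just-identified LIML reproduces 2SLS with kappa = 1", {
  set.seed(55)
  d <- simulate_iv(n = 120, beta = 1.2, pi = 0.5, n_instruments = 1,
                   rho = 0.6)
  fit <- fit_liml(d, "y", "x", "w", "z1")
  expect_equal(fit$kappa, 1, tolerance = 1e-8)

  # explicit 2SLS oracle
  Zbar <- cbind(1, d$w, d$z1)
  R <- cbind(d$x, 1, d$w)
  P <- Zbar %*% solve(crossprod(Zbar), t(Zbar))
  tsls <- drop(solve(t(R) %*% P %*% R, t(R) %*% P %*% d$y))
  expect_equal(unname(fit$coefficients[c("x", "(Intercept)", "w")]), tsls,
               tolerance = 1e-8)
  # ratio-form IV for the slope after partialling the exogenous block
  expect_true(fit$overid$df == 0 && !fit$overid$applicable)
  expect_true(is.na(fit$overid$hansen_j))
})

test_that("over-identified LIML matches an independent eigen + k-class oracle", {
  set.seed(56)
  d <- simulate_iv(n = 40, beta = 0.8, pi = 0.6, n_instruments = 3, rho = 0.5)
  fit <- fit_liml(d, "y", "x", "w", paste0("z", 1:3))

  # oracle kappa: minimize the variance ratio over the scalar slope b
  X <- cbind(1, d$w)
  Zbar <- cbind(X, d$z1, d$z2, d$z3)
  Mx <- diag(40) - X %*% solve(crossprod(X), t(X))
  Mz <- diag(40) - Zbar %*% solve(crossprod(Zbar), t(Zbar))
  ratio <- function(b) {
    e <- d$y - b * d$x
    drop(t(e) %*% Mx %*% e) / drop(t(e) %*% Mz %*% e)
  }
  kappa_oracle <- stats::optimize(ratio, c(-50, 50), tol = 1e-12)$objective
  expect_equal(fit$kappa, kappa_oracle, tolerance = 1e-8)
  expect_gte(fit$kappa, 1)

  # oracle k-class coefficients at that kappa
  R <- cbind(d$x, X)
  A <- t(R) %*% (diag(40) - kappa_oracle * Mz) %*% R
  b <- t(R) %*% (diag(40) - kappa_oracle * Mz) %*% d$y
  delta_oracle <- drop(solve(A, b))
  expect_equal(unname(fit$coefficients[c("x", "(Intercept)", "w")]),
               delta_oracle, tolerance = 1e-8)
})

test_that("Cragg-Donald equals the squared first-stage t with one instrument", {
  set.seed(57)
  d <- simulate_iv(n = 200, beta = 1, pi = 0.4, n_instruments = 1, rho = 0.4)
  cd <- cragg_donald_f(d, "x", "w", "z1")
  fs <- summary(stats::lm(x ~ w + z1, d))
  tstat <- fs$coefficients["z1", "t value"]
  expect_equal(cd, tstat^2, tolerance = 1e-8)
})

test_that("Cragg-Donald F grows with instrument strength and sits near 1 under none", {
  set.seed(58)
  f_null <- vapply(1:200, function(i) {
    d <- simulate_iv(n = 250, pi = 0, n_instruments = 3, rho = 0.4)
    cragg_donald_f(d, "x", "w", paste0("z", 1:3))
  }, numeric(1))
  expect_equal(mean(f_null), 1, tolerance = 0.15)

  f_weak <- vapply(1:60, function(i) {
    d <- simulate_iv(n = 250, pi = 0.15, n_instruments = 3, rho = 0.4)
    cragg_donald_f(d, "x", "w", paste0("z", 1:3))
  }, numeric(1))
  f_strong <- vapply(1:60, function(i) {
    d <- simulate_iv(n = 250, pi = 0.3, n_instruments = 3, rho = 0.4)
    cragg_donald_f(d, "x", "w", paste0("z", 1:3))
  }, numeric(1))
  expect_gt(median(f_strong), median(f_weak))
})

test_that("Anderson LM test behaves under strong and absent identification", {
  set.seed(59)
  d <- simulate_iv(n = 290, pi = 0.3, n_instruments = 4, rho = 0.5)
  lm_strong <- anderson_lm(d, "x", "w", paste0("z", 1:4))
  expect_gte(lm_strong$statistic, 0)
  expect_equal(lm_strong$df, 4)
  expect_lt(lm_strong$p_value, 0.01)

  d0 <- simulate_iv(n = 290, pi = 0, n_instruments = 4, rho = 0.5)
  lm_null <- anderson_lm(d0, "x", "w", paste0("z", 1:4))
  expect_gte(lm_null$statistic, 0)
})

test_that("LIML is centred with OLS when confounding is switched off", {
  set.seed(60)
  est <- vapply(1:120, function(i) {
    d <- simulate_iv(n = 300, beta = 1, pi = 0.4, n_instruments = 4, rho = 0)
    f_iv <- fit_liml(d, "y", "x", "w", paste0("z", 1:4))
    f_ols <- fit_ols(y ~ x + w, d)
    c(f_iv$coefficients["x"], f_ols$coefficients["x"])
  }, numeric(2))
  # paired within-replicate gap between the two estimators is within
  # Monte-Carlo error of zero (its variance is var(IV) - var(OLS))
  gap <- est[1, ] - est[2, ]
  expect_lt(abs(median(gap)),
            4 * 1.2533 * sd(gap) / sqrt(length(gap)))
  # and LIML is centred on the truth within three Monte-Carlo SEs of the median
  mc_se <- 1.2533 * sd(est[1, ]) / sqrt(ncol(est))
  expect_lt(abs(median(est[1, ]) - 1), 3 * mc_se)
})

test_that("underidentified or malformed designs are refused", {
  set.seed(61)
  d <- simulate_iv(n = 60, n_instruments = 1)
  expect_error(fit_liml(d, "y", "x", "w", character(0)), "underidentified")
  expect_error(fit_liml(d, "y", "x", c("w", "z1"), "z1"), "both sides")
  d$zdup <- d$w
  expect_error(fit_liml(d, "y", "x", "w", "zdup"), "rank deficient")
})
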