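#' Asset-based wealth index
#'
#' First principal component of the standardized household asset
#' indicators, oriented so that owning more assets raises the score, then
#' affinely rescaled to the 0-100 range. Constant asset columns carry no
#' information and are dropped with a warning.
#'
#' @param assets Data frame with `household_id` and two or more numeric
#'   (typically 0/1) asset columns.
#' @return Tibble `household_id`, `wealth_score`.
#' @export
wealth_index <- function(assets) {
  assert_cols(assets, "household_id", "asset table")
  cols <- setdiff(names(assets), "household_id")
  if (length(cols) < 2) abort("need at least 2 asset indicators")
  if (nrow(assets) < 3) abort("need at least 3 households")
  mat <- as.matrix(assets[, cols])
  constant <- apply(mat, 2, sd) == 0
  if (any(constant)) {
    warn(paste("dropping constant asset column(s):",
               paste(cols[constant], collapse = ", ")))
    mat <- mat[, !constant, drop = FALSE]
    if (ncol(mat) < 2) abort("fewer than 2 informative asset indicators remain")
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = TRUE)
  score <- pc$x[, 1]
  # orient so the index increases with overall asset ownership
  if (stats::cor(score, rowSums(scale(mat))) < 0) score <- -score
  rng <- range(score)
  if (diff(rng) == 0) abort("degenerate first principal component")
  tibble::tibble(household_id = assets$household_id,
                 wealth_score = 100 * (score - rng[1]) / diff(rng))
}

#' Standardized regression coefficient
#'
#' Rescales a slope to standard-deviation units of the regressor and the
#' outcome: `beta * sd_x / sd_y`, making slopes comparable across
#' production-diversity indices measured on different scales.
#'
#' @param beta Estimated slope.
#' @param sd_x,sd_y Sample standard deviations of regressor and outcome.
#' @return Scalar.
#' @export
standardized_coefficient <- function(beta, sd_x, sd_y) {
  if (sd_y <= 0) abort("sd_y must be positive")
  beta * sd_x / sd_y
}

significance_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p < 0.01 ~ "***", p < 0.05 ~ "**",
                   p < 0.10 ~ "*", TRUE ~ "")
}

model_matrix_checked <- function(data, cols, label) {
  assert_cols(data, cols, label)
  X <- as.matrix(data[, cols, drop = FALSE])
  if (!all(is.finite(X))) abort(paste(label, "contains non-finite values"))
  storage.mode(X) <- "double"
  X
}

#' Ordinary least squares with heteroskedasticity-robust errors
#'
#' Thin wrapper around [stats::lm()] reporting HC1 (Huber-White with
#' small-sample correction) sandwich standard errors. Rank-deficient
#' designs are refused, naming the collinear columns.
#'
#' @param formula,data Passed to [stats::lm()].
#' @return An object of class `agridiet_ols` with `tidy()`/`glance()`
#'   methods; fields `coefficients`, `se`, `vcov`, `nobs`, `lm`.
#' @export
fit_ols <- function(formula, data) {
  fit <- stats::lm(formula, data = data)
  aliased <- is.na(stats::coef(fit))
  if (any(aliased)) {
    abort(paste("rank-deficient design; collinear column(s):",
                paste(names(aliased)[aliased], collapse = ", ")))
  }
  V <- sandwich::vcovHC(fit, type = "HC1")
  est <- stats::coef(fit)
  se <- sqrt(diag(V))
  z <- est / se
  structure(
    list(coefficients = est, se = se, vcov = V,
         statistic = z, p_value = 2 * pnorm(-abs(z)),
         nobs = stats::nobs(fit), residuals = stats::resid(fit), lm = fit),
    class = "agridiet_ols")
}

#' @export
print.agridiet_ols <- function(x, ...) {
  cat("OLS fit (HC1 robust SEs), n =", x$nobs, "\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

# ---- LIML / k-class core -------------------------------------------------

residual_maker_mult <- function(X, A) {
  # M_X %*% A without forming M_X: A - X (X'X)^-1 X'A via QR
  A - stats::lm.fit(X, A)$fitted.values
}

#' Limited-information maximum likelihood (LIML) IV estimation
#'
#' Estimates a linear outcome equation with endogenous regressors by LIML,
#' the k-class estimator whose k equals the smallest eigenvalue kappa of
#' the pencil `det(W' M_X W - kappa W' M_Z W) = 0`, where `W = [y, Y]`
#' collects the outcome and the endogenous regressors, `M_X` annihilates
#' the included exogenous variables, and `M_Z` annihilates instruments and
#' exogenous variables jointly. Kappa is always at least one; the
#' just-identified case gives kappa = 1 and reproduces two-stage least
#' squares exactly. Standard errors are heteroskedasticity-robust
#' (Huber-White sandwich with HC1 small-sample factor).
#'
#' The fit carries the full instrument-diagnostic block: the Cragg-Donald
#' minimum-eigenvalue F (with the Stock-Yogo reference value for the
#' requested criterion), the Anderson canonical-correlation LM
#' underidentification test, and the Sargan and robust Hansen J tests of
#' the overidentifying restrictions (Hansen J is the headline; both are
#' reported, and both are `NA` with zero degrees of freedom when the model
#' is just identified).
#'
#' @param data Data frame holding all columns.
#' @param outcome Name of the outcome column.
#' @param endogenous Character vector of endogenous regressor columns.
#' @param exogenous Character vector of included exogenous columns (an
#'   intercept is always added).
#' @param instruments Character vector of excluded instrument columns; at
#'   least as many as endogenous regressors.
#' @param sy_criterion Stock-Yogo criterion to report (default `"size10"`).
#' @param sy_estimator Stock-Yogo estimator column (default `"LIML"`).
#' @return Object of class `agridiet_liml` with `tidy()`/`glance()`
#'   methods. Fields include `coefficients`, `se`, `vcov`, `kappa`,
#'   `cragg_donald_f`, `stock_yogo`, `underid`, `overid`,
#'   `std_beta1`, `nobs`, `df_overid`.
#' @export
fit_liml <- function(data, outcome, endogenous, exogenous, instruments,
                     sy_criterion = "size10", sy_estimator = "LIML") {
  y <- model_matrix_checked(data, outcome, "outcome")
  Yend <- model_matrix_checked(data, endogenous, "endogenous regressors")
  Xinc <- cbind(`(Intercept)` = 1,
                model_matrix_checked(data, exogenous, "exogenous regressors"))
  Zexc <- model_matrix_checked(data, instruments, "instruments")

  overlap <- intersect(c(exogenous, outcome), instruments)
  if (length(overlap) > 0) {
    abort(paste("column(s) appear on both sides:",
                paste(overlap, collapse = ", ")))
  }
  n <- nrow(y)
  m <- ncol(Yend)
  L <- ncol(Zexc)
  if (L < m) abort("underidentified: fewer excluded instruments than endogenous regressors")
  k_total <- ncol(Xinc) + L + m
  if (n <= k_total) abort("not enough observations for the requested design")
  if (qr(cbind(Xinc, Zexc))$rank < ncol(Xinc) + L) {
    abort("instrument + exogenous matrix is rank deficient")
  }

  Zbar <- cbind(Xinc, Zexc)
  W <- cbind(y, Yend)
  A <- crossprod(W, residual_maker_mult(Xinc, W))   # W' M_X W
  B <- crossprod(W, residual_maker_mult(Zbar, W))   # W' M_Zbar W
  kappa <- min(Re(eigen(solve(B, A), only.values = TRUE)$values))
  if (kappa < 1 - 1e-8) {
    abort(sprintf("numerical failure: LIML kappa = %.10f < 1", kappa))
  }
  kappa <- max(kappa, 1)

  R <- cbind(Yend, Xinc)
  Rhat <- R - kappa * residual_maker_mult(Zbar, R)   # (I - kappa M_Zbar) R
  bread <- solve(crossprod(Rhat, R))
  delta <- drop(bread %*% crossprod(Rhat, y))
  names(delta) <- colnames(R)
  e <- drop(y - R %*% delta)

  meat <- crossprod(Rhat * e)
  V <- bread %*% meat %*% t(bread) * n / (n - ncol(R))
  dimnames(V) <- list(colnames(R), colnames(R))
  se <- sqrt(diag(V))

  cd <- cragg_donald_f(data, endogenous, exogenous, instruments)
  underid <- anderson_lm(data, endogenous, exogenous, instruments)
  overid <- sargan_hansen_stats(e, Zbar, n, L, m)

  sy <- tryCatch(
    stock_yogo_critical_value(sy_estimator, sy_criterion, m, L),
    agridiet_not_tabulated = function(cnd) NA_real_)

  sd_y <- sd(y)
  std_beta1 <- standardized_coefficient(delta[endogenous[1]],
                                        sd(Yend[, 1]), sd_y)

  z <- delta / se
  structure(
    list(coefficients = delta, se = se, vcov = V, statistic = z,
         p_value = 2 * pnorm(-abs(z)), kappa = kappa,
         cragg_donald_f = cd,
         stock_yogo = list(critical_value = sy, estimator = sy_estimator,
                           criterion = sy_criterion),
         underid = underid, overid = overid,
         std_beta1 = unname(std_beta1),
         nobs = n, n_endog = m, n_instruments = L, df_overid = L - m,
         outcome = outcome, endogenous = endogenous,
         residuals = e),
    class = "agridiet_liml")
}

#' @export
print.agridiet_liml <- function(x, ...) {
  cat("LIML fit, n =", x$nobs, " kappa =", format(x$kappa, digits = 8), "\n")
  print(tidy(x), n = Inf)
  cat(sprintf("Cragg-Donald F = %.3f (Stock-Yogo %s %s: %s)\n",
              x$cragg_donald_f, x$stock_yogo$estimator,
              x$stock_yogo$criterion,
              format(x$stock_yogo$critical_value)))
  cat(sprintf("Anderson LM underidentification p = %.4f\n", x$underid$p_value))
  if (x$df_overid > 0) {
    cat(sprintf("Hansen J = %.3f (df %d, p = %.4f); Sargan p = %.4f\n",
                x$overid$hansen_j, x$df_overid, x$overid$hansen_p,
                x$overid$sargan_p))
  } else {
    cat("Overidentification test not applicable (just identified)\n")
  }
  invisible(x)
}

partialled <- function(data, endogenous, exogenous, instruments) {
  Xinc <- cbind(1, model_matrix_checked(data, exogenous, "exogenous regressors"))
  Yt <- residual_maker_mult(Xinc, model_matrix_checked(data, endogenous,
                                                       "endogenous regressors"))
  Zt <- residual_maker_mult(Xinc, model_matrix_checked(data, instruments,
                                                       "instruments"))
  list(Yt = Yt, Zt = Zt, k1 = ncol(Xinc))
}

#' Cragg-Donald weak-instrument statistic
#'
#' Minimum eigenvalue of the first-stage concentration matrix after
#' partialling the included exogenous variables out of both the endogenous
#' regressors and the excluded instruments. With a single endogenous
#' regressor this is the first-stage F statistic on the excluded
#' instruments.
#'
#' @inheritParams fit_liml
#' @return Scalar F-type statistic.
#' @export
cragg_donald_f <- function(data, endogenous, exogenous, instruments) {
  p <- partialled(data, endogenous, exogenous, instruments)
  L <- ncol(p$Zt)
  n <- nrow(p$Yt)
  fitted <- p$Yt - residual_maker_mult(p$Zt, p$Yt)   # P_Zt Yt
  S_res <- crossprod(p$Yt - fitted)                  # Y' M_[X,Z] Y
  S_fit <- crossprod(p$Yt, fitted)                   # Y' P_partial Y
  ev <- Re(eigen(solve(S_res, S_fit), only.values = TRUE)$values)
  min(ev) * (n - p$k1 - L) / L
}

#' Anderson canonical-correlation underidentification test
#'
#' LM statistic `n` times the smallest squared canonical correlation
#' between the partialled endogenous regressors and the partialled
#' excluded instruments; chi-squared with `n_excl - n_endog + 1` degrees
#' of freedom under the null of underidentification.
#'
#' @inheritParams fit_liml
#' @return List with `statistic`, `df`, `p_value`.
#' @export
anderson_lm <- function(data, endogenous, exogenous, instruments) {
  p <- partialled(data, endogenous, exogenous, instruments)
  n <- nrow(p$Yt)
  Syy <- crossprod(p$Yt)
  Szz <- crossprod(p$Zt)
  Syz <- crossprod(p$Yt, p$Zt)
  cc2 <- Re(eigen(solve(Syy, Syz %*% solve(Szz, t(Syz))),
                  only.values = TRUE)$values)
  stat <- n * min(cc2)
  df <- ncol(p$Zt) - ncol(p$Yt) + 1
  list(statistic = max(stat, 0), df = df,
       p_value = stats::pchisq(max(stat, 0), df, lower.tail = FALSE))
}

sargan_hansen_stats <- function(e, Zbar, n, L, m) {
  df <- L - m
  if (df <= 0) {
    return(list(sargan = NA_real_, sargan_p = NA_real_,
                hansen_j = NA_real_, hansen_p = NA_real_, df = 0L,
                applicable = FALSE))
  }
  Pe <- e - residual_maker_mult(Zbar, e)
  sargan <- n * sum(Pe^2) / sum(e^2)
  g <- crossprod(Zbar, e)
  Omega <- crossprod(Zbar * e)
  hansen <- drop(t(g) %*% solve(Omega, g))
  list(sargan = sargan,
       sargan_p = stats::pchisq(sargan, df, lower.tail = FALSE),
       hansen_j = hansen,
       hansen_p = stats::pchisq(hansen, df, lower.tail = FALSE),
       df = as.integer(df), applicable = TRUE)
}

#' Sargan and Hansen J overidentification tests
#'
#' Convenience wrapper returning the overidentification block of a fitted
#' LIML model (see [fit_liml()]); `NA` statistics with `applicable =
#' FALSE` when the model is just identified.
#'
#' @param fit An `agridiet_liml` object.
#' @return List with `sargan`, `sargan_p`, `hansen_j`, `hansen_p`, `df`,
#'   `applicable`.
#' @export
overid_test <- function(fit) {
  stopifnot(inherits(fit, "agridiet_liml"))
  fit$overid
}

#' Simple instrumental-variable data simulator
#'
#' Minimal Gaussian linear IV data generator used to study the sampling
#' behaviour of the estimator and its diagnostics (size of the Hansen J
#' test, uniformity of the Anderson LM p-value, first-stage strength).
#' Draws `n_instruments` standard-normal instruments, an endogenous
#' regressor `x = Z pi + v`, and an outcome `y = beta x + u` with
#' `cor(u, v) = rho`. Setting `invalid_loading` non-zero adds a direct
#' effect of the first instrument on the outcome, violating the exclusion
#' restriction.
#'
#' @param n Sample size.
#' @param beta Structural coefficient.
#' @param pi First-stage coefficient (scalar, shared by all instruments).
#' @param n_instruments Number of excluded instruments.
#' @param rho Endogeneity correlation between structural and first-stage
#'   errors.
#' @param invalid_loading Direct outcome loading of instrument 1.
#' @return Tibble with `y`, `x`, `z1..zL` and an exogenous control `w`.
#' @export
simulate_iv <- function(n = 300, beta = 1, pi = 0.3, n_instruments = 4,
                        rho = 0.5, invalid_loading = 0) {
  Z <- matrix(rnorm(n * n_instruments), n, n_instruments)
  colnames(Z) <- paste0("z", seq_len(n_instruments))
  w <- rnorm(n)
  v <- rnorm(n)
  u <- rho * v + sqrt(1 - rho^2) * rnorm(n)
  x <- drop(Z %*% rep(pi, n_instruments)) + 0.5 * w + v
  y <- beta * x + 0.5 * w + invalid_loading * Z[, 1] + u
  tibble::tibble(y = y, x = x, w = w, !!!as.data.frame(Z))
}
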