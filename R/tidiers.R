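#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy methods for fitted models
#'
#' Broom-style one-row-per-term (`tidy()`) and one-row-per-model
#' (`glance()`) summaries for the package's OLS and LIML fits.
#'
#' @param x An `agridiet_ols` or `agridiet_liml` object.
#' @param ... Unused.
#' @return A tibble.
#' @name agridiet_tidiers
NULL

tidy_coef_table <- function(x) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(x$statistic),
    p.value = unname(x$p_value),
    stars = significance_stars(unname(x$p_value)))
}

#' @rdname agridiet_tidiers
#' @method tidy agridiet_ols
#' @export
tidy.agridiet_ols <- function(x, ...) tidy_coef_table(x)

#' @rdname agridiet_tidiers
#' @method tidy agridiet_liml
#' @export
tidy.agridiet_liml <- function(x, ...) tidy_coef_table(x)

#' @rdname agridiet_tidiers
#' @method glance agridiet_ols
#' @export
glance.agridiet_ols <- function(x, ...) {
  s <- summary(x$lm)
  tibble::tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
                 sigma = s$sigma, nobs = x$nobs)
}

#' @rdname agridiet_tidiers
#' @method glance agridiet_liml
#' @export
glance.agridiet_liml <- function(x, ...) {
  tibble::tibble(
    kappa = x$kappa,
    cragg_donald_f = x$cragg_donald_f,
    stock_yogo_critical = x$stock_yogo$critical_value,
    underid_statistic = x$underid$statistic,
    underid_p = x$underid$p_value,
    sargan_p = x$overid$sargan_p,
    hansen_j = x$overid$hansen_j,
    hansen_p = x$overid$hansen_p,
    df_overid = x$df_overid,
    std_beta1 = x$std_beta1,
    nobs = x$nobs)
}
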