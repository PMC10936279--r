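#' Tidy and glance methods for fitted result objects
#'
#' broom-style accessors: `tidy()` returns one row per model term,
#' `glance()` a one-row model summary.
#'
#' @param x A `power_fit`, `rm_anova_result` or `stepwise_model`.
#' @param ... Unused.
#' @return A tibble.
#' @name twitchtdi-tidiers
NULL

#' @rdname twitchtdi-tidiers
#' @export
tidy.power_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(
    term = c("b0", "b1"),
    estimate = c(x$b0, x$b1),
    std.error = c(x$b0 * sm[1, 2], sm[2, 2]),  # delta method for exp(b0_log)
    p.value = sm[, 4]
  )
}

#' @rdname twitchtdi-tidiers
#' @export
glance.power_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, statistic = x$f_statistic,
         p.value = x$p_value, nobs = x$n)
}

#' @rdname twitchtdi-tidiers
#' @export
tidy.rm_anova_result <- function(x, ...) {
  tibble(
    term = c("condition", "subject", "error"),
    sumsq = c(x$ss_condition, x$ss_subject, x$ss_error),
    df = c(x$df1, x$n_subjects - 1, x$df2),
    statistic = c(x$f_statistic, NA, NA),
    p.value = c(x$p_value, NA, NA)
  )
}

#' @rdname twitchtdi-tidiers
#' @export
glance.rm_anova_result <- function(x, ...) {
  tibble(statistic = x$f_statistic, df = x$df1, df.residual = x$df2,
         p.value = x$p_value, partial.eta.squared = x$partial_eta_squared)
}

#' @rdname twitchtdi-tidiers
#' @export
tidy.stepwise_model <- function(x, ...) {
  if (!length(x$selected_features)) {
    return(tibble(term = character(), estimate = double(),
                  std.error = double(), statistic = double(),
                  p.value = double()))
  }
  sm <- summary(x$fit)$coefficients
  rows <- x$selected_features
  tibble(term = rows, estimate = sm[rows, 1], std.error = sm[rows, 2],
         statistic = sm[rows, 3], p.value = sm[rows, 4])
}

#' @rdname twitchtdi-tidiers
#' @export
glance.stepwise_model <- function(x, ...) {
  tibble(r.squared = x$r_squared, p.value = x$overall_p, nobs = x$n,
         n.selected = length(x$selected_features))
}
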