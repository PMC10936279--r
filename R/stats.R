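#' Normalize study measures to each subject's baseline mean
#'
#' Divides every measure by that subject's mean value of the same measure
#' over its baseline (pre-fatigue) rows, so that baseline averages are 1 and
#' post-fatigue values are fractions of baseline.
#'
#' @param table A study/feature table with `subject` and `phase` columns
#'   (`phase == "baseline"` marks pre-fatigue rows).
#' @param measures Character vector of measure columns to normalize;
#'   defaults to the torque and feature columns present.
#' @return The table with the measure columns replaced by normalized
#'   values.
#' @export
normalize_to_baseline <- function(table,
                                  measures = intersect(
                                    c("torque_nm", "peak_velocity_mps",
                                      "time_to_zero_s", "total_duration_s",
                                      "peak_vti_m", "peak_strain_rate_per_s"),
                                    names(table))) {
  stopifnot(is.data.frame(table), all(c("subject", "phase") %in% names(table)),
            length(measures) > 0, all(measures %in% names(table)))
  for (s in unique(table$subject)) {
    base_rows <- table$subject == s & table$phase == "baseline"
    if (!any(base_rows)) {
      abort(sprintf("subject %s has no baseline rows.", s),
            class = "twitchtdi_invalid_argument")
    }
    for (m in measures) {
      mu <- mean(table[[m]][base_rows], na.rm = TRUE)
      if (!is.finite(mu) || mu == 0) {
        abort(sprintf(
          "cannot normalize measure `%s` for subject %s: baseline mean is %s.",
          m, s, ifelse(is.finite(mu), "zero", "not finite")),
          class = "twitchtdi_zero_baseline")
      }
      table[[m]][table$subject == s] <- table[[m]][table$subject == s] / mu
    }
  }
  table
}

#' Paired t-tests with Holm-Bonferroni correction
#'
#' Two-sided paired t-tests over a family of labelled comparisons, with the
#' Holm step-down adjustment (sorted raw p-values multiplied by m, m-1, ...,
#' cumulative-maximum enforced, capped at 1) and the paired Cohen's d
#' (mean difference / SD of differences).
#'
#' @param pairs A named list; each element a list/data frame with numeric
#'   `x` and `y` of equal length (>= 3 complete pairs).
#' @return A tibble with columns `label`, `n`, `mean_diff`, `t`, `df`,
#'   `p_raw`, `p_holm`, `cohens_d`.
#' @examples
#' holm_paired_tests(list(a = list(x = 1:5, y = c(2, 3, 3, 5, 6))))
#' @export
holm_paired_tests <- function(pairs) {
  stopifnot(is.list(pairs), length(pairs) > 0, !is.null(names(pairs)))
  rows <- purrr::imap(pairs, function(p, label) {
    x <- as.numeric(p$x)
    y <- as.numeric(p$y)
    keep <- complete.cases(x, y)
    x <- x[keep]
    y <- y[keep]
    if (length(x) < 3) {
      abort(sprintf("comparison `%s` has fewer than 3 complete pairs.", label),
            class = "twitchtdi_invalid_argument")
    }
    d <- x - y
    if (sd(d) == 0) {
      tt <- list(statistic = c(t = 0), parameter = c(df = length(d) - 1),
                 p.value = 1)
      cd <- 0
    } else {
      tt <- t.test(x, y, paired = TRUE)
      cd <- mean(d) / sd(d)
    }
    tibble(label = label, n = length(d), mean_diff = mean(d),
           t = unname(tt$statistic), df = unname(tt$parameter),
           p_raw = tt$p.value, cohens_d = cd)
  })
  out <- dplyr::bind_rows(rows)
  out$p_holm <- p.adjust(out$p_raw, method = "holm")
  out[, c("label", "n", "mean_diff", "t", "df", "p_raw", "p_holm", "cohens_d")]
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject one-way ANOVA on a complete subjects-by-conditions layout:
#' `F = MS_condition / MS_(condition x subject)` with `(k - 1)` and
#' `(k - 1)(n - 1)` degrees of freedom, and partial eta squared
#' `SS_condition / (SS_condition + SS_error)`. No sphericity correction is
#' applied. Missing cells are an error (no imputation).
#'
#' @param data Either a numeric matrix (subjects in rows, conditions in
#'   columns) or a long data frame.
#' @param value,subject,condition Column names (strings) when `data` is a
#'   long data frame.
#' @return An object of class `rm_anova_result` with fields `f_statistic`,
#'   `df1`, `df2`, `p_value`, `partial_eta_squared` and the component sums
#'   of squares; has [tidy()] and [glance()] methods.
#' @examples
#' m <- matrix(rnorm(20), nrow = 4)
#' rm_anova(m)
#' @export
rm_anova <- function(data, value = "value", subject = "subject",
                     condition = "condition") {
  if (is.data.frame(data)) {
    wide <- tidyr::pivot_wider(
      data[, c(subject, condition, value)],
      names_from = dplyr::all_of(condition),
      values_from = dplyr::all_of(value))
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- as.character(wide[[1]])
  } else {
    m <- as.matrix(data)
  }
  if (anyNA(m)) {
    abort("missing cells in the subjects x conditions matrix.",
          class = "twitchtdi_invalid_argument")
  }
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) {
    abort("need at least 2 subjects and 2 conditions.",
          class = "twitchtdi_invalid_argument")
  }
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  f <- if (ms_err > 0) ms_cond / ms_err else if (ms_cond == 0) 0 else Inf
  p <- pf(f, df1, df2, lower.tail = FALSE)
  pes <- if (ss_cond + ss_err > 0) ss_cond / (ss_cond + ss_err) else 0
  structure(
    list(f_statistic = f, df1 = df1, df2 = df2, p_value = p,
         partial_eta_squared = pes,
         ss_condition = ss_cond, ss_subject = ss_subj, ss_error = ss_err,
         n_subjects = n, n_conditions = k),
    class = "rm_anova_result"
  )
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf(
    "<rm_anova> F(%d, %d) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
    x$df1, x$df2, x$f_statistic, x$p_value, x$partial_eta_squared))
  invisible(x)
}

#' Fit a power-law recovery trend
#'
#' Fits `y = b0 * x^b1` by ordinary least squares on `log(y) ~ log(x)`
#' (deterministic, matching the reporting of the trend as a regression with
#' R-squared, F and p), back-transforming the intercept to `b0`. The model
#' describes the monotone return of a normalized measure toward baseline
#' over post-fatigue twitch index.
#'
#' @param x Twitch indices (all > 0), or a data frame with columns `x`, `y`.
#' @param y Normalized measure values (all > 0).
#' @return An object of class `power_fit` with fields `b0`, `b1`,
#'   `r_squared`, `f_statistic`, `p_value`, `n` and the underlying `lm`
#'   fit; has [tidy()] and [glance()] methods.
#' @examples
#' fit_power_trend(1:5, 0.614 * (1:5)^0.236)
#' @export
fit_power_trend <- function(x, y = NULL) {
  if (is.data.frame(x)) {
    y <- x$y
    x <- x$x
  }
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3) {
    abort("need at least 3 (x, y) pairs.",
          class = "twitchtdi_invalid_argument")
  }
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x <= 0) || any(y <= 0)) {
    abort("power trend requires finite, strictly positive x and y.",
          class = "twitchtdi_invalid_argument")
  }
  fit <- lm(log(y) ~ log(x))
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- if (is.null(fstat) || !is.finite(fstat[1])) NA_real_ else
    unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0   # zero-variance response: flat trend
  structure(
    list(b0 = unname(exp(coef(fit)[1])), b1 = unname(coef(fit)[2]),
         r_squared = r2,
         f_statistic = if (is.null(fstat) || !is.finite(fstat[1])) 0 else
           unname(fstat[1]),
         p_value = p, n = length(x), fit = fit),
    class = "power_fit"
  )
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf(
    "<power_fit> y = %.4g * x^%.4g  (R^2 = %.3f, F = %.3f, p = %.4g, n = %d)\n",
    x$b0, x$b1, x$r_squared, x$f_statistic, x$p_value, x$n))
  invisible(x)
}

#' Stepwise multiple linear regression with entry/removal p thresholds
#'
#' Forward-backward stepwise selection starting from the constant model:
#' at each step the candidate with the smallest partial-F p-value is added
#' if below `p_enter`, then any retained predictor whose p-value exceeds
#' `p_remove` is removed (largest first); iteration stops when neither
#' happens. Ties are broken by lower p, then by column order. Candidates
#' whose addition makes the design rank deficient are skipped with a
#' warning.
#'
#' @param data A data frame holding the response and candidate predictors.
#' @param response Name of the response column (e.g. recorded twitch torque).
#' @param predictors Character vector of candidate predictor columns
#'   (e.g. the five waveform features).
#' @param p_enter Entry threshold for the partial-F p-value.
#' @param p_remove Removal threshold.
#' @return An object of class `stepwise_model` with fields
#'   `selected_features` (in entry order), `coefficients`, `intercept`,
#'   `r_squared`, `overall_p`, `steps` (log tibble) and the final `lm`
#'   fit; has [tidy()] and [glance()] methods.
#' @examples
#' d <- data.frame(x1 = rnorm(30), x2 = rnorm(30))
#' d$y <- 2 * d$x1 + rnorm(30, sd = 0.1)
#' stepwise_regression(d, "y", c("x1", "x2"))
#' @export
stepwise_regression <- function(data, response, predictors,
                                p_enter = 0.05, p_remove = 0.10) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(predictors %in% names(data)))
  d <- data[, c(response, predictors)]
  if (!all(vapply(d, function(col) all(is.finite(col)), logical(1)))) {
    abort("non-finite values in response or predictors.",
          class = "twitchtdi_invalid_argument")
  }
  if (nrow(d) <= length(predictors) + 2) {
    abort("need more rows than candidate predictors + 2.",
          class = "twitchtdi_invalid_argument")
  }
  selected <- character(0)
  steps <- list()
  coef_p <- function(vars) {
    f <- stats::reformulate(if (length(vars)) vars else "1",
                            response = response)
    fit <- lm(f, data = d)
    pr <- summary(fit)$coefficients[, 4]
    list(fit = fit, p = pr[names(pr) != "(Intercept)"])
  }
  repeat {
    changed <- FALSE
    ## entry step
    candidates <- setdiff(predictors, selected)
    if (length(candidates)) {
      entry_p <- rep(NA_real_, length(candidates))
      for (i in seq_along(candidates)) {
        vars <- c(selected, candidates[i])
        fit <- lm(stats::reformulate(vars, response = response), data = d)
        if (anyNA(coef(fit))) {
          warn(sprintf("candidate `%s` makes the design rank deficient; skipped.",
                       candidates[i]))
          next
        }
        sm <- summary(fit)$coefficients
        entry_p[i] <- sm[candidates[i], 4]
      }
      if (any(!is.na(entry_p)) && min(entry_p, na.rm = TRUE) < p_enter) {
        best <- which(entry_p == min(entry_p, na.rm = TRUE))[1]
        selected <- c(selected, candidates[best])
        steps[[length(steps) + 1]] <- tibble(
          action = "add", feature = candidates[best], p = entry_p[best])
        changed <- TRUE
      }
    }
    ## removal step
    repeat {
      if (!length(selected)) break
      p <- coef_p(selected)$p
      p <- p[selected]  # guard against reordering
      if (max(p) > p_remove) {
        worst <- names(p)[which(p == max(p))[length(which(p == max(p)))]]
        selected <- setdiff(selected, worst)
        steps[[length(steps) + 1]] <- tibble(
          action = "remove", feature = worst, p = max(p))
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  final <- coef_p(selected)
  fit <- final$fit
  sm <- summary(fit)
  fstat <- sm$fstatistic
  overall_p <- if (is.null(fstat)) NA_real_ else
    unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(
    list(selected_features = selected,
         coefficients = coef(fit)[selected],
         intercept = unname(coef(fit)["(Intercept)"]),
         r_squared = sm$r.squared,
         overall_p = overall_p,
         n = nrow(d),
         steps = if (length(steps)) dplyr::bind_rows(steps) else
           tibble(action = character(), feature = character(), p = double()),
         fit = fit),
    class = "stepwise_model"
  )
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat("<stepwise_model>\n")
  if (length(x$selected_features)) {
    cat("  selected:", paste(x$selected_features, collapse = ", "), "\n")
    cat(sprintf("  R^2 = %.3f, overall p = %.4g, n = %d\n",
                x$r_squared, x$overall_p, x$n))
  } else {
    cat("  empty model (no feature met the entry threshold)\n")
  }
  invisible(x)
}
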