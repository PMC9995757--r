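#' Correlation screening of features against fall frequency
#'
#' Pearson correlations on pairwise-complete observations; features are
#' ranked by the absolute correlation with the outcome and the top `k`
#' returned in order.  A constant feature has undefined correlations
#' (`NA`), not zero.
#'
#' @param features Feature tibble (e.g. from
#'   [compile_feature_table()]); non-numeric columns are dropped.
#' @param outcome Name of the outcome column (default `"fall_freq"`).
#' @param k Number of top features to rank (default 10).
#' @return A `correlation_screen`: list with `matrix` (full pairwise
#'   correlation matrix), `ranking` (tibble `feature`, `r`), `outcome`.
#' @export
correlation_screen <- function(features, outcome = "fall_freq", k = 10) {
  features <- as_tibble(features)
  num <- features[, vapply(features, is.numeric, logical(1)), drop = FALSE]
  if (!outcome %in% names(num))
    abort(paste0("outcome column not found: ", outcome),
          class = "nearfallr_validation_error")
  if (sum(!is.na(num[[outcome]])) < 3)
    abort("need at least 3 subjects with a non-missing outcome",
          class = "nearfallr_validation_error")
  cm <- suppressWarnings(cor(as.matrix(num), use = "pairwise.complete.obs"))
  r_out <- cm[, outcome]
  cand <- setdiff(names(num), outcome)
  ord <- cand[order(abs(r_out[cand]), decreasing = TRUE, na.last = TRUE)]
  top <- head(ord, k)
  structure(list(matrix = cm,
                 ranking = tibble(feature = top, r = unname(r_out[top])),
                 outcome = outcome),
            class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat(sprintf("<correlation_screen> outcome=%s, %d features\n",
              x$outcome, ncol(x$matrix) - 1))
  print(x$ranking)
  invisible(x)
}

#' @export
tidy.correlation_screen <- function(x, ...) x$ranking

default_fall_terms <- function() {
  c("nfall_freq", "tot_num_abs", "sit_freq", "updrs_pull", "alpha_8")
}

#' Multivariable linear model of fall frequency
#'
#' Ordinary least squares of weekly fall frequency on five
#' home-monitoring and clinical features that are not highly correlated
#' with each other: near-fall frequency, number of ambulatory bouts,
#' sitting frequency, the UPDRS pull-test score and the bout-duration
#' power-law exponent (plus an intercept).  Complete cases only.
#'
#' @param data Feature tibble (one row per subject).
#' @param terms Regressor column names (default the five above).
#' @param outcome Outcome column name.
#' @return A `fall_model` object; see [tidy()], [glance()],
#'   [anova_summary()].
#' @export
fit_ols <- function(data, terms = default_fall_terms(),
                    outcome = "fall_freq") {
  data <- as_tibble(data)
  need <- c(outcome, terms)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0)
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "nearfallr_validation_error")
  cc <- complete.cases(data[, need])
  d <- data[cc, need]
  n <- nrow(d)
  p <- length(terms)
  if (n <= p + 1)
    abort(sprintf("need more subjects (n = %d) than terms + intercept (%d)",
                  n, p + 1),
          class = "nearfallr_validation_error")
  X <- cbind("(Intercept)" = 1, as.matrix(d[, terms]))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(aliased, collapse = ", ")),
          class = "nearfallr_collinearity_error")
  }
  fml <- stats::reformulate(terms, response = outcome)
  fit <- lm(fml, data = d)
  structure(list(lm = fit, terms = terms, outcome = outcome,
                 n = n, df_model = p, df_residual = n - p - 1),
            class = "fall_model")
}

#' @export
print.fall_model <- function(x, ...) {
  cat(sprintf("<fall_model> %s ~ %s  (n = %d)\n", x$outcome,
              paste(x$terms, collapse = " + "), x$n))
  print(tidy(x))
  invisible(x)
}

#' Per-term coefficient table of a fall model
#'
#' @param x A `fall_model`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `t_stat`
#'   (estimate / SE; `NA` when SE = 0), `p_value` (two-sided Student t
#'   on the residual df).
#' @export
tidy.fall_model <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  est <- s[, "Estimate"]
  se <- s[, "Std. Error"]
  tibble(term = rownames(s), estimate = unname(est),
         std_error = unname(se),
         t_stat = unname(term_t_statistics(est, se)),
         p_value = unname(ifelse(se == 0, NA_real_,
                                 2 * pt(-abs(est / se), x$df_residual))))
}

#' Model-level summary of a fall model
#'
#' @param x A `fall_model`.
#' @param ... Unused.
#' @return One-row tibble with `r_squared`, `adj_r_squared`, `sigma`,
#'   `f_stat`, `p_value`, `df_model`, `df_residual`, `n`.
#' @export
glance.fall_model <- function(x, ...) {
  a <- anova_summary(x)
  f <- a$f[a$source == "model"]
  tibble(r_squared = summary(x$lm)$r.squared,
         adj_r_squared = summary(x$lm)$adj.r.squared,
         sigma = summary(x$lm)$sigma,
         f_stat = f,
         p_value = a$p_value[a$source == "model"],
         df_model = x$df_model, df_residual = x$df_residual, n = x$n)
}

#' t statistics from estimates and standard errors
#'
#' Elementwise `estimate / SE`; a zero standard error yields `NA`.
#'
#' @param estimates,ses Equal-length numeric vectors (`ses >= 0`).
#' @return Numeric vector of t statistics.
#' @export
term_t_statistics <- function(estimates, ses) {
  if (length(estimates) != length(ses))
    abort("estimates and SEs must have the same length",
          class = "nearfallr_validation_error")
  if (any(ses < 0, na.rm = TRUE))
    abort("standard errors must be non-negative",
          class = "nearfallr_validation_error")
  ifelse(ses == 0, NA_real_, estimates / ses)
}

#' ANOVA decomposition of a fall model
#'
#' Total / model / residual sums of squares about the outcome mean,
#' mean squares (SumSq / df), the model F statistic
#' (MeanSq_model / MeanSq_residual) and its p-value on
#' (df_model, df_residual).  The decomposition satisfies
#' SumSq_total = SumSq_model + SumSq_residual.  A zero-residual fit has
#' an undefined F (`NA`).
#'
#' @param fit A `fall_model`.
#' @return Tibble with rows `total`, `model`, `residual` and columns
#'   `source`, `sumsq`, `df`, `meansq`, `f`, `p_value`.
#' @export
anova_summary <- function(fit) {
  stopifnot(inherits(fit, "fall_model"))
  y <- fit$lm$model[[1]]
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(stats::residuals(fit$lm)^2)
  ss_mod <- ss_tot - ss_res
  df_m <- fit$df_model
  df_r <- fit$df_residual
  ms_mod <- ss_mod / df_m
  ms_res <- ss_res / df_r
  f_stat <- if (ms_res == 0) NA_real_ else ms_mod / ms_res
  p_mod <- if (is.na(f_stat)) NA_real_ else pf(f_stat, df_m, df_r,
                                               lower.tail = FALSE)
  tibble(source = c("total", "model", "residual"),
         sumsq = c(ss_tot, ss_mod, ss_res),
         df = c(df_m + df_r, df_m, df_r),
         meansq = c(ss_tot / (df_m + df_r), ms_mod, ms_res),
         f = c(NA_real_, f_stat, NA_real_),
         p_value = c(NA_real_, p_mod, NA_real_))
}

#' Published reference fall-frequency regression
#'
#' The printed coefficient table (estimate, standard error, t, p) and
#' ANOVA summary (sums of squares, mean squares, F) of the
#' fall-frequency model fitted on the original 5-feature cohort data,
#' bundled as arithmetic-identity fixtures: `t = estimate / SE`,
#' `F = MeanSq_model / MeanSq_residual` and SumSq additivity must
#' reproduce the printed values.
#'
#' @return List with tibbles `terms` and `anova`.
#' @export
reference_fall_model <- function() {
  terms <- readr::read_csv(
    system.file("extdata", "reference_fall_model_terms.csv",
                package = "nearfallr"),
    col_types = readr::cols(term = readr::col_character(),
                            .default = readr::col_double()),
    progress = FALSE)
  anova <- readr::read_csv(
    system.file("extdata", "reference_fall_model_anova.csv",
                package = "nearfallr"),
    col_types = readr::cols(source = readr::col_character(),
                            .default = readr::col_double()),
    progress = FALSE)
  list(terms = terms, anova = anova)
}
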