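# Non-genetic comparator analyses: covariate-adjusted linear models,
# percentile-group descriptive tables and trend tests.

#' Covariate-adjusted observational association
#'
#' OLS of the outcome on the exposure and covariates on complete cases;
#' returns the exposure coefficient with normal-theory confidence interval
#' and p-value (z inference, appropriate at cohort scale).
#'
#' @param data Data frame.
#' @param outcome,exposure Column names.
#' @param covariates Character vector of covariate column names or `NULL`.
#' @return One-row tibble: `beta`, `se`, `ci_low`, `ci_high`, `p`, `n_used`,
#'   `covariates` (list column).
#' @export
multivariable_ols <- function(data, outcome, exposure, covariates = NULL) {
  used <- c(outcome, exposure, covariates)
  cc <- stats::complete.cases(data[, used, drop = FALSE])
  data <- data[cc, , drop = FALSE]
  y <- as.numeric(data[[outcome]])
  M <- cbind(exposure = as.numeric(data[[exposure]]),
             design_from(data, covariates))
  check_full_rank(M, "observational design")
  qf <- qr(M)
  b <- qr.coef(qf, y)
  e <- qr.resid(qf, y)
  sigma2 <- sum(e^2) / (length(y) - ncol(M))
  se <- sqrt(sigma2 * chol2inv(qr.R(qf))[1, 1])
  beta <- b[["exposure"]]
  tibble::tibble(beta = beta, se = se,
                 ci_low = beta - Z975 * se, ci_high = beta + Z975 * se,
                 p = two_sided_p(beta / se), n_used = length(y),
                 covariates = list(covariates %||% character(0)))
}

#' Group values by empirical percentile
#'
#' Labels each value by the right-closed percentile bin it falls in, with
#' default edges at the 50th, 75th, 90th and 95th percentiles (the
#' descriptive-table layout: 0-50, 51-75, 76-90, 91-95, 96-100).
#'
#' @param values Numeric vector (non-empty).
#' @param cuts Strictly increasing percentile edges within (0, 100).
#' @return Ordered factor of group labels, same length as `values`.
#' @export
percentile_grouping <- function(values, cuts = c(50, 75, 90, 95)) {
  if (length(values) == 0) abort("empty input.", class = "lvmr_data_error")
  if (any(diff(cuts) <= 0) || any(cuts <= 0) || any(cuts >= 100)) {
    abort("`cuts` must be strictly increasing within (0, 100).",
          class = "lvmr_config_error")
  }
  qs <- quantile(values, probs = cuts / 100, type = 7, na.rm = TRUE)
  if (anyDuplicated(qs)) {
    warn("tied percentile edges: degenerate grouping.")
    qs <- qs + seq_along(qs) * 0  # keep as-is; cut() below handles via unique
  }
  edges <- c(-Inf, unique(qs), Inf)
  lo <- c(0, cuts)
  hi <- c(cuts, 100)
  labels <- sprintf("%d%%-%d%%", ifelse(lo == 0, 0, lo + 1), hi)
  labels <- labels[seq_len(length(edges) - 1)]
  cut(values, breaks = edges, labels = labels, right = TRUE,
      include.lowest = TRUE, ordered_result = TRUE)
}

#' Cuzick trend test across ordered groups
#'
#' Rank-based extension of the Wilcoxon test to an ordered-group trend:
#' with group scores 1..G and midranks under ties, the statistic
#' `T = sum_g score_g * R_g` is standardized by its permutation-null mean
#' and variance (with the usual tie correction) and referred to the normal
#' distribution, two-sided.
#'
#' @param values Numeric vector.
#' @param groups Ordered factor (or coercible) of the same length; >= 2
#'   non-empty groups.
#' @return One-row tibble: `statistic` (z), `p`, `test_name`.
#' @export
cuzick_trend <- function(values, groups) {
  ok <- stats::complete.cases(values, groups)
  values <- values[ok]
  groups <- droplevels(as.ordered(groups[ok]))
  G <- nlevels(groups)
  if (G < 2) abort("need at least 2 non-empty groups.",
                   class = "lvmr_domain_error")
  n <- length(values)
  r <- rank(values)                       # midranks
  l <- as.integer(groups)                 # scores 1..G
  T_stat <- sum(l * r)
  ng <- tabulate(l, nbins = G)
  L <- sum(seq_len(G) * ng)
  E_T <- (n + 1) / 2 * L
  ties <- table(values)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  var_T <- (n + 1) / 12 * (n * sum(seq_len(G)^2 * ng) - L^2) * tie_corr
  z <- (T_stat - E_T) / sqrt(var_T)
  tibble::tibble(statistic = z, p = two_sided_p(z), test_name = "cuzick")
}

#' Chi-square test for trend in proportions (Cochran-Armitage)
#'
#' @param success_counts Successes per ordered group.
#' @param group_sizes Totals per group (all > 0).
#' @param scores Group scores (default 1..G).
#' @return One-row tibble: `statistic` (chi-squared, 1 df), `p`,
#'   `test_name`.
#' @export
chi2_trend <- function(success_counts, group_sizes,
                       scores = seq_along(success_counts)) {
  if (any(group_sizes <= 0)) {
    abort("zero-size group.", class = "lvmr_data_error")
  }
  if (any(success_counts > group_sizes)) {
    abort("counts exceed group sizes.", class = "lvmr_data_error")
  }
  tst <- suppressWarnings(
    prop.trend.test(success_counts, group_sizes, score = scores))
  tibble::tibble(statistic = unname(tst$statistic), p = tst$p.value,
                 test_name = "chi2_trend")
}

#' Descriptive table by exposure percentile group
#'
#' Summarizes each variable per percentile group of the exposure (mean, SD,
#' median, IQR bounds) with a Cuzick trend p-value, mirroring a baseline
#' demographics table.
#'
#' @param data Data frame.
#' @param exposure Column used for grouping.
#' @param variables Character vector of numeric columns to summarize.
#' @param cuts Percentile edges, as in [percentile_grouping()].
#' @return Tibble with one row per variable x group plus trend p.
#' @export
baseline_table <- function(data, exposure, variables,
                           cuts = c(50, 75, 90, 95)) {
  grp <- percentile_grouping(data[[exposure]], cuts = cuts)
  purrr::map_dfr(variables, function(v) {
    vals <- data[[v]]
    tr <- cuzick_trend(vals, grp)
    dplyr::bind_cols(
      tibble::tibble(variable = v, group = levels(grp)),
      purrr::map_dfr(levels(grp), function(g) {
        x <- vals[grp == g]
        tibble::tibble(n = sum(grp == g), mean = mean(x, na.rm = TRUE),
                       sd = sd(x, na.rm = TRUE),
                       median = median(x, na.rm = TRUE),
                       q25 = unname(quantile(x, 0.25, na.rm = TRUE)),
                       q75 = unname(quantile(x, 0.75, na.rm = TRUE)))
      }),
      tibble::tibble(trend_p = tr$p)
    )
  })
}
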