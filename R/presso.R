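# MR-PRESSO: residual-sum-of-squares global pleiotropy test, per-variant
# outlier detection and the distortion test. The null distribution is
# parametric: exposure effects are resampled from N(gamma, se_gamma) and
# outcome effects from N(gamma * beta_loo, se_Gamma) under the fitted
# no-pleiotropy model, with leave-one-out IVW slopes throughout so each
# variant never informs its own expected value.

# Leave-one-out fixed IVW slopes for each variant (vectorized).
loo_ivw <- function(gamma, Gamma, w) {
  s1 <- sum(w * gamma * Gamma)
  s2 <- sum(w * gamma^2)
  (s1 - w * gamma * Gamma) / (s2 - w * gamma^2)
}

#' MR-PRESSO pleiotropy residual sum and outlier test
#'
#' Three procedures: (1) the global test compares the observed weighted
#' residual sum of squares around leave-one-out IVW fits with its parametric
#' null distribution; (2) the outlier test flags variants whose observed
#' residual contribution exceeds its simulated null at a Bonferroni-adjusted
#' level; (3) the distortion test asks whether removing the flagged outliers
#' changes the IVW estimate more than removing an equally sized random
#' subset would.
#'
#' @param h A [harmonize()]d set with at least 4 variants.
#' @param n_sim Parametric simulations for the null (default 1000).
#' @param seed Simulation seed.
#' @param outlier_alpha Family-wise level for outlier flagging (default
#'   0.05, Bonferroni over variants).
#' @return A list of class `presso_result`: `global_rss`, `global_p`,
#'   `outlier_ids`, `beta_raw`, `beta_outlier_corrected`, `distortion_p`,
#'   `per_variant` tibble.
#' @export
mr_presso <- function(h, n_sim = 1000, seed = 1L, outlier_alpha = 0.05) {
  h <- h[h$gamma != 0, ]
  J <- nrow(h)
  if (J < 4) abort("MR-PRESSO needs at least 4 variants.",
                   class = "lvmr_method_minimum")
  w <- 1 / h$se_Gamma^2
  b_loo <- loo_ivw(h$gamma, h$Gamma, w)
  rss_j <- w * (h$Gamma - h$gamma * b_loo)^2
  rss_obs <- sum(rss_j)

  set.seed(seed)
  # n_sim x J draws under the fitted no-pleiotropy model
  Gm <- matrix(rnorm(n_sim * J, mean = rep(h$gamma, each = n_sim),
                     sd = rep(h$se_gamma, each = n_sim)), n_sim, J)
  Om <- matrix(rnorm(n_sim * J, mean = rep(h$gamma * b_loo, each = n_sim),
                     sd = rep(h$se_Gamma, each = n_sim)), n_sim, J)
  W <- matrix(w, n_sim, J, byrow = TRUE)
  s1 <- rowSums(W * Gm * Om)
  s2 <- rowSums(W * Gm^2)
  b_loo_sim <- (s1 - W * Gm * Om) / (s2 - W * Gm^2)
  rss_sim_j <- W * (Om - Gm * b_loo_sim)^2
  rss_sim <- rowSums(rss_sim_j)
  global_p <- (sum(rss_sim >= rss_obs) + 1) / (n_sim + 1)

  # Per-variant empirical p without the +1 continuity term: the Bonferroni
  # cut alpha/J must remain attainable at moderate n_sim.
  p_j <- colSums(rss_sim_j >= rep(rss_j, each = n_sim)) / n_sim
  is_outlier <- p_j < outlier_alpha / J
  if (all(is_outlier)) {
    abort("every variant flagged as an outlier; correction undefined.",
          class = "lvmr_degenerate_error")
  }
  outlier_ids <- h$variant_id[is_outlier]

  ivw_beta <- function(g, G, wt) sum(wt * g * G) / sum(wt * g^2)
  beta_raw <- ivw_beta(h$gamma, h$Gamma, w)
  beta_corr <- NA_real_
  distortion_p <- NA_real_
  n_out <- sum(is_outlier)
  if (n_out > 0) {
    keep <- which(!is_outlier)
    beta_corr <- ivw_beta(h$gamma[keep], h$Gamma[keep], w[keep])
    d_obs <- beta_raw - beta_corr
    # Expected distortion if the flagged slots held ordinary variants:
    # refill them by resampling from the non-outliers.
    d_null <- vapply(seq_len(n_sim), function(i) {
      fill <- sample(keep, n_out, replace = TRUE)
      idx <- c(keep, fill)
      ivw_beta(h$gamma[idx], h$Gamma[idx], w[idx]) - beta_corr
    }, numeric(1))
    distortion_p <- (sum(abs(d_null) >= abs(d_obs)) + 1) / (n_sim + 1)
  }
  structure(list(
    global_rss = rss_obs, global_p = global_p,
    outlier_ids = outlier_ids,
    beta_raw = beta_raw, beta_outlier_corrected = beta_corr,
    distortion_p = distortion_p,
    per_variant = tibble::tibble(variant_id = h$variant_id, rss = rss_j,
                                 p = p_j, outlier = is_outlier)
  ), class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("<presso_result> global RSS = %.3f, global p = %.4g\n",
              x$global_rss, x$global_p))
  cat(sprintf("  outliers: %s\n",
              if (length(x$outlier_ids) == 0) "none"
              else paste(x$outlier_ids, collapse = ", ")))
  if (!is.na(x$beta_outlier_corrected)) {
    cat(sprintf("  beta raw %.4f -> corrected %.4f (distortion p = %.4g)\n",
                x$beta_raw, x$beta_outlier_corrected, x$distortion_p))
  }
  invisible(x)
}

#' @export
tidy.presso_result <- function(x, ...) x$per_variant

#' @export
glance.presso_result <- function(x, ...) {
  tibble::tibble(global_rss = x$global_rss, global_p = x$global_p,
                 n_outliers = length(x$outlier_ids),
                 beta_raw = x$beta_raw,
                 beta_outlier_corrected = x$beta_outlier_corrected,
                 distortion_p = x$distortion_p)
}

#' MR-Steiger directionality test
#'
#' Compares the exposure and outcome variance explained by the instruments:
#' `r2_gx = sum_j 2 eaf_j (1 - eaf_j) gamma_j^2 / var_exposure` and the
#' analogue for the outcome. The causal direction exposure -> outcome is
#' supported when `r2_gx > r2_gy`; the p-value compares the
#' Fisher-transformed square-root correlations with variance
#' `1/(n_exposure - 3) + 1/(n_outcome - 3)`.
#'
#' @param h A [harmonize()]d set with an `eaf` column.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param var_exposure,var_outcome Trait variances (1 if standardized).
#' @return One-row tibble: `r2_gx`, `r2_gy`, `direction_correct`, `p`.
#' @export
mr_steiger <- function(h, n_exposure, n_outcome,
                       var_exposure = 1, var_outcome = 1) {
  v <- 2 * h$eaf * (1 - h$eaf)
  r2_gx <- sum(v * h$gamma^2) / var_exposure
  r2_gy <- sum(v * h$Gamma^2) / var_outcome
  if (r2_gx >= 1 || r2_gy >= 1) {
    abort("computed r-squared of 1 or more: inconsistent inputs.",
          class = "lvmr_data_error")
  }
  z <- (atanh(sqrt(r2_gx)) - atanh(sqrt(r2_gy))) /
    sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  tibble::tibble(
    r2_gx = r2_gx, r2_gy = r2_gy,
    direction_correct = if (r2_gx == r2_gy) NA else r2_gx > r2_gy,
    p = two_sided_p(z)
  )
}
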