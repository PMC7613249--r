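# Summary-statistic Mendelian randomization: harmonization, Wald ratios,
# IVW (fixed / multiplicative random-effects, robust, penalized), MR-Egger,
# weighted median and mode, and multivariable MR. MR-PRESSO and MR-Steiger
# live in their own files.

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

flip_strand <- function(a) unname(COMPLEMENT[a])

#' Harmonize exposure and outcome GWAS summary statistics
#'
#' Intersects variants by id and aligns outcome effects to the exposure
#' effect allele: a swapped effect/other coding flips the outcome beta sign
#' and complements its EAF; a strand flip (complement alleles) is resolved
#' the same way after complementing. Palindromic (A/T, C/G) variants whose
#' exposure EAF lies within `0.5 +/- palindrome_eaf_window` cannot be
#' oriented and are dropped. Variants whose allele pairs cannot be
#' reconciled are excluded per-variant (with a warning), never a global
#' failure.
#'
#' @param exposure,outcome GWAS summary tibbles (columns `variant_id`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, and optionally
#'   `p`, `n`).
#' @param palindrome_eaf_window Half-width of the ambiguous EAF zone around
#'   0.5 for palindromic variants (default 0.08).
#' @return A tibble of class `harmonized_set`, ordered by `variant_id`, with
#'   columns `variant_id`, `gamma`, `se_gamma` (variant-exposure), `Gamma`,
#'   `se_Gamma` (variant-outcome), `eaf`, `sign_flipped`. Dropped variants
#'   are recorded in `attr(, "dropped")`.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(shared) == 0) {
    abort("no shared variants between exposure and outcome sets.",
          class = "lvmr_data_error")
  }
  ex <- exposure[match(shared, exposure$variant_id), ]
  ou <- outcome[match(shared, outcome$variant_id), ]

  same <- ou$effect_allele == ex$effect_allele &
    ou$other_allele == ex$other_allele
  swapped <- ou$effect_allele == ex$other_allele &
    ou$other_allele == ex$effect_allele
  strand_same <- flip_strand(ou$effect_allele) == ex$effect_allele &
    flip_strand(ou$other_allele) == ex$other_allele
  strand_swapped <- flip_strand(ou$effect_allele) == ex$other_allele &
    flip_strand(ou$other_allele) == ex$effect_allele

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  ambiguous <- pal & abs(ex$eaf - 0.5) < palindrome_eaf_window
  # For palindromic variants "same" and "strand_swapped" coincide; outside
  # the ambiguous EAF zone, orient by EAF agreement.
  flip <- ifelse(pal, abs(ou$eaf - ex$eaf) > abs((1 - ou$eaf) - ex$eaf),
                 swapped | strand_swapped)
  recognized <- same | swapped | strand_same | strand_swapped

  drop_reason <- dplyr::case_when(
    !recognized ~ "allele_mismatch",
    ambiguous ~ "palindromic_ambiguous",
    TRUE ~ NA_character_
  )
  if (any(drop_reason %in% "allele_mismatch")) {
    warn(sprintf("%d variant(s) excluded: unresolvable allele coding.",
                 sum(drop_reason %in% "allele_mismatch")))
  }
  keep <- is.na(drop_reason)
  h <- tibble::tibble(
    variant_id = shared,
    gamma = ex$beta, se_gamma = ex$se,
    Gamma = ifelse(flip, -ou$beta, ou$beta),
    se_Gamma = ou$se,
    eaf = ex$eaf,
    sign_flipped = flip
  )
  dropped <- tibble::tibble(variant_id = shared[!keep],
                            reason = drop_reason[!keep])
  h <- h[keep, ]
  h <- h[order(h$variant_id), ]
  attr(h, "dropped") <- dropped
  class(h) <- c("harmonized_set", class(h))
  h
}

#' Per-variant Wald ratio estimates
#'
#' `ratio_j = Gamma_j / gamma_j` with first-order standard error
#' `se_Gamma_j / |gamma_j|`. Variants with a zero exposure effect are
#' excluded (warned).
#'
#' @param h A [harmonize()]d set.
#' @return Tibble: `variant_id`, `ratio`, `se`.
#' @export
wald_ratios <- function(h) {
  zero <- h$gamma == 0
  if (any(zero)) {
    warn(sprintf("%d variant(s) with zero exposure effect excluded.",
                 sum(zero)))
    h <- h[!zero, ]
  }
  tibble::tibble(variant_id = h$variant_id,
                 ratio = h$Gamma / h$gamma,
                 se = h$se_Gamma / abs(h$gamma))
}

mr_result_row <- function(method, beta, se, p = NULL, q = NA_real_,
                          n_variants, ...) {
  p <- p %||% two_sided_p(beta / se)
  out <- tibble::tibble(
    method = method, beta = beta, se = se,
    ci_low = beta - Z975 * se, ci_high = beta + Z975 * se,
    p = p, heterogeneity_q = q, n_variants = n_variants
  )
  extras <- list(...)
  for (nm in names(extras)) out[[nm]] <- extras[[nm]]
  class(out) <- c("mr_result", class(out))
  out
}

# Tukey-bisquare IRLS for weighted regression of Gamma on columns of X
# (no intercept unless a 1-column is included). Returns coefficients and the
# final robustness weights.
bisquare_irls <- function(X, y, w, c_tune = 4.685, tol = 1e-8,
                          max_iter = 200) {
  X <- as.matrix(X)
  sw <- sqrt(w)
  Xs <- X * sw
  ys <- y * sw
  beta <- qr.coef(qr(Xs), ys)
  for (it in seq_len(max_iter)) {
    r <- ys - drop(Xs %*% beta)
    s <- mad(r, center = 0)
    if (s < 1e-12) s <- sd(r)
    if (!is.finite(s) || s < 1e-12) break
    u <- r / (c_tune * s)
    rw <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (all(rw == 0)) break
    qrx <- qr(Xs * sqrt(rw))
    beta_new <- qr.coef(qrx, ys * sqrt(rw))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  r <- ys - drop(Xs %*% beta)
  s <- mad(r, center = 0)
  u <- r / (c_tune * max(s, 1e-12))
  rw <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  list(beta = beta, rob_weights = rw)
}

#' Inverse-variance-weighted MR
#'
#' Weighted regression of the variant-outcome effects on the
#' variant-exposure effects through the origin, weights `1/se_Gamma^2` --
#' algebraically the inverse-variance weighted mean of the per-variant Wald
#' ratios. `mode = "multiplicative_random"` (the default) inflates the
#' standard error by `max(1, sqrt(Q/(J-1)))` where Q is Cochran's
#' heterogeneity statistic. `penalized` down-weights variants with outlying
#' ratios by `min(1, 20 * q_j)` with `q_j` the upper chi-squared(1) tail of
#' the variant's Q contribution; `robust` replaces least squares by a
#' Tukey-bisquare M-estimator (tuning constant 4.685, tolerance 1e-8). The
#' robust penalized combination is the estimator used for headline
#' two-sample effects.
#'
#' @param h A [harmonize()]d set (>= 2 variants).
#' @param mode `"multiplicative_random"` or `"fixed"`.
#' @param robust,penalized Logical toggles, see Description.
#' @param penalty_scale Multiplier on the penalty p-value (default 20).
#' @param c_tune Tukey bisquare tuning constant (default 4.685).
#' @return One-row `mr_result` tibble.
#' @export
mr_ivw <- function(h, mode = c("multiplicative_random", "fixed"),
                   robust = FALSE, penalized = FALSE, penalty_scale = 20,
                   c_tune = 4.685) {
  mode <- match.arg(mode)
  h <- h[h$gamma != 0, ]
  J <- nrow(h)
  if (J < 2) abort("IVW needs at least 2 variants.", class = "lvmr_method_minimum")
  w <- 1 / h$se_Gamma^2
  beta_plain <- sum(w * h$gamma * h$Gamma) / sum(w * h$gamma^2)
  if (penalized) {
    ratio <- h$Gamma / h$gamma
    w_ratio <- h$gamma^2 / h$se_Gamma^2
    Qj <- w_ratio * (ratio - beta_plain)^2
    qp <- pchisq(Qj, df = 1, lower.tail = FALSE)
    w <- w * pmin(1, penalty_scale * qp)
  }
  if (robust) {
    fit <- bisquare_irls(matrix(h$gamma, ncol = 1), h$Gamma, w,
                         c_tune = c_tune)
    w_eff <- w * fit$rob_weights
    beta <- unname(fit$beta[1])
  } else {
    w_eff <- w
    beta <- sum(w * h$gamma * h$Gamma) / sum(w * h$gamma^2)
  }
  se <- 1 / sqrt(sum(w_eff * h$gamma^2))
  Q <- sum(w_eff * (h$Gamma - beta * h$gamma)^2)
  if (mode == "multiplicative_random" && J > 1) {
    se <- se * max(1, sqrt(Q / (J - 1)))
  }
  label <- paste0("ivw", if (robust) "_robust", if (penalized) "_penalized",
                  if (mode == "fixed") "_fixed")
  mr_result_row(label, beta, se, q = Q, n_variants = J)
}

#' MR-Egger regression
#'
#' Variants are oriented so every exposure effect is positive, then the
#' outcome effects are regressed on the exposure effects WITH an intercept,
#' weights `1/se_Gamma^2`. The slope is the pleiotropy-corrected causal
#' estimate; the intercept estimates directional pleiotropy, flagged when
#' its p-value is below `intercept_alpha` (default 0.10). Standard errors
#' use the multiplicative random-effects inflation `max(1, sqrt(Q/(J-2)))`.
#'
#' @param h A [harmonize()]d set (>= 3 variants).
#' @param intercept_alpha Pleiotropy-flag level for the intercept test.
#' @return One-row `mr_result` with `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_p`, `pleiotropy_flag`.
#' @export
mr_egger <- function(h, intercept_alpha = 0.10) {
  h <- h[h$gamma != 0, ]
  J <- nrow(h)
  if (J < 3) abort("MR-Egger needs at least 3 variants.",
                   class = "lvmr_method_minimum")
  flip <- h$gamma < 0
  g <- ifelse(flip, -h$gamma, h$gamma)
  G <- ifelse(flip, -h$Gamma, h$Gamma)
  w <- 1 / h$se_Gamma^2
  X <- cbind(intercept = 1, gamma = g)
  sw <- sqrt(w)
  qrx <- qr(X * sw)
  b <- qr.coef(qrx, G * sw)
  resid <- G * sw - drop((X * sw) %*% b)
  Q <- sum(resid^2)
  XtXinv <- chol2inv(qr.R(qrx))
  infl <- max(1, sqrt(Q / (J - 2)))
  ses <- sqrt(diag(XtXinv)) * infl
  mr_result_row("mr_egger", unname(b["gamma"]), ses[2], q = Q, n_variants = J,
                egger_intercept = unname(b["intercept"]),
                egger_intercept_se = ses[1],
                egger_intercept_p = two_sided_p(b["intercept"] / ses[1]),
                pleiotropy_flag = two_sided_p(b["intercept"] / ses[1]) <
                  intercept_alpha)
}

# Resample summary statistics from their sampling distributions; used for
# bootstrap SEs of the median and mode estimators.
boot_estimates <- function(h, n_boot, seed, estimator) {
  set.seed(seed)
  J <- nrow(h)
  vapply(seq_len(n_boot), function(b) {
    hb <- h
    hb$gamma <- rnorm(J, h$gamma, h$se_gamma)
    hb$Gamma <- rnorm(J, h$Gamma, h$se_Gamma)
    estimator(hb)
  }, numeric(1))
}

weighted_median_point <- function(ratio, weight) {
  o <- order(ratio)
  ratio <- ratio[o]
  w <- weight[o] / sum(weight)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(ratio[1])
  if (cum[length(cum)] <= 0.5) return(ratio[length(cum)])
  stats::approx(cum, ratio, xout = 0.5, ties = "ordered")$y
}

#' Weighted median MR estimator
#'
#' Consistent when at least half the total weight comes from valid
#' instruments. Ratios are ordered and the inverse-variance weighted
#' empirical quantile function is interpolated at cumulative weight one
#' half. The standard error comes from a parametric bootstrap that
#' resamples both summary-statistic sets from their normal sampling
#' distributions.
#'
#' @param h A [harmonize()]d set (>= 3 variants).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Bootstrap seed.
#' @return One-row `mr_result`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1L) {
  h <- h[h$gamma != 0, ]
  J <- nrow(h)
  if (J < 3) abort("weighted median needs at least 3 variants.",
                   class = "lvmr_method_minimum")
  point_of <- function(hh) {
    wr <- hh$Gamma / hh$gamma
    weight <- hh$gamma^2 / hh$se_Gamma^2
    weighted_median_point(wr, weight)
  }
  beta <- point_of(h)
  se <- sd(boot_estimates(h, n_boot, seed, point_of))
  mr_result_row("weighted_median", beta, se, n_variants = J)
}

weighted_mode_point <- function(ratio, weight, phi = 1, n_grid = 512) {
  if (length(unique(ratio)) == 1) return(ratio[1])
  w <- weight / sum(weight)
  s <- sqrt(sum(w * (ratio - sum(w * ratio))^2) * length(ratio) /
              max(length(ratio) - 1, 1))
  m <- mad(ratio)
  spread <- if (m > 0) min(s, m) else s
  bw <- phi * 0.9 * spread * length(ratio)^(-1 / 5)
  if (bw <= 0 || !is.finite(bw)) return(weighted_median_point(ratio, weight))
  grid <- seq(min(ratio) - 3 * bw, max(ratio) + 3 * bw, length.out = n_grid)
  dens <- drop(w %*% dnorm(outer(ratio, grid, "-") / bw)) # / bw constant
  grid[which.max(dens)]
}

#' Weighted mode MR estimator
#'
#' Consistent when the largest homogeneous cluster of variants is valid
#' (plurality validity). A normal-kernel density of the Wald ratios,
#' weighted by inverse ratio variance, is evaluated on a 512-point grid
#' spanning the ratios plus/minus three bandwidths; the estimate is the
#' density argmax. Bandwidth is `phi` times the modified Silverman rule
#' `0.9 * min(sd, mad) * J^(-1/5)`.
#'
#' @inheritParams mr_weighted_median
#' @param phi Bandwidth multiplier (default 1).
#' @return One-row `mr_result`.
#' @export
mr_weighted_mode <- function(h, phi = 1, n_boot = 1000, seed = 1L) {
  h <- h[h$gamma != 0, ]
  J <- nrow(h)
  if (J < 3) abort("weighted mode needs at least 3 variants.",
                   class = "lvmr_method_minimum")
  point_of <- function(hh) {
    wr <- hh$Gamma / hh$gamma
    weight <- hh$gamma^2 / hh$se_Gamma^2
    weighted_mode_point(wr, weight, phi = phi)
  }
  beta <- point_of(h)
  se <- sd(boot_estimates(h, n_boot, seed, point_of))
  mr_result_row("weighted_mode", beta, se, n_variants = J)
}

#' Multivariable MR
#'
#' Weighted multiple regression (no intercept) of the variant-outcome
#' effects on k variant-exposure effect columns, weights `1/se_Gamma^2`,
#' giving each exposure's direct effect conditional on the others. With
#' k = 1 this reduces exactly to fixed-effect IVW.
#'
#' @param data Tibble with one row per variant: outcome columns `Gamma`,
#'   `se_Gamma`, and one effect column per exposure named in `gamma_cols`.
#' @param gamma_cols Character vector of exposure effect column names.
#' @param mode SE mode as in [mr_ivw()].
#' @return `mr_result` tibble with one row per exposure.
#' @export
mr_mvmr <- function(data, gamma_cols,
                    mode = c("multiplicative_random", "fixed")) {
  mode <- match.arg(mode)
  k <- length(gamma_cols)
  J <- nrow(data)
  if (J < k + 1) abort("need more variants than exposures.",
                       class = "lvmr_method_minimum")
  X <- as.matrix(data[, gamma_cols, drop = FALSE])
  storage.mode(X) <- "double"
  if (qr(X)$rank < k) {
    abort("exposure effect matrix is rank deficient.",
          class = "lvmr_identification_error")
  }
  w <- 1 / data$se_Gamma^2
  sw <- sqrt(w)
  qrx <- qr(X * sw)
  b <- qr.coef(qrx, data$Gamma * sw)
  resid <- data$Gamma * sw - drop((X * sw) %*% b)
  Q <- sum(resid^2)
  XtXinv <- chol2inv(qr.R(qrx))
  infl <- if (mode == "multiplicative_random" && J > k) {
    max(1, sqrt(Q / (J - k)))
  } else 1
  ses <- sqrt(diag(XtXinv)) * infl
  out <- purrr::map_dfr(seq_len(k), function(i) {
    mr_result_row("mvmr", unname(b[i]), ses[i], q = Q, n_variants = J,
                  exposure = gamma_cols[i])
  })
  out
}

#' Rescale an MR estimate to different exposure units
#'
#' Multiplying the exposure scale by `factor` (e.g. one SD of the exposure
#' in mg/dl) multiplies the causal estimate and its uncertainty by the same
#' factor.
#'
#' @param result An `mr_result` (or any tibble with `beta`, `se`, `ci_low`,
#'   `ci_high`).
#' @param factor Positive scale factor.
#' @export
scale_estimate <- function(result, factor) {
  stopifnot(factor > 0)
  for (col in c("beta", "se", "ci_low", "ci_high")) {
    if (col %in% names(result)) result[[col]] <- result[[col]] * factor
  }
  result
}
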