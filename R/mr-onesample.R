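# Individual-level causal estimation: two-stage least squares with
# covariates, Durbin-Wu-Hausman endogeneity testing, multi-exposure
# adjustment, statin-interaction analysis and instrumental-variable power.

# Build a design matrix (with intercept) from covariate column names.
# Character/factor covariates are dummy-coded.
design_from <- function(data, covariates) {
  n <- nrow(data)
  if (is.null(covariates) || length(covariates) == 0) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  model.matrix(~ ., data = as.data.frame(data[, covariates, drop = FALSE]))
}

check_full_rank <- function(M, what) {
  q <- qr(M)
  if (q$rank < ncol(M)) {
    bad <- colnames(M)[q$pivot[(q$rank + 1):ncol(M)]]
    abort(paste0("rank-deficient ", what, ": ", paste(bad, collapse = ", ")),
          class = "lvmr_collinearity_error")
  }
  invisible(q)
}

# Core 2SLS on matrices: y (n), X (n x k endogenous), Z (n x k instruments),
# C covariate design incl. intercept. Just-identified.
tsls_fit_matrices <- function(y, X, Z, C, robust_se = FALSE) {
  n <- length(y)
  Zfull <- cbind(Z, C)
  colnames(Zfull) <- c(colnames(Z), colnames(C))
  check_full_rank(Zfull, "instrument design")
  # Stage 1: project each endogenous regressor on [instruments, covariates]
  qz <- qr(Zfull)
  Xhat <- qr.fitted(qz, X)
  W <- cbind(X, C)
  What <- cbind(Xhat, C)
  colnames(W) <- colnames(What) <- c(colnames(X), colnames(C))
  check_full_rank(What, "second-stage design")
  A <- crossprod(What)           # W' P_Z W (since What = P_Z W)
  Ainv <- solve(A)
  beta <- drop(Ainv %*% crossprod(What, y))
  names(beta) <- colnames(W)
  # Residuals at the point estimate use the OBSERVED exposures
  resid <- drop(y - W %*% beta)
  p <- ncol(W)
  if (robust_se) {
    meat <- crossprod(What * resid)
    vc <- Ainv %*% meat %*% Ainv
  } else {
    sigma2 <- sum(resid^2) / (n - p)
    vc <- sigma2 * Ainv
  }
  # First-stage partial F of the instruments given covariates, per exposure
  fs_f <- vapply(seq_len(ncol(X)), function(j) {
    r0 <- qr.resid(qr(C), X[, j])
    r1 <- qr.resid(qz, X[, j])
    q <- ncol(Z)
    ((sum(r0^2) - sum(r1^2)) / q) / (sum(r1^2) / (n - ncol(Zfull)))
  }, numeric(1))
  list(beta = beta, vcov = vc, resid = resid, n = n,
       first_stage_f = fs_f, qz = qz, endog = colnames(X))
}

#' One-sample Mendelian randomization by two-stage least squares
#'
#' Stage 1 regresses the exposure on the instrument (a genetic risk score)
#' and covariates; stage 2 regresses the outcome on the fitted exposure and
#' the same covariates. Standard errors follow the usual 2SLS convention:
#' residuals are taken at the point estimate with the observed (not fitted)
#' exposure. A weak-instrument warning fires when the first-stage partial F
#' is at most 10.
#'
#' @param data Data frame of complete cases.
#' @param outcome,exposure,instrument Column names (single strings).
#' @param covariates Character vector of covariate column names (may be
#'   `NULL`).
#' @param robust_se Use a heteroskedasticity-robust (HC0) variance instead of
#'   the homoskedastic default.
#' @return An object of class `tsls_fit`; use [tidy()] for the estimate
#'   tibble (`beta`, `se`, `ci_low`, `ci_high`, `p`, `n_used`,
#'   `first_stage_f`).
#' @export
tsls <- function(data, outcome, exposure, instrument, covariates = NULL,
                 robust_se = FALSE) {
  used <- c(outcome, exposure, instrument, covariates)
  cc <- stats::complete.cases(data[, used, drop = FALSE])
  data <- data[cc, , drop = FALSE]
  y <- as.numeric(data[[outcome]])
  X <- matrix(as.numeric(data[[exposure]]), ncol = 1,
              dimnames = list(NULL, exposure))
  Z <- matrix(as.numeric(data[[instrument]]), ncol = 1,
              dimnames = list(NULL, instrument))
  C <- design_from(data, covariates)
  fit <- tsls_fit_matrices(y, X, Z, C, robust_se = robust_se)
  if (fit$first_stage_f[1] <= 10) {
    warn(sprintf("weak instrument: first-stage F = %.2f <= 10",
                 fit$first_stage_f[1]))
  }
  structure(c(fit, list(outcome = outcome)), class = "tsls_fit")
}

#' Joint one-sample MR with several exposures and instruments
#'
#' Just-identified 2SLS with k endogenous exposures instrumented by k
#' genetic risk scores (e.g. all three lipid scores at once); per-exposure
#' estimates come from the joint covariance.
#'
#' @param data Data frame.
#' @param outcome Outcome column name.
#' @param exposures,instruments Character vectors of equal length k.
#' @inheritParams tsls
#' @return `tsls_fit` whose [tidy()] has one row per exposure.
#' @export
tsls_multi <- function(data, outcome, exposures, instruments,
                       covariates = NULL, robust_se = FALSE) {
  stopifnot(length(exposures) == length(instruments))
  used <- c(outcome, exposures, instruments, covariates)
  cc <- stats::complete.cases(data[, used, drop = FALSE])
  data <- data[cc, , drop = FALSE]
  y <- as.numeric(data[[outcome]])
  X <- as.matrix(data[, exposures, drop = FALSE]); storage.mode(X) <- "double"
  Z <- as.matrix(data[, instruments, drop = FALSE]); storage.mode(Z) <- "double"
  C <- design_from(data, covariates)
  qtest <- qr(cbind(Z, C))
  if (qtest$rank < ncol(Z) + ncol(C)) {
    abort("instruments are rank-deficient given covariates.",
          class = "lvmr_identification_error")
  }
  fit <- tsls_fit_matrices(y, X, Z, C, robust_se = robust_se)
  structure(c(fit, list(outcome = outcome)), class = "tsls_fit")
}

#' @export
tidy.tsls_fit <- function(x, ...) {
  idx <- match(x$endog, names(x$beta))
  beta <- x$beta[idx]
  se <- sqrt(diag(x$vcov)[idx])
  tibble::tibble(
    term = x$endog, beta = unname(beta), se = unname(se),
    ci_low = unname(beta - Z975 * se), ci_high = unname(beta + Z975 * se),
    p = two_sided_p(beta / se), n_used = x$n,
    first_stage_f = x$first_stage_f
  )
}

#' @export
glance.tsls_fit <- function(x, ...) {
  tibble::tibble(n_used = x$n, n_endogenous = length(x$endog),
                 min_first_stage_f = min(x$first_stage_f),
                 weak_instrument = min(x$first_stage_f) <= 10)
}

#' @export
print.tsls_fit <- function(x, ...) {
  cat("<tsls_fit> two-stage least squares\n")
  print(tidy(x))
  invisible(x)
}

#' Durbin-Wu-Hausman test of exposure endogeneity
#'
#' Augmented-regression form: the first-stage residual of the exposure on
#' the instrument and covariates is added to the outcome regression; the
#' statistic is the squared t on that residual term, referred to chi-squared
#' with 1 df. A small p indicates the observational (OLS) and instrumental
#' estimates disagree beyond sampling error.
#'
#' @inheritParams tsls
#' @return One-row tibble: `statistic`, `p`, `df`.
#' @export
durbin_wu_hausman <- function(data, outcome, exposure, instrument,
                              covariates = NULL) {
  used <- c(outcome, exposure, instrument, covariates)
  cc <- stats::complete.cases(data[, used, drop = FALSE])
  data <- data[cc, , drop = FALSE]
  y <- as.numeric(data[[outcome]])
  x <- as.numeric(data[[exposure]])
  z <- as.numeric(data[[instrument]])
  C <- design_from(data, covariates)
  vhat <- qr.resid(qr(cbind(z, C)), x)
  M <- cbind(x = x, vhat = vhat, C)
  check_full_rank(M, "augmented design")
  qf <- qr(M)
  b <- qr.coef(qf, y)
  e <- qr.resid(qf, y)
  sigma2 <- sum(e^2) / (length(y) - ncol(M))
  XtXinv <- chol2inv(qr.R(qf))
  se_v <- sqrt(sigma2 * XtXinv[2, 2])
  stat <- (b[["vhat"]] / se_v)^2
  tibble::tibble(statistic = stat,
                 p = pchisq(stat, df = 1, lower.tail = FALSE), df = 1L)
}

#' Statin-by-genetic-risk interaction on measured LDL
#'
#' OLS of the UNadjusted measured exposure on the standardized genetic risk
#' score, statin use, their product and covariates. A negative product
#' coefficient means statin users show a flatter score-exposure slope
#' (attenuated measured LDL per unit of genetic risk).
#'
#' @param data Data frame.
#' @param measured_exposure,score,statin Column names; `score` is
#'   standardized internally to mean 0, SD 1; `statin` must be logical/0-1
#'   with both strata present.
#' @param covariates Covariate column names or `NULL`.
#' @return One-row tibble: `interaction_beta`, `se`, `p`, `n_used`.
#' @export
interaction_test <- function(data, measured_exposure, score, statin,
                             covariates = NULL) {
  used <- c(measured_exposure, score, statin, covariates)
  cc <- stats::complete.cases(data[, used, drop = FALSE])
  data <- data[cc, , drop = FALSE]
  st <- as.numeric(as.logical(data[[statin]]))
  if (all(st == 0) || all(st == 1)) {
    abort("statin flag has a single stratum.", class = "lvmr_degenerate_error")
  }
  z <- as.numeric(scale(data[[score]]))
  M <- cbind(score = z, statin = st, interaction = z * st,
             design_from(data, covariates))
  qf <- qr(M)
  y <- as.numeric(data[[measured_exposure]])
  b <- qr.coef(qf, y)
  e <- qr.resid(qf, y)
  sigma2 <- sum(e^2) / (length(y) - ncol(M))
  XtXinv <- chol2inv(qr.R(qf))
  se <- sqrt(sigma2 * XtXinv[3, 3])
  tibble::tibble(interaction_beta = b[["interaction"]], se = se,
                 p = two_sided_p(b[["interaction"]] / se),
                 n_used = length(y))
}

#' Minimum detectable effect of an instrumental-variable analysis
#'
#' Closed-form approximation for a continuous outcome: the standardized
#' minimum effect is `(z_{1-alpha/2} + z_{power}) / sqrt(n * r2_gx)`, where
#' `r2_gx` is the exposure variance explained by the instrument; the natural
#' scale multiplies by `sd_outcome / sd_exposure`.
#'
#' @param n Sample size.
#' @param r2_gx Exposure variance explained by the instrument, in (0, 1).
#' @param alpha Two-sided type-I error (default 0.05).
#' @param power Target power (default 0.8).
#' @param sd_exposure,sd_outcome Natural-unit standard deviations.
#' @return Minimum detectable effect in outcome units per exposure unit.
#' @export
min_detectable_effect <- function(n, r2_gx, alpha = 0.05, power = 0.8,
                                  sd_exposure = 1, sd_outcome = 1) {
  if (r2_gx <= 0 || r2_gx >= 1) {
    abort("`r2_gx` must be in (0, 1).", class = "lvmr_domain_error")
  }
  beta_std <- (qnorm(1 - alpha / 2) + qnorm(power)) / sqrt(n * r2_gx)
  beta_std * sd_outcome / sd_exposure
}

#' @rdname min_detectable_effect
#' @param effect Effect size in outcome units per exposure unit.
#' @return `power_at_effect`: the power to detect `effect` at level `alpha`.
#' @export
power_at_effect <- function(effect, n, r2_gx, alpha = 0.05,
                            sd_exposure = 1, sd_outcome = 1) {
  if (r2_gx <= 0 || r2_gx >= 1) {
    abort("`r2_gx` must be in (0, 1).", class = "lvmr_domain_error")
  }
  beta_std <- abs(effect) * sd_exposure / sd_outcome
  pnorm(beta_std * sqrt(n * r2_gx) - qnorm(1 - alpha / 2))
}
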