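# Synthetic cohorts and two-sample GWAS summary statistics with known ground
# truth, so every downstream estimator can be checked by parameter recovery.
#
# Generative model:
#   X = G %*% gamma + a_x * U + eps_x          (exposure, e.g. lifetime LDL)
#   Y = beta * X + a_y * U + G %*% alpha + eps_y   (outcome, e.g. LV mass)
# with U a standard-normal unobserved confounder and alpha nonzero only for
# the invalid (pleiotropic) fraction of variants. Dosages are Binomial(2, MAF)
# (Hardy-Weinberg). Statin users' measured exposure is the true exposure
# divided by the LDL reduction factor, so the multiplicative statin
# adjustment is its exact inverse.

#' Simulation parameters with study-scale defaults
#'
#' Defaults emulate the cohort the package is aimed at: about 17,000
#' individuals with ~100 independent biallelic variants whose weighted score
#' explains 10.8% of exposure variance (the LDL instrument; 7.3% and 5.0%
#' correspond to HDL and triglycerides), an unobserved confounder able to
#' flip the observational sign, and statin use that rises with genetic risk.
#' Under the defaults the omitted-variable bias of the naive regression is
#' `a_x * a_y * (1 - R2) / (a_x^2 + noise_sd_exposure^2)` = -0.71, larger in
#' magnitude than the causal effect +0.5, so the observational estimate is
#' sign-flipped by construction.
#'
#' @param n_individuals Cohort size.
#' @param n_variants Number of instrument variants.
#' @param maf_range Minor-allele-frequency range, within (0, 0.5].
#' @param causal_beta True causal effect of exposure on outcome
#'   (outcome units per exposure unit).
#' @param confounder_loadings Length-2 numeric `c(a_x, a_y)`: loadings of the
#'   standard-normal confounder on exposure and outcome.
#' @param pleiotropy List: `fraction_invalid` in \[0,1\], `mean` and `sd` of
#'   the direct variant-outcome effects for invalid variants.
#' @param noise_sd_exposure,noise_sd_outcome Residual standard deviations.
#' @param exposure_mean Location of the exposure (an LDL-like positive
#'   offset so multiplicative treatment adjustments stay in-domain); effects
#'   and estimators are invariant to it.
#' @param target_r2 Fraction of exposure variance explained by the true
#'   genetic score, in (0, 1).
#' @param palindromic_fraction Fraction of variants drawn with A/T or C/G
#'   allele pairs (exercises harmonization).
#' @param statin_model List: logistic `intercept`, `slope` on the
#'   standardized true score, and `ldl_reduction_factor` dividing true
#'   exposure to give the measured value for statin users.
#' @param seed Master integer seed; all stage streams derive from it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_individuals = 17000,
                       n_variants = 101,
                       maf_range = c(0.05, 0.5),
                       causal_beta = 0.5,
                       confounder_loadings = c(a_x = 1, a_y = -1),
                       pleiotropy = list(fraction_invalid = 0, mean = 0, sd = 0),
                       noise_sd_exposure = 0.5,
                       noise_sd_outcome = 1,
                       exposure_mean = 150,
                       target_r2 = 0.108,
                       palindromic_fraction = 0.15,
                       statin_model = list(intercept = -1.6, slope = 0.5,
                                           ldl_reduction_factor = 1.43),
                       seed = 1L) {
  stopifnot(length(maf_range) == 2)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] >= maf_range[2]) {
    abort("`maf_range` must be increasing within (0, 0.5].",
          class = "lvmr_config_error")
  }
  if (target_r2 <= 0 || target_r2 >= 1) {
    abort("`target_r2` must be in (0, 1).", class = "lvmr_config_error")
  }
  if (pleiotropy$fraction_invalid < 0 || pleiotropy$fraction_invalid > 1) {
    abort("`fraction_invalid` must be in [0, 1].", class = "lvmr_config_error")
  }
  structure(list(
    n_individuals = n_individuals, n_variants = n_variants,
    maf_range = maf_range, causal_beta = causal_beta,
    confounder_loadings = confounder_loadings, pleiotropy = pleiotropy,
    noise_sd_exposure = noise_sd_exposure, noise_sd_outcome = noise_sd_outcome,
    exposure_mean = exposure_mean,
    target_r2 = target_r2, palindromic_fraction = palindromic_fraction,
    statin_model = statin_model, seed = as.integer(seed)
  ), class = "sim_params")
}

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Simulate an instrument variant panel
#'
#' Draws MAFs uniformly in `maf_range`, allele pairs with a configurable
#' palindromic (A/T, C/G) fraction, and per-allele exposure effects `gamma`
#' from N(0, effect_sd), optionally rescaled so the weighted score explains
#' `target_r2` of exposure variance given non-genetic variance
#' `nongenetic_var`.
#'
#' @param n_variants Panel size (>= 1).
#' @param maf_range MAF bounds within (0, 0.5].
#' @param effect_sd SD of raw per-allele effects.
#' @param seed Integer seed.
#' @param palindromic_fraction Fraction of A/T or C/G pairs.
#' @param target_r2 Optional target exposure variance explained.
#' @param nongenetic_var Non-genetic exposure variance used in the rescaling
#'   (confounder plus residual), default 1.
#' @return Tibble: `variant_id`, `effect_allele`, `other_allele`, `maf`,
#'   `gamma`.
#' @export
simulate_variants <- function(n_variants, maf_range = c(0.05, 0.5),
                              effect_sd = 0.1, seed = 1L,
                              palindromic_fraction = 0,
                              target_r2 = NULL, nongenetic_var = 1) {
  stopifnot(n_variants >= 1)
  if (maf_range[1] >= maf_range[2]) {
    abort("`maf_range` must be strictly increasing.", class = "lvmr_config_error")
  }
  set.seed(derive_seed(seed, 11))
  maf <- runif(n_variants, maf_range[1], maf_range[2])
  n_pal <- round(palindromic_fraction * n_variants)
  is_pal <- seq_len(n_variants) %in% sample.int(n_variants, n_pal)
  ea <- character(n_variants)
  oa <- character(n_variants)
  for (j in seq_len(n_variants)) {
    if (is_pal[j]) {
      ea[j] <- sample(BASES, 1)
      oa[j] <- unname(COMPLEMENT[ea[j]])
    } else {
      pair <- sample(BASES, 2)
      while (COMPLEMENT[pair[1]] == pair[2]) pair <- sample(BASES, 2)
      ea[j] <- pair[1]; oa[j] <- pair[2]
    }
  }
  gamma <- rnorm(n_variants, 0, effect_sd)
  if (!is.null(target_r2)) {
    v_score <- sum(2 * maf * (1 - maf) * gamma^2)
    v_target <- target_r2 * nongenetic_var / (1 - target_r2)
    gamma <- gamma * sqrt(v_target / v_score)
  }
  tibble::tibble(
    variant_id = sprintf("rs%05d", seq_len(n_variants)),
    effect_allele = ea, other_allele = oa, maf = maf, gamma = gamma
  )
}

# Draw pleiotropic direct effects: nonzero only for the invalid fraction.
draw_alpha <- function(n_variants, pleiotropy, seed) {
  set.seed(derive_seed(seed, 13))
  alpha <- numeric(n_variants)
  n_inv <- round(pleiotropy$fraction_invalid * n_variants)
  if (n_inv > 0) {
    idx <- sample.int(n_variants, n_inv)
    alpha[idx] <- rnorm(n_inv, pleiotropy$mean, pleiotropy$sd)
  }
  alpha
}

# Hardy-Weinberg dosage matrix, individuals x variants.
draw_dosages <- function(n, maf, seed) {
  set.seed(derive_seed(seed, 17))
  m <- length(maf)
  matrix(rbinom(n * m, 2L, rep(maf, each = n)), nrow = n, ncol = m)
}

simulate_covariates <- function(n, seed) {
  set.seed(derive_seed(seed, 19))
  sex <- ifelse(runif(n) < 0.46, "male", "female")
  height <- rnorm(n, ifelse(sex == "male", 175, 162), 7)
  bmi <- rlnorm(n, log(27), 0.15)
  weight <- bmi * (height / 100)^2
  on_aht <- runif(n) < 0.23
  tibble::tibble(
    age = pmin(pmax(rnorm(n, 57.5, 7.5), 40), 70),
    sex = sex, height = height, weight = weight, bmi = bmi,
    bsa = bsa_dubois(height, weight),
    sbp = rnorm(n, 138, 18),
    on_antihypertensive = on_aht,
    met_min_week = pmax(rlnorm(n, log(1500), 1) - 100, 0),
    smoking = sample(c("never", "former", "current"), n, TRUE,
                     prob = c(0.55, 0.35, 0.10)),
    hba1c = rlnorm(n, log(35.5), 0.08),
    cvd_present = runif(n) < 0.06,
    pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n), pc4 = rnorm(n),
    pc5 = rnorm(n)
  )
}

#' Simulate an individual-level cohort with known causal truth
#'
#' @param params A [sim_params()] object.
#' @return A list of class `synthetic_cohort` with elements `participants`
#'   (tibble: exposure_true, exposure_measured, outcome, confounder, score,
#'   on_statin, covariates), `dosages` (n x m matrix), `variants` (panel
#'   tibble with true `gamma` and `alpha`), and `truth` (the params).
#' @export
simulate_cohort <- function(params = sim_params()) {
  p <- params
  a_x <- p$confounder_loadings[[1]]
  a_y <- p$confounder_loadings[[2]]
  nongenetic_var <- a_x^2 + p$noise_sd_exposure^2
  variants <- simulate_variants(
    p$n_variants, p$maf_range, effect_sd = 0.1, seed = p$seed,
    palindromic_fraction = p$palindromic_fraction,
    target_r2 = p$target_r2, nongenetic_var = nongenetic_var
  )
  variants$alpha <- draw_alpha(p$n_variants, p$pleiotropy, p$seed)
  G <- draw_dosages(p$n_individuals, variants$maf, p$seed)
  colnames(G) <- variants$variant_id
  set.seed(derive_seed(p$seed, 23))
  n <- p$n_individuals
  U <- rnorm(n)
  score <- drop(G %*% variants$gamma)
  x <- p$exposure_mean + score + a_x * U + rnorm(n, 0, p$noise_sd_exposure)
  y <- p$causal_beta * x + a_y * U + drop(G %*% variants$alpha) +
    rnorm(n, 0, p$noise_sd_outcome)
  z_score <- (score - mean(score)) / sd(score)
  sm <- p$statin_model
  on_statin <- runif(n) < stats::plogis(sm$intercept + sm$slope * z_score)
  x_meas <- ifelse(on_statin, x / sm$ldl_reduction_factor, x)
  participants <- dplyr::bind_cols(
    tibble::tibble(
      id = sprintf("ind%05d", seq_len(n)),
      exposure_true = x, exposure_measured = x_meas, outcome = y,
      confounder = U, score = score, on_statin = on_statin
    ),
    simulate_covariates(n, p$seed)
  )
  structure(list(participants = participants, dosages = G,
                 variants = variants, truth = p),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d individuals x %d variants (causal beta = %g, target R2 = %g)\n",
    nrow(x$participants), nrow(x$variants),
    x$truth$causal_beta, x$truth$target_r2))
  invisible(x)
}

# Per-variant simple-regression summary statistics of `trait` on each dosage
# column, vectorized over variants.
summary_stats_from <- function(G, trait, variants, n_label = nrow(G)) {
  n <- nrow(G)
  gc_ <- scale(G, center = TRUE, scale = FALSE)
  tc <- trait - mean(trait)
  sxx <- colSums(gc_^2)
  beta <- colSums(gc_ * tc) / sxx
  sse <- sum(tc^2) - beta^2 * sxx
  se <- sqrt(pmax(sse, 0) / (n - 2) / sxx)
  pval <- pmax(two_sided_p(beta / se), 1e-300)
  tibble::tibble(
    variant_id = variants$variant_id,
    effect_allele = variants$effect_allele,
    other_allele = variants$other_allele,
    eaf = colMeans(G) / 2,
    beta = beta, se = se, p = pval, n = n_label
  )
}

#' Simulate two-sample GWAS summary statistics
#'
#' Generates two independent cohorts under the same generative truth
#' (variant panel, causal effect, pleiotropy) and returns per-variant
#' variant-exposure and variant-outcome summary statistics, as a two-sample
#' Mendelian-randomization analysis would consume. In `analytic` mode the
#' noiseless population values are returned with a vanishing standard error,
#' so ratio identities hold exactly.
#'
#' @param params A [sim_params()] object.
#' @param n_exposure,n_outcome Sample sizes of the two non-overlapping GWAS.
#' @param analytic If `TRUE`, return exact population betas with
#'   `se = analytic_se`.
#' @param analytic_se Standard error reported in analytic mode.
#' @param scramble_fraction Fraction of outcome-side variants whose allele
#'   coding is swapped (beta negated, EAF complemented) to exercise
#'   harmonization.
#' @return List with tibbles `exposure` and `outcome` (GWAS summary layout:
#'   variant_id, effect_allele, other_allele, eaf, beta, se, p, n) and the
#'   `variants` truth panel.
#' @export
simulate_two_sample <- function(params = sim_params(),
                                n_exposure = 188577, n_outcome = 16923,
                                analytic = FALSE, analytic_se = 1e-8,
                                scramble_fraction = 0) {
  p <- params
  a_x <- p$confounder_loadings[[1]]
  nongenetic_var <- a_x^2 + p$noise_sd_exposure^2
  variants <- simulate_variants(
    p$n_variants, p$maf_range, effect_sd = 0.1, seed = p$seed,
    palindromic_fraction = p$palindromic_fraction,
    target_r2 = p$target_r2, nongenetic_var = nongenetic_var
  )
  variants$alpha <- draw_alpha(p$n_variants, p$pleiotropy, p$seed)

  if (analytic) {
    exp_ss <- tibble::tibble(
      variant_id = variants$variant_id,
      effect_allele = variants$effect_allele,
      other_allele = variants$other_allele,
      eaf = variants$maf, beta = variants$gamma, se = analytic_se,
      p = pmax(two_sided_p(variants$gamma / analytic_se), 1e-300),
      n = n_exposure
    )
    gam_out <- p$causal_beta * variants$gamma + variants$alpha
    out_ss <- exp_ss
    out_ss$beta <- gam_out
    out_ss$p <- pmax(two_sided_p(gam_out / analytic_se), 1e-300)
    out_ss$n <- n_outcome
  } else {
    sim_one <- function(n, seed_off, keep = c("exposure", "outcome")) {
      keep <- match.arg(keep)
      G <- draw_dosages(n, variants$maf, derive_seed(p$seed, seed_off))
      set.seed(derive_seed(p$seed, seed_off + 1))
      U <- rnorm(n)
      x <- drop(G %*% variants$gamma) + a_x * U +
        rnorm(n, 0, p$noise_sd_exposure)
      if (keep == "exposure") return(summary_stats_from(G, x, variants, n))
      y <- p$causal_beta * x + p$confounder_loadings[[2]] * U +
        drop(G %*% variants$alpha) + rnorm(n, 0, p$noise_sd_outcome)
      summary_stats_from(G, y, variants, n)
    }
    exp_ss <- sim_one(n_exposure, 101, "exposure")
    out_ss <- sim_one(n_outcome, 201, "outcome")
  }

  if (scramble_fraction > 0) {
    set.seed(derive_seed(p$seed, 31))
    k <- sample.int(nrow(out_ss), round(scramble_fraction * nrow(out_ss)))
    ea <- out_ss$effect_allele[k]
    out_ss$effect_allele[k] <- out_ss$other_allele[k]
    out_ss$other_allele[k] <- ea
    out_ss$beta[k] <- -out_ss$beta[k]
    out_ss$eaf[k] <- 1 - out_ss$eaf[k]
  }
  list(exposure = exp_ss, outcome = out_ss, variants = variants)
}

#' Write / read a synthetic cohort as CSV plus a JSON truth sidecar
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort` invisibly returns the paths written;
#'   `read_cohort` returns the reconstructed `synthetic_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    participants = file.path(dir, "participants.csv"),
    dosages = file.path(dir, "dosages.csv"),
    variants = file.path(dir, "variants.csv"),
    truth = file.path(dir, "truth.json")
  )
  utils::write.csv(cohort$participants, paths$participants, row.names = FALSE)
  utils::write.csv(as.data.frame(cohort$dosages), paths$dosages,
                   row.names = FALSE)
  utils::write.csv(cohort$variants, paths$variants, row.names = FALSE)
  jsonlite::write_json(unclass(cohort$truth), paths$truth,
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  participants <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "participants.csv")))
  dosages <- as.matrix(utils::read.csv(file.path(dir, "dosages.csv"),
                                       check.names = FALSE))
  variants <- tibble::as_tibble(utils::read.csv(file.path(dir, "variants.csv")))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  truth$confounder_loadings <- unlist(truth$confounder_loadings)
  truth$seed <- as.integer(truth$seed)
  class(truth) <- "sim_params"
  structure(list(participants = participants, dosages = dosages,
                 variants = variants, truth = truth),
            class = "synthetic_cohort")
}

#' Write GWAS summary statistics as TSV
#' @param ss A GWAS summary tibble.
#' @param path Output file path.
#' @export
write_gwas_summary <- function(ss, path) {
  utils::write.table(ss, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gwas_summary
#' @export
read_gwas_summary <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}
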