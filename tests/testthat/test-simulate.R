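test_that("variant panel generation is deterministic and honours options", {
  v1 <- simulate_variants(101, seed = 3, palindromic_fraction = 0)
  v2 <- simulate_variants(101, seed = 3, palindromic_fraction = 0)
  expect_identical(v1, v2)
  expect_false(any((v1$effect_allele == "A" & v1$other_allele == "T") |
                   (v1$effect_allele == "T" & v1$other_allele == "A") |
                   (v1$effect_allele == "C" & v1$other_allele == "G") |
                   (v1$effect_allele == "G" & v1$other_allele == "C")))
  v3 <- simulate_variants(100, seed = 3, palindromic_fraction = 0.2)
  pal <- (v3$effect_allele == "A" & v3$other_allele == "T") |
    (v3$effect_allele == "T" & v3$other_allele == "A") |
    (v3$effect_allele == "C" & v3$other_allele == "G") |
    (v3$effect_allele == "G" & v3$other_allele == "C")
  expect_equal(sum(pal), 20)
  expect_error(simulate_variants(10, maf_range = c(0.4, 0.1)),
               class = "lvmr_config_error")
})

test_that("cohort dosages respect Hardy-Weinberg structure", {
  cohort <- simulate_cohort(sim_params(n_individuals = 10000, n_variants = 30,
                                       seed = 5))
  G <- cohort$dosages
  expect_true(all(G >= 0 & G <= 2))
  # column means approximate 2*MAF
  expect_equal(unname(colMeans(G)), 2 * cohort$variants$maf,
               tolerance = 0.05)
  # genotype frequencies within chi-square 99% bounds
  p_hwe <- vapply(seq_len(ncol(G)), function(j) {
    obs <- tabulate(G[, j] + 1, nbins = 3)
    maf <- cohort$variants$maf[j]
    expd <- nrow(G) * c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
    stats::pchisq(sum((obs - expd)^2 / expd), df = 2, lower.tail = FALSE)
  }, numeric(1))
  expect_gt(min(p_hwe), 0.01 / 30)  # no column grossly out of HWE
})

test_that("realized score R2 tracks the generative target across seeds", {
  r2s <- vapply(1:20, function(s) {
    cohort <- simulate_cohort(sim_params(n_individuals = 17000, seed = s,
                                         target_r2 = 0.108))
    pts <- cohort$participants
    summary(lm(pts$exposure_true ~ pts$score))$r.squared
  }, numeric(1))
  expect_gt(mean(r2s), 0.098)
  expect_lt(mean(r2s), 0.118)
  # each realization stays within sampling error of the target
  expect_true(all(abs(r2s - 0.108) < 0.02))
})

test_that("pure-null cohort shows no score-outcome correlation", {
  p <- sim_params(n_individuals = 8000, causal_beta = 0,
                  confounder_loadings = c(0, 0), seed = 11)
  cohort <- simulate_cohort(p)
  pts <- cohort$participants
  expect_lt(abs(cor(pts$score, pts$outcome)), 3 / sqrt(nrow(pts)))
})

test_that("confounding biases the naive slope per the closed form", {
  p <- sim_params(n_individuals = 20000, causal_beta = 0.5,
                  confounder_loadings = c(a_x = 1, a_y = -1), seed = 13)
  cohort <- simulate_cohort(p)
  pts <- cohort$participants
  ols <- coef(lm(outcome ~ exposure_true, data = pts))[2]
  expected <- 0.5 + (1 * -1) * 1 / var(pts$exposure_true)
  expect_equal(unname(ols), expected, tolerance = 0.05)
  expect_lt(ols, 0)  # sign-flipped relative to +0.5 under the defaults
})

test_that("statin users show attenuated measured exposure", {
  cohort <- simulate_cohort(sim_params(n_individuals = 10000, seed = 17))
  pts <- cohort$participants
  expect_gt(mean(pts$on_statin), 0.05)
  u <- pts$on_statin
  expect_lt(mean(pts$exposure_measured[u]), mean(pts$exposure_true[u]))
  expect_equal(pts$exposure_measured[u] * 1.43, pts$exposure_true[u])
  expect_equal(pts$exposure_measured[!u], pts$exposure_true[!u])
})

test_that("two-sample summaries recover the ratio identity and pleiotropy", {
  p <- sim_params(n_variants = 40, causal_beta = 0.7, seed = 19)
  ts <- simulate_two_sample(p, analytic = TRUE)
  expect_equal(ts$outcome$beta / ts$exposure$beta,
               rep(0.7, 40), tolerance = 1e-12)
  # directional pleiotropy shifts outcome effects by its mean
  p2 <- sim_params(n_variants = 200, causal_beta = 0.5,
                   pleiotropy = list(fraction_invalid = 1, mean = 0.05,
                                     sd = 0.005), seed = 23)
  ts2 <- simulate_two_sample(p2, analytic = TRUE)
  expect_equal(mean(ts2$outcome$beta - 0.5 * ts2$exposure$beta), 0.05,
               tolerance = 0.005)
  # allele scrambling flips signs and complements EAF
  ts3 <- simulate_two_sample(sim_params(n_variants = 30, seed = 29),
                             n_exposure = 2000, n_outcome = 2000,
                             scramble_fraction = 0.5)
  ts3_clean <- simulate_two_sample(sim_params(n_variants = 30, seed = 29),
                                   n_exposure = 2000, n_outcome = 2000)
  swapped <- ts3$outcome$effect_allele != ts3_clean$outcome$effect_allele
  expect_equal(sum(swapped), 15)
  expect_equal(ts3$outcome$beta[swapped], -ts3_clean$outcome$beta[swapped])
  expect_equal(ts3$outcome$eaf[swapped], 1 - ts3_clean$outcome$eaf[swapped])
})

test_that("cohort serialization round-trips the generating truth", {
  cohort <- simulate_cohort(sim_params(n_individuals = 50, n_variants = 5,
                                       seed = 31))
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_equal(back$truth$causal_beta, cohort$truth$causal_beta)
  expect_equal(back$truth$target_r2, cohort$truth$target_r2)
  expect_equal(unname(back$truth$confounder_loadings),
               unname(cohort$truth$confounder_loadings))
  expect_equal(back$dosages, cohort$dosages, ignore_attr = TRUE)
  expect_equal(back$variants$gamma, cohort$variants$gamma)
})

test_that("GWAS summary p-values are consistent with beta/se", {
  ts <- simulate_two_sample(sim_params(n_variants = 20, seed = 37),
                            n_exposure = 3000, n_outcome = 3000)
  for (ss in list(ts$exposure, ts$outcome)) {
    expect_true(all(ss$se > 0))
    expect_equal(ss$p, 2 * pnorm(-abs(ss$beta / ss$se)), tolerance = 1e-6)
    expect_true(all(ss$effect_allele != ss$other_allele))
  }
})
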