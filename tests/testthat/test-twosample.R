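test_that("harmonization aligns allele codings and drops ambiguous
           palindromes", {
  exp_ss <- tibble::tibble(
    variant_id = c("v1", "v2", "v3", "v4"),
    effect_allele = c("A", "C", "A", "G"),
    other_allele = c("G", "T", "T", "C"),
    eaf = c(0.3, 0.4, 0.5, 0.2),
    beta = c(0.1, 0.2, 0.15, 0.12), se = rep(0.01, 4))
  # v1 identical coding; v2 swapped; v3 palindromic ambiguous (eaf 0.5);
  # v4 palindromic far from 0.5 (kept, eaf-matched orientation)
  out_ss <- tibble::tibble(
    variant_id = c("v1", "v2", "v3", "v4"),
    effect_allele = c("A", "T", "A", "G"),
    other_allele = c("G", "C", "T", "C"),
    eaf = c(0.3, 0.6, 0.5, 0.22),
    beta = c(0.05, 0.08, 0.02, 0.06), se = rep(0.02, 4))
  h <- harmonize(exp_ss, out_ss)
  expect_setequal(h$variant_id, c("v1", "v2", "v4"))
  expect_equal(h$Gamma[h$variant_id == "v1"], 0.05)
  expect_equal(h$Gamma[h$variant_id == "v2"], -0.08)  # swapped -> flipped
  expect_equal(h$Gamma[h$variant_id == "v4"], 0.06)
  expect_equal(attr(h, "dropped")$variant_id, "v3")
})

test_that("harmonizing scrambled codings reproduces the clean ratios", {
  p <- sim_params(n_variants = 60, causal_beta = 0.5, seed = 41,
                  palindromic_fraction = 0)
  clean <- simulate_two_sample(p, n_exposure = 4000, n_outcome = 4000)
  scram <- simulate_two_sample(p, n_exposure = 4000, n_outcome = 4000,
                               scramble_fraction = 0.4)
  h_clean <- harmonize(clean$exposure, clean$outcome)
  h_scram <- harmonize(scram$exposure, scram$outcome)
  expect_equal(wald_ratios(h_scram)$ratio, wald_ratios(h_clean)$ratio)
})

test_that("Wald ratios follow the delta-method formula", {
  h <- tibble::tibble(variant_id = c("a", "b"), gamma = c(0.1, 0.2),
                      se_gamma = c(0.01, 0.01), Gamma = c(0.2, 0.1),
                      se_Gamma = c(0.05, 0.04), eaf = c(0.3, 0.4))
  wr <- wald_ratios(h)
  expect_equal(wr$ratio, c(2.0, 0.5))
  expect_equal(wr$se, c(0.5, 0.2))
  h$gamma[2] <- 0
  expect_warning(wr2 <- wald_ratios(h), "zero exposure effect")
  expect_equal(nrow(wr2), 1)
})

test_that("fixed IVW equals the weighted-mean-of-ratios closed form", {
  h <- make_harmonized(J = 30, beta = 0.5, seed = 2)
  got <- mr_ivw(h, mode = "fixed")
  ratio <- h$Gamma / h$gamma
  w <- h$gamma^2 / h$se_Gamma^2
  expect_equal(got$beta, sum(w * ratio) / sum(w), tolerance = 1e-10)
  # degenerate consensus: all ratios identical
  ha <- make_analytic_harmonized(J = 8, beta = 0.7)
  for (args in list(list(), list(mode = "fixed"), list(robust = TRUE),
                    list(penalized = TRUE),
                    list(robust = TRUE, penalized = TRUE))) {
    res <- do.call(mr_ivw, c(list(ha), args))
    expect_equal(res$beta, 0.7, tolerance = 1e-8)
    expect_equal(res$heterogeneity_q, 0, tolerance = 1e-10)
  }
  expect_error(mr_ivw(ha[1, ]), class = "lvmr_method_minimum")
})

test_that("estimators are order-invariant and scale-equivariant", {
  h <- make_harmonized(J = 25, beta = 0.5, seed = 4)
  perm <- h[sample.int(nrow(h)), ]
  class(perm) <- class(h)
  expect_equal(mr_ivw(perm)$beta, mr_ivw(h)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(perm)$beta, mr_egger(h)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(perm, n_boot = 50)$beta,
               mr_weighted_median(h, n_boot = 50)$beta, tolerance = 1e-12)
  hc <- h
  c_ <- 2.5
  hc$gamma <- hc$gamma * c_
  hc$se_gamma <- hc$se_gamma * c_
  for (f in list(mr_ivw, mr_egger,
                 function(x) mr_weighted_median(x, n_boot = 50),
                 function(x) mr_weighted_mode(x, n_boot = 50))) {
    expect_equal(f(hc)$beta, f(h)$beta / c_, tolerance = 1e-6)
  }
})

test_that("MR-Egger recovers slope and directional pleiotropy intercept", {
  # exact line through the origin
  ha <- make_analytic_harmonized(J = 10, beta = 0.7)
  e <- mr_egger(ha)
  expect_lt(abs(e$egger_intercept), 1e-10)
  expect_equal(e$beta, 0.7, tolerance = 1e-10)
  # directional pleiotropy with mean 0.05 appears in the intercept
  ints <- vapply(1:200, function(s) {
    h <- make_harmonized(J = 30, beta = 0.5, alpha = rnorm(30, 0.05, 0.01),
                         seed = 6000 + s)
    mr_egger(h)$egger_intercept
  }, numeric(1))
  expect_equal(mean(ints), 0.05, tolerance = 3 * sd(ints) / sqrt(200))
  expect_error(mr_egger(ha[1:2, ]), class = "lvmr_method_minimum")
})

test_that("Egger intercept test is calibrated under balanced pleiotropy", {
  rej <- vapply(1:500, function(s) {
    h <- make_harmonized(J = 25, beta = 0.5, alpha = rnorm(25, 0, 0.02),
                         seed = 7000 + s)
    mr_egger(h)$egger_intercept_p < 0.10
  }, logical(1))
  expect_gte(mean(rej), 0.07)
  expect_lte(mean(rej), 0.13)
})

test_that("weighted median reduces to the sample median and resists 45%
           invalid instruments", {
  # equal weights, odd count -> the middle ratio exactly
  h <- make_analytic_harmonized(J = 9, beta = 0.4)
  h$Gamma <- h$gamma * seq(0.1, 0.9, by = 0.1)   # distinct ratios
  h$se_Gamma <- h$gamma * 0.05                   # equal ratio-scale weights
  wm <- mr_weighted_median(h, n_boot = 50)
  expect_equal(wm$beta, 0.5, tolerance = 1e-10)
  # duplicated dataset leaves the estimate unchanged
  h2 <- dplyr::bind_rows(h, h)
  class(h2) <- class(h)
  expect_equal(mr_weighted_median(h2, n_boot = 50)$beta, wm$beta,
               tolerance = 1e-10)
  # 45% invalid with large sign-balanced pleiotropy: median stays near
  # truth while IVW is dragged by the invalid weight
  ok <- vapply(1:100, function(s) {
    J <- 20
    set.seed(77000 + s)
    alpha <- c(rep(0, 11), sample(c(-1, 1), 9, TRUE) * 0.4)
    h <- make_harmonized(J = J, beta = 0.5, alpha = alpha,
                         se_G = rep(0.01, J), seed = 8000 + s)
    m <- mr_weighted_median(h, n_boot = 100, seed = s)
    i <- mr_ivw(h, mode = "fixed")
    c(abs(m$beta - 0.5) < 3 * m$se, abs(i$beta - 0.5) > 2 * i$se)
  }, logical(2))
  expect_gte(mean(ok[1, ]), 0.9)
  expect_gte(mean(ok[2, ]), 0.85)
})

test_that("weighted mode finds the plurality-valid cluster", {
  h <- make_analytic_harmonized(J = 7, beta = 0.3)
  expect_equal(mr_weighted_mode(h, n_boot = 50)$beta, 0.3, tolerance = 1e-9)
  # 40% valid at 0.5 vs two 30% invalid clusters at well-separated ratios
  hits <- vapply(1:50, function(s) {
    set.seed(9000 + s)
    J <- 20
    g <- rep(0.125, J)
    ratio_shift <- c(rep(0, 8), rep(0.4, 6), rep(-0.35, 6))
    h <- tibble::tibble(
      variant_id = sprintf("v%03d", seq_len(J)), gamma = g,
      se_gamma = rep(0.005, J),
      Gamma = (0.5 + ratio_shift) * g + rnorm(J, 0, 0.005),
      se_Gamma = rep(0.005, J), eaf = runif(J, 0.1, 0.9))
    class(h) <- c("harmonized_set", class(h))
    m <- mr_weighted_mode(h, n_boot = 100, seed = s)
    abs(m$beta - 0.5) < 3 * m$se
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # doubling the bandwidth keeps the argmax basin on separated clusters
  hsep <- make_harmonized(J = 15, beta = 0.5,
                          alpha = c(rep(0, 9), rep(0.4, 6)),
                          se_G = rep(0.005, 15), seed = 10)
  m1 <- mr_weighted_mode(hsep, phi = 1, n_boot = 50)
  m2 <- mr_weighted_mode(hsep, phi = 2, n_boot = 50)
  expect_equal(m1$beta, m2$beta, tolerance = 0.05)
})

test_that("multivariable MR reduces to IVW and separates joint effects", {
  h <- make_harmonized(J = 30, beta = 0.5, seed = 11)
  mv <- mr_mvmr(dplyr::rename(h, g1 = gamma), "g1", mode = "fixed")
  expect_equal(mv$beta, mr_ivw(h, mode = "fixed")$beta, tolerance = 1e-12)
  expect_equal(mv$se, mr_ivw(h, mode = "fixed")$se, tolerance = 1e-12)
  # two exposures with effects (0.5, 0), correlated instruments
  set.seed(12)
  J <- 40
  g1 <- runif(J, 0.05, 0.2)
  g2 <- 0.5 * g1 + runif(J, 0.02, 0.1)
  seG <- runif(J, 0.01, 0.03)
  dat <- tibble::tibble(g1 = g1, g2 = g2,
                        Gamma = 0.5 * g1 + 0 * g2 + rnorm(J, 0, seG),
                        se_Gamma = seG)
  mv2 <- mr_mvmr(dat, c("g1", "g2"))
  expect_lt(abs(mv2$beta[1] - 0.5), 3 * mv2$se[1])
  expect_lt(abs(mv2$beta[2] - 0), 3 * mv2$se[2])
  dat$gz <- 0
  expect_error(mr_mvmr(dat, c("g1", "gz")),
               class = "lvmr_identification_error")
})

test_that("robust penalized IVW outperforms plain IVW under a gross
           outlier", {
  wins <- vapply(1:200, function(s) {
    J <- 21
    alpha <- c(rep(0, J - 1), 1)                # one gross outlier
    h <- make_harmonized(J = J, beta = 0.5, alpha = alpha, seed = 11000 + s)
    b_rob <- mr_ivw(h, robust = TRUE, penalized = TRUE)$beta
    b_plain <- mr_ivw(h)$beta
    abs(b_rob - 0.5) < abs(b_plain - 0.5)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("plain IVW CIs attain nominal coverage on clean data", {
  cover <- vapply(1:300, function(s) {
    h <- make_harmonized(J = 25, beta = 0.5, seed = 12000 + s)
    r <- mr_ivw(h)
    r$ci_low <= 0.5 && 0.5 <= r$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.91)
  expect_lte(mean(cover), 0.99)
})

test_that("all estimators return exactly the true effect in analytic mode", {
  ts <- simulate_two_sample(sim_params(n_variants = 101, causal_beta = 0.5,
                                       seed = 51), analytic = TRUE)
  h <- harmonize(ts$exposure, ts$outcome)
  expect_equal(mr_ivw(h)$beta, 0.5, tolerance = 1e-8)
  expect_equal(mr_ivw(h, robust = TRUE, penalized = TRUE)$beta, 0.5,
               tolerance = 1e-8)
  expect_equal(mr_egger(h)$beta, 0.5, tolerance = 1e-6)
  expect_equal(mr_weighted_median(h, n_boot = 50)$beta, 0.5,
               tolerance = 1e-8)
  expect_equal(mr_weighted_mode(h, n_boot = 50)$beta, 0.5, tolerance = 1e-6)
  expect_equal(mr_ivw(h)$heterogeneity_q, 0, tolerance = 1e-8)
})

test_that("per-SD rescaling reproduces the printed mg/dl increments", {
  h <- make_harmonized(J = 20, beta = 0.04, seed = 13)
  res <- mr_ivw(h)
  # 1 SD of LDL = 0.87 mmol/l -> 34 mg/dl
  sd_mgdl <- convert_units(0.87, "cholesterol", "mmol_to_mgdl")
  expect_equal(round_presentation(sd_mgdl), 34)
  scaled <- scale_estimate(res, sd_mgdl)
  expect_equal(scaled$beta, res$beta * sd_mgdl)
  expect_equal(scaled$ci_high - scaled$ci_low,
               (res$ci_high - res$ci_low) * sd_mgdl)
  expect_equal(round_presentation(
    convert_units(c(0.38, 1.02), c("cholesterol", "triglyceride")[c(1, 2)],
                  "mmol_to_mgdl")[1]), 15)
  expect_equal(round_presentation(
    convert_units(1.02, "triglyceride", "mmol_to_mgdl")), 90)
})
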