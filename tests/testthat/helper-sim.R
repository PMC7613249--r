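# Small fixtures built in code for the two-sample estimators.

# Harmonized set generated directly at the summary level: J variants with
# exposure effects in [0.05, 0.2], true causal slope `beta`, optional
# per-variant direct (pleiotropic) effects `alpha`, and outcome noise at the
# stated standard errors.
make_harmonized <- function(J = 25, beta = 0.5, alpha = rep(0, J),
                            se_G = NULL, se_g = 0.005, seed = 1) {
  set.seed(seed)
  g <- runif(J, 0.05, 0.2)
  se_G <- se_G %||% runif(J, 0.02, 0.05)
  G <- beta * g + alpha + rnorm(J, 0, se_G)
  h <- tibble::tibble(
    variant_id = sprintf("v%03d", seq_len(J)),
    gamma = g, se_gamma = rep(se_g, J),
    Gamma = G, se_Gamma = se_G,
    eaf = runif(J, 0.1, 0.9),
    sign_flipped = FALSE
  )
  class(h) <- c("harmonized_set", class(h))
  h
}

# Noiseless harmonized set: every Wald ratio is exactly beta.
make_analytic_harmonized <- function(J = 10, beta = 0.7, seed = 1) {
  set.seed(seed)
  g <- runif(J, 0.05, 0.2)
  h <- tibble::tibble(
    variant_id = sprintf("v%03d", seq_len(J)),
    gamma = g, se_gamma = rep(1e-10, J),
    Gamma = beta * g, se_Gamma = runif(J, 0.02, 0.05),
    eaf = runif(J, 0.1, 0.9),
    sign_flipped = FALSE
  )
  class(h) <- c("harmonized_set", class(h))
  h
}

# Individual-level instrument/exposure/outcome tibble for 2SLS tests.
# r2 is the exposure variance explained by the instrument.
make_iv_data <- function(n = 2000, beta = 0.5, r2 = 0.1,
                         a_x = 0, a_y = 0, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  u <- rnorm(n)
  x <- sqrt(r2) * z + a_x * u + sqrt(max(1 - r2 - a_x^2, 0.05)) * rnorm(n)
  y <- beta * x + a_y * u + rnorm(n)
  tibble::tibble(z = z, x = x, y = y, u = u)
}
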