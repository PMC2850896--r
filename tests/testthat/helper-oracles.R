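# Shared fixtures and independent oracles.

# Random physiological component masses (kg); BV is NOT drawn, it is implied.
random_subjects <- function(n, seed = 1) {
  set.seed(seed)
  fm <- runif(n, 0.8, 18)
  tbw <- runif(n, 35, 55)
  mo <- runif(n, 2.4, 4.2)
  protein <- runif(n, 10.5, 17)
  ms <- 0.0129 * tbw
  data.frame(fm = fm, tbw = tbw, mo = mo, ms = ms, protein = protein,
             bw = fm + tbw + mo + ms + protein)
}

# Sign-flip permutation oracle for a paired comparison (two-sided, on the
# mean difference).
sign_flip_p <- function(d, n_flip = 20000, seed = 99) {
  set.seed(seed)
  obs <- abs(mean(d))
  hits <- replicate(n_flip, {
    s <- sample(c(-1, 1), length(d), replace = TRUE)
    abs(mean(d * s)) >= obs
  })
  mean(hits)
}

# Brute-force OLS via the normal equations (no lm).
ols_oracle <- function(y, x) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  list(slope = slope, intercept = intercept,
       see = sqrt(sum(res^2) / (n - 2)))
}

# One bivariate-normal sample with population correlation r.
rbvn <- function(n, r) {
  z1 <- rnorm(n); z2 <- rnorm(n)
  cbind(z1, r * z1 + sqrt(1 - r^2) * z2)
}

# A tiny valid two-phase cohort built by hand around exact compositions.
manual_cohort <- function(n = 6, seed = 7) {
  s <- random_subjects(n, seed)
  bv <- body_volume_from_components(s$fm, s$tbw, s$mo, s$ms, s$protein)
  set.seed(seed + 1)
  mk <- function(phase, scale) {
    fm <- s$fm * scale
    bw <- fm + s$tbw + s$mo + s$ms + s$protein
    data.frame(subject_id = sprintf("M%02d", seq_len(n)), phase = phase,
               bw_kg = bw,
               bv_l = body_volume_from_components(fm, s$tbw, s$mo, s$ms, s$protein),
               tbw_kg = s$tbw, bmc_kg = s$mo / 1.0436,
               dxa_fm_kg = fm + rnorm(n, 0.5, 0.3),
               dxa_ffm_kg = NA_real_)
  }
  a <- mk("stability", 1); b <- mk("precompetition", 0.9)
  out <- rbind(a, b)
  out$dxa_ffm_kg <- out$bw_kg - out$dxa_fm_kg
  out
}
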