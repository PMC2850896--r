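test_that("scalar compartment operations match direct arithmetic", {
  expect_identical(soft_tissue_mineral(0), 0)
  expect_equal(soft_tissue_mineral(47), 0.6063)
  expect_equal(soft_tissue_mineral(100), 1.29)
  expect_error(soft_tissue_mineral(-1), "non-negative")

  expect_identical(bone_mineral_from_bmc(0), 0)
  expect_equal(bone_mineral_from_bmc(3), 3.1308)
  expect_equal(bone_mineral_from_bmc(1), 1.0436)
  expect_error(bone_mineral_from_bmc(-0.1), "non-negative")

  expect_identical(total_mineral(0, 0), 0)
  expect_equal(total_mineral(3.15, 0.614), 3.764)

  expect_equal(percent_fm(0, 70), 0)
  expect_equal(percent_fm(6.8, 72.8), 100 * 6.8 / 72.8)
  expect_equal(percent_fm(36.4, 72.8), 50)
  expect_error(percent_fm(1, 0), "positive")
})

test_that("derived 4C coefficients agree with the published equation", {
  k <- fm_4c_coefficients()
  # published: FM = 2.748 BV - 0.699 TBW + 1.129 Mo - 2.051 BW; derived
  # values match to <= 0.001 (the published BV/BW entries carry their own
  # last-digit rounding)
  published <- c(bv = 2.748, tbw = -0.699, mo = 1.129, bw = -2.051)
  expect_lte(max(abs(k - published)), 0.001)
  expect_equal(round(k[c("tbw", "mo")], 3), published[c("tbw", "mo")])
})

test_that("fm_4c inverts the density identity (round trip)", {
  ms <- soft_tissue_mineral(47)
  bw <- 7 + 47 + 3.2 + ms + 14
  bv <- body_volume_from_components(7, 47, 3.2, ms, 14)
  expect_equal(bv, 66.773, tolerance = 1e-4)
  expect_equal(fm_4c(bv, 47, 3.2, bw), 7, tolerance = 1e-6)

  # zero-fat limit (fm_4c flags FM ~ 0 falling a hair below 0 numerically)
  bv0 <- body_volume_from_components(0, 47, 3.2, ms, 14)
  expect_equal(suppressWarnings(fm_4c(bv0, 47, 3.2, bw - 7)), 0,
               tolerance = 1e-6)

  # linear form: doubling all inputs doubles the output
  expect_equal(fm_4c(2 * bv, 2 * 47, 2 * 3.2, 2 * bw),
               2 * fm_4c(bv, 47, 3.2, bw))

  expect_error(fm_4c(60, 50, 25, 70), "less than")
  expect_warning(fm_4c(100, 47, 3.2, bw), "non-physiological")
})

test_that("decompose_ffm computes residual protein and exact mass closure", {
  ms <- soft_tissue_mineral(47)
  comp <- decompose_ffm(bw = 7 + 47 + 3.2 + ms + 14, fm = 7, tbw = 47,
                        mo = 3.2, ms = ms)
  expect_equal(comp$protein, 14)
  expect_equal(comp$ffm, 64.8063)
  expect_equal(comp$tbw_ffm, 47 / 64.8063, tolerance = 1e-6)
  expect_equal(comp$fm + 47 + 3.2 + ms + comp$protein,
               7 + 47 + 3.2 + ms + 14)
  expect_equal(comp$tbw_ffm + comp$m_ffm + comp$protein_ffm, 1)

  expect_error(decompose_ffm(bw = 60, fm = 0, tbw = 57, mo = 3.2,
                             ms = 0.7, subject_id = "X9"),
               "negative residual protein.*X9")
})

test_that("mass conservation and round trip hold over random subjects", {
  s <- random_subjects(1000, seed = 11)
  bv <- body_volume_from_components(s$fm, s$tbw, s$mo, s$ms, s$protein)
  fm_hat <- fm_4c(bv, s$tbw, s$mo, s$bw)
  expect_lt(max(abs(fm_hat - s$fm)), 1e-6)
  comp <- decompose_ffm(s$bw, fm_hat, s$tbw, s$mo, s$ms)
  expect_equal(comp$fm + s$tbw + s$mo + s$ms + comp$protein, s$bw)
  expect_true(all(comp$ffm_d > 0.9 & comp$ffm_d < 1.2))
})

test_that("ffm_density matches hand arithmetic and printed group values", {
  expect_equal(ffm_density(1, 0, 0, 0), 0.9937)
  expect_equal(ffm_density(0.5, 0, 0, 0.5), 1 / (0.5 / 0.9937 + 0.5 / 1.34))

  # group-level reconstruction from the published stability fractions:
  # water 0.72, total mineral 0.057 split via Ms = 0.0129 * TBW, protein
  # as the residual (printed fractions sum to 0.997 from rounding)
  msf <- 0.0129 * 0.72
  protein <- 1 - 0.72 - 0.057
  expect_equal(protein, 0.223)
  d <- ffm_density(0.72, 0.057 - msf, msf, protein)
  expect_equal(d, 1.100, tolerance = 0.005)

  expect_error(ffm_density(0.5, 0.2, 0.1, 0.1), "sum to 1")
  expect_error(ffm_density(-0.1, 0.5, 0.1, 0.5), "non-negative")
})

test_that("ffm_density is bounded by and monotone toward component densities", {
  set.seed(21)
  d <- component_densities()
  for (i in 1:200) {
    f <- as.numeric(stats::rgamma(4, 1)); f <- f / sum(f)
    v <- ffm_density(f[1], f[2], f[3], f[4])
    expect_gte(v, min(unlist(d[1:4])) - 1e-12)
    expect_lte(v, max(unlist(d[1:4])) + 1e-12)
  }
  # moving mass from protein into water pulls the density toward water's
  base <- ffm_density(0.70, 0.05, 0.01, 0.24)
  shifted <- ffm_density(0.75, 0.05, 0.01, 0.19)
  expect_true(abs(shifted - d$water) < abs(base - d$water))
})

test_that("percent_fm of fm_4c is invariant under uniform rescaling", {
  s <- random_subjects(50, seed = 31)
  bv <- body_volume_from_components(s$fm, s$tbw, s$mo, s$ms, s$protein)
  p1 <- percent_fm(fm_4c(bv, s$tbw, s$mo, s$bw), s$bw)
  p2 <- percent_fm(fm_4c(1.7 * bv, 1.7 * s$tbw, 1.7 * s$mo, 1.7 * s$bw),
                   1.7 * s$bw)
  expect_equal(p1, p2)
})

test_that("body_volume_from_components handles limits", {
  expect_identical(body_volume_from_components(0, 0, 0, 0, 0), 0)
  expect_equal(body_volume_from_components(0, 1, 0, 0, 0), 1 / 0.9937)
})

test_that("cohort CSV round-trips through write_cohort/read_cohort", {
  co <- manual_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path, bw_tol = 1e-6)
  expect_equal(back$bw_kg, co$bw_kg, tolerance = 1e-12)
  expect_identical(back$phase, co$phase)
  expect_false(any(startsWith(names(back), "latent_")))

  bad <- co; bad$tbw_kg[1] <- bad$bw_kg[1] + 1
  expect_error(validate_records(bad), "TBW < BW")
  bad2 <- co; bad2$phase[2] <- "midseason"
  expect_error(validate_records(bad2), "phase")
  bad3 <- co; bad3$dxa_ffm_kg[1] <- bad3$dxa_ffm_kg[1] + 10
  expect_error(validate_records(bad3), "deviates")
})
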