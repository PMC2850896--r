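test_that("generated cohorts are valid, exact under the 4C identity, and reproducible", {
  cfg <- cohort_config(n_subjects = 27, seed = 101)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 54)
  expect_setequal(unique(co$phase), c("stability", "precompetition"))
  expect_silent(validate_records(co, bw_tol = 1e-6))
  expect_true(all(co$tbw_kg > 0 & co$tbw_kg < co$bw_kg))
  expect_true(all(co$bmc_kg > 0 & co$bmc_kg < co$bw_kg))
  expect_true(all(co$latent_pfm >= cfg$pfm_floor - 1e-9))

  # the raw columns reproduce the latent fat mass through fm_4c
  comp <- compose_cohort(co)
  expect_lt(max(abs(comp$fm_4c_kg - co$latent_fm_kg)), 1e-6)

  # same seed => byte-identical CSV; different seed => different cohort
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(generate_cohort(cfg), f1)
  write_cohort(generate_cohort(cohort_config(n_subjects = 27, seed = 101)), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(co$bw_kg,
                         generate_cohort(cohort_config(27, seed = 102))$bw_kg))

  # metadata records the seed and derived calibration
  meta <- attr(co, "meta")
  expect_identical(meta$seed, 101)
  expect_true(abs(meta$derived_change_correlation) <= 1)
})

test_that("large-cohort change moments match the configured calibration", {
  cfg <- cohort_config(n_subjects = 1e5, seed = 1)
  ch <- change_records(compose_cohort(generate_cohort(cfg)))
  # law-of-large-numbers check against the stated moments (1% relative)
  expect_equal(mean(ch$d_pfm_4c), -1.22, tolerance = 0.01)
  expect_equal(sd(ch$d_pfm_4c), 2.70, tolerance = 0.01)
  expect_equal(cor(ch$d_pfm_dxa, ch$d_pfm_4c), 0.53, tolerance = 0.01 / 0.53)
  # DXA change targets
  expect_equal(mean(ch$d_pfm_dxa), -0.41, tolerance = 0.05 / 0.41)
  expect_equal(sd(ch$d_pfm_dxa), 1.05, tolerance = 0.02)
  # implied FFM-change SD honours the configured target
  expect_equal(sd(ch$d_ffm_4c), 2.04, tolerance = 0.05)
})

test_that("infeasible configurations fail with the violated constraint named", {
  expect_error(generate_cohort(cohort_config(d_ffm_sd = 10)),
               "infeasible change-moment")
  expect_error(cohort_config(trend_coef = 1.2), "trend_coef")
  expect_error(generate_cohort(cohort_config(dxa_d_pfm_sd = 5)),
               "trend coefficient")
})

test_that("measurement-noise injection matches its contract", {
  co <- generate_cohort(cohort_config(n_subjects = 20, seed = 8))

  zero <- inject_measurement_noise(co, tem_profile(0, 0, 0), seed = 1)
  expect_identical(zero$bv_l, co$bv_l)
  expect_identical(zero$tbw_kg, co$tbw_kg)

  n1 <- inject_measurement_noise(co, tem_profile(), seed = 9)
  n2 <- inject_measurement_noise(co, tem_profile(), seed = 9)
  expect_identical(n1, n2)
  expect_false(identical(n1$bv_l, co$bv_l))
  # latent truth preserved
  expect_identical(n1$latent_bv_l, co$bv_l)
  expect_identical(n1$latent_fm_kg, co$latent_fm_kg)
})

test_that("injected noise reproduces the analytic TEM propagation", {
  # 1e5 replicates of a single subject: the SD of the fat-mass perturbation
  # must match the quadrature-sum propagation within 1%
  s <- random_subjects(1, seed = 3)
  n <- 1e5
  rec <- data.frame(subject_id = sprintf("T%06d", 1:n), phase = "stability",
                    bw_kg = s$bw,
                    bv_l = body_volume_from_components(s$fm, s$tbw, s$mo,
                                                       s$ms, s$protein),
                    tbw_kg = s$tbw, bmc_kg = s$mo / 1.0436)
  noisy <- inject_measurement_noise(rec, tem_profile(), seed = 4)
  mo <- bone_mineral_from_bmc(noisy$bmc_kg)
  fm_noisy <- fm_4c(noisy$bv_l, noisy$tbw_kg, mo, noisy$bw_kg)
  analytic <- propagate_tem(tem_profile(), mean_bw = s$bw)
  expect_equal(sd(fm_noisy - s$fm), analytic$fm_tem,
               tolerance = 0.01)
})
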