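# Synthetic two-phase athlete cohorts.
#
# The generator states a world calibrated to the published group moments:
# a weight-stability phase and a pre-competition phase for n male judo
# athletes, with 4C change scores and a DXA error model whose change-score
# correlation, SD and bias are construction targets. Latent compositions
# are exact under the density identity, so the 4C arithmetic is exercised
# end-to-end rather than bypassed.

#' Configuration of the synthetic athlete cohort
#'
#' Defaults are the published cohort's marginal moments (baseline body
#' weight 72.8 +/- 7.1 kg, %FM 9.2 +/- 4.1, FFM hydration 0.72 +/- 0.02,
#' mineral fraction 0.057 +/- 0.003), change-score moments (delta %FM
#' -1.22 +/- 2.70, delta BW -0.87 +/- 1.93, delta FFM 0.07 +/- 2.04,
#' delta hydration 0.006 +/- 0.016) and the DXA error model (cross-sectional
#' bias +2.9 %FM with SD 3.1 and r 0.78 at stability; change-score
#' correlation 0.53 with SD 1.05 and mean -0.41 for %FM).
#'
#' The correlation between the %FM and body-weight changes is not a free
#' parameter: it is derived (delta method) so that the implied FFM-change
#' SD matches `d_ffm_sd`. The Bland-Altman trend in change scores is
#' governed by `trend_coef`, the proportional shrinkage of DXA changes
#' relative to 4C changes (`SD_dxa = (1 - trend_coef) * SD_4c`): at 0 the
#' two methods have equal change variance and the difference is independent
#' of the mean (a true no-trend null); by default it is derived from the
#' configured SD targets, `1 - d_pfm_dxa_sd / d_pfm_sd`.
#'
#' @param n_subjects cohort size.
#' @param seed integer RNG seed; the cohort is a deterministic function of it.
#' @param bw_mean,bw_sd baseline body weight moments, kg.
#' @param stature_mean,stature_sd stature moments, m (reporting only).
#' @param pfm_mean,pfm_sd baseline 4C %FM moments.
#' @param water_frac_mean,water_frac_sd baseline TBW/FFM moments.
#' @param mineral_frac_mean,mineral_frac_sd baseline M/FFM moments.
#' @param d_pfm_mean,d_pfm_sd 4C %FM change moments.
#' @param d_bw_mean,d_bw_sd body-weight change moments, kg.
#' @param d_ffm_sd target SD of the 4C FFM change, kg (drives the derived
#'   change correlation).
#' @param d_water_frac_mean,d_water_frac_sd hydration change moments.
#' @param dxa_cs_bias,dxa_cs_sd,dxa_cs_r cross-sectional DXA %FM error
#'   model at stability: bias (+%FM), SD and correlation with 4C.
#' @param dxa_d_pfm_mean,dxa_d_pfm_sd DXA %FM change moments (targets).
#' @param dxa_change_r DXA-vs-4C change-score correlation target for %FM.
#' @param trend_coef proportional-trend coefficient in `[0, 1)`; `NULL`
#'   (default) derives it from the SD targets.
#' @param pfm_floor latent %FM floor (athletes reach ~3 %FM; 2.5 guards
#'   physiology). Floors shift a subject's whole two-phase trajectory so
#'   change scores are preserved; events are counted in the metadata.
#' @param dxa_pfm_floor floor for DXA %FM readings.
#' @param ms_per_tbw,bmc_factor model constants.
#' @param densities a [component_densities()] object.
#' @param regional if TRUE, emit proportional trunk/arms/legs splits of the
#'   DXA fat and lean-soft-tissue masses.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 27, seed = 1,
                          bw_mean = 72.8, bw_sd = 7.1,
                          stature_mean = 1.76, stature_sd = 0.05,
                          pfm_mean = 9.2, pfm_sd = 4.1,
                          water_frac_mean = 0.72, water_frac_sd = 0.02,
                          mineral_frac_mean = 0.057, mineral_frac_sd = 0.003,
                          d_pfm_mean = -1.22, d_pfm_sd = 2.70,
                          d_bw_mean = -0.87, d_bw_sd = 1.93,
                          d_ffm_sd = 2.04,
                          d_water_frac_mean = 0.006, d_water_frac_sd = 0.016,
                          dxa_cs_bias = 2.9, dxa_cs_sd = 3.1, dxa_cs_r = 0.78,
                          dxa_d_pfm_mean = -0.41, dxa_d_pfm_sd = 1.05,
                          dxa_change_r = 0.53,
                          trend_coef = NULL,
                          pfm_floor = 2.5, dxa_pfm_floor = 1.0,
                          ms_per_tbw = 0.0129, bmc_factor = 1.0436,
                          densities = component_densities(),
                          regional = FALSE) {
  cfg <- as.list(environment())
  if (cfg$n_subjects < 1) .stop("`n_subjects` must be >= 1")
  for (nm in c("bw_sd", "pfm_sd", "water_frac_sd", "mineral_frac_sd",
               "d_pfm_sd", "d_bw_sd", "d_ffm_sd", "d_water_frac_sd",
               "dxa_cs_sd", "dxa_d_pfm_sd"))
    .check_num(cfg[[nm]], nm, non_negative = TRUE)
  for (nm in c("dxa_cs_r", "dxa_change_r"))
    if (abs(cfg[[nm]]) > 1) .stop("`%s` must lie in [-1, 1]", nm)
  if (!is.null(trend_coef) && (trend_coef < 0 || trend_coef >= 1))
    .stop("`trend_coef` must lie in [0, 1): DXA change SD would be infeasible")
  structure(cfg, class = "cohort_config")
}

# Delta-method correlation between the %FM change and the body-weight
# change implied by the configured FFM-change SD. Linearising
# dFM ~ a * dpfm + b * dBW with a = bw_mean/100, b = pfm_mean/100 and
# dFFM = dBW - dFM gives
#   Var(dFFM) = (1-b)^2 s_w^2 + a^2 s_p^2 - 2 a (1-b) c s_p s_w.
.derive_change_correlation <- function(cfg) {
  a <- cfg$bw_mean / 100
  b <- cfg$pfm_mean / 100
  num <- cfg$d_bw_sd^2 * (1 - b)^2 + a^2 * cfg$d_pfm_sd^2 - cfg$d_ffm_sd^2
  den <- 2 * a * (1 - b) * cfg$d_pfm_sd * cfg$d_bw_sd
  c_pw <- num / den
  if (!is.finite(c_pw) || abs(c_pw) > 1)
    .stop(paste0("infeasible change-moment combination: implied ",
                 "corr(d%%FM, dBW) = %.3f outside [-1, 1]; adjust d_pfm_sd, ",
                 "d_bw_sd or d_ffm_sd"), c_pw)
  c_pw
}

# Clamp x to [lo, hi]; returns the clamped vector and the event count.
.clamp_logged <- function(x, lo = -Inf, hi = Inf) {
  n <- sum(x < lo | x > hi)
  list(x = pmin(pmax(x, lo), hi), n_truncated = n)
}

#' Generate a synthetic two-phase cohort
#'
#' Draws latent baseline compositions and change scores from the configured
#' moments, maps them to internally consistent raw instrument inputs (BW,
#' BV, TBW, BMC) for both phases, and adds DXA fat / fat-free mass readings
#' from the configured error model. Body volume is computed exactly from
#' the component masses and densities, so [fm_4c()] applied to the emitted
#' raw columns recovers the latent fat mass to machine precision.
#'
#' Construction outline, per subject:
#' * baseline: BW, %FM, TBW/FFM, M/FFM from truncated normals; Mo, Ms,
#'   protein and BV derived; BMC = Mo / 1.0436.
#' * change: (d%FM, dBW) bivariate normal with the derived correlation;
#'   hydration change drawn separately; Mo held constant across phases
#'   (the mineral fraction change is ~0 in this population).
#' * DXA: stability %FM from the cross-sectional error model; the DXA %FM
#'   change conditionally normal given the 4C change (correlation
#'   `dxa_change_r`, SD set by the trend coefficient); phase-2 DXA = phase-1
#'   DXA + change; fat/fat-free masses close on body weight exactly.
#' * floors: a trajectory that dips under a floor is shifted up as a pair,
#'   preserving the change score; counts land in `attr(, "meta")`.
#'
#' @param config a [cohort_config()].
#' @return data.frame with two rows per subject (phases `stability`,
#'   `precompetition`), the standard measurement-record columns, a
#'   `stature_m` column, and latent-truth columns `latent_fm_kg`,
#'   `latent_pfm`, `latent_protein_kg`. Generator metadata (seed, derived
#'   parameters, truncation counts) is in `attr(, "meta")`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 5, seed = 42))
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  n <- cfg$n_subjects
  set.seed(cfg$seed)

  # --- baseline latent state -------------------------------------------
  bw1 <- rnorm(n, cfg$bw_mean, cfg$bw_sd)
  stature <- rnorm(n, cfg$stature_mean, cfg$stature_sd)
  pfm1 <- rnorm(n, cfg$pfm_mean, cfg$pfm_sd)
  wf1 <- .clamp_logged(rnorm(n, cfg$water_frac_mean, cfg$water_frac_sd), 0.60, 0.80)
  mf1 <- .clamp_logged(rnorm(n, cfg$mineral_frac_mean, cfg$mineral_frac_sd), 0.040, 0.080)

  # --- change scores ----------------------------------------------------
  c_pw <- .derive_change_correlation(cfg)
  z1 <- rnorm(n); z2 <- rnorm(n)
  d_pfm <- cfg$d_pfm_mean + cfg$d_pfm_sd * z1
  d_bw <- cfg$d_bw_mean + cfg$d_bw_sd * (c_pw * z1 + sqrt(1 - c_pw^2) * z2)
  d_wf <- rnorm(n, cfg$d_water_frac_mean, cfg$d_water_frac_sd)

  # --- DXA error model --------------------------------------------------
  rho <- cfg$dxa_change_r
  tau <- if (is.null(cfg$trend_coef)) 1 - cfg$dxa_d_pfm_sd / cfg$d_pfm_sd else cfg$trend_coef
  if (tau < 0 || tau >= 1)
    .stop("infeasible trend coefficient %.3f (needs dxa_d_pfm_sd <= d_pfm_sd)", tau)
  sd_d <- (1 - tau) * cfg$d_pfm_sd
  pd1 <- (cfg$pfm_mean + cfg$dxa_cs_bias) +
    cfg$dxa_cs_r * (cfg$dxa_cs_sd / cfg$pfm_sd) * (pfm1 - cfg$pfm_mean) +
    rnorm(n, 0, cfg$dxa_cs_sd * sqrt(1 - cfg$dxa_cs_r^2))
  d_pd <- cfg$dxa_d_pfm_mean + rho * (sd_d / cfg$d_pfm_sd) * (d_pfm - cfg$d_pfm_mean) +
    rnorm(n, 0, sd_d * sqrt(1 - rho^2))

  # --- floors: shift whole trajectories, preserving change scores -------
  shift4 <- pmax(0, cfg$pfm_floor - pmin(pfm1, pfm1 + d_pfm))
  pfm1 <- pfm1 + shift4
  pfm2 <- pfm1 + d_pfm
  shiftd <- pmax(0, cfg$dxa_pfm_floor - pmin(pd1, pd1 + d_pd))
  pd1 <- pd1 + shiftd
  pd2 <- pd1 + d_pd

  # body-weight floor, same trajectory-shift rule (rare at the defaults)
  shift_bw <- pmax(0, 40 - pmin(bw1, bw1 + d_bw))
  bw1 <- bw1 + shift_bw
  bw2 <- bw1 + d_bw
  wf2 <- .clamp_logged(wf1$x + d_wf, 0.60, 0.80)

  # --- map to component masses (phase 1 defines Mo, held constant) ------
  phase_state <- function(bw, pfm, wf, mo = NULL, mf = NULL) {
    fm <- pfm / 100 * bw
    ffm <- bw - fm
    tbw <- wf * ffm
    ms <- soft_tissue_mineral(tbw, cfg$ms_per_tbw)
    if (is.null(mo)) mo <- mf * ffm - ms
    if (any(mo <= 0)) .stop("implied osseous mineral <= 0; mineral/water fractions inconsistent")
    protein <- ffm - tbw - mo - ms
    if (any(protein <= 0)) .stop("implied protein <= 0; fractions inconsistent")
    bv <- body_volume_from_components(fm, tbw, mo, ms, protein, cfg$densities)
    list(bw = bw, fm = fm, pfm = pfm, ffm = ffm, tbw = tbw, mo = mo,
         ms = ms, protein = protein, bv = bv,
         bmc = mo / cfg$bmc_factor)
  }
  s1 <- phase_state(bw1, pfm1, wf1$x, mf = mf1$x)
  s2 <- phase_state(bw2, pfm2, wf2$x, mo = s1$mo)

  ids <- sprintf("S%03d", seq_len(n))
  row_block <- function(s, phase, pd) {
    dxa_fm <- pd / 100 * s$bw
    data.frame(subject_id = ids, phase = phase,
               bw_kg = s$bw, bv_l = s$bv, tbw_kg = s$tbw, bmc_kg = s$bmc,
               dxa_fm_kg = dxa_fm, dxa_ffm_kg = s$bw - dxa_fm,
               stature_m = stature,
               latent_fm_kg = s$fm, latent_pfm = s$pfm,
               latent_protein_kg = s$protein)
  }
  out <- rbind(row_block(s1, "stability", pd1),
               row_block(s2, "precompetition", pd2))
  out <- out[order(out$subject_id, match(out$phase, .phases)), ]
  rownames(out) <- NULL

  if (cfg$regional) {
    # crude proportional split of DXA soft tissue; jitter is cosmetic
    split_frac <- c(trunk = 0.50, arms = 0.15, legs = 0.35)
    lst <- out$dxa_ffm_kg - bone_mineral_from_bmc(out$bmc_kg, 1) # LST excludes bone mineral
    for (region in names(split_frac)) {
      f <- split_frac[[region]] * (1 + rnorm(nrow(out), 0, 0.03))
      out[[paste0(region, "_fm_kg")]] <- f * out$dxa_fm_kg
      out[[paste0(region, "_lst_kg")]] <- f * lst
    }
  }

  attr(out, "meta") <- list(
    seed = cfg$seed, n_subjects = n,
    derived_change_correlation = c_pw,
    trend_coef = tau, dxa_change_sd = sd_d,
    n_truncated = list(
      water_frac = wf1$n_truncated + wf2$n_truncated,
      mineral_frac = mf1$n_truncated,
      pfm_floor = sum(shift4 > 0), dxa_pfm_floor = sum(shiftd > 0),
      bw_floor = sum(shift_bw > 0)),
    note = paste("change-score structure is matched exactly by construction;",
                 "cross-sectional pre-competition moments are implied, not targeted"))
  validate_records(out, bw_tol = 1e-6)
  out
}

#' Inject instrument measurement noise
#'
#' Adds independent zero-mean Gaussian noise with the profile's TEMs to the
#' raw instrument columns (`bv_l`, `tbw_kg`, `bmc_kg`, and `bw_kg` if the
#' profile carries a non-zero body-weight TEM). Clean values are preserved
#' in `latent_bv_l`, `latent_tbw_kg`, `latent_bmc_kg` (created on first
#' injection); existing `latent_*` columns are never touched.
#'
#' @param records a measurement-record data.frame.
#' @param profile a [tem_profile()].
#' @param seed integer RNG seed.
#' @return `records` with noisy instrument columns.
#' @export
inject_measurement_noise <- function(records, profile = tem_profile(), seed = 1) {
  stopifnot(inherits(profile, "tem_profile"))
  validate_records(records, bw_tol = Inf)
  set.seed(seed)
  n <- nrow(records)
  pairs <- list(c("bv_l", "bv_tem"), c("tbw_kg", "tbw_tem"),
                c("bmc_kg", "bmc_tem"), c("bw_kg", "bw_tem"))
  for (p in pairs) {
    col <- p[1]; tem <- profile[[p[2]]]
    if (tem > 0) {
      latent <- paste0("latent_", col)
      if (is.null(records[[latent]])) records[[latent]] <- records[[col]]
      records[[col]] <- records[[col]] + rnorm(n, 0, tem)
    }
  }
  records
}
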