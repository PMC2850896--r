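#' Soft-tissue (non-osseous) mineral from total body water
#'
#' Soft-tissue mineral is modelled as a fixed proportion of total body
#' water: Ms = 0.0129 x TBW.
#'
#' @param tbw total body water, kg (vectorised).
#' @param coef proportionality constant (default 0.0129).
#' @return Soft-tissue mineral, kg.
#' @export
soft_tissue_mineral <- function(tbw, coef = 0.0129) {
  .check_num(tbw, "tbw", non_negative = TRUE)
  coef * tbw
}

#' Total bone mineral from DXA bone mineral content
#'
#' DXA bone mineral content (BMC) represents ashed bone; it is converted to
#' total-body osseous mineral by Mo = 1.0436 x BMC.
#'
#' @param bmc bone mineral content, kg (vectorised).
#' @param factor ash-to-mineral conversion factor (default 1.0436).
#' @return Osseous mineral Mo, kg.
#' @export
bone_mineral_from_bmc <- function(bmc, factor = 1.0436) {
  .check_num(bmc, "bmc", non_negative = TRUE)
  factor * bmc
}

#' Total body mineral
#'
#' @param mo osseous mineral, kg.
#' @param ms soft-tissue mineral, kg.
#' @return Total mineral M = Mo + Ms, kg.
#' @export
total_mineral <- function(mo, ms) {
  .check_num(mo, "mo", non_negative = TRUE)
  .check_num(ms, "ms", non_negative = TRUE)
  mo + ms
}

#' Fat mass from the four-compartment model
#'
#' Evaluates the 4C fat-mass estimate as the linear combination of body
#' volume, total body water, osseous mineral and body weight whose
#' coefficients are derived from the component densities (see
#' [fm_4c_coefficients()]). Soft-tissue mineral is folded in through the
#' Ms = 0.0129 TBW substitution, so it is not an input here.
#'
#' Estimates outside the physiological interval `[0, bw]` are returned
#' unchanged but raised through the warning channel (they usually indicate
#' inconsistent inputs, not values to be clipped).
#'
#' @param bv body volume, L.
#' @param tbw total body water, kg.
#' @param mo osseous mineral, kg.
#' @param bw body weight, kg.
#' @param densities a [component_densities()] object.
#' @param ms_per_tbw soft-tissue mineral per kg TBW.
#' @return Fat mass, kg (vectorised).
#' @examples
#' fm_4c(bv = 66.77, tbw = 47, mo = 3.2, bw = 71.8)
#' @export
fm_4c <- function(bv, tbw, mo, bw, densities = component_densities(),
                  ms_per_tbw = 0.0129) {
  .check_num(bv, "bv", positive = TRUE)
  .check_num(tbw, "tbw", positive = TRUE)
  .check_num(mo, "mo", positive = TRUE)
  .check_num(bw, "bw", positive = TRUE)
  if (any(tbw + mo >= bw))
    .stop("`tbw` + `mo` must be less than `bw` for every subject")
  k <- fm_4c_coefficients(densities, ms_per_tbw)
  fm <- k[["bv"]] * bv + k[["tbw"]] * tbw + k[["mo"]] * mo + k[["bw"]] * bw
  bad <- which(fm < 0 | fm > bw)
  if (length(bad))
    warning(sprintf(
      "fm_4c: %d non-physiological fat-mass estimate(s) outside [0, bw] (first at index %d: %.3f kg)",
      length(bad), bad[1], fm[bad[1]]), call. = FALSE)
  unname(fm)
}

#' Percent fat mass
#'
#' @param fm fat mass, kg.
#' @param bw body weight, kg.
#' @return Fat mass as a percentage of body weight.
#' @export
percent_fm <- function(fm, bw) {
  .check_num(fm, "fm")
  .check_num(bw, "bw", positive = TRUE)
  100 * fm / bw
}

#' Decompose fat-free mass into its molecular components
#'
#' Given body weight, 4C fat mass, total body water and the two mineral
#' compartments, computes protein as the residual
#' `protein = BW - FM - TBW - Mo - Ms`, the fat-free mass `FFM = BW - FM`,
#' the FFM component fractions, and the FFM density. Mass conservation
#' (`fm + tbw + mo + ms + protein == bw`) holds exactly by construction.
#'
#' @param bw body weight, kg.
#' @param fm fat mass, kg.
#' @param tbw total body water, kg.
#' @param mo osseous mineral, kg.
#' @param ms soft-tissue mineral, kg.
#' @param densities a [component_densities()] object.
#' @param subject_id optional identifiers used in error messages.
#' @return A `data.frame` with columns `fm`, `ffm`, `pfm`, `mo`, `ms`, `m`,
#'   `protein`, `ffm_d`, `tbw_ffm`, `m_ffm`, `protein_ffm` (one row per
#'   subject).
#' @examples
#' decompose_ffm(bw = 71.8063, fm = 7, tbw = 47, mo = 3.2, ms = 0.6063)
#' @export
decompose_ffm <- function(bw, fm, tbw, mo, ms,
                          densities = component_densities(),
                          subject_id = NULL) {
  .check_num(bw, "bw", positive = TRUE)
  .check_num(fm, "fm")
  .check_num(tbw, "tbw", non_negative = TRUE)
  .check_num(mo, "mo", non_negative = TRUE)
  .check_num(ms, "ms", non_negative = TRUE)
  n <- max(length(bw), length(fm), length(tbw), length(mo), length(ms))
  bw <- rep_len(bw, n); fm <- rep_len(fm, n); tbw <- rep_len(tbw, n)
  mo <- rep_len(mo, n); ms <- rep_len(ms, n)
  if (is.null(subject_id)) subject_id <- as.character(seq_len(n))
  if (any(fm >= bw)) .stop("`fm` must be less than `bw`")
  ffm <- bw - fm
  protein <- ffm - tbw - mo - ms
  if (any(protein < 0)) {
    i <- which(protein < 0)[1]
    .stop("negative residual protein (%.3f kg) for subject '%s': inputs are inconsistent",
          protein[i], subject_id[i])
  }
  wf <- tbw / ffm; mof <- mo / ffm; msf <- ms / ffm; pf <- protein / ffm
  data.frame(
    fm = fm, ffm = ffm, pfm = percent_fm(fm, bw),
    mo = mo, ms = ms, m = mo + ms, protein = protein,
    ffm_d = ffm_density(wf, mof, msf, pf, densities),
    tbw_ffm = wf, m_ffm = mof + msf, protein_ffm = pf
  )
}

#' Density of fat-free mass from component fractions
#'
#' FFM density is the harmonic combination
#' \deqn{FFM_D = 1 / \sum_i f_i / d_i}
#' over the water, osseous-mineral, soft-tissue-mineral and protein
#' fractions of fat-free mass. Fractions must sum to 1 (tolerance 1e-6).
#'
#' @param tbw_frac,mo_frac,ms_frac,protein_frac FFM component fractions.
#' @param densities a [component_densities()] object.
#' @return FFM density, g/cc (vectorised).
#' @examples
#' ffm_density(1, 0, 0, 0)                 # all-water limit: 0.9937
#' ffm_density(0.72, 0.047712, 0.009288, 0.223)
#' @export
ffm_density <- function(tbw_frac, mo_frac, ms_frac, protein_frac,
                        densities = component_densities()) {
  stopifnot(inherits(densities, "component_densities"))
  for (f in list(tbw_frac, mo_frac, ms_frac, protein_frac))
    .check_num(f, "fraction", non_negative = TRUE)
  tot <- tbw_frac + mo_frac + ms_frac + protein_frac
  if (any(abs(tot - 1) > 1e-6))
    .stop("FFM fractions must sum to 1 (got %.8f)", tot[which.max(abs(tot - 1))])
  1 / (tbw_frac / densities$water + mo_frac / densities$mo +
         ms_frac / densities$ms + protein_frac / densities$protein)
}

#' Body volume implied by the component masses
#'
#' Inverse of the 4C density identity: the body volume occupied by given
#' masses of fat, water, mineral and protein at their reference densities.
#' Used by the synthetic-cohort generator so that [fm_4c()] applied to the
#' generated (BV, TBW, Mo, BW) recovers the latent fat mass exactly.
#'
#' @param fm,tbw,mo,ms,protein component masses, kg.
#' @param densities a [component_densities()] object.
#' @return Body volume, L (vectorised).
#' @export
body_volume_from_components <- function(fm, tbw, mo, ms, protein,
                                        densities = component_densities()) {
  stopifnot(inherits(densities, "component_densities"))
  for (m in list(fm, tbw, mo, ms, protein))
    .check_num(m, "mass", non_negative = TRUE)
  fm / densities$fat + tbw / densities$water + mo / densities$mo +
    ms / densities$ms + protein / densities$protein
}
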