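# Test-retest reliability (technical error of measurement) and its
# propagation through the 4C linear model.

#' Technical error of measurement from duplicate trials
#'
#' Dahlberg's formula for paired test-retest data:
#' \deqn{TEM = \sqrt{\sum_i d_i^2 / (2n)}}
#' where `d_i` is the difference between the two trials of subject i.
#'
#' @param trial1,trial2 replicate measurements, same units, length >= 2.
#' @return TEM in the units of the input.
#' @export
tem_from_replicates <- function(trial1, trial2) {
  .check_num(trial1, "trial1"); .check_num(trial2, "trial2")
  if (length(trial1) != length(trial2)) .stop("replicate vectors differ in length")
  if (length(trial1) < 2) .stop("at least 2 replicate pairs are required")
  d <- trial1 - trial2
  sqrt(sum(d^2) / (2 * length(d)))
}

#' Coefficient of variation from duplicate trials
#'
#' CV (%) = 100 x TEM / grand mean of all measurements.
#'
#' @inheritParams tem_from_replicates
#' @return CV in percent.
#' @export
cv_from_replicates <- function(trial1, trial2) {
  g <- mean(c(trial1, trial2))
  if (!is.finite(g) || g <= 0) .stop("grand mean must be positive for a CV")
  100 * tem_from_replicates(trial1, trial2) / g
}

#' Laboratory TEM profile of the 4C input instruments
#'
#' Container for the per-instrument technical errors of measurement used in
#' error propagation. Defaults are the laboratory test-retest values: body
#' volume 0.2 L (ADP), total body water 0.3 kg (deuterium dilution), bone
#' mineral content 0.02 kg (DXA). Body-weight TEM defaults to 0 (scale
#' precision is negligible against the other instruments).
#'
#' @param bv_tem body-volume TEM, L.
#' @param tbw_tem total-body-water TEM, kg.
#' @param bmc_tem bone-mineral-content TEM, kg.
#' @param bw_tem body-weight TEM, kg.
#' @param cv optional named numeric vector of per-instrument CVs (%), kept
#'   for reporting only.
#' @return An object of class `tem_profile`.
#' @export
tem_profile <- function(bv_tem = 0.2, tbw_tem = 0.3, bmc_tem = 0.02,
                        bw_tem = 0, cv = NULL) {
  p <- list(bv_tem = bv_tem, tbw_tem = tbw_tem, bmc_tem = bmc_tem,
            bw_tem = bw_tem, cv = cv)
  for (nm in c("bv_tem", "tbw_tem", "bmc_tem", "bw_tem"))
    .check_num(p[[nm]], nm, non_negative = TRUE)
  structure(p, class = "tem_profile")
}

#' Propagate instrument TEMs into the 4C fat-mass estimate
#'
#' Because the 4C fat-mass model is linear in its inputs and squared
#' technical errors of measurement are independent and additive, the
#' propagated fat-mass TEM is the quadrature sum of the per-input TEMs
#' weighted by the model coefficients:
#' \deqn{TEM_{FM} = \sqrt{\sum_i (c_i \cdot TEM_i)^2}}
#' The BMC TEM is first converted to Mo units (x 1.0436). The percent-fat
#' TEM is expressed at a caller-supplied mean body weight.
#'
#' @param profile a [tem_profile()].
#' @param coeffs 4C linear coefficients, as from [fm_4c_coefficients()].
#' @param mean_bw mean body weight (kg) used to express the error in %FM.
#' @param bmc_factor BMC-to-Mo conversion factor.
#' @return List with `fm_tem` (kg) and `pfm_tem` (%FM units).
#' @examples
#' propagate_tem(tem_profile(), mean_bw = 72.8)
#' @export
propagate_tem <- function(profile = tem_profile(),
                          coeffs = fm_4c_coefficients(),
                          mean_bw, bmc_factor = 1.0436) {
  stopifnot(inherits(profile, "tem_profile"))
  .check_num(mean_bw, "mean_bw", positive = TRUE)
  fm_tem <- sqrt((coeffs[["bv"]] * profile$bv_tem)^2 +
                   (coeffs[["tbw"]] * profile$tbw_tem)^2 +
                   (coeffs[["mo"]] * bmc_factor * profile$bmc_tem)^2 +
                   (coeffs[["bw"]] * profile$bw_tem)^2)
  list(fm_tem = fm_tem, pfm_tem = 100 * fm_tem / mean_bw)
}

#' TEM/CV report from a replicate table
#'
#' Computes per-instrument TEM and CV from a long table of duplicate trials
#' (columns `subject_id`, `instrument`, `trial`, `value`; trials coded 1
#' and 2). A log line per instrument goes to `message()`.
#'
#' @param replicates data.frame or path to a CSV in the layout above.
#' @return data.frame with columns `instrument`, `n_pairs`, `tem`, `cv_pct`.
#' @export
tem_report <- function(replicates) {
  if (is.character(replicates)) replicates <- utils::read.csv(replicates)
  need <- c("subject_id", "instrument", "trial", "value")
  if (!all(need %in% names(replicates)))
    .stop("replicate table needs columns: %s", paste(need, collapse = ", "))
  out <- do.call(rbind, lapply(split(replicates, replicates$instrument), function(g) {
    w <- merge(g[g$trial == 1, c("subject_id", "value")],
               g[g$trial == 2, c("subject_id", "value")],
               by = "subject_id", suffixes = c("_1", "_2"))
    tem <- tem_from_replicates(w$value_1, w$value_2)
    data.frame(instrument = g$instrument[1], n_pairs = nrow(w), tem = tem,
               cv_pct = cv_from_replicates(w$value_1, w$value_2))
  }))
  rownames(out) <- NULL
  for (i in seq_len(nrow(out)))
    message(sprintf("TEM[%s] = %.4f (CV %.2f%%, n = %d pairs)",
                    out$instrument[i], out$tem[i], out$cv_pct[i], out$n_pairs[i]))
  out
}
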