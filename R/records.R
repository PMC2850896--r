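# Measurement-record tables: the CSV dialect shared by the generator,
# the pipeline and external data. One row per subject-phase.

.phases <- c("stability", "precompetition")

.core_cols <- c("subject_id", "phase", "bw_kg", "bv_l", "tbw_kg", "bmc_kg")
.dxa_cols <- c("dxa_fm_kg", "dxa_ffm_kg")
.regional_cols <- c("trunk_fm_kg", "trunk_lst_kg", "arms_fm_kg",
                    "arms_lst_kg", "legs_fm_kg", "legs_lst_kg")

#' Validate a measurement-record table
#'
#' Checks the structural invariants of a subject-phase table of raw inputs:
#' required columns present, phases restricted to `"stability"` /
#' `"precompetition"`, positive body weight and volume, `0 < TBW < BW`,
#' `0 < BMC < BW`, and (when DXA outputs are present)
#' `|dxa_fm + dxa_ffm - bw| <= bw_tol`.
#'
#' @param records a data.frame of measurement records.
#' @param bw_tol tolerance (kg) for the DXA mass-closure check (default 2).
#' @return `records`, invisibly, if valid; otherwise an error.
#' @export
validate_records <- function(records, bw_tol = 2) {
  if (!is.data.frame(records)) .stop("`records` must be a data.frame")
  missing_cols <- setdiff(.core_cols, names(records))
  if (length(missing_cols))
    .stop("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  if (!all(records$phase %in% .phases))
    .stop("`phase` must be one of: %s", paste(.phases, collapse = ", "))
  if (anyDuplicated(records[c("subject_id", "phase")]))
    .stop("duplicated subject_id/phase rows")
  with(records, {
    if (any(bw_kg <= 0) || any(bv_l <= 0)) .stop("bw_kg and bv_l must be positive")
    if (any(tbw_kg <= 0 | tbw_kg >= bw_kg)) .stop("tbw_kg must satisfy 0 < TBW < BW")
    if (any(bmc_kg <= 0 | bmc_kg >= bw_kg)) .stop("bmc_kg must satisfy 0 < BMC < BW")
  })
  if (all(.dxa_cols %in% names(records))) {
    ok <- is.na(records$dxa_fm_kg) | is.na(records$dxa_ffm_kg) |
      abs(records$dxa_fm_kg + records$dxa_ffm_kg - records$bw_kg) <= bw_tol
    if (!all(ok))
      .stop("dxa_fm_kg + dxa_ffm_kg deviates from bw_kg by more than %.2f kg (subject '%s')",
            bw_tol, records$subject_id[which(!ok)[1]])
  }
  invisible(records)
}

#' Read a cohort CSV
#'
#' @param path CSV file with header
#'   `subject_id, phase, bw_kg, bv_l, tbw_kg, bmc_kg, dxa_fm_kg, dxa_ffm_kg`
#'   and optional regional columns; empty cells encode missing optional
#'   values.
#' @param validate run [validate_records()] on the result (default TRUE).
#' @param bw_tol passed to the validator.
#' @return A data.frame of measurement records.
#' @export
read_cohort <- function(path, validate = TRUE, bw_tol = 2) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (validate) validate_records(records, bw_tol = bw_tol)
  records
}

#' Write a cohort CSV
#'
#' Writes the standard measurement-record dialect. Latent-truth columns
#' (`latent_*`, present in generated cohorts) are dropped unless
#' `include_latent = TRUE`. If the table carries generator metadata (seed,
#' truncation log), it is recorded in an adjacent `<path>.meta.json`.
#'
#' @param records data.frame of measurement records.
#' @param path output CSV path.
#' @param include_latent keep `latent_*` columns in the CSV.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path, include_latent = FALSE) {
  cols <- names(records)
  if (!include_latent) cols <- cols[!startsWith(cols, "latent_")]
  utils::write.csv(records[cols], path, row.names = FALSE, quote = FALSE)
  meta <- attr(records, "meta")
  if (!is.null(meta))
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Compute 4C compositions for every row of a cohort
#'
#' Applies the full 4C chain to each subject-phase row: Mo from BMC, Ms from
#' TBW, fat mass from the density-derived linear model, then the FFM
#' decomposition and density. DXA percent fat is added when DXA columns are
#' present.
#'
#' @param records measurement-record data.frame.
#' @param densities a [component_densities()] object.
#' @param ms_per_tbw soft-tissue mineral per kg TBW.
#' @param bmc_factor BMC-to-Mo conversion factor.
#' @return `records` with appended columns `mo_kg`, `ms_kg`, `fm_4c_kg`,
#'   `ffm_4c_kg`, `pfm_4c`, `m_kg`, `protein_kg`, `ffm_d`, `tbw_ffm`,
#'   `m_ffm`, `protein_ffm` and, if DXA present, `pfm_dxa`.
#' @export
compose_cohort <- function(records, densities = component_densities(),
                           ms_per_tbw = 0.0129, bmc_factor = 1.0436) {
  validate_records(records, bw_tol = Inf)
  mo <- bone_mineral_from_bmc(records$bmc_kg, bmc_factor)
  ms <- soft_tissue_mineral(records$tbw_kg, ms_per_tbw)
  fm <- fm_4c(records$bv_l, records$tbw_kg, mo, records$bw_kg,
              densities, ms_per_tbw)
  comp <- decompose_ffm(records$bw_kg, fm, records$tbw_kg, mo, ms,
                        densities, subject_id = records$subject_id)
  out <- cbind(records,
               mo_kg = comp$mo, ms_kg = comp$ms, fm_4c_kg = comp$fm,
               ffm_4c_kg = comp$ffm, pfm_4c = comp$pfm, m_kg = comp$m,
               protein_kg = comp$protein, ffm_d = comp$ffm_d,
               tbw_ffm = comp$tbw_ffm, m_ffm = comp$m_ffm,
               protein_ffm = comp$protein_ffm)
  if (all(.dxa_cols %in% names(records)))
    out$pfm_dxa <- percent_fm(records$dxa_fm_kg, records$bw_kg)
  out
}
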