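#' Component densities of the molecular body compartments
#'
#' Densities (g/cc, equivalently kg/L) of the four fat-free-mass components
#' plus fat, used throughout the 4C model. Defaults are the reference values
#' for water, osseous mineral, soft-tissue mineral and protein, and the
#' standard triglyceride density for fat. Masses are carried in kg and
#' volumes in L, so densities are applied without unit conversion factors.
#'
#' @param water,mineral_osseous,mineral_soft,protein,fat densities in g/cc.
#' @return An object of class `component_densities`: a named list with
#'   elements `water`, `mo`, `ms`, `protein`, `fat`.
#' @examples
#' component_densities()
#' @export
component_densities <- function(water = 0.9937, mineral_osseous = 2.982,
                                mineral_soft = 3.317, protein = 1.34,
                                fat = 0.9007) {
  d <- list(water = water, mo = mineral_osseous, ms = mineral_soft,
            protein = protein, fat = fat)
  for (nm in names(d)) .check_num(d[[nm]], nm, positive = TRUE)
  structure(d, class = "component_densities")
}

#' Linear coefficients of the 4C fat-mass model
#'
#' The 4C model expresses fat mass as a linear combination of body volume
#' (BV, L), total body water (TBW, kg), osseous mineral (Mo, kg) and body
#' weight (BW, kg). The coefficients are derived analytically from the
#' two-equation system
#' \deqn{BW = FM + TBW + Mo + Ms + P}
#' \deqn{BV = FM/d_{fat} + TBW/d_{water} + Mo/d_{mo} + Ms/d_{ms} + P/d_{protein}}
#' solved for FM after substituting the soft-tissue mineral model
#' Ms = 0.0129 TBW. With the default densities this evaluates to
#' (2.747, -0.699, 1.129, -2.050), matching the published equation
#' (2.748 BV - 0.699 TBW + 1.129 Mo - 2.051 BW) to within one unit in the
#' third decimal; the residual discrepancy traces to rounding in the
#' published coefficients, so the derived (self-consistent) values are used.
#'
#' @param densities a [component_densities()] object.
#' @param ms_per_tbw soft-tissue mineral per kg of TBW (default 0.0129).
#' @return Named numeric vector with elements `bv`, `tbw`, `mo`, `bw`.
#' @examples
#' round(fm_4c_coefficients(), 3)
#' @export
fm_4c_coefficients <- function(densities = component_densities(),
                               ms_per_tbw = 0.0129) {
  stopifnot(inherits(densities, "component_densities"))
  .check_num(ms_per_tbw, "ms_per_tbw", non_negative = TRUE)
  inv <- lapply(densities, function(d) 1 / d)
  k <- 1 / (inv$fat - inv$protein)
  c(bv  = k,
    tbw = -k * ((inv$water - inv$protein) + ms_per_tbw * (inv$ms - inv$protein)),
    mo  = -k * (inv$mo - inv$protein),
    bw  = -k * inv$protein)
}
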