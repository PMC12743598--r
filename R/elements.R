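# Physical constants used by the stopping-power routines.
# Proton and electron rest energies in MeV; molar masses at 4 significant
# figures per the tabulation conventions of the stoichiometric literature.
PROTON_MASS_MEV <- 938.272
ELECTRON_MASS_MEV <- 0.511

#' Element data for Bragg-additivity stopping-power calculations
#'
#' Atomic number, molar mass (g/mol) and mean excitation energy I (eV) for
#' the elements occurring in human reference tissues, following the I-value
#' convention of ICRU reports 37/49. The packaged table can be replaced by
#' any CSV with columns `symbol, Z, A, I_eV`, e.g. to study the sensitivity
#' of SPR ratios to the chosen I-value set.
#'
#' @param path Optional path to an alternative element-data CSV.
#' @return A data frame with columns `symbol`, `Z`, `A`, `I_eV`.
#' @examples
#' head(element_data())
#' @export
element_data <- function(path = NULL) {
  if (is.null(path)) path <- mrispr_extdata("element_data.csv")
  el <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("symbol", "Z", "A", "I_eV")
  if (!all(need %in% names(el))) {
    stop("element data must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- el$Z < 1 | el$A <= 0 | el$I_eV <= 0
  if (any(bad)) {
    stop("invalid element data for: ", paste(el$symbol[bad], collapse = ", "),
         call. = FALSE)
  }
  el
}

#' Water reference medium
#'
#' The water constants against which tissue hydrogen concentrations and
#' stopping powers are normalised.
#'
#' Two conventions are provided. `"icru46"` uses the hydrogen weight
#' fraction as printed in the ICRU 46 composition tables (11.2 %, three
#' significant figures) and unit density; this is the reference that
#' reproduces the published tissue hydrogen-ratio values at three decimals.
#' `"molar"` derives the fraction from molar masses (2 x 1.008 / 18.015 =
#' 11.19 %) with the room-temperature density 0.998 g/cm3, and is the
#' natural reference for the D2O-H2O phantom chemistry where all quantities
#' come from the same molar-mass arithmetic.
#'
#' @param convention `"icru46"` (default) or `"molar"`.
#' @return A list with elements `wh` (hydrogen weight percent), `rho`
#'   (g/cm3) and `fractions` (named weight-percent vector).
#' @examples
#' water_reference()$wh
#' water_reference("molar")$wh
#' @export
water_reference <- function(convention = c("icru46", "molar")) {
  convention <- match.arg(convention)
  if (convention == "icru46") {
    wh <- 11.2
    rho <- 1.000
  } else {
    wh <- 100 * 2 * MOLAR_MASS$H / MOLAR_MASS$H2O
    rho <- 0.998
  }
  list(wh = wh, rho = rho, fractions = c(H = wh, O = 100 - wh),
       convention = convention)
}
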