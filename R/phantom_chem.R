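# Molar masses (g/mol) for the D2O-H2O mixture arithmetic.
MOLAR_MASS <- list(H = 1.008, H2O = 18.015, D2O = 20.028)
# Room-temperature default densities (g/cm3); overridable everywhere, and a
# measured density always takes precedence because D2O-H2O mixing shows a
# partial-molar-volume deviation from ideal behaviour.
DEFAULT_RHO_H2O <- 0.998
DEFAULT_RHO_D2O <- 1.105

#' Weight fractions of a two-component mixture
#'
#' @param m_h2o,m_d2o Masses (g) of H2O and D2O, non-negative, not both
#'   zero.
#' @return Named vector `c(w_h2o, w_d2o)` in percent, summing to 100.
#' @examples
#' weight_fractions(29.95, 70.05)
#' @export
weight_fractions <- function(m_h2o, m_d2o) {
  if (m_h2o < 0 || m_d2o < 0 || (m_h2o + m_d2o) == 0) {
    stop("masses must be >= 0 and not both zero", call. = FALSE)
  }
  w <- 100 * m_h2o / (m_h2o + m_d2o)
  c(w_h2o = w, w_d2o = 100 - w)
}

#' Hydrogen weight fraction of a D2O-H2O solution
#'
#' Only the light-water component carries MRI-visible hydrogen (two
#' hydrogen atoms per H2O molecule); deuterium resonates elsewhere and is
#' invisible at the hydrogen frequency. The hydrogen weight percent is
#' \deqn{w_H = 100 \cdot w_{H2O} \cdot 2 M_H /
#'   (w_{H2O} M_{H2O} + w_{D2O} M_{D2O}).}
#'
#' @param w_h2o,w_d2o Weight percentages summing to 100 (within 0.01).
#' @return Hydrogen weight percent.
#' @examples
#' hydrogen_weight_fraction(100, 0)   # 11.19
#' hydrogen_weight_fraction(0, 100)   # 0
#' @export
hydrogen_weight_fraction <- function(w_h2o, w_d2o) {
  if (any(c(w_h2o, w_d2o) < 0)) {
    stop("weight fractions must be >= 0", call. = FALSE)
  }
  # tolerance accommodates tables of independently rounded fractions
  if (abs(w_h2o + w_d2o - 100) > 0.1) {
    stop("weight fractions must sum to 100", call. = FALSE)
  }
  100 * w_h2o * 2 * MOLAR_MASS$H /
    (w_h2o * MOLAR_MASS$H2O + w_d2o * MOLAR_MASS$D2O)
}

#' Ideal-mixture density of a D2O-H2O solution
#'
#' Mass-weighted harmonic mean of the component densities, i.e. the
#' density the mixture would have if the volumes were additive:
#' \deqn{\rho = (w_{H2O} + w_{D2O}) /
#'   (w_{H2O}/\rho_{H2O} + w_{D2O}/\rho_{D2O}).}
#' Real D2O-H2O solutions deviate slightly (partial molar volume effect),
#' so a measured density should be preferred when available; see
#' [partial_molar_deviation()].
#'
#' @param w_h2o,w_d2o Weight percentages.
#' @param rho_h2o,rho_d2o Component densities, g/cm3, > 0.
#' @return Ideal mixture density, g/cm3.
#' @examples
#' ideal_density(50, 50)
#' @export
ideal_density <- function(w_h2o, w_d2o, rho_h2o = DEFAULT_RHO_H2O,
                          rho_d2o = DEFAULT_RHO_D2O) {
  if (rho_h2o <= 0 || rho_d2o <= 0) {
    stop("component densities must be positive", call. = FALSE)
  }
  (w_h2o + w_d2o) / (w_h2o / rho_h2o + w_d2o / rho_d2o)
}

#' Describe a D2O-H2O solution
#'
#' Builds the full record of one calibration solution from the component
#' masses: weight fractions, hydrogen weight fraction, density (measured
#' when given, otherwise the ideal-mixture estimate) and the
#' solution-water hydrogen-concentration ratio.
#'
#' @param m_h2o,m_d2o Component masses (g).
#' @param rho_measured Measured solution density (g/cm3), or `NA`.
#' @param rho_h2o,rho_d2o Component densities for the ideal estimate and
#'   the water reference.
#' @return A one-row data frame of class `"solution_spec"` with columns
#'   `m_h2o`, `m_d2o`, `w_h2o`, `w_d2o`, `w_h`, `rho_ideal`,
#'   `rho_measured`, `rho`, `h_ratio`.
#' @examples
#' solution_spec(50.08, 49.92)
#' @export
solution_spec <- function(m_h2o, m_d2o, rho_measured = NA_real_,
                          rho_h2o = DEFAULT_RHO_H2O,
                          rho_d2o = DEFAULT_RHO_D2O) {
  w <- weight_fractions(m_h2o, m_d2o)
  wh <- hydrogen_weight_fraction(w[["w_h2o"]], w[["w_d2o"]])
  rho_i <- ideal_density(w[["w_h2o"]], w[["w_d2o"]], rho_h2o, rho_d2o)
  rho <- if (!is.na(rho_measured)) rho_measured else rho_i
  out <- data.frame(m_h2o = m_h2o, m_d2o = m_d2o,
                    w_h2o = w[["w_h2o"]], w_d2o = w[["w_d2o"]],
                    w_h = wh, rho_ideal = rho_i,
                    rho_measured = rho_measured, rho = rho,
                    h_ratio = solution_h_ratio(wh, rho, rho_h2o = rho_h2o))
  class(out) <- c("solution_spec", class(out))
  out
}

#' Solution-water hydrogen-concentration ratio
#'
#' Same ratio as [hydrogen_ratio()], with the water reference taken from
#' the molar-mass convention (pure H2O: wH = 2 x 1.008 / 18.015, density
#' `rho_h2o`) so that a 100 % H2O solution gives exactly 1.
#'
#' @param w_h Hydrogen weight percent of the solution.
#' @param rho Solution density (g/cm3); pass the measured value when one
#'   exists -- the ideal-mixture estimate ignores the partial molar volume
#'   effect.
#' @param rho_h2o Density of the pure-water reference.
#' @return Dimensionless hydrogen-concentration ratio in [0, 1] for any
#'   D2O-H2O mixture.
#' @examples
#' solution_h_ratio(hydrogen_weight_fraction(100, 0), 0.998)  # 1
#' @export
solution_h_ratio <- function(w_h, rho, rho_h2o = DEFAULT_RHO_H2O) {
  if (any(rho <= 0)) stop("solution density must be positive", call. = FALSE)
  wh_w <- 100 * 2 * MOLAR_MASS$H / MOLAR_MASS$H2O
  (w_h / 100 * rho) / (wh_w / 100 * rho_h2o)
}

#' Design a D2O-H2O solution for a target hydrogen ratio
#'
#' Inverse-solves the chemistry chain (weight fraction, hydrogen weight
#' fraction, ideal density, hydrogen ratio) for the H2O weight fraction
#' that realises a requested solution-water hydrogen-concentration ratio.
#' The ideal-mixture density serves as the design estimate; the realised
#' solution should still have its density measured.
#'
#' @param target_h Target hydrogen ratio in (0, 1].
#' @param rho_h2o,rho_d2o Component densities.
#' @param total_mass Total solution mass (g) used to report the component
#'   masses.
#' @return A `"solution_spec"` row (see [solution_spec()]) whose
#'   `h_ratio` matches `target_h` to better than 1e-6.
#' @examples
#' design_solution(0.30)$w_h2o  # about 29.9
#' @export
design_solution <- function(target_h, rho_h2o = DEFAULT_RHO_H2O,
                            rho_d2o = DEFAULT_RHO_D2O, total_mass = 100) {
  if (is.na(target_h) || target_h <= 0 || target_h > 1) {
    stop("target hydrogen ratio must lie in (0, 1]", call. = FALSE)
  }
  f <- function(w) {
    wh <- hydrogen_weight_fraction(w, 100 - w)
    rho <- ideal_density(w, 100 - w, rho_h2o, rho_d2o)
    solution_h_ratio(wh, rho, rho_h2o) - target_h
  }
  w <- if (target_h == 1) 100 else
    stats::uniroot(f, c(1e-9, 100), tol = 1e-10)$root
  solution_spec(total_mass * w / 100, total_mass * (100 - w) / 100,
                rho_h2o = rho_h2o, rho_d2o = rho_d2o)
}

#' Design the full calibration phantom
#'
#' One solution per target hydrogen ratio, spanning the hydrogen range of
#' human tissues (inflated lung ~0.24 up to water 1.00).
#'
#' @param targets Vector of target hydrogen ratios (default the ten-level
#'   grid 1.00 down to 0.30).
#' @param ... Passed to [design_solution()].
#' @return A data frame, one `"solution_spec"` row per target, with a
#'   `target_h` column prepended.
#' @examples
#' design_phantom()[, c("target_h", "w_h2o", "h_ratio")]
#' @export
design_phantom <- function(targets = c(1.00, 0.95, 0.90, 0.85, 0.80,
                                       0.70, 0.60, 0.50, 0.40, 0.30),
                           ...) {
  rows <- lapply(targets, function(t) {
    s <- design_solution(t, ...)
    cbind(data.frame(target_h = t), as.data.frame(s))
  })
  do.call(rbind, rows)
}

#' Partial-molar-volume deviation of a measured density
#'
#' Percent deviation of a measured solution density from the ideal
#' (volume-additive) mixture density. A non-zero value is the signature
#' of the partial molar volume effect and the reason measured densities
#' override calculated ones throughout the phantom chemistry.
#'
#' @param rho_measured Measured density (g/cm3).
#' @param rho_ideal Ideal-mixture density (g/cm3), e.g. from
#'   [ideal_density()].
#' @return Signed percent deviation.
#' @examples
#' partial_molar_deviation(1.05, 1.04)
#' @export
partial_molar_deviation <- function(rho_measured, rho_ideal) {
  100 * (rho_measured - rho_ideal) / rho_ideal
}

#' Published phantom solution table
#'
#' The ten-solution D2O-H2O calibration phantom of the reference FSE/GRE
#' measurement campaign: target hydrogen ratios, realised weight
#' fractions, and the SNR measured with the FSE- and GRE-based
#' proton-density-weighted sequences.
#'
#' @return Data frame `solution`, `h_ratio`, `w_h2o`, `w_d2o`,
#'   `snr_fse`, `snr_gre`.
#' @examples
#' phantom_solutions()
#' @export
phantom_solutions <- function() {
  utils::read.csv(mrispr_extdata("d2o_phantom_solutions.csv"))
}

#' Published positional SNR relative differences
#'
#' Per-solution relative differences (percent) between the SNR measured
#' at two arbitrary phantom positions (90 degree rotation; couch edge)
#' and at the primary position, for the FSE-based sequence.
#'
#' @return Data frame `solution`, `rotation_90`, `couch_edge`.
#' @examples
#' type_a_rms(positional_reference_deltas()$rotation_90)
#' @export
positional_reference_deltas <- function() {
  utils::read.csv(mrispr_extdata("snr_positional_deltas.csv"))
}
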