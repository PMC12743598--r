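#' Relativistic beta squared of a proton
#'
#' \eqn{\beta^2 = 1 - (m_p c^2 / (T + m_p c^2))^2} for kinetic energy
#' `T` (MeV), with \eqn{m_p c^2 = 938.272} MeV.
#'
#' @param kinetic_energy Proton kinetic energy in MeV (vectorised, > 0).
#' @return Dimensionless \eqn{\beta^2} in (0, 1).
#' @examples
#' beta_squared(100)
#' @export
beta_squared <- function(kinetic_energy) {
  if (any(kinetic_energy <= 0)) {
    stop("kinetic energy must be positive", call. = FALSE)
  }
  1 - (PROTON_MASS_MEV / (kinetic_energy + PROTON_MASS_MEV))^2
}

# Electron-mole density per gram: sum_i w_i Z_i / A_i (w in percent).
# Returns a vector, one value per composition row.
.electrons_per_gram <- function(comp, elements) {
  el_cols <- intersect(setdiff(names(comp), .comp_meta_cols),
                       elements$symbol)
  missing <- setdiff(setdiff(names(comp), .comp_meta_cols), elements$symbol)
  if (length(missing) > 0) {
    stop("no element data for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  w <- as.matrix(comp[, el_cols, drop = FALSE])
  e <- elements[match(el_cols, elements$symbol), ]
  list(za = as.vector(w %*% (e$Z / e$A)) / 100,
       w = w, el = e)
}

#' Mean excitation energy of a compound medium (Bragg additivity)
#'
#' Combines elemental mean excitation energies into the compound I-value by
#' electron-fraction-weighted log averaging:
#' \deqn{\ln I = \sum_i (w_i Z_i / A_i \ln I_i) / \sum_i (w_i Z_i / A_i).}
#'
#' @param comp A composition data frame (one or more rows) or a named
#'   numeric vector of weight percentages (names are element symbols).
#' @param elements Element data (see [element_data()]).
#' @return Mean excitation energy (or energies) in eV.
#' @examples
#' mean_excitation_energy(c(H = 11.19, O = 88.81))
#' @export
mean_excitation_energy <- function(comp, elements = element_data()) {
  if (is.numeric(comp) && !is.null(names(comp))) {
    comp <- as.data.frame(as.list(comp))
    comp$name <- "medium"
    comp$rho_g_cm3 <- 1
  }
  x <- .electrons_per_gram(comp, elements)
  if (any(x$za <= 0)) {
    stop("medium has no electrons: cannot form a mean excitation energy",
         call. = FALSE)
  }
  lnI <- as.vector(x$w %*% ((x$el$Z / x$el$A) * log(x$el$I_eV))) / 100 / x$za
  exp(lnI)
}

# First-order Bethe stopping number L = ln(2 me c^2 b^2 / (I (1-b^2))) - b^2
# with I in eV. No shell, Barkas or density-effect corrections: in the
# tissue-to-water ratio at therapeutic energies these cancel to well below
# the percent scale of the uncertainty budget.
.stopping_number <- function(I_eV, energy) {
  b2 <- beta_squared(energy)
  arg <- 2 * ELECTRON_MASS_MEV * 1e6 * b2 / (I_eV * (1 - b2))
  if (any(arg <= exp(1))) {
    stop("Bethe stopping number invalid at ", format(energy),
         " MeV for I = ", format(I_eV),
         " eV; use energies in the therapeutic range (>= 1 MeV)",
         call. = FALSE)
  }
  log(arg) - b2
}

#' Proton mass stopping power of a medium (first-order Bethe-Bloch)
#'
#' Electronic mass stopping power in MeV cm2/g from the first-order Bethe
#' formula with Bragg-additivity mean excitation energy. Intended for
#' forming tissue-water ratios; nuclear interactions, straggling and the
#' shell/Barkas/density-effect corrections are out of scope.
#'
#' @param comp Composition data frame (one or more rows) or named
#'   weight-percent vector.
#' @param energy Proton kinetic energy in MeV.
#' @param elements Element data.
#' @return Mass stopping power(s), MeV cm2/g.
#' @examples
#' mass_stopping_power(c(H = 11.19, O = 88.81), 100)
#' @export
mass_stopping_power <- function(comp, energy, elements = element_data()) {
  if (is.numeric(comp) && !is.null(names(comp))) {
    comp <- as.data.frame(as.list(comp))
    comp$name <- "medium"
    comp$rho_g_cm3 <- 1
  }
  x <- .electrons_per_gram(comp, elements)
  I <- mean_excitation_energy(comp, elements)
  b2 <- beta_squared(energy)
  K <- 0.307075  # 4 pi N_A re^2 me c^2, MeV cm2 / mol
  K * x$za / b2 * .stopping_number(I, energy)
}

#' Tissue-water SPR from the Bethe-Bloch equation
#'
#' Computes the linear stopping-power ratio of each medium in a composition
#' table to water at a given proton energy:
#' \deqn{SPR = \frac{\rho_t \sum w_i Z_i/A_i}{\rho_w \sum w_i Z_i/A_i|_w}
#'   \cdot \frac{L(I_t)}{L(I_w)}}
#' with \eqn{L} the first-order Bethe stopping number. The water
#' denominator uses the same Bragg-additivity I-value rule as the
#' numerator, so identical media give exactly 1 at every energy and the
#' systematic bias of the first-order form cancels in the ratio.
#'
#' @param comp Composition data frame (one or more rows).
#' @param water Water composition used as the denominator. Default is the
#'   molar-mass water composition (H 11.19 %, O 88.81 %, rho 1.000 g/cm3).
#' @param energy Proton kinetic energy in MeV, 1-300.
#' @param elements Element data.
#' @return Numeric vector of SPR values, one per composition row.
#' @examples
#' comp <- icru46_compositions()
#' round(spr_bethe(comp[comp$name == "Cortical bone", ], energy = 100), 3)
#' @export
spr_bethe <- function(comp, water = NULL, energy = 100,
                      elements = element_data()) {
  if (energy < 1 || energy > 300) {
    stop("energy must lie in [1, 300] MeV", call. = FALSE)
  }
  if (is.null(water)) {
    wm <- water_reference("molar")
    water <- data.frame(name = "Water", group = "reference",
                        rho_g_cm3 = 1.000,
                        H = wm$wh, O = 100 - wm$wh,
                        stringsAsFactors = FALSE)
  }
  xt <- .electrons_per_gram(comp, elements)
  xw <- .electrons_per_gram(water, elements)
  It <- mean_excitation_energy(comp, elements)
  Iw <- mean_excitation_energy(water, elements)
  num <- comp$rho_g_cm3 * xt$za * .stopping_number(It, energy)
  den <- water$rho_g_cm3[1] * xw$za[1] * .stopping_number(Iw, energy)
  num / den
}
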