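# Columns of a composition table that are not element weight fractions.
.comp_meta_cols <- c("name", "group", "source", "note", "rho_g_cm3",
                     "lipid_pct")
.comp_groups <- c("soft", "bone", "lung_related", "reference")

#' Read and validate a medium composition table
#'
#' Reads a CSV of media (tissues, reference liquids, air) described by mass
#' density and elemental weight fractions. The expected dialect is
#' comma-separated UTF-8 with one header row: a `name` column, a `group`
#' column (`soft`, `bone`, `lung_related` or `reference`), a density column
#' `rho_g_cm3`, and one column per element labelled by its chemical symbol,
#' holding weight percentages. Optional columns `source`, `note` and
#' `lipid_pct` are carried through.
#'
#' Each row is validated: density must be positive, all fractions
#' non-negative, fractions must sum to 100 within +/- 0.1, and every element
#' symbol must be known to [element_data()]. Violations are reported with
#' the offending row name.
#'
#' @param path Path to the CSV file.
#' @param elements Element data frame used to check symbols.
#' @return A validated data frame, row order preserved.
#' @seealso [icru46_compositions()], [alt_compositions()]
#' @examples
#' comp <- icru46_compositions()
#' nrow(comp)
#' @export
read_compositions <- function(path, elements = element_data()) {
  comp <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(comp) == 0) {
    stop("composition table '", path, "' has no rows", call. = FALSE)
  }
  if (!all(c("name", "rho_g_cm3") %in% names(comp))) {
    stop("composition table must declare 'name' and 'rho_g_cm3' columns",
         call. = FALSE)
  }
  el_cols <- setdiff(names(comp), .comp_meta_cols)
  unknown <- setdiff(el_cols, elements$symbol)
  if (length(unknown) > 0) {
    stop("unknown element symbol(s) in composition table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!("group" %in% names(comp))) comp$group <- "soft"
  badg <- !(comp$group %in% .comp_groups)
  if (any(badg)) {
    stop("invalid group for '", comp$name[which(badg)[1]],
         "': must be one of ", paste(.comp_groups, collapse = ", "),
         call. = FALSE)
  }
  frac <- as.matrix(comp[, el_cols, drop = FALSE])
  if (any(is.na(frac)) || any(is.na(comp$rho_g_cm3))) {
    stop("malformed row '",
         comp$name[which(rowSums(is.na(frac)) > 0 | is.na(comp$rho_g_cm3))[1]],
         "': missing density or fraction value", call. = FALSE)
  }
  if (any(comp$rho_g_cm3 <= 0)) {
    stop("malformed row '", comp$name[which(comp$rho_g_cm3 <= 0)[1]],
         "': density must be positive", call. = FALSE)
  }
  if (any(frac < 0)) {
    stop("malformed row '", comp$name[which(rowSums(frac < 0) > 0)[1]],
         "': negative weight fraction", call. = FALSE)
  }
  s <- rowSums(frac)
  off <- s < 99.9 | s > 100.1
  if (any(off)) {
    stop("malformed row '", comp$name[which(off)[1]],
         "': weight fractions sum to ", format(s[which(off)[1]]),
         " (must lie in [99.9, 100.1])", call. = FALSE)
  }
  attr(comp, "element_cols") <- el_cols
  comp
}

#' Reference tissue compositions (ICRU 46 adult tissues)
#'
#' The 34 adult reference media (33 tissues plus water) used throughout the
#' package: mass density and elemental weight fractions. Values were
#' transcribed from the ICRU 46 / Woodard & White compendia; every row was
#' verified to reproduce the published tissue-water hydrogen-concentration
#' ratio at three decimals and the published 100 MeV SPR within 1 %. The
#' congested-lung row could not be transcribed from a primary source and was
#' reconstructed (density 1.04 g/cm3, wH 10.5 %) to be consistent with the
#' published hydrogen ratio and SPR of that tissue.
#'
#' @return A validated composition data frame (see [read_compositions()]).
#' @examples
#' subset(icru46_compositions(), group == "bone")$name
#' @export
icru46_compositions <- function() {
  read_compositions(mrispr_extdata("icru46_compositions.csv"))
}

#' Alternative tissue compositions for composition-variability analysis
#'
#' A representative subset of tissue compositions from sources other than
#' ICRU 46: Woodard & White grade-1/2/3 soft tissues (including the three
#' adipose grades with their lipid weight percentages), ICRP 110 media (air
#' and compressed lung for the lung-related calibration, alternative
#' cortical bone), and Hough et al. bone samples. Rows whose values could
#' not be transcribed verbatim from the reference compendia carry
#' `note == "reconstructed"`: they are synthetic but span the realistic
#' composition ranges of the sources. The set is deliberately small; it
#' exercises the composition-variability machinery rather than reproducing
#' any particular published Type B value.
#'
#' @return A validated composition data frame.
#' @examples
#' table(alt_compositions()$source)
#' @export
alt_compositions <- function() {
  read_compositions(mrispr_extdata("alt_compositions.csv"))
}

#' Published hydrogen-ratio and SPR values for the ICRU 46 tissues
#'
#' The reference table of tissue-water hydrogen-concentration ratios and
#' 100 MeV linear stopping-power ratios for the 34 adult media, as published
#' (three decimals). This is the canonical input for fitting the
#' hydrogen-to-SPR calibration; `group` assigns water to the soft-tissue
#' group and cartilage to the bone group (the package's default grouping,
#' adjustable via [assign_groups()]).
#'
#' @return A data frame with columns `name`, `group`, `h_ratio`, `spr`.
#' @examples
#' head(icru46_reference_values())
#' @export
icru46_reference_values <- function() {
  ref <- utils::read.csv(mrispr_extdata("icru46_reference_values.csv"),
                         stringsAsFactors = FALSE)
  ref
}

#' Reassign group membership of individual media
#'
#' The published analysis does not state explicitly whether water and
#' cartilage were pooled with the soft or the skeletal group when group-wise
#' statistics were computed. This helper makes the assignment explicit and
#' reproducible.
#'
#' @param tissues Data frame with `name` and `group` columns.
#' @param ... Named assignments, e.g. `Cartilage = "soft"`.
#' @return The data frame with updated `group` values.
#' @examples
#' t1 <- assign_groups(icru46_reference_values(), Cartilage = "soft")
#' @export
assign_groups <- function(tissues, ...) {
  changes <- list(...)
  for (nm in names(changes)) {
    hit <- tissues$name == nm
    if (!any(hit)) stop("no medium named '", nm, "'", call. = FALSE)
    grp <- as.character(changes[[nm]])
    if (!(grp %in% .comp_groups)) {
      stop("invalid group '", grp, "'", call. = FALSE)
    }
    tissues$group[hit] <- grp
  }
  tissues
}

#' Combine composition tables with different column sets
#'
#' Row-binds composition tables whose element columns differ: absent
#' element columns are filled with zero weight, absent metadata columns
#' with `NA`.
#'
#' @param ... Composition data frames.
#' @return One combined composition data frame.
#' @export
rbind_compositions <- function(...) {
  tabs <- list(...)
  cols <- unique(unlist(lapply(tabs, names)))
  meta <- intersect(cols, .comp_meta_cols)
  cols <- c(meta, setdiff(cols, .comp_meta_cols))
  do.call(rbind, lapply(tabs, function(t) {
    for (cl in setdiff(cols, names(t))) {
      t[[cl]] <- if (cl %in% .comp_meta_cols) NA else 0
    }
    t[, cols, drop = FALSE]
  }))
}

#' Tissue-water hydrogen-concentration ratio
#'
#' The hydrogen concentration of a medium per unit volume is its hydrogen
#' weight fraction times its mass density; the tissue-water ratio
#' normalises this to water:
#' \deqn{H = (wH_t/100 \times \rho_t) / (wH_w/100 \times \rho_w).}
#' A medium without hydrogen (e.g. air) has ratio 0.
#'
#' @param wh Hydrogen weight percent of the medium (vectorised).
#' @param rho Mass density of the medium in g/cm3 (vectorised).
#' @param water Water reference, see [water_reference()].
#' @return Dimensionless hydrogen-concentration ratio(s).
#' @examples
#' hydrogen_ratio(3.4, 1.92)   # cortical bone -> 0.583
#' hydrogen_ratio(11.4, 0.95)  # adipose -> 0.967
#' @export
hydrogen_ratio <- function(wh, rho, water = water_reference()) {
  if (any(wh < 0) || any(rho <= 0)) {
    stop("hydrogen fraction must be >= 0 and density > 0", call. = FALSE)
  }
  if (water$wh <= 0) {
    stop("reference water has no hydrogen: ratio undefined", call. = FALSE)
  }
  (wh / 100 * rho) / (water$wh / 100 * water$rho)
}

#' Hydrogen ratios for a composition table
#'
#' Applies [hydrogen_ratio()] to every row of a validated composition table.
#'
#' @param comp Composition data frame (see [read_compositions()]).
#' @param water Water reference.
#' @return Numeric vector of hydrogen-concentration ratios, one per row.
#' @examples
#' comp <- icru46_compositions()
#' round(composition_h_ratio(comp)[comp$name == "Cortical bone"], 3)
#' @export
composition_h_ratio <- function(comp, water = water_reference()) {
  wh <- if ("H" %in% names(comp)) comp$H else rep(0, nrow(comp))
  hydrogen_ratio(wh, comp$rho_g_cm3, water)
}

#' Linear stopping-power ratio from mass stopping powers
#'
#' The linear stopping power of a medium is its mass stopping power times
#' its density; the tissue-water ratio is therefore
#' \deqn{SPR = (S/\rho)_t \rho_t / ((S/\rho)_w \rho_w).}
#'
#' @param s_over_rho_t Tissue mass stopping power, MeV cm2/g.
#' @param rho_t Tissue mass density, g/cm3.
#' @param s_over_rho_w Water mass stopping power, MeV cm2/g.
#' @param rho_w Water mass density, g/cm3.
#' @return Dimensionless linear stopping-power ratio.
#' @examples
#' spr_from_mass_stopping_power(6.0, 1.5, 7.5, 1.0)  # 1.2
#' @export
spr_from_mass_stopping_power <- function(s_over_rho_t, rho_t,
                                         s_over_rho_w, rho_w = 1.0) {
  args <- c(s_over_rho_t, rho_t, s_over_rho_w, rho_w)
  if (any(args <= 0)) {
    stop("all stopping powers and densities must be positive", call. = FALSE)
  }
  (s_over_rho_t * rho_t) / (s_over_rho_w * rho_w)
}

#' Tissue records: hydrogen ratio plus SPR per energy
#'
#' Builds the per-tissue record table used by the calibration and the
#' uncertainty analysis: for every row of a composition table, the
#' hydrogen-concentration ratio and the Bethe-Bloch SPR at each requested
#' proton energy.
#'
#' @param comp Composition data frame.
#' @param energies Proton kinetic energies in MeV (default the reporting
#'   grid 70, 100, 150, 230).
#' @param water Water reference for the hydrogen ratio.
#' @param elements Element data for the Bethe-Bloch computation.
#' @return A data frame with columns `name`, `group`, `h_ratio` and one
#'   `spr_<E>` column per energy.
#' @examples
#' rec <- tissue_records(icru46_compositions(), energies = 100)
#' head(rec)
#' @export
tissue_records <- function(comp, energies = c(70, 100, 150, 230),
                           water = water_reference(),
                           elements = element_data()) {
  rec <- data.frame(name = comp$name, group = comp$group,
                    h_ratio = composition_h_ratio(comp, water),
                    stringsAsFactors = FALSE)
  for (e in energies) {
    rec[[paste0("spr_", format(e))]] <- spr_bethe(comp, energy = e,
                                                  elements = elements)
  }
  rec
}
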