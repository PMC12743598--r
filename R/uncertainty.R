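#' Type A uncertainty: root mean square of relative differences
#'
#' Statistically evaluated (Type A) uncertainty of a set of signed percent
#' deviations, \eqn{u_A = \sqrt{\sum_i \delta_i^2 / N}}. Equals the
#' population standard deviation whenever the deltas have zero mean.
#'
#' @param deltas Non-empty numeric vector of relative differences (percent).
#' @return RMS value (percent).
#' @examples
#' type_a_rms(c(1, -1))
#' @export
type_a_rms <- function(deltas) {
  if (length(deltas) == 0 || any(is.na(deltas))) {
    stop("need a non-empty vector of relative differences", call. = FALSE)
  }
  sqrt(mean(deltas^2))
}

#' Type B uncertainty: rectangular distribution over an observed range
#'
#' When only the extreme deviations are trusted, the deviations are
#' modelled as uniform over `[delta_min, delta_max]`; the standard
#' uncertainty of that rectangular distribution is the half-range over
#' \eqn{\sqrt 3}: \eqn{u_B = (\delta_{max} - \delta_{min}) / (2\sqrt 3)}.
#'
#' @param delta_max,delta_min Extreme relative differences (percent),
#'   `delta_max >= delta_min`. Alternatively pass a vector of deltas as
#'   the first argument and the extremes are taken from it.
#' @return Standard uncertainty (percent).
#' @examples
#' type_b_rectangular(1, -1)          # 0.577
#' type_b_rectangular(c(2, 0.3, -1))  # same as (2, -1)
#' @export
type_b_rectangular <- function(delta_max, delta_min = NULL) {
  if (is.null(delta_min)) {
    if (length(delta_max) < 1) stop("empty delta vector", call. = FALSE)
    delta_min <- min(delta_max)
    delta_max <- max(delta_max)
  }
  if (delta_max < delta_min) {
    stop("delta_max must be >= delta_min", call. = FALSE)
  }
  (delta_max - delta_min) / (2 * sqrt(3))
}

#' Root-sum-square composition of uncertainty components
#'
#' @param components Non-empty numeric vector of standard uncertainties
#'   (percent), or an `"uncertainty_budget"` component table.
#' @return Composite standard uncertainty \eqn{\sqrt{\sum u_i^2}}.
#' @examples
#' composite_rss(c(3, 4))  # 5
#' @export
composite_rss <- function(components) {
  if (is.data.frame(components)) components <- components$value
  if (length(components) == 0) {
    stop("need at least one uncertainty component", call. = FALSE)
  }
  if (any(components < 0)) {
    stop("uncertainty components must be >= 0", call. = FALSE)
  }
  sqrt(sum(components^2))
}

#' Welch-Satterthwaite effective degrees of freedom
#'
#' \deqn{\nu_{eff} = (\sum u_i^2)^2 / \sum (u_i^4 / \nu_i).}
#' Components without a stated degrees of freedom (`NA`) are excluded, the
#' convention used when a sensitivity term is recorded in a budget without
#' a statistical sample behind it.
#'
#' @param u Standard uncertainties (percent).
#' @param dof Degrees of freedom, same length as `u`; `NA` to exclude a
#'   component.
#' @return Effective degrees of freedom.
#' @examples
#' welch_satterthwaite(c(1, 1), c(10, 10))  # 20
#' @export
welch_satterthwaite <- function(u, dof) {
  if (length(u) != length(dof)) {
    stop("'u' and 'dof' must have the same length", call. = FALSE)
  }
  keep <- !is.na(dof)
  u <- u[keep]; dof <- dof[keep]
  if (length(u) == 0) {
    stop("no component carries a degrees-of-freedom value", call. = FALSE)
  }
  if (any(dof <= 0)) stop("degrees of freedom must be > 0", call. = FALSE)
  sum(u^2)^2 / sum(u^4 / dof)
}

#' Default degrees-of-freedom registry
#'
#' Degrees of freedom attached to the budget rows when an effective
#' degrees of freedom is requested: the lung regression fit uses six
#' density-scaled samples (v = 5); the lung composition variability is
#' conservatively assigned v = 10; the positional SNR comparison pools 20
#' deltas (v = 19); the voxel-level SNR statistic pools 150 slice/solution
#' combinations (v = 149). The energy-sensitivity row is a recorded drift,
#' not a statistic, and carries no degrees of freedom.
#'
#' @return Named numeric vector (`NA` = excluded from `v_eff`).
#' @export
default_dof <- function() {
  c("Linear regression fit" = 5,
    "Variability in tissue composition" = 10,
    "Sensitivity to proton energy variation" = NA,
    "Positional uncertainty in FSE" = 19,
    "Voxel-level uncertainty in SNR" = 149)
}

#' Assemble an uncertainty budget for a tissue group
#'
#' Collects the five standard budget rows -- regression fit (Type A),
#' composition variability (Type B), energy sensitivity (recorded drift),
#' positional SNR (Type A) and voxel-level SNR (Type A) -- into a budget
#' with their root-sum-square composite and, when degrees of freedom are
#' supplied, the Welch-Satterthwaite effective degrees of freedom.
#'
#' @param group Group label (`"soft"`, `"bone"`, `"lung"`, ...).
#' @param fit_rms Type A regression-fit RMS (percent).
#' @param composition_rect Type B composition-variability value (percent).
#' @param energy_drift Recorded energy-sensitivity drift (percent).
#' @param positional Type A positional SNR uncertainty (percent).
#' @param voxel Type A voxel-level SNR uncertainty (percent).
#' @param dof Degrees of freedom per row, in the same order as the rows
#'   (`NA` = excluded from `v_eff`); `NULL` skips `v_eff`.
#' @return An object of class `"uncertainty_budget"`: the component table,
#'   the composite (percent) and `v_eff` (or `NA`).
#' @examples
#' b <- build_budget("lung", 0.05, 0.66, 0.00, 1.00, 1.50,
#'                   dof = default_dof())
#' b
#' @export
build_budget <- function(group, fit_rms, composition_rect, energy_drift,
                         positional, voxel, dof = NULL) {
  vals <- list("Linear regression fit" = fit_rms,
               "Variability in tissue composition" = composition_rect,
               "Sensitivity to proton energy variation" = energy_drift,
               "Positional uncertainty in FSE" = positional,
               "Voxel-level uncertainty in SNR" = voxel)
  absent <- names(vals)[vapply(vals, function(v)
    is.null(v) || length(v) != 1 || is.na(v), logical(1))]
  if (length(absent) > 0) {
    stop("missing budget component(s): ", paste(absent, collapse = "; "),
         call. = FALSE)
  }
  components <- data.frame(
    label = names(vals),
    kind = c("A", "B", "", "A", "A"),
    value = unlist(vals, use.names = FALSE),
    dof = if (is.null(dof)) NA_real_ else unname(dof[names(vals)]),
    stringsAsFactors = FALSE
  )
  new_budget(group, components)
}

# Internal constructor: validates and computes composite / v_eff.
new_budget <- function(group, components) {
  if (any(components$value < 0)) {
    stop("uncertainty components must be >= 0", call. = FALSE)
  }
  composite <- composite_rss(components$value)
  v_eff <- if (all(is.na(components$dof))) NA_real_ else
    welch_satterthwaite(components$value, components$dof)
  structure(list(group = group, components = components,
                 composite = composite, v_eff = v_eff),
            class = "uncertainty_budget")
}

#' @export
print.uncertainty_budget <- function(x, digits = 2, ...) {
  cat("Uncertainty budget --", x$group, "tissue\n")
  tab <- x$components
  wid <- max(nchar(tab$label))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-*s %s %6.2f %%%s\n", wid, tab$label[i],
                ifelse(nzchar(tab$kind[i]),
                       paste0("(Type ", tab$kind[i], ")"), "        "),
                tab$value[i],
                ifelse(is.na(tab$dof[i]), "",
                       sprintf("   v = %g", tab$dof[i]))))
  }
  cat(sprintf("  %-*s          %6.2f %%\n", wid, "Composite uncertainty",
              round(x$composite, digits)))
  if (!is.na(x$v_eff)) {
    cat(sprintf("  effective degrees of freedom v_eff = %.2f\n", x$v_eff))
  }
  invisible(x)
}

#' @export
as.data.frame.uncertainty_budget <- function(x, ...) {
  rbind(x$components,
        data.frame(label = "Composite uncertainty", kind = "",
                   value = x$composite, dof = x$v_eff))
}

#' Add a density-sensitivity Type B component to a budget
#'
#' Reference mass densities are believed accurate to roughly +/- 2 %; a
#' density error with unchanged elemental composition shifts the estimated
#' SPR directly. This what-if appends the corresponding Type B component
#' and recomputes the composite (the effective degrees of freedom is left
#' untouched: the appended component carries no statistical sample).
#'
#' @param budget An `"uncertainty_budget"`.
#' @param extra_type_b Additional Type B standard uncertainty (percent,
#'   >= 0).
#' @param label Row label for the appended component.
#' @return A new `"uncertainty_budget"` with the appended component.
#' @examples
#' b <- build_budget("soft", 2.51, 4.60, 0.05, 2.94, 3.38)
#' round(density_sensitivity(b, 4.83)$composite, 2)
#' @export
density_sensitivity <- function(budget, extra_type_b,
                                label = "Mass-density sensitivity") {
  if (extra_type_b < 0) stop("extra component must be >= 0", call. = FALSE)
  comps <- rbind(budget$components,
                 data.frame(label = label, kind = "B",
                            value = extra_type_b, dof = NA_real_))
  out <- new_budget(budget$group, comps)
  out$v_eff <- budget$v_eff
  out
}

#' Published budget components
#'
#' The per-group budget component values and the lung degrees-of-freedom
#' registry of the reference FSE-based analysis, packaged so budgets can
#' be assembled and cross-checked without rerunning the full pipeline.
#'
#' @return Data frame with columns `label`, `kind`, `soft`, `bone`,
#'   `lung`, `dof_lung`.
#' @examples
#' budget_components()
#' @export
budget_components <- function() {
  utils::read.csv(mrispr_extdata("budget_components.csv"),
                  stringsAsFactors = FALSE)
}

#' Regression-fit and composition uncertainties across proton energies
#'
#' Recomputes the calibration fit and its group-wise Type A RMS, plus the
#' Type B composition-variability value from alternative compositions, at
#' each requested proton energy (default the reporting grid 70, 100, 150,
#' 230 MeV). All SPR values come from the Bethe-Bloch path so the energy
#' dependence is internally consistent. The attribute `max_drift` holds
#' the largest absolute change of any cell from its 100 MeV value.
#'
#' @param comp Primary composition table (fit set), e.g.
#'   [icru46_compositions()].
#' @param alt Alternative composition table for the Type B evaluation;
#'   `NULL` skips the `uB_comp` columns.
#' @param energies Proton energies in MeV.
#' @param water Water reference.
#' @param elements Element data.
#' @return Data frame `energy`, `group`, `uA_fit`, `uB_comp` (long form),
#'   with attribute `max_drift` (percent).
#' @examples
#' sw <- energy_sweep(icru46_compositions(), alt_compositions(),
#'                    energies = c(70, 100))
#' attr(sw, "max_drift") < 0.14
#' @export
energy_sweep <- function(comp, alt = NULL,
                         energies = c(70, 100, 150, 230),
                         water = water_reference(),
                         elements = element_data()) {
  if (!(100 %in% energies)) energies <- sort(c(energies, 100))
  h <- composition_h_ratio(comp, water)
  grp <- comp$group
  grp[grp == "reference"] <- "soft"
  fitk <- grp %in% c("soft", "bone")
  halt <- if (!is.null(alt)) composition_h_ratio(alt, water)
  rows <- list()
  for (e in energies) {
    s <- spr_bethe(comp, energy = e, elements = elements)
    m <- fit_line(h[fitk], s[fitk], comp$name[fitk],
                  domain_label = "soft+bone", xlab = "h_ratio", ylab = "spr")
    est <- predict(m, h, warn_extrapolation = FALSE)
    delta <- 100 * (est - s) / s
    for (g in c("soft", "bone")) {
      ub <- NA_real_
      if (!is.null(alt)) {
        k <- alt$group == g
        if (any(k)) {
          salt <- spr_bethe(alt[k, , drop = FALSE], energy = e,
                            elements = elements)
          estalt <- predict(m, halt[k], warn_extrapolation = FALSE)
          ub <- type_b_rectangular(100 * (estalt - salt) / salt)
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        energy = e, group = g,
        uA_fit = type_a_rms(delta[grp == g]),
        uB_comp = ub)
    }
  }
  out <- do.call(rbind, rows)
  ref <- out[out$energy == 100, ]
  drift <- 0
  for (g in c("soft", "bone")) {
    sel <- out$group == g
    r <- ref[ref$group == g, ]
    drift <- max(drift,
                 abs(out$uA_fit[sel] - r$uA_fit),
                 abs(out$uB_comp[sel] - r$uB_comp), na.rm = TRUE)
  }
  attr(out, "max_drift") <- drift
  out
}
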