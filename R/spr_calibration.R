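#' Fit the hydrogen-to-SPR calibration model
#'
#' The central model of the package: ordinary least squares of the
#' tissue-water linear stopping-power ratio on the tissue-water
#' hydrogen-concentration ratio over the soft and bone reference tissues.
#' The inflated lung (and any other `lung_related` medium) is excluded from
#' the joint fit because its air content places it far off the soft/bone
#' cluster; a dedicated lung-related line ([build_lung_model()]) and an
#' adipose lipid line ([build_adipose_lipid_model()]) can be attached so
#' that [predict.spr_calibration()] routes each query to the right model.
#'
#' By default one joint line is fitted over soft and bone tissues together.
#' `separate_groups = TRUE` instead fits one line per group, an option the
#' analysis keeps available because the soft-tissue residual trend suggests
#' a separate soft fit could reduce uncertainty.
#'
#' @param tissues Data frame with columns `name`, `group`, `h_ratio` and
#'   `spr` (or `spr_<energy>`), e.g. [icru46_reference_values()] or the
#'   output of [tissue_records()].
#' @param energy Proton energy (MeV) selecting the SPR column when the
#'   table carries one per energy; recorded as model metadata.
#' @param separate_groups Fit soft and bone separately instead of jointly.
#' @param lung Optional `"spr_line"` for lung-related media.
#' @param adipose Optional `"spr_line"` mapping lipid percent to SPR.
#' @param lipid_threshold Lipid weight percent above which a voxel is
#'   routed to the adipose line (default 50).
#' @return An object of class `"spr_calibration"`.
#' @examples
#' cal <- spr_calibration(icru46_reference_values())
#' cal
#' predict(cal, h_ratio = 0.95)
#' @export
spr_calibration <- function(tissues, energy = 100, separate_groups = FALSE,
                            lung = NULL, adipose = NULL,
                            lipid_threshold = 50) {
  spr_col <- paste0("spr_", format(energy))
  if (!(spr_col %in% names(tissues))) {
    if (!("spr" %in% names(tissues))) {
      stop("tissue table carries no 'spr' column", call. = FALSE)
    }
    spr_col <- "spr"
  }
  fitset <- tissues[tissues$group %in% c("soft", "bone", "reference"), ,
                    drop = FALSE]
  if (nrow(fitset) < 2) stop("not enough soft/bone tissues", call. = FALSE)
  models <- if (separate_groups) {
    fitset$group[fitset$group == "reference"] <- "soft"
    lapply(split(fitset, fitset$group), function(g) {
      if (nrow(g) < 2) {
        stop("group '", g$group[1], "' has fewer than two tissues",
             call. = FALSE)
      }
      fit_line(g$h_ratio, g[[spr_col]], g$name,
               domain_label = g$group[1], xlab = "h_ratio", ylab = "spr")
    })
  } else {
    list(joint = fit_line(fitset$h_ratio, fitset[[spr_col]], fitset$name,
                          domain_label = "soft+bone",
                          xlab = "h_ratio", ylab = "spr"))
  }
  structure(list(
    models = models,
    separate_groups = separate_groups,
    lung = lung,
    adipose = adipose,
    lipid_threshold = lipid_threshold,
    energy = energy,
    tissues = tissues,
    spr_col = spr_col
  ), class = "spr_calibration")
}

# Pick the spr_line that serves a given group label.
.calibration_route <- function(object, group) {
  if (identical(group, "lung_related")) {
    if (is.null(object$lung)) {
      stop("no lung-related model attached to this calibration; ",
           "see build_lung_model()", call. = FALSE)
    }
    return(object$lung)
  }
  if (object$separate_groups && group %in% names(object$models)) {
    return(object$models[[group]])
  }
  object$models[[1]]
}

#' Predict SPR from hydrogen ratio (and optionally lipid fraction)
#'
#' Routes each query to the appropriate calibration line: queries with a
#' lipid fraction above the calibration's threshold go to the adipose
#' lipid line; `lung_related` queries go to the lung line; everything else
#' uses the soft+bone line (or the per-group line when the calibration was
#' fitted group-wise).
#'
#' @param object An `"spr_calibration"`.
#' @param h_ratio Hydrogen-concentration ratio(s).
#' @param group Group label(s): `"soft"`, `"bone"` or `"lung_related"`
#'   (recycled).
#' @param lipid Optional lipid weight percent(s); `NA` means no lipid map
#'   value is available for that query.
#' @param ... Unused.
#' @return Estimated SPR value(s).
#' @examples
#' cal <- spr_calibration(icru46_reference_values())
#' predict(cal, h_ratio = c(0.96, 0.75), group = c("soft", "bone"))
#' @export
predict.spr_calibration <- function(object, h_ratio, group = "soft",
                                    lipid = NULL, ...) {
  n <- length(h_ratio)
  group <- rep_len(group, n)
  lipid <- if (is.null(lipid)) rep(NA_real_, n) else rep_len(lipid, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (!is.na(lipid[i]) && lipid[i] > object$lipid_threshold) {
      if (is.null(object$adipose)) {
        stop("lipid fraction exceeds ", object$lipid_threshold,
             " % but no adipose lipid model is attached; ",
             "see build_adipose_lipid_model()", call. = FALSE)
      }
      out[i] <- predict(object$adipose, lipid[i], warn_extrapolation = FALSE)
    } else {
      m <- .calibration_route(object, group[i])
      out[i] <- predict(m, h_ratio[i], warn_extrapolation = FALSE)
    }
  }
  out
}

#' Route a single voxel-style query and predict its SPR
#'
#' Thin convenience wrapper over [predict.spr_calibration()] documenting
#' the routing rule: lipid fraction above the threshold selects the
#' adipose lipid model, `lung_related` tissue class selects the lung
#' model, otherwise the soft+bone line is used.
#'
#' @param calibration An `"spr_calibration"`.
#' @param h_ratio Hydrogen-concentration ratio.
#' @param tissue_class `"soft"`, `"bone"` or `"lung_related"`.
#' @param lipid_percent Optional lipid weight percent.
#' @return Estimated SPR.
#' @export
route_and_predict <- function(calibration, h_ratio, tissue_class = "soft",
                              lipid_percent = NA_real_) {
  predict(calibration, h_ratio, group = tissue_class, lipid = lipid_percent)
}

#' @export
print.spr_calibration <- function(x, ...) {
  cat("Hydrogen-to-SPR calibration at", x$energy, "MeV\n")
  for (m in x$models) print(m)
  if (!is.null(x$lung)) cat("  + lung-related line attached\n")
  if (!is.null(x$adipose)) {
    cat("  + adipose lipid line attached (threshold",
        x$lipid_threshold, "% lipid)\n")
  }
  invisible(x)
}

#' @export
coef.spr_calibration <- function(object, ...) {
  t(vapply(object$models, coef, numeric(2)))
}

#' Per-tissue relative differences of a fitted calibration
#'
#' `residuals` of the calibration are expressed the way the uncertainty
#' analysis consumes them: signed percent differences between estimated
#' and reference SPR for every tissue in the fitted table (including any
#' tissue excluded from the fit itself).
#'
#' @param object An `"spr_calibration"`.
#' @param ... Unused.
#' @return Data frame `name`, `delta` (percent), `group`.
#' @export
residuals.spr_calibration <- function(object, ...) {
  rec <- object$tissues
  spr <- rec[[object$spr_col]]
  delta <- rep(NA_real_, nrow(rec))
  for (i in seq_len(nrow(rec))) {
    m <- tryCatch(.calibration_route(object, rec$group[i]),
                  error = function(e) NULL)
    if (is.null(m)) next  # e.g. lung_related tissue with no lung line
    est <- predict(m, rec$h_ratio[i], warn_extrapolation = FALSE)
    delta[i] <- 100 * (est - spr[i]) / spr[i]
  }
  data.frame(name = rec$name, group = rec$group, delta = delta,
             stringsAsFactors = FALSE)
}

#' @export
summary.spr_calibration <- function(object, ...) {
  d <- residuals(object)
  d <- d[!is.na(d$delta), , drop = FALSE]
  groups <- split(d, d$group)
  stats <- data.frame(
    group = names(groups),
    n = vapply(groups, nrow, integer(1)),
    rms_delta = vapply(groups, function(g) type_a_rms(g$delta), numeric(1)),
    max_abs_delta = vapply(groups, function(g) max(abs(g$delta)), numeric(1))
  )
  rownames(stats) <- NULL
  out <- list(calibration = object, group_stats = stats, deltas = d)
  class(out) <- "summary.spr_calibration"
  out
}

#' @export
print.summary.spr_calibration <- function(x, ...) {
  print(x$calibration)
  cat("\nGroup-wise relative differences (percent of SPR):\n")
  s <- x$group_stats
  s$rms_delta <- round(s$rms_delta, 2)
  s$max_abs_delta <- round(s$max_abs_delta, 2)
  print(s, row.names = FALSE)
  invisible(x)
}

#' @export
plot.spr_calibration <- function(x, ...) {
  t <- x$tissues
  spr <- t[[x$spr_col]]
  cols <- c(soft = "grey25", bone = "grey55", lung_related = "grey80",
            reference = "grey25")
  graphics::plot(t$h_ratio, spr, pch = 19, col = cols[t$group],
                 xlab = "hydrogen-concentration ratio (tissue/water)",
                 ylab = paste0("SPR at ", x$energy, " MeV"), ...)
  for (m in x$models) graphics::abline(m$intercept, m$slope, lty = 1)
  if (!is.null(x$lung)) {
    graphics::abline(x$lung$intercept, x$lung$slope, lty = 3)
  }
  invisible(x)
}

#' Simulate SPR observations from a fitted calibration
#'
#' Draws SPR values at the fitted tissues' hydrogen ratios from the
#' calibration line plus Gaussian residual scatter with the fitted
#' residual standard deviation. Useful for sanity-checking downstream
#' statistics against a model whose truth is known.
#'
#' @param object An `"spr_calibration"`.
#' @param nsim Number of simulated replicates.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A data frame with one column per replicate.
#' @export
simulate.spr_calibration <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  m <- object$models[[1]]
  mu <- predict(m, warn_extrapolation = FALSE)
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, m$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- m$fit_samples$name
  out
}

#' Fit the lung-related hydrogen-to-SPR line
#'
#' Air, inflated lung and compressed lung differ essentially only in how
#' much air dilutes the lung parenchyma, so mass density scales while the
#' elemental composition stays fixed; hydrogen concentration and SPR then
#' scale together and the three media define a tight line through the
#' near-origin air anchor. The line is fitted unconstrained (no forced
#' zero intercept) on the three base media; density-scaled variants of the
#' inflated lung (default +/- 2, 10, 20 percent) form an evaluation-only
#' set whose RMS relative difference quantifies the fit uncertainty.
#'
#' @param air,inflated,compressed One-row composition data frames.
#' @param density_factors Positive multipliers applied to the inflated
#'   lung's density for the evaluation set.
#' @param energy Proton energy in MeV.
#' @param spr_inflated Optional reference SPR for the inflated lung (e.g.
#'   the published table value); default computes it by Bethe-Bloch.
#' @param water Water reference for the hydrogen ratios.
#' @param elements Element data.
#' @return An `"spr_line"` with extra fields `eval_samples` (the scaled
#'   variants and their deltas) and `rms_fit_percent`.
#' @examples
#' alt <- alt_compositions()
#' lung <- build_lung_model(alt[alt$name == "Air", ],
#'                          icru46_compositions()[9, ],
#'                          alt[alt$name == "Lung (compressed)", ])
#' round(predict(lung, 0.239), 3)
#' @export
build_lung_model <- function(air, inflated, compressed,
                             density_factors = c(0.98, 1.02, 0.90, 1.10,
                                                 0.80, 1.20),
                             energy = 100, spr_inflated = NULL,
                             water = water_reference(),
                             elements = element_data()) {
  if (any(density_factors <= 0)) {
    stop("density factors must be positive", call. = FALSE)
  }
  base <- rbind_compositions(air, inflated, compressed)
  h <- composition_h_ratio(base, water)
  s <- spr_bethe(base, energy = energy, elements = elements)
  if (!is.null(spr_inflated)) s[2] <- spr_inflated
  m <- fit_line(h, s, base$name, domain_label = "lung_related",
                xlab = "h_ratio", ylab = "spr")
  # density scaling moves h and spr by the same factor (composition fixed)
  ev <- data.frame(
    name = sprintf("%s x %.2f", inflated$name, density_factors),
    h_ratio = h[2] * density_factors,
    spr = s[2] * density_factors
  )
  ev$delta <- 100 * (predict(m, ev$h_ratio, warn_extrapolation = FALSE) -
                       ev$spr) / ev$spr
  m$eval_samples <- ev
  m$rms_fit_percent <- type_a_rms(ev$delta)
  m
}

#' Fit the adipose lipid-fraction to SPR line
#'
#' Over the reference adipose grades, SPR falls linearly as the lipid
#' weight fraction rises (lipid displaces water and lowers mass density),
#' so voxels known to be lipid-rich can be calibrated on lipid fraction
#' directly instead of the hydrogen ratio.
#'
#' @param adipose_samples Data frame with columns `lipid_pct` and `spr`
#'   (at least two samples with distinct lipid fractions).
#' @return An `"spr_line"` with x = lipid percent, y = SPR.
#' @examples
#' alt <- alt_compositions()
#' gr <- alt[grepl("Adipose grade", alt$name), ]
#' gr$spr <- spr_bethe(gr, energy = 100)
#' fit <- build_adipose_lipid_model(gr)
#' coef(fit)[["slope"]] < 0
#' @export
build_adipose_lipid_model <- function(adipose_samples) {
  if (!all(c("lipid_pct", "spr") %in% names(adipose_samples))) {
    stop("adipose samples need 'lipid_pct' and 'spr' columns", call. = FALSE)
  }
  fit_line(adipose_samples$lipid_pct, adipose_samples$spr,
           adipose_samples$name, domain_label = "adipose lipid",
           xlab = "lipid_pct", ylab = "spr")
}

#' Bone-mineral versus hydrogen concentration correlation
#'
#' Bone tissues owe their stopping power largely to hydroxyapatite
#' (calcium + phosphorus); the mineral weight fraction is inversely related
#' to the hydrogen fraction, which is why a hydrogen measurement predicts
#' bone SPR so well. This helper quantifies that relationship over a
#' composition table.
#'
#' @param comp Composition data frame (typically the bone rows).
#' @return Pearson correlation between the Ca+P weight fraction and the H
#'   weight fraction.
#' @examples
#' comp <- icru46_compositions()
#' bone_mineral_correlation(comp[comp$group == "bone", ])
#' @export
bone_mineral_correlation <- function(comp) {
  ca <- if ("Ca" %in% names(comp)) comp$Ca else 0
  p <- if ("P" %in% names(comp)) comp$P else 0
  stats::cor(ca + p, comp$H)
}
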