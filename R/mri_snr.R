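#' Construct an image slice
#'
#' A 2-D voxel grid with physical geometry: voxel spacing in mm and the mm
#' position of the centre of voxel (1, 1). Voxel centres sit at
#' `origin + (index - 1) * spacing`; rows index the first coordinate.
#'
#' @param grid Numeric matrix of voxel intensities (arbitrary units).
#' @param spacing Voxel spacing in mm, length 1 or 2 (row, col).
#' @param origin mm position of the centre of voxel (1, 1), length 2.
#' @param slice_index Slice number within its series.
#' @return An object of class `"image_slice"`.
#' @examples
#' sl <- image_slice(matrix(1, 4, 4), spacing = 1)
#' @export
image_slice <- function(grid, spacing, origin = NULL, slice_index = 1L) {
  grid <- as.matrix(grid)
  spacing <- rep_len(as.numeric(spacing), 2)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  if (is.null(origin)) {
    # centre the grid on (0, 0)
    origin <- -(dim(grid) - 1) / 2 * spacing
  }
  structure(list(grid = grid, spacing = spacing,
                 origin = as.numeric(origin),
                 slice_index = as.integer(slice_index)),
            class = "image_slice")
}

#' @export
print.image_slice <- function(x, ...) {
  cat(sprintf("image_slice %d x %d, spacing %.3f x %.3f mm, slice %d\n",
              nrow(x$grid), ncol(x$grid), x$spacing[1], x$spacing[2],
              x$slice_index))
  invisible(x)
}

#' Define a circular region of interest
#'
#' @param center ROI centre in mm (length 2).
#' @param radius ROI radius in mm (> 0).
#' @param kind `"solution"` or `"background"`.
#' @return An object of class `"roi_spec"`.
#' @examples
#' roi_spec(c(0, 0), 12)
#' @export
roi_spec <- function(center, radius, kind = c("solution", "background")) {
  if (radius <= 0) stop("ROI radius must be positive", call. = FALSE)
  structure(list(center = as.numeric(center), radius = radius,
                 kind = match.arg(kind)),
            class = "roi_spec")
}

# Logical mask of voxels whose centres fall strictly inside the ROI circle.
.roi_mask <- function(slice, roi) {
  nr <- nrow(slice$grid); nc <- ncol(slice$grid)
  xs <- slice$origin[1] + (seq_len(nr) - 1) * slice$spacing[1]
  ys <- slice$origin[2] + (seq_len(nc) - 1) * slice$spacing[2]
  dx2 <- (xs - roi$center[1])^2
  dy2 <- (ys - roi$center[2])^2
  outer(dx2, dy2, "+") < roi$radius^2
}

#' ROI statistics
#'
#' Mean, sample standard deviation and voxel count over the voxels whose
#' centres lie strictly inside the ROI circle. The voxel-centre rule is
#' deterministic and resolution-stable; no partial-volume weighting is
#' applied.
#'
#' @param slice An [image_slice()].
#' @param roi An [roi_spec()].
#' @return A list with `mean`, `sd` and `n`.
#' @examples
#' sl <- image_slice(matrix(5, 64, 64), spacing = 1)
#' roi_stats(sl, roi_spec(c(0, 0), 10))$mean
#' @export
roi_stats <- function(slice, roi) {
  mask <- .roi_mask(slice, roi)
  n <- sum(mask)
  if (n == 0) {
    stop("ROI at (", paste(format(roi$center), collapse = ", "),
         ") mm contains no voxel centres", call. = FALSE)
  }
  v <- slice$grid[mask]
  list(mean = mean(v), sd = if (n > 1) stats::sd(v) else 0, n = n)
}

#' Background ROI placement around a container
#'
#' Four small background ROIs at 90 degree intervals around a container,
#' each placed just outside the container wall: the ROI centres sit at
#' `inner_radius + wall + gap + roi_radius` from the container centre, so
#' the near ROI edge clears the outer wall by `gap` mm.
#'
#' @param center Container centre (mm).
#' @param inner_radius Container inner radius (mm, default 19).
#' @param wall Container wall thickness (mm, default 1).
#' @param gap Clearance between outer wall and near ROI edge (mm,
#'   default 3).
#' @param roi_radius Background ROI radius (mm, default 3).
#' @param angles Placement angles in degrees.
#' @return List of four background [roi_spec()]s.
#' @examples
#' length(default_background_rois(c(0, 0)))
#' @export
default_background_rois <- function(center, inner_radius = 19, wall = 1,
                                    gap = 3, roi_radius = 3,
                                    angles = c(0, 90, 180, 270)) {
  r <- inner_radius + wall + gap + roi_radius
  lapply(angles, function(a) {
    rad <- a * pi / 180
    roi_spec(center + r * c(cos(rad), sin(rad)), roi_radius, "background")
  })
}

#' NEMA Method-4 signal-to-noise ratio
#'
#' SNR of a solution as the ratio of the mean voxel value inside the
#' solution ROI to the mean of the four background ROI means. The raw
#' background mean is used as printed in the method definition; no
#' Rayleigh correction factor is applied.
#'
#' @param slice An [image_slice()].
#' @param solution_roi The solution [roi_spec()].
#' @param background_rois List of exactly four background ROIs.
#' @return Dimensionless SNR.
#' @examples
#' g <- matrix(2, 64, 64); g[20:44, 20:44] <- 100
#' sl <- image_slice(g, spacing = 1)
#' snr_method4(sl, roi_spec(c(0, 0), 8),
#'             default_background_rois(c(0, 0), inner_radius = 16,
#'                                     wall = 0, gap = 1, roi_radius = 3))
#' @export
snr_method4 <- function(slice, solution_roi, background_rois) {
  if (length(background_rois) != 4) {
    stop("Method 4 requires exactly four background ROIs", call. = FALSE)
  }
  sig <- roi_stats(slice, solution_roi)
  bg <- vapply(background_rois, function(r) roi_stats(slice, r)$mean,
               numeric(1))
  bg_mean <- mean(bg)
  if (bg_mean == 0) {
    stop("background mean is zero: SNR undefined", call. = FALSE)
  }
  sig$mean / bg_mean
}

#' Multi-slice SNR measurement of one solution
#'
#' Repeats the Method-4 SNR over several slices (default protocol: five)
#' and averages, which is the accuracy-improving replication used in the
#' phantom protocol. Also records per-slice voxel-level variability: the
#' relative standard deviation of the solution ROI,
#' \eqn{\sigma_{l,rel} = 100 \sigma_l / \bar I_{l}}, whose RMS across
#' slices summarises voxel-level uncertainty.
#'
#' @param series List of [image_slice()]s.
#' @param solution_roi Solution ROI.
#' @param background_rois List of four background ROIs.
#' @param solution_id Identifier used when pairing measurements across
#'   phantom positions.
#' @return An object of class `"snr_measurement"`: `solution_id`,
#'   `per_slice` (data frame `mean`, `sd`, `snr`, `sigma_rel`),
#'   `snr_avg`, `sigma_rel_rms`.
#' @export
multi_slice_snr <- function(series, solution_roi, background_rois,
                            solution_id = "solution") {
  if (length(series) < 1) stop("need at least one slice", call. = FALSE)
  per <- lapply(series, function(sl) {
    st <- roi_stats(sl, solution_roi)
    data.frame(mean = st$mean, sd = st$sd,
               snr = snr_method4(sl, solution_roi, background_rois),
               sigma_rel = 100 * st$sd / st$mean)
  })
  per <- do.call(rbind, per)
  structure(list(solution_id = solution_id, per_slice = per,
                 snr_avg = mean(per$snr),
                 sigma_rel_rms = type_a_rms(per$sigma_rel)),
            class = "snr_measurement")
}

#' @export
print.snr_measurement <- function(x, ...) {
  cat(sprintf("SNR of %s: %.2f (mean of %d slices), voxel sigma_rel RMS %.2f %%\n",
              x$solution_id, x$snr_avg, nrow(x$per_slice), x$sigma_rel_rms))
  invisible(x)
}

#' Positional SNR relative differences
#'
#' Percent differences between SNR measured with the phantom at an
#' arbitrary position and at the primary position, paired by solution id:
#' \eqn{\delta_k = 100 (SNR_{arb,k} - SNR_{pri,k}) / SNR_{pri,k}}.
#' Feed the result to [type_a_rms()] for the positional Type A
#' uncertainty.
#'
#' @param primary,arbitrary Lists of `"snr_measurement"`s (or named
#'   numeric vectors of SNR values).
#' @return Numeric vector of percent differences, named by solution id,
#'   ordered as `primary`.
#' @export
positional_deltas <- function(primary, arbitrary) {
  as_named <- function(x) {
    if (is.numeric(x)) {
      if (is.null(names(x))) names(x) <- as.character(seq_along(x))
      return(x)
    }
    stats::setNames(vapply(x, function(m) m$snr_avg, numeric(1)),
                    vapply(x, function(m) as.character(m$solution_id),
                           character(1)))
  }
  pri <- as_named(primary)
  arb <- as_named(arbitrary)
  missing <- setdiff(names(pri), names(arb))
  extra <- setdiff(names(arb), names(pri))
  if (length(missing) > 0 || length(extra) > 0) {
    stop("solution ids do not pair up (missing: ",
         paste(missing, collapse = ", "), "; unmatched: ",
         paste(extra, collapse = ", "), ")", call. = FALSE)
  }
  arb <- arb[names(pri)]
  100 * (arb - pri) / pri
}

#' Calibrate measured SNR against hydrogen-concentration ratio
#'
#' Ordinary least squares of SNR on the solution-water hydrogen ratio
#' over the phantom solutions. With a proton-density-weighted sequence
#' the relation is linear, so the inverse map
#' `h = (snr - intercept) / slope` converts a patient-image SNR into a
#' hydrogen ratio; see [h_from_snr()].
#'
#' @param h_ratio Hydrogen ratios of the solutions (should span about
#'   0.3 to 1.0; at least 3 values).
#' @param snr Measured SNR values (same length).
#' @param names Optional solution names.
#' @return An `"spr_line"` with x = hydrogen ratio, y = SNR.
#' @examples
#' ph <- phantom_solutions()
#' cal <- calibrate_snr_to_h(ph$h_ratio, ph$snr_fse, ph$solution)
#' round(cal$r_squared, 2)
#' @export
calibrate_snr_to_h <- function(h_ratio, snr, names = NULL) {
  if (length(h_ratio) < 3) {
    stop("need at least three solutions for the SNR calibration",
         call. = FALSE)
  }
  if (diff(range(h_ratio)) < 0.2) {
    stop("degenerate hydrogen-ratio spread (need a wide dilution range)",
         call. = FALSE)
  }
  fit_line(h_ratio, snr, names, domain_label = "SNR calibration",
           xlab = "h_ratio", ylab = "snr")
}

#' Invert an SNR calibration
#'
#' @param model An `"spr_line"` from [calibrate_snr_to_h()].
#' @param snr Measured SNR value(s).
#' @return Estimated hydrogen-concentration ratio(s).
#' @examples
#' ph <- phantom_solutions()
#' cal <- calibrate_snr_to_h(ph$h_ratio, ph$snr_fse)
#' round(h_from_snr(cal, ph$snr_fse[1]), 2)
#' @export
h_from_snr <- function(model, snr) {
  (snr - model$intercept) / model$slope
}
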