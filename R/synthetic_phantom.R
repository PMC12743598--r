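#' Hexagonally packed phantom layout
#'
#' Deterministic container placement on a hexagonal grid, mirroring a
#' hexagonal frame holding cylindrical containers: candidate positions are
#' the origin and the surrounding hexagonal rings at the given pitch,
#' taken in order of distance from the centre (ties broken by angle), so a
#' given `n_containers` always yields the same layout.
#'
#' @param n_containers Number of containers (1 to 12).
#' @param inner_radius Container inner radius, mm (default 19).
#' @param wall Container wall thickness, mm (default 1).
#' @param fov Field of view, mm (default 240, square).
#' @param matrix_size Acquisition matrix (default 256, square).
#' @param pitch Centre-to-centre spacing, mm. The default 50 keeps every
#'   background ROI ring (radius 26 + 3 mm) clear of neighbouring
#'   containers.
#' @return An object of class `"phantom_layout"`: `centers` (data frame
#'   `x`, `y`), plus the geometry parameters.
#' @examples
#' phantom_layout(10)
#' @export
phantom_layout <- function(n_containers, inner_radius = 19, wall = 1,
                           fov = 240, matrix_size = 256, pitch = 50) {
  if (n_containers < 1 || n_containers > 12) {
    stop("n_containers must be between 1 and 12", call. = FALSE)
  }
  # hexagonal grid candidates out to two rings
  ij <- expand.grid(i = -3:3, j = -3:3)
  x <- pitch * (ij$i + ij$j / 2)
  y <- pitch * ij$j * sqrt(3) / 2
  d <- sqrt(x^2 + y^2)
  ang <- atan2(y, x) %% (2 * pi)
  ord <- order(round(d, 9), round(ang, 9))
  x <- x[ord]; y <- y[ord]; d <- d[ord]
  keep <- seq_len(n_containers)
  # full reach of a container's analysis region: outer wall + background ring
  reach <- inner_radius + wall + 3 + 2 * 3
  if (any(d[keep] + reach > fov / 2)) {
    stop("layout does not fit: ", n_containers,
         " containers at pitch ", pitch, " exceed the ", fov,
         " mm field of view", call. = FALSE)
  }
  structure(list(centers = data.frame(x = x[keep], y = y[keep]),
                 inner_radius = inner_radius, wall = wall,
                 fov = fov, matrix_size = matrix_size, pitch = pitch),
            class = "phantom_layout")
}

#' @export
print.phantom_layout <- function(x, ...) {
  cat(sprintf("phantom_layout: %d containers (r = %g mm) in %g mm FOV, %d^2 matrix\n",
              nrow(x$centers), x$inner_radius, x$fov, x$matrix_size))
  invisible(x)
}

#' Ground truth for a synthetic phantom acquisition
#'
#' The programmed signal model behind [render_phantom_series()]: each
#' container's noiseless intensity is `gain * h_ratio`; magnitude images
#' carry Rician noise of scale `noise`. An optional linear shading field
#' (relative intensity gradient across the field of view) emulates the
#' mild spatial non-uniformity of real receive chains at the image level,
#' which is what makes SNR depend on phantom position.
#'
#' @param h_ratios Per-container hydrogen ratios.
#' @param gain Intensity per unit hydrogen ratio (> 0). The default,
#'   with `noise = 1`, programs SNR of about 39 to 131 over hydrogen
#'   ratios 0.3 to 1.0, the range of the reference FSE phantom data.
#' @param noise Rician noise scale (Gaussian sigma per quadrature
#'   channel, >= 0).
#' @param shading Relative intensity change across the full field of
#'   view along x (default 0 = uniform).
#' @param seed Integer seed making renders bit-reproducible.
#' @return An object of class `"ground_truth"`.
#' @examples
#' ground_truth(c(1, 0.5), gain = 163, noise = 1, seed = 7)
#' @export
ground_truth <- function(h_ratios, gain = 163, noise = 1, shading = 0,
                         seed = 1L) {
  if (gain <= 0) stop("gain must be positive", call. = FALSE)
  if (noise < 0) stop("noise scale must be >= 0", call. = FALSE)
  structure(list(h_ratios = h_ratios, gain = gain, noise = noise,
                 shading = shading, seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d containers, gain %g, noise %g, shading %g, seed %d\n",
              length(x$h_ratios), x$gain, x$noise, x$shading, x$seed))
  invisible(x)
}

# Rotate (degrees, counter-clockwise) then translate (mm) a set of points.
.transform_points <- function(xy, rotation = 0, translation = c(0, 0)) {
  a <- rotation * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  sweep(as.matrix(xy) %*% t(R), 2, translation, "+")
}

#' Transformed container centres
#'
#' Container centres after the phantom is rotated and/or translated,
#' mirroring a repositioning of the physical phantom on the couch.
#'
#' @param layout A [phantom_layout()].
#' @param rotation Rotation in degrees (counter-clockwise).
#' @param translation Translation in mm (length 2).
#' @return Data frame of transformed centres `x`, `y`.
#' @export
container_centers <- function(layout, rotation = 0, translation = c(0, 0)) {
  xy <- .transform_points(layout$centers, rotation, translation)
  data.frame(x = xy[, 1], y = xy[, 2])
}

#' Render a synthetic phantom image series
#'
#' Renders `n_slices` magnitude images of the phantom: container
#' interiors take the programmed noiseless intensity (gain x hydrogen
#' ratio, times the shading field), the background is zero signal, and
#' Rician noise is applied by adding independent Gaussian noise to two
#' quadrature channels and taking the magnitude. Voxel membership is by
#' voxel-centre (no supersampling), matching the analysis-side ROI rule.
#' Rendering is bit-reproducible for a fixed seed.
#'
#' @param layout A [phantom_layout()].
#' @param truth A [ground_truth()] with one hydrogen ratio per container.
#' @param n_slices Number of slices (default 5, the replication of the
#'   reference protocol).
#' @param rotation,translation Phantom repositioning applied to this
#'   acquisition (degrees; mm).
#' @param seed Overrides the seed stored in `truth`.
#' @param floor_eps Intensity floor applied to noiseless renders so that
#'   the background mean stays non-zero and the SNR pipeline remains
#'   well defined (the programmed SNR of a noiseless container is then
#'   exactly `gain * h / floor_eps`).
#' @return List of [image_slice()]s.
#' @examples
#' lay <- phantom_layout(3)
#' tr <- ground_truth(c(1, 0.6, 0.3), seed = 42)
#' series <- render_phantom_series(lay, tr, n_slices = 2)
#' length(series)
#' @export
render_phantom_series <- function(layout, truth, n_slices = 5,
                                  rotation = 0, translation = c(0, 0),
                                  seed = NULL, floor_eps = 1e-6) {
  stopifnot(inherits(layout, "phantom_layout"),
            inherits(truth, "ground_truth"))
  if (length(truth$h_ratios) != nrow(layout$centers)) {
    stop("truth carries ", length(truth$h_ratios),
         " hydrogen ratios for ", nrow(layout$centers), " containers",
         call. = FALSE)
  }
  if (is.null(seed)) seed <- truth$seed
  n <- layout$matrix_size
  sp <- layout$fov / n
  org <- -(n - 1) / 2 * sp
  xs <- org + (seq_len(n) - 1) * sp
  centers <- container_centers(layout, rotation, translation)
  # noiseless signal image (shared by all slices)
  A <- matrix(0, n, n)
  for (k in seq_len(nrow(centers))) {
    m <- outer((xs - centers$x[k])^2, (xs - centers$y[k])^2, "+") <
      layout$inner_radius^2
    A[m] <- truth$gain * truth$h_ratios[k]
  }
  if (truth$shading != 0) {
    shade <- 1 + truth$shading * xs / layout$fov
    A <- A * matrix(shade, n, n, byrow = FALSE)
  }
  set.seed(seed)
  lapply(seq_len(n_slices), function(l) {
    g <- if (truth$noise > 0) {
      sqrt((A + stats::rnorm(n * n, 0, truth$noise))^2 +
             stats::rnorm(n * n, 0, truth$noise)^2)
    } else {
      pmax(A, floor_eps)
    }
    image_slice(matrix(g, n, n), spacing = sp, slice_index = l)
  })
}

# Mean of a Rician variate with noiseless amplitude A and channel sigma s,
# via the Laguerre half polynomial written with scaled Bessel functions so
# large signal-to-noise does not overflow: with z = A^2 / (4 s^2),
#   E[M] = s sqrt(pi/2) ((1 + 2z) I0(z) + 2z I1(z)) exp(-z).
rician_mean <- function(A, sigma) {
  if (sigma == 0) return(A)
  z <- A^2 / (4 * sigma^2)
  i0 <- besselI(z, 0, expon.scaled = TRUE)
  i1 <- besselI(z, 1, expon.scaled = TRUE)
  sigma * sqrt(pi / 2) * ((1 + 2 * z) * i0 + 2 * z * i1)
}

# Standard deviation of the same Rician variate: E[M^2] = A^2 + 2 s^2.
rician_sd <- function(A, sigma) {
  sqrt(pmax(A^2 + 2 * sigma^2 - rician_mean(A, sigma)^2, 0))
}

#' Analytic SNR of a rendered container
#'
#' The expected Method-4 SNR of a container under the Rician signal
#' model: mean Rician magnitude at the programmed amplitude divided by
#' the mean background magnitude (Rayleigh mean,
#' \eqn{\sigma\sqrt{\pi/2}}). This is the independent oracle against
#' which the measurement pipeline is validated. A container with zero
#' programmed signal has expected SNR 1 (its ROI is pure noise); with
#' zero noise the SNR is unbounded and `Inf` is returned.
#'
#' @param truth A [ground_truth()].
#' @param container Container index (into `truth$h_ratios`).
#' @return Expected SNR (possibly `Inf`).
#' @examples
#' truth_snr(ground_truth(1, gain = 163, noise = 1), 1)
#' @export
truth_snr <- function(truth, container = 1) {
  A <- truth$gain * truth$h_ratios[container]
  if (truth$noise == 0) return(Inf)
  rician_mean(A, truth$noise) / (truth$noise * sqrt(pi / 2))
}

#' Analytic voxel-level relative standard deviation of a container
#'
#' Expected relative standard deviation (percent) of the voxel values in
#' a solution ROI under the Rician model; oracle for the voxel-level
#' uncertainty statistic of [multi_slice_snr()].
#'
#' @param truth A [ground_truth()].
#' @param container Container index.
#' @return Percent relative standard deviation.
#' @export
truth_sigma_rel <- function(truth, container = 1) {
  A <- truth$gain * truth$h_ratios[container]
  if (truth$noise == 0) return(0)
  100 * rician_sd(A, truth$noise) / rician_mean(A, truth$noise)
}

#' Analysis ROIs for a (possibly repositioned) synthetic phantom
#'
#' Solution and background ROI sets matching the layout geometry:
#' 12 mm solution ROIs at the container centres and four 3 mm background
#' ROIs around each container, transformed together with the phantom.
#'
#' @param layout A [phantom_layout()].
#' @param rotation,translation Repositioning applied to the acquisition.
#' @param solution_radius Solution ROI radius, mm (default 12).
#' @return List with one element per container, each holding `solution`
#'   (an [roi_spec()]) and `background` (list of four).
#' @export
phantom_rois <- function(layout, rotation = 0, translation = c(0, 0),
                         solution_radius = 12) {
  centers <- container_centers(layout, rotation, translation)
  lapply(seq_len(nrow(centers)), function(k) {
    ctr <- c(centers$x[k], centers$y[k])
    list(solution = roi_spec(ctr, solution_radius, "solution"),
         background = default_background_rois(
           ctr, inner_radius = layout$inner_radius, wall = layout$wall))
  })
}

#' Measure a rendered series with the full SNR pipeline
#'
#' Convenience wrapper running [multi_slice_snr()] for every container of
#' a synthetic phantom series.
#'
#' @param series List of [image_slice()]s from [render_phantom_series()].
#' @param layout The [phantom_layout()] that produced them.
#' @param rotation,translation The repositioning used for the render.
#' @return List of `"snr_measurement"`s, one per container, ids
#'   `"1", "2", ...`.
#' @export
measure_phantom_series <- function(series, layout, rotation = 0,
                                   translation = c(0, 0)) {
  rois <- phantom_rois(layout, rotation, translation)
  lapply(seq_along(rois), function(k) {
    multi_slice_snr(series, rois[[k]]$solution, rois[[k]]$background,
                    solution_id = as.character(k))
  })
}
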