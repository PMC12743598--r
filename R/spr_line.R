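#' Fit a straight calibration line by ordinary least squares
#'
#' The workhorse behind every linear model in the package: the
#' hydrogen-to-SPR calibration, the lung-related line, the adipose lipid
#' line and the SNR-to-hydrogen phantom calibration. Fits `y = a x + b` by
#' ordinary least squares and records the fit sample registry so the fit
#' can be reproduced and audited.
#'
#' @param x,y Numeric vectors of equal length (>= 2 distinct x values).
#' @param names Optional sample names (recycled to the data length).
#' @param domain_label Free-text label describing what the line calibrates
#'   (e.g. `"soft+bone"`).
#' @param xlab,ylab Axis names used by `predict` and `plot`.
#' @return An object of class `"spr_line"`: a list with `slope`,
#'   `intercept`, `r_squared`, `sigma` (residual standard deviation),
#'   `fit_samples` (data frame `name`, `x`, `y`) and `domain_label`.
#' @examples
#' m <- fit_line(c(0, 1), c(1, 3))
#' coef(m)
#' @export
fit_line <- function(x, y, names = NULL, domain_label = "",
                     xlab = "x", ylab = "y") {
  if (length(x) != length(y) || length(x) < 2) {
    stop("need at least two (x, y) pairs", call. = FALSE)
  }
  if (length(unique(x)) < 2) {
    stop("degenerate fit: all x values identical", call. = FALSE)
  }
  if (is.null(names)) names <- paste0("sample_", seq_along(x))
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  # noiseless calibrations fit exactly; lm's perfect-fit warning is benign
  sm <- suppressWarnings(summary(fit))
  r2 <- if (stats::var(y) == 0) 1 else sm$r.squared
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    sigma = sm$sigma,
    fit_samples = data.frame(name = names, x = x, y = y,
                             stringsAsFactors = FALSE),
    domain_label = domain_label,
    xlab = xlab, ylab = ylab
  ), class = "spr_line")
}

#' @export
print.spr_line <- function(x, digits = 4, ...) {
  cat("Linear calibration",
      if (nzchar(x$domain_label)) paste0("(", x$domain_label, ")"), "\n")
  cat(sprintf("  %s = %s * %s + %s\n", x$ylab,
              format(x$slope, digits = digits), x$xlab,
              format(x$intercept, digits = digits)))
  cat(sprintf("  R^2 = %.4f over %d samples (residual sd %.4g)\n",
              x$r_squared, nrow(x$fit_samples), x$sigma))
  invisible(x)
}

#' @export
coef.spr_line <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict from a fitted calibration line
#'
#' @param object An `"spr_line"` fit.
#' @param newdata Numeric vector of x values, or a data frame holding a
#'   column named like the fit's x axis. Omitted: the fit samples.
#' @param warn_extrapolation Message when predicting outside the fitted
#'   x range (extrapolation is permitted but logged).
#' @param ... Unused.
#' @return Numeric vector of fitted y values.
#' @export
predict.spr_line <- function(object, newdata = NULL,
                             warn_extrapolation = TRUE, ...) {
  if (is.null(newdata)) {
    x <- object$fit_samples$x
  } else if (is.data.frame(newdata)) {
    col <- if (object$xlab %in% names(newdata)) object$xlab else names(newdata)[1]
    x <- newdata[[col]]
  } else {
    x <- as.numeric(newdata)
  }
  rng <- range(object$fit_samples$x)
  if (warn_extrapolation && any(x < rng[1] | x > rng[2])) {
    message("predict.spr_line: extrapolating outside the fitted ",
            object$xlab, " range [", format(rng[1]), ", ", format(rng[2]), "]")
  }
  object$slope * x + object$intercept
}

#' @export
residuals.spr_line <- function(object, ...) {
  object$fit_samples$y -
    predict(object, object$fit_samples$x, warn_extrapolation = FALSE)
}

#' @export
summary.spr_line <- function(object, ...) {
  res <- residuals(object)
  out <- list(line = object,
              n = nrow(object$fit_samples),
              rmse = sqrt(mean(res^2)),
              max_abs_residual = max(abs(res)))
  class(out) <- "summary.spr_line"
  out
}

#' @export
print.summary.spr_line <- function(x, ...) {
  print(x$line)
  cat(sprintf("  residual RMSE %.4g, max |residual| %.4g\n",
              x$rmse, x$max_abs_residual))
  invisible(x)
}

#' @export
plot.spr_line <- function(x, ...) {
  s <- x$fit_samples
  graphics::plot(s$x, s$y, xlab = x$xlab, ylab = x$ylab,
                 main = x$domain_label, pch = 19, ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  invisible(x)
}

#' Relative differences between model-estimated and reference SPR
#'
#' For each record, the signed percent difference between the SPR estimated
#' from the calibration line at the record's hydrogen ratio and the
#' reference ("calculated") SPR:
#' \deqn{\delta_i = 100 (SPR_{est,i} - SPR_{cal,i}) / SPR_{cal,i}.}
#' These deltas feed the Type A RMS ([type_a_rms()]) and Type B rectangular
#' ([type_b_rectangular()]) uncertainty evaluations.
#'
#' @param model An `"spr_line"` calibration (x = hydrogen ratio, y = SPR).
#' @param records Data frame with columns `name`, `h_ratio` and either an
#'   `spr` column or an `spr_<energy>` column.
#' @param energy Proton energy selecting the `spr_<energy>` column when
#'   present (default 100).
#' @return Data frame `name`, `group` (if present), `delta` (percent),
#'   input order preserved.
#' @examples
#' t1 <- icru46_reference_values()
#' cal <- fit_line(t1$h_ratio, t1$spr, t1$name)
#' head(relative_differences(cal, t1))
#' @export
relative_differences <- function(model, records, energy = 100) {
  spr_col <- paste0("spr_", format(energy))
  if (!(spr_col %in% names(records))) {
    if ("spr" %in% names(records)) {
      spr_col <- "spr"
    } else {
      stop("records carry no SPR column for energy ", format(energy),
           call. = FALSE)
    }
  }
  est <- predict(model, records$h_ratio, warn_extrapolation = FALSE)
  cal <- records[[spr_col]]
  out <- data.frame(name = records$name,
                    delta = 100 * (est - cal) / cal,
                    stringsAsFactors = FALSE)
  if ("group" %in% names(records)) out$group <- records$group
  out
}

#' Serialise a fitted calibration line to a text file
#'
#' Writes slope, intercept, R-squared, the fit-sample registry and creation
#' metadata as JSON, so fitted models can be shared between pipeline steps
#' and reloaded with [read_spr_model()].
#'
#' @param model An `"spr_line"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spr_model <- function(model, path) {
  stopifnot(inherits(model, "spr_line"))
  payload <- list(
    type = "spr_line",
    slope = model$slope, intercept = model$intercept,
    r_squared = model$r_squared, sigma = model$sigma,
    domain_label = model$domain_label,
    xlab = model$xlab, ylab = model$ylab,
    fit_samples = model$fit_samples,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("mrispr"))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialised calibration line
#'
#' @param path Path written by [write_spr_model()].
#' @return An `"spr_line"` object.
#' @export
read_spr_model <- function(path) {
  p <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) NULL)
  if (is.null(p) || is.null(p$type) || p$type != "spr_line") {
    stop("'", path, "' is not a serialised spr_line model", call. = FALSE)
  }
  structure(list(
    slope = p$slope, intercept = p$intercept,
    r_squared = p$r_squared, sigma = p$sigma,
    fit_samples = as.data.frame(p$fit_samples),
    domain_label = p$domain_label,
    xlab = p$xlab, ylab = p$ylab
  ), class = "spr_line")
}
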