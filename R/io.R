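#' Write an image series as a plain-text gridded format
#'
#' Portable, language-neutral storage for phantom image series: one CSV
#' of voxel values per slice (`slice_001.csv`, ...) plus a `series.yaml`
#' sidecar holding the voxel spacing (mm), the origin of voxel (1, 1) and
#' the slice indices. The format stands in for a scanner DICOM export in
#' tests and pipelines.
#'
#' @param series List of [image_slice()]s.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [read_image_series()]
#' @export
write_image_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    n_slices = length(series),
    spacing_mm = as.numeric(series[[1]]$spacing),
    origin_mm = as.numeric(series[[1]]$origin),
    slice_index = vapply(series, function(s) s$slice_index, integer(1)),
    dim = dim(series[[1]]$grid)
  )
  yaml::write_yaml(meta, file.path(dir, "series.yaml"))
  for (i in seq_along(series)) {
    utils::write.table(series[[i]]$grid,
                       file.path(dir, sprintf("slice_%03d.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read an image series written by [write_image_series()]
#'
#' @param dir Directory holding `series.yaml` and the slice CSV files.
#' @return List of [image_slice()]s.
#' @export
read_image_series <- function(dir) {
  meta_path <- file.path(dir, "series.yaml")
  if (!file.exists(meta_path)) {
    stop("'", dir, "' is not an image-series directory ",
         "(missing series.yaml with the voxel spacing)", call. = FALSE)
  }
  meta <- yaml::read_yaml(meta_path)
  if (is.null(meta$spacing_mm)) {
    stop("series.yaml in '", dir, "' lacks the spacing_mm entry",
         call. = FALSE)
  }
  lapply(seq_len(meta$n_slices), function(i) {
    path <- file.path(dir, sprintf("slice_%03d.csv", i))
    if (!file.exists(path)) stop("missing slice file '", path, "'",
                                 call. = FALSE)
    g <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(g) <- NULL
    image_slice(g, spacing = meta$spacing_mm, origin = meta$origin_mm,
                slice_index = meta$slice_index[i])
  })
}
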