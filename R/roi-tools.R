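# Circular-ROI extraction from 2-D parametric maps and the ROI-averaging
# convention used for organ-level values.

#' Circular ROI specification
#'
#' A circular region of interest on a 2-D parametric map, in 0-based
#' pixel coordinates. Standard labels follow the placement convention
#' (two ROIs in the right hepatic lobe, one in the left lobe when
#' visible, one in the posterior spleen), but any label is accepted.
#'
#' @param label ROI label, e.g. `"liver_right_posterior"`,
#'   `"liver_right_anterior"`, `"liver_left"`, `"spleen_posterior"`.
#' @param center_row,center_col Center pixel coordinates (0-based).
#' @param radius Radius in pixels (> 0).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(label, center_row, center_col, radius) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0) {
    stop("`radius` must be a single positive number (pixels)", call. = FALSE)
  }
  stopifnot(is.numeric(center_row), is.numeric(center_col))
  structure(list(label = as.character(label),
                 center_row = as.numeric(center_row),
                 center_col = as.numeric(center_col),
                 radius = as.numeric(radius)),
            class = "roi_spec")
}

#' Mean map value inside a circular ROI
#'
#' A pixel belongs to the ROI when the Euclidean distance from its
#' (0-based) row/column index to the ROI center is at most the radius.
#' The arithmetic mean of the finite member pixels is returned together
#' with the number of pixels used. Non-finite pixels are ignored; a disc
#' with no finite member pixels inside the map is an error.
#'
#' @param map Numeric matrix (2-D parametric map).
#' @param roi An [roi_spec].
#' @return A list with `mean` (map units) and `n_pixels`.
#' @export
roi_mean <- function(map, roi) {
  stopifnot(is.matrix(map), is.numeric(map), inherits(roi, "roi_spec"))
  if (roi$center_row < 0 || roi$center_row > nrow(map) - 1 ||
      roi$center_col < 0 || roi$center_col > ncol(map) - 1) {
    stop("ROI center lies outside the map", call. = FALSE)
  }
  rows <- seq(floor(roi$center_row - roi$radius),
              ceiling(roi$center_row + roi$radius))
  cols <- seq(floor(roi$center_col - roi$radius),
              ceiling(roi$center_col + roi$radius))
  rows <- rows[rows >= 0 & rows <= nrow(map) - 1]
  cols <- cols[cols >= 0 & cols <= ncol(map) - 1]
  if (length(rows) == 0L || length(cols) == 0L) {
    stop("ROI disc lies fully outside the map", call. = FALSE)
  }
  rc <- expand.grid(row = rows, col = cols)
  inside <- (rc$row - roi$center_row)^2 + (rc$col - roi$center_col)^2 <=
    roi$radius^2
  vals <- map[cbind(rc$row[inside] + 1L, rc$col[inside] + 1L)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) {
    stop("no finite pixels inside the ROI", call. = FALSE)
  }
  list(mean = mean(vals), n_pixels = length(vals))
}

#' Aggregate ROI means into an organ value
#'
#' Unweighted arithmetic mean of per-ROI means (each ROI counts equally
#' regardless of its pixel count), matching per-ROI reporting practice.
#'
#' @param means Numeric vector of ROI mean values (>= 1).
#' @return The organ-level value.
#' @export
aggregate_rois <- function(means) {
  means <- as.numeric(means)
  if (length(means) == 0L || any(!is.finite(means))) {
    stop("`means` must be a non-empty vector of finite ROI means",
         call. = FALSE)
  }
  mean(means)
}

#' Read a 2-D parametric map
#'
#' Reads a single-slice map from a NIfTI file (`.nii`/`.nii.gz`; a slice
#' index selects one plane of a 3-D volume) or from a plain CSV grid of
#' numbers (no header).
#'
#' @param path File path.
#' @param slice Slice index for 3-D NIfTI volumes (default 1).
#' @return A numeric matrix.
#' @export
read_map <- function(path, slice = 1L) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) == 2L) return(arr[, , drop = TRUE])
    if (length(dim(arr)) >= 3L) {
      if (slice < 1L || slice > dim(arr)[3L]) {
        stop("slice index out of range", call. = FALSE)
      }
      return(arr[, , slice, drop = TRUE])
    }
    stop("unsupported NIfTI dimensionality", call. = FALSE)
  }
  as.matrix(utils::read.csv(path, header = FALSE))
}

#' Read ROI specifications from JSON
#'
#' The JSON file holds an array of objects with fields `label`,
#' `center_row`, `center_col`, `radius` (0-based pixels).
#'
#' @param path Path to a JSON file.
#' @return A list of [roi_spec] objects.
#' @export
read_roi_specs <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  purrr::pmap(x, function(label, center_row, center_col, radius) {
    roi_spec(label, center_row, center_col, radius)
  })
}

#' Organ value from a map and several ROIs
#'
#' Convenience wrapper: per-ROI means via [roi_mean()], aggregated with
#' [aggregate_rois()].
#'
#' @param map Numeric matrix.
#' @param rois List of [roi_spec] objects.
#' @return A list with `value`, `roi_means` and `n_pixels`.
#' @export
extract_organ_value <- function(map, rois) {
  res <- purrr::map(rois, ~ roi_mean(map, .x))
  means <- vapply(res, `[[`, numeric(1), "mean")
  list(value = aggregate_rois(means), roi_means = means,
       n_pixels = vapply(res, `[[`, integer(1), "n_pixels"))
}
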