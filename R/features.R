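#' Extract the (maxHU, ppLapl) feature pair for a stone
#'
#' The method's entire feature space: \code{max_hu} is the attenuation of
#' the single highest-attenuating voxel inside the mask, and \code{pp_lapl}
#' is the scaled-Laplacian value at that same voxel, i.e. the difference
#' between the peak attenuation and the weighted mean of its 26 3D
#' neighbours. Neighbours are taken from the full volume, not restricted to
#' the mask. Ties for the maximum are broken deterministically by the
#' lexicographically smallest (slice, row, col) index.
#'
#' @param volume a \code{\link{ct_volume}}.
#' @param mask a congruent, non-empty \code{\link{stone_mask}}.
#' @param kernel a \code{\link{laplacian_kernel}} or scheme name.
#' @param size logical; also measure the largest axial diameter
#'   (\code{\link{measure_size}}).
#' @return An object of class \code{stone_features}: list with
#'   \code{max_hu} (HU), \code{pp_lapl} (HU), \code{peak_index} (1-based
#'   voxel triple), \code{size_mm} (or \code{NA}), and \code{border_peak}
#'   (TRUE when the peak voxel lies on the volume border, where replicate
#'   padding affects the neighbourhood).
#' @examples
#' v <- ct_volume(array(100, c(5, 5, 5)))
#' v$values[3, 3, 3] <- 700
#' m <- stone_mask(v$values > 130)
#' f <- extract_features(v, m, laplacian_kernel("uniform"))
#' c(f$max_hu, f$pp_lapl)  # 700 600
#' @export
extract_features <- function(volume, mask, kernel = laplacian_kernel(),
                             size = TRUE) {
  stopifnot(is_ct_volume(volume))
  if (!inherits(mask, "stone_mask")) stop("'mask' must be a stone_mask")
  check_congruent(volume, mask)
  kernel <- as_laplacian_kernel(kernel)
  v <- volume$values
  d <- dim(v)
  members <- which(mask$membership, arr.ind = TRUE)
  if (nrow(members) == 0L) stop("mask is empty")
  vals <- v[coords_to_linear(members, d)]
  mx <- max(vals)
  cand <- members[vals == mx, , drop = FALSE]
  peak <- cand[order(cand[, 1], cand[, 2], cand[, 3])[1L], ]
  pp <- point_laplacian(volume, peak, kernel)
  border <- any(peak == 1L) || any(peak == d)
  structure(list(
    max_hu = mx,
    pp_lapl = pp,
    peak_index = as.integer(peak),
    size_mm = if (size) measure_size(mask, volume$spacing) else NA_real_,
    border_peak = border
  ), class = "stone_features")
}

#' @export
print.stone_features <- function(x, ...) {
  cat(sprintf("Stone features: maxHU %.1f HU, ppLapl %.1f HU\n",
              x$max_hu, x$pp_lapl))
  cat(sprintf("  peak voxel (slice,row,col): (%d,%d,%d)%s\n",
              x$peak_index[1], x$peak_index[2], x$peak_index[3],
              if (isTRUE(x$border_peak)) " [on volume border]" else ""))
  if (!is.na(x$size_mm)) cat(sprintf("  largest axial diameter: %.1f mm\n", x$size_mm))
  invisible(x)
}

# Coerce stone_features / data.frame / named vector into a feature
# data.frame with columns max_hu, pp_lapl (one row per stone).
as_feature_frame <- function(features) {
  if (inherits(features, "stone_features")) {
    return(data.frame(max_hu = features$max_hu, pp_lapl = features$pp_lapl))
  }
  if (is.data.frame(features)) {
    if (!all(c("max_hu", "pp_lapl") %in% names(features))) {
      stop("feature table must have columns 'max_hu' and 'pp_lapl'")
    }
    return(features[, c("max_hu", "pp_lapl"), drop = FALSE])
  }
  if (is.numeric(features) && !is.null(names(features)) &&
      all(c("max_hu", "pp_lapl") %in% names(features))) {
    return(data.frame(max_hu = features[["max_hu"]],
                      pp_lapl = features[["pp_lapl"]]))
  }
  stop("'features' must be stone_features, a feature data.frame, or a named vector")
}

check_finite_features <- function(fr) {
  if (!all(is.finite(fr$max_hu)) || !all(is.finite(fr$pp_lapl))) {
    stop("features must be finite")
  }
  invisible(fr)
}

#' Write / read per-stone feature tables
#'
#' CSV with columns \code{stone_id, max_hu, pp_lapl, peak_i, peak_j,
#' peak_k, size_mm}. Peak indices are written 0-based in (slice, row, col)
#' order; \code{read_features_csv} converts them back to the package's
#' 1-based in-memory convention. Dialect: UTF-8, comma separator, header
#' row, decimal point.
#'
#' @param features data.frame with the columns above (1-based peaks).
#' @param path CSV path.
#' @return \code{write_features_csv}: \code{path} invisibly;
#'   \code{read_features_csv}: the data.frame (1-based peaks).
#' @export
write_features_csv <- function(features, path) {
  need <- c("stone_id", "max_hu", "pp_lapl", "peak_i", "peak_j", "peak_k", "size_mm")
  if (!all(need %in% names(features))) {
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  }
  out <- features[, need, drop = FALSE]
  out$peak_i <- out$peak_i - 1L
  out$peak_j <- out$peak_j - 1L
  out$peak_k <- out$peak_k - 1L
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  if (!file.exists(path)) stop("feature CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("stone_id", "max_hu", "pp_lapl")
  if (!all(need %in% names(df))) {
    stop("feature CSV '", path, "' must have columns: ", paste(need, collapse = ", "))
  }
  for (col in c("peak_i", "peak_j", "peak_k")) {
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]]) + 1L
  }
  df
}
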