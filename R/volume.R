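#' CT volume in Hounsfield units
#'
#' Container for a 3D non-enhanced CT attenuation volume. Values are stored
#' as a numeric array indexed \code{[slice, row, col]} (1-based, R native);
#' \code{spacing} gives the voxel size in mm along the same axes. All file
#' formats read and written by the package map onto this convention and use
#' 0-based indices in tabular output (documented per writer).
#'
#' @param values numeric 3D array of attenuation values (HU). Air is
#'   approximately -1000 HU; all values must be finite (no NaN/Inf).
#' @param spacing numeric length-3, strictly positive voxel size in mm for
#'   the (slice, row, col) axes.
#' @return An object of class \code{ct_volume}: a list with elements
#'   \code{values} and \code{spacing}.
#' @examples
#' vol <- ct_volume(array(0, c(5, 5, 5)), spacing = c(1, 1, 1))
#' dim(vol$values)
#' @export
ct_volume <- function(values, spacing = c(1, 1, 1)) {
  if (is.null(dim(values))) stop("'values' must be a 3D array")
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("'values' must have exactly 3 dimensions")
  if (any(dim(values) < 1L)) stop("all three dimensions must be >= 1")
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) {
    stop("attenuation values must be finite (found NA/NaN/Inf)")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    stop("'spacing' must be 3 strictly positive voxel sizes in mm")
  }
  structure(list(values = values, spacing = spacing), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("CT volume: %d x %d x %d voxels (slice x row x col)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  spacing: %.3g x %.3g x %.3g mm\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range: [%.1f, %.1f]\n", min(x$values), max(x$values)))
  invisible(x)
}

is_ct_volume <- function(x) inherits(x, "ct_volume")

as_ct_volume <- function(x, spacing = c(1, 1, 1)) {
  if (is_ct_volume(x)) x else ct_volume(x, spacing)
}

#' Binary stone mask
#'
#' Voxel membership of one segmented stone, congruent with its CT volume.
#' Member voxels must form a single 26-connected component (checked by
#' \code{\link{segment_stone}}, which is the usual constructor).
#'
#' @param membership logical 3D array, same shape as the volume.
#' @param seed optional 1-based voxel index triple that initiated the
#'   segmentation.
#' @param truncated logical flag: the component touched the segmentation
#'   clip boundary and may be cut off.
#' @return An object of class \code{stone_mask}.
#' @export
stone_mask <- function(membership, seed = NULL, truncated = FALSE) {
  if (is.null(dim(membership)) || length(dim(membership)) != 3L) {
    stop("'membership' must be a logical 3D array")
  }
  membership <- array(as.logical(membership), dim(membership))
  if (anyNA(membership)) stop("mask membership must not contain NA")
  if (!any(membership)) stop("mask must contain at least one voxel")
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (length(seed) != 3L) stop("'seed' must be a voxel index triple")
  }
  structure(list(membership = membership, seed = seed,
                 truncated = isTRUE(truncated)),
            class = "stone_mask")
}

#' @export
print.stone_mask <- function(x, ...) {
  cat(sprintf("Stone mask: %d voxels%s\n", sum(x$membership),
              if (x$truncated) " [truncated at clip boundary]" else ""))
  invisible(x)
}

check_congruent <- function(volume, mask) {
  if (!identical(dim(volume$values), dim(mask$membership))) {
    stop("mask and volume shapes differ")
  }
  invisible(TRUE)
}

#' Read a CT volume
#'
#' Reads a NIfTI file (\code{.nii}/\code{.nii.gz}) or a raw little-endian
#' array with a JSON sidecar. NIfTI stores arrays as (x, y, z) = (col, row,
#' slice); on read the axes are permuted to the package's (slice, row, col)
#' order and the pixel dimensions reversed to match, so \code{spacing[1]} is
#' the slice thickness.
#'
#' @param path path to a \code{.nii}, \code{.nii.gz} or \code{.raw} file.
#'   For raw input a sidecar \code{<path>.json} with fields \code{shape}
#'   (slice, row, col), \code{spacing} (mm) and optional \code{dtype}
#'   (\code{"float64"}, default) must sit next to it.
#' @return A \code{\link{ct_volume}}.
#' @export
read_ct_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                    error = function(e) stop("malformed NIfTI file '", path,
                                             "': ", conditionMessage(e)))
    arr <- as.array(img)
    if (length(dim(arr)) != 3L) {
      stop("NIfTI file '", path, "' is not a 3D volume")
    }
    sp <- RNifti::pixdim(img)
    if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0)) {
      sp <- c(1, 1, 1)
    }
    ct_volume(aperm(arr, c(3, 2, 1)), spacing = rev(sp[1:3]))
  } else if (grepl("\\.raw$", path)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      stop("raw volume '", path, "' needs a JSON sidecar: ", sidecar)
    }
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(meta$shape) || is.null(meta$spacing)) {
      stop("sidecar '", sidecar, "' must provide 'shape' and 'spacing'")
    }
    shape <- as.integer(meta$shape)
    dtype <- if (is.null(meta$dtype)) "float64" else meta$dtype
    size <- switch(dtype, float64 = 8L, float32 = 4L, int16 = 2L,
                   stop("unsupported raw dtype: ", dtype))
    what <- if (dtype == "int16") integer() else double()
    n <- prod(shape)
    con <- file(path, "rb"); on.exit(close(con))
    vals <- readBin(con, what, n = n, size = size, endian = "little")
    if (length(vals) != n) stop("raw volume '", path, "' is shorter than its declared shape")
    # raw layout: slice-major C order (slice, row, col), matching the sidecar
    arr <- aperm(array(as.double(vals), dim = rev(shape)), c(3, 2, 1))
    ct_volume(arr, spacing = as.numeric(meta$spacing))
  } else {
    stop("unrecognised volume format (expected .nii, .nii.gz or .raw): ", path)
  }
}

#' Write a CT volume or mask as NIfTI
#'
#' Inverse of \code{\link{read_ct_volume}}: the internal (slice, row, col)
#' array is permuted back to NIfTI (x, y, z) order.
#'
#' @param x a \code{ct_volume} or \code{stone_mask}.
#' @param path output path ending in \code{.nii} or \code{.nii.gz}.
#' @return \code{path}, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  if (inherits(x, "stone_mask")) {
    arr <- array(as.double(x$membership), dim(x$membership))
    sp <- c(1, 1, 1)
  } else if (is_ct_volume(x)) {
    arr <- x$values
    sp <- x$spacing
  } else {
    stop("'x' must be a ct_volume or stone_mask")
  }
  img <- RNifti::asNifti(aperm(arr, c(3, 2, 1)))
  img <- RNifti::`pixdim<-`(img, rev(sp))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a stone mask from NIfTI
#'
#' Nonzero voxels are members. A congruent \code{ct_volume} may be supplied
#' to check shapes.
#'
#' @param path NIfTI file.
#' @param volume optional \code{ct_volume} for congruence checking.
#' @return A \code{stone_mask} when the file is binary; if the file holds
#'   several positive integer labels, a named list of \code{stone_mask}
#'   objects (one per label, names \code{"1"}, \code{"2"}, ...).
#' @export
read_stone_mask <- function(path, volume = NULL) {
  vol <- read_ct_volume(path)
  vals <- round(vol$values)
  labels <- sort(unique(vals[vals > 0]))
  if (length(labels) == 0L) stop("mask file '", path, "' has no positive voxels")
  if (!is.null(volume) && !identical(dim(volume$values), dim(vals))) {
    stop("mask '", path, "' is not congruent with the volume")
  }
  if (length(labels) == 1L) {
    return(stone_mask(vals > 0))
  }
  out <- lapply(labels, function(l) stone_mask(vals == l))
  names(out) <- as.character(labels)
  out
}

#' Resample a volume to isotropic voxels
#'
#' Trilinear interpolation onto an isotropic grid, used before Laplacian
#' filtering when the acquisition spacing is anisotropic. The peak features
#' are defined on the 1/1 mm axial reformat, so 1 mm is the default target.
#'
#' @param volume a \code{ct_volume}.
#' @param target_mm target isotropic voxel size, mm.
#' @return A resampled \code{ct_volume} with spacing
#'   \code{c(target_mm, target_mm, target_mm)}.
#' @export
resample_isotropic <- function(volume, target_mm = 1) {
  stopifnot(is_ct_volume(volume), is_scalar_number(target_mm), target_mm > 0)
  d <- dim(volume$values)
  sp <- volume$spacing
  extent <- (d - 1) * sp
  nd <- pmax(1L, as.integer(floor(extent / target_mm)) + 1L)
  out <- array(0, nd)
  # continuous source coordinates of each target grid line, per axis
  src <- lapply(1:3, function(a) {
    pos <- (seq_len(nd[a]) - 1) * target_mm / sp[a] + 1
    pmin(pmax(pos, 1), d[a])
  })
  lo <- lapply(1:3, function(a) pmin(floor(src[[a]]), d[a] - ifelse(d[a] > 1, 1, 0)))
  fr <- lapply(1:3, function(a) src[[a]] - lo[[a]])
  v <- volume$values
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    wi <- if (di == 0) 1 - fr[[1]] else fr[[1]]
    wj <- if (dj == 0) 1 - fr[[2]] else fr[[2]]
    wk <- if (dk == 0) 1 - fr[[3]] else fr[[3]]
    ii <- clamp_index(lo[[1]] + di, d[1])
    jj <- clamp_index(lo[[2]] + dj, d[2])
    kk <- clamp_index(lo[[3]] + dk, d[3])
    w <- outer(outer(wi, wj), wk)
    out <- out + w * v[ii, jj, kk, drop = FALSE]
  }
  ct_volume(out, spacing = rep(target_mm, 3))
}
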