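#' Laplacian kernel specification
#'
#' Defines the weighting of the 26 neighbours in the 3x3x3 stencil used by
#' \code{\link{scaled_laplacian}}. Two schemes are offered:
#' \describe{
#'   \item{\code{"inverse-distance"}}{weight 1 for the 6 face neighbours,
#'     1/sqrt(2) for the 12 edge neighbours and 1/sqrt(3) for the 8 corner
#'     neighbours (distances in voxel units), normalised to sum 1. This is
#'     the standard 27-point discrete Laplacian family and the default.}
#'   \item{\code{"uniform"}}{all 26 neighbours weighted equally.}
#' }
#' Boundary voxels are handled by replicate padding (nearest voxel inside
#' the volume).
#'
#' @param scheme \code{"inverse-distance"} or \code{"uniform"}.
#' @return An object of class \code{laplacian_kernel} with the 26 neighbour
#'   offsets and their normalised weights (strictly positive, sum 1).
#' @examples
#' k <- laplacian_kernel()
#' sum(k$weights)  # 1
#' @export
laplacian_kernel <- function(scheme = c("inverse-distance", "uniform")) {
  scheme <- match.arg(scheme)
  offsets <- neighbor_offsets_26()
  w <- switch(scheme,
    "inverse-distance" = 1 / sqrt(rowSums(offsets^2)),
    "uniform" = rep(1, nrow(offsets))
  )
  w <- w / sum(w)
  structure(list(scheme = scheme, offsets = offsets, weights = w,
                 boundary = "replicate-pad"),
            class = "laplacian_kernel")
}

#' @export
print.laplacian_kernel <- function(x, ...) {
  cat(sprintf("26-neighbour Laplacian kernel (%s weights, %s boundary)\n",
              x$scheme, x$boundary))
  invisible(x)
}

as_laplacian_kernel <- function(kernel) {
  if (inherits(kernel, "laplacian_kernel")) return(kernel)
  if (is.character(kernel) && length(kernel) == 1L) return(laplacian_kernel(kernel))
  stop("'kernel' must be a laplacian_kernel or a scheme name")
}

#' Scaled Laplacian filter
#'
#' At every voxel, the filtered value is the voxel's attenuation minus the
#' weighted mean of its 26 neighbours: a high value marks a voxel that
#' stands out sharply from its 3D surroundings. On a stone's peak voxel
#' this is the ppLapl feature. The neighbourhood is isotropic in voxel
#' units; strongly anisotropic spacing triggers a warning (consider
#' \code{\link{resample_isotropic}} first).
#'
#' @param volume a \code{\link{ct_volume}} (or bare 3D array).
#' @param kernel a \code{\link{laplacian_kernel}} or scheme name.
#' @return A \code{ct_volume} of the same shape holding the filtered field
#'   (HU).
#' @examples
#' v <- ct_volume(array(100, c(5, 5, 5)))
#' v$values[3, 3, 3] <- 700
#' lap <- scaled_laplacian(v, laplacian_kernel("uniform"))
#' lap$values[3, 3, 3]  # 600
#' @export
scaled_laplacian <- function(volume, kernel = laplacian_kernel()) {
  volume <- as_ct_volume(volume)
  kernel <- as_laplacian_kernel(kernel)
  sp <- volume$spacing
  if (max(sp) / min(sp) > 1.05) {
    warning("anisotropic voxel spacing (", paste(signif(sp, 3), collapse = " x "),
            " mm): the 26-neighbour stencil is defined in voxel units; ",
            "consider resample_isotropic() first")
  }
  v <- volume$values
  d <- dim(v)
  seqs <- lapply(d, seq_len)
  acc <- array(0, d)
  for (m in seq_len(nrow(kernel$offsets))) {
    off <- kernel$offsets[m, ]
    acc <- acc + kernel$weights[m] *
      v[clamp_index(seqs[[1]] + off[1], d[1]),
        clamp_index(seqs[[2]] + off[2], d[2]),
        clamp_index(seqs[[3]] + off[3], d[3]), drop = FALSE]
  }
  ct_volume(v - acc, spacing = sp)
}

# Filtered value at a single voxel (replicate padding), identical to
# scaled_laplacian(volume)$values[idx] but without filtering the whole
# volume. idx is a 1-based (slice,row,col) triple.
point_laplacian <- function(volume, idx, kernel = laplacian_kernel()) {
  volume <- as_ct_volume(volume)
  kernel <- as_laplacian_kernel(kernel)
  v <- volume$values
  d <- dim(v)
  nb <- sweep(kernel$offsets, 2, as.integer(idx), "+")
  nb[, 1] <- clamp_index(nb[, 1], d[1])
  nb[, 2] <- clamp_index(nb[, 2], d[2])
  nb[, 3] <- clamp_index(nb[, 3], d[3])
  v[idx[1], idx[2], idx[3]] - sum(kernel$weights * v[coords_to_linear(nb, d)])
}
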