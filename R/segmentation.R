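#' Segment a stone from a seed point
#'
#' Region growing: returns the 26-connected component of voxels at or above
#' \code{threshold} that contains the seed, clipped to a cube of side
#' \code{max_extent} mm centred on the seed. Deterministic for fixed inputs,
#' and independent of which voxel inside the component is used as seed
#' (up to the clip window, which follows the seed).
#'
#' @param volume a \code{\link{ct_volume}}.
#' @param seed 1-based (slice, row, col) voxel index inside the volume; its
#'   attenuation must be at or above \code{threshold}.
#' @param threshold segmentation threshold in HU. The default 130 HU sits
#'   well below the attenuation of any urinary stone while excluding soft
#'   tissue.
#' @param max_extent side length of the clip cube in mm (default 40 mm,
#'   comfortably above the 3-20 mm stone size range).
#' @return A \code{\link{stone_mask}}. If the component touches the clip
#'   boundary (and that boundary is interior to the volume) the mask is
#'   flagged \code{truncated} and a warning is raised.
#' @export
segment_stone <- function(volume, seed, threshold = 130, max_extent = 40) {
  stopifnot(is_ct_volume(volume))
  v <- volume$values
  d <- dim(v)
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > d)) {
    stop("'seed' must be a 1-based voxel index inside the volume")
  }
  if (!is_scalar_number(threshold)) stop("'threshold' must be a single HU value")
  if (!is_scalar_number(max_extent) || max_extent <= 0) {
    stop("'max_extent' must be a positive length in mm")
  }
  if (v[seed[1], seed[2], seed[3]] < threshold) {
    stop(sprintf(
      "seed voxel (%d,%d,%d) has %.1f HU, below the %.1f HU threshold: re-seed inside the stone",
      seed[1], seed[2], seed[3], v[seed[1], seed[2], seed[3]], threshold))
  }
  half <- pmax(0L, as.integer(floor((max_extent / 2) / volume$spacing)))
  lo <- pmax(seed - half, 1L)
  hi <- pmin(seed + half, d)

  offsets <- neighbor_offsets_26()
  visited <- array(FALSE, d)
  visited[seed[1], seed[2], seed[3]] <- TRUE
  frontier <- matrix(seed, nrow = 1L)
  while (nrow(frontier) > 0L) {
    nf <- nrow(frontier)
    cand <- frontier[rep(seq_len(nf), each = 26L), , drop = FALSE] +
      offsets[rep(1:26, nf), , drop = FALSE]
    keep <- cand[, 1] >= lo[1] & cand[, 1] <= hi[1] &
            cand[, 2] >= lo[2] & cand[, 2] <= hi[2] &
            cand[, 3] >= lo[3] & cand[, 3] <= hi[3]
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0L) break
    lin <- coords_to_linear(cand, d)
    first <- !duplicated(lin)
    cand <- cand[first, , drop = FALSE]
    lin <- lin[first]
    keep <- !visited[lin] & v[lin] >= threshold
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0L) break
    visited[coords_to_linear(cand, d)] <- TRUE
    frontier <- cand
  }

  members <- which(visited, arr.ind = TRUE)
  truncated <- FALSE
  for (a in 1:3) {
    if (lo[a] > 1L && any(members[, a] == lo[a])) truncated <- TRUE
    if (hi[a] < d[a] && any(members[, a] == hi[a])) truncated <- TRUE
  }
  if (truncated) {
    warning("segmented component touches the clip boundary; the stone may be truncated ",
            "(increase 'max_extent')")
  }
  stone_mask(visited, seed = seed, truncated = truncated)
}

#' Largest axial stone diameter
#'
#' Automates the manual axial caliper measurement: for every axial slice,
#' the largest distance between member-voxel footprints (voxel centres
#' extended by half a voxel at each end of the measuring direction) is
#' computed, and the maximum over slices returned. A single voxel with 1 mm
#' in-plane spacing therefore measures 1 mm, and 5 collinear voxels 5 mm.
#'
#' @param mask a \code{\link{stone_mask}}.
#' @param spacing voxel spacing triple in mm, (slice, row, col); the axial
#'   plane uses \code{spacing[2:3]}.
#' @return Largest axial diameter in mm.
#' @export
measure_size <- function(mask, spacing = c(1, 1, 1)) {
  if (!inherits(mask, "stone_mask")) stop("'mask' must be a stone_mask")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("'spacing' must be 3 positive voxel sizes in mm")
  }
  members <- which(mask$membership, arr.ind = TRUE)
  sr <- spacing[2]; sc <- spacing[3]
  best <- 0
  for (s in unique(members[, 1])) {
    pts <- members[members[, 1] == s, 2:3, drop = FALSE]
    r <- pts[, 1] * sr
    c <- pts[, 2] * sc
    dr <- abs(outer(r, r, "-"))
    dc <- abs(outer(c, c, "-"))
    dd <- sqrt(dr^2 + dc^2)
    # extend by the projected half-footprints at both ends
    ext <- ifelse(dd > 0, dd + (sr * dr + sc * dc) / dd, max(sr, sc))
    best <- max(best, ext)
  }
  best
}
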