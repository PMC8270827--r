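# Study-condition constants: per-class feature moments (mean, SD, range)
# of maxHU and ppLapl, class sizes, and stone size distributions used as
# generator defaults throughout the package.
stone_reference_moments <- function() {
  list(
    ua = list(
      max_hu = list(mean = 537, sd = 155, range = c(223, 794)),
      pp_lapl = list(mean = 122, sd = 39, range = c(47, 212)),
      size_mm = list(mean = 7.3, sd = 4.1, range = c(3.0, 19))
    ),
    nonua = list(
      max_hu = list(mean = 1286, sd = 292, range = c(536, 1796)),
      pp_lapl = list(mean = 282, sd = 96, range = c(51, 546)),
      size_mm = list(mean = 6.3, sd = 2.5, range = c(3.0, 15))
    )
  )
}

#' Specification of one synthetic stone phantom
#'
#' Describes a single simulated stone embedded in soft tissue: an
#' axis-aligned ellipsoid whose largest axial diameter is
#' \code{diameter_mm}, with an internal attenuation profile depending on
#' composition. UA stones are modelled with a flat profile at
#' \code{peak_hu}; non-UA (calcium-based) stones with a centre-peaked
#' profile (Gaussian tip of width \code{tip_width_mm} rising from
#' \code{edge_fraction * peak_hu} at the rim to \code{peak_hu} at the
#' core), reproducing the larger peak-to-neighbourhood contrast of calcium
#' stones. The volume is convolved with a Gaussian point-spread function
#' and Gaussian noise is added.
#'
#' @param composition \code{"UA"} or \code{"non-UA"}.
#' @param peak_hu target peak attenuation of the noise-free stone, HU.
#' @param diameter_mm largest axial diameter, mm; must lie in the 3-20 mm
#'   study inclusion range.
#' The imaged attenuation field is rendered analytically at the voxel
#' centres. The total smoothing combines the reconstruction PSF with the
#' voxel aperture (a voxel averages its footprint, adding variance
#' \code{spacing^2/12} per axis): \code{sigma_eff = sqrt(blur_sigma_mm^2 +
#' mean(spacing^2)/12)}. The blurred ellipsoid plateau follows an erf edge
#' model (normal CDF of the signed surface distance over
#' \code{sigma_eff}), and the blurred non-UA core keeps its Gaussian form
#' with width \code{sqrt(tip_width_mm^2 + sigma_eff^2)}. Rendering the
#' blurred continuum directly avoids the grid aliasing a discrete
#' convolution of a sub-voxel core would introduce, and makes the imaged
#' peak equal \code{peak_hu} exactly (before noise). The intrinsic
#' pre-blur core of a dense calcification is correspondingly sharper and
#' higher, as in micro-CT of calcium stones.
#'
#' @param background_hu soft-tissue background, HU (default 30).
#' @param blur_sigma_mm PSF sigma, mm (default 0.4, about 1 mm FWHM,
#'   consistent with a 0.6 mm detector acquisition reconstructed at 1 mm;
#'   the resulting edge partial-volume keeps the attenuation peak interior
#'   to the stone, as in real scans, without turning small flat stones
#'   into sharply peaked ones).
#' @param noise_sd_hu Gaussian noise SD, HU (default 30, typical for a
#'   1 mm abdominal reformat).
#' @param tip_width_mm intrinsic (pre-blur) Gaussian core width of the
#'   non-UA profile, mm (default 1.2).
#' @param edge_fraction rim attenuation of the non-UA profile as a fraction
#'   of \code{peak_hu} (default 0.5).
#' @param spacing voxel spacing triple, mm (default 1 mm isotropic).
#' @param margin_mm background margin around the stone, mm (default 6).
#' @param seed RNG seed fixing the noise realization; the same spec and
#'   seed give bit-identical volumes.
#' @return An object of class \code{stone_phantom_spec}.
#' @export
stone_phantom_spec <- function(composition, peak_hu, diameter_mm,
                               background_hu = 30, blur_sigma_mm = 0.4,
                               noise_sd_hu = 30, tip_width_mm = 1.2,
                               edge_fraction = 0.5, spacing = c(1, 1, 1),
                               margin_mm = 6, seed = NULL) {
  composition <- normalize_label(composition, allow_mixed = FALSE)
  if (!is_scalar_number(peak_hu)) stop("'peak_hu' must be a single HU value")
  if (!is_scalar_number(diameter_mm) || diameter_mm < 3 || diameter_mm > 20) {
    stop("'diameter_mm' must lie in the 3-20 mm inclusion range")
  }
  if (peak_hu <= background_hu) stop("'peak_hu' must exceed the background attenuation")
  if (blur_sigma_mm < 0 || noise_sd_hu < 0) stop("blur and noise must be non-negative")
  if (tip_width_mm <= 0) stop("'tip_width_mm' must be positive")
  if (edge_fraction <= 0 || edge_fraction > 1) stop("'edge_fraction' must be in (0, 1]")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("invalid 'spacing'")
  structure(list(composition = composition, peak_hu = peak_hu,
                 diameter_mm = diameter_mm, background_hu = background_hu,
                 blur_sigma_mm = blur_sigma_mm, noise_sd_hu = noise_sd_hu,
                 tip_width_mm = tip_width_mm, edge_fraction = edge_fraction,
                 spacing = spacing, margin_mm = margin_mm, seed = seed),
            class = "stone_phantom_spec")
}

# separable Gaussian blur with replicate padding; sigma in voxel units,
# one value per axis. Kernel truncated at 3 sigma.
gaussian_blur3 <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (a in 1:3) {
    s <- sigma_vox[a]
    if (s < 1e-8) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    w <- exp(-((-r):r)^2 / (2 * s^2))
    w <- w / sum(w)
    seqs <- lapply(d, seq_len)
    out <- array(0, d)
    for (t in (-r):r) {
      idx <- seqs
      idx[[a]] <- clamp_index(seqs[[a]] + t, d[a])
      out <- out + w[t + r + 1L] * arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    }
    arr <- out
  }
  arr
}

#' Generate a synthetic stone phantom volume
#'
#' Renders the stone described by a \code{\link{stone_phantom_spec}} into a
#' CT volume, applies the PSF blur and noise, and returns the noise-free
#' ellipsoid membership as ground-truth mask.
#'
#' @param spec a \code{\link{stone_phantom_spec}}.
#' @return List with elements \code{volume} (\code{ct_volume}), \code{mask}
#'   (\code{stone_mask}, ground truth), \code{label} (the composition) and
#'   \code{spec}.
#' @examples
#' ph <- generate_phantom(stone_phantom_spec("UA", peak_hu = 550,
#'   diameter_mm = 8, blur_sigma_mm = 0, noise_sd_hu = 0))
#' max(ph$volume$values)  # 550
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "stone_phantom_spec"))
  sp <- spec$spacing
  # near-equant ellipsoid (renal calculi are roundish); the largest axial
  # diameter runs along the row axis
  semi <- c(0.9, 1, 0.95) * spec$diameter_mm / 2
  extent <- 2 * (semi + spec$margin_mm)
  d <- as.integer(ceiling(extent / sp))
  d <- d + (1L - d %% 2L)  # odd dims so the centre is a voxel
  if (any(d < 3L)) stop("stone plus margin does not fit a 3-voxel volume")
  centre <- (d + 1L) / 2
  co <- lapply(1:3, function(a) ((seq_len(d[a])) - centre[a]) * sp[a])
  # squared normalised ellipsoid coordinate and mm radius from centre
  e2 <- outer(outer((co[[1]] / semi[1])^2, (co[[2]] / semi[2])^2, "+"),
              (co[[3]] / semi[3])^2, "+")
  inside <- e2 <= 1
  if (!any(inside)) stop("stone is smaller than one voxel at this spacing")
  r2 <- outer(outer(co[[1]]^2, co[[2]]^2, "+"), co[[3]]^2, "+")
  # total smoothing: reconstruction PSF plus voxel aperture in quadrature
  sigma <- sqrt(spec$blur_sigma_mm^2 + mean(sp^2) / 12)
  # blurred plateau: erf edge model on the radial signed distance to the
  # ellipsoid surface, (1 - |x|_e) * r / |x|_e (positive inside)
  en <- sqrt(e2)
  r <- sqrt(r2)
  sdist <- ifelse(en > 0, (1 - en) * r / en, min(semi))
  step <- stats::pnorm(sdist / sigma)
  bg <- spec$background_hu
  if (spec$composition == LBL_UA) {
    vol <- bg + (spec$peak_hu - bg) * step
  } else {
    edge <- spec$edge_fraction * spec$peak_hu
    # imaged Gaussian core: total smoothing widens the intrinsic tip
    w2 <- spec$tip_width_mm^2 + sigma^2
    vol <- bg + (edge - bg) * step +
      (spec$peak_hu - edge) * exp(-r2 / (2 * w2))
  }
  if (spec$noise_sd_hu > 0) {
    noise <- with_seed(spec$seed, stats::rnorm(length(vol), 0, spec$noise_sd_hu))
    vol <- vol + array(noise, d)
  }
  list(volume = ct_volume(vol, spacing = sp),
       mask = stone_mask(inside, seed = as.integer(centre)),
       label = spec$composition,
       spec = spec)
}

#' Per-class feature distribution specification
#'
#' Truncated bivariate normal model of the (maxHU, ppLapl) feature plane
#' used to draw surrogate training sets. Defaults are the study-condition
#' class moments: UA maxHU 537 +/- 155 HU on [223, 794], UA ppLapl
#' 122 +/- 39 HU on [47, 212]; non-UA maxHU 1286 +/- 292 HU on
#' [536, 1796], non-UA ppLapl 282 +/- 96 HU on [51, 546]; class sizes 22
#' UA and 104 non-UA (the annotated reference dataset the kNN model stands
#' in for).
#'
#' @param n_ua,n_nonua class counts (>= 1).
#' @param correlation within-class Pearson correlation between maxHU and
#'   ppLapl (default 0.6: both features grow with mineral density).
#' @param ua,nonua per-class lists with elements \code{max_hu} and
#'   \code{pp_lapl}, each \code{list(mean=, sd=, range=c(lo, hi))}.
#' @param seed RNG seed.
#' @return An object of class \code{feature_distribution_spec}.
#' @export
feature_distribution_spec <- function(n_ua = 22L, n_nonua = 104L,
                                      correlation = 0.6,
                                      ua = stone_reference_moments()$ua[c("max_hu", "pp_lapl")],
                                      nonua = stone_reference_moments()$nonua[c("max_hu", "pp_lapl")],
                                      seed = NULL) {
  if (!is_scalar_number(n_ua) || !is_scalar_number(n_nonua) ||
      n_ua < 1 || n_nonua < 1) {
    stop("class counts must be >= 1")
  }
  if (!is_scalar_number(correlation) || abs(correlation) >= 1) {
    stop("'correlation' must lie in (-1, 1)")
  }
  for (cls in list(ua, nonua)) {
    for (f in c("max_hu", "pp_lapl")) {
      m <- cls[[f]]
      if (is.null(m$mean) || is.null(m$sd) || is.null(m$range)) {
        stop("each feature needs mean, sd and range")
      }
      if (m$range[1] >= m$range[2]) stop("empty truncation range for ", f)
      if (m$mean < m$range[1] || m$mean > m$range[2]) {
        stop("truncation range must contain the mean for ", f)
      }
      if (m$sd <= 0) stop("feature sd must be positive")
    }
  }
  structure(list(n_ua = as.integer(n_ua), n_nonua = as.integer(n_nonua),
                 correlation = correlation, ua = ua, nonua = nonua,
                 seed = seed),
            class = "feature_distribution_spec")
}

# Rejection sampling of n truncated bivariate normal pairs.
sample_truncated_bvn <- function(n, mx, px, rho) {
  out <- matrix(NA_real_, 0, 2)
  a <- rho * px$sd / mx$sd
  resid_sd <- px$sd * sqrt(1 - rho^2)
  guard <- 0L
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 64L)
    x <- stats::rnorm(m, mx$mean, mx$sd)
    y <- px$mean + a * (x - mx$mean) + stats::rnorm(m, 0, resid_sd)
    ok <- x >= mx$range[1] & x <= mx$range[2] &
          y >= px$range[1] & y <= px$range[2]
    out <- rbind(out, cbind(x[ok], y[ok]))
    guard <- guard + 1L
    if (guard > 10000L) stop("truncation region rejects essentially all draws")
  }
  out[seq_len(n), , drop = FALSE]
}

#' Draw a surrogate training set
#'
#' Samples labeled (maxHU, ppLapl) pairs from the truncated bivariate
#' normal model in a \code{\link{feature_distribution_spec}}. Reproducible
#' by seed; the surrogate is an approximation of the unknown empirical
#' feature distribution, plausible but not identical to any annotated
#' clinical dataset.
#'
#' @param spec a \code{\link{feature_distribution_spec}}.
#' @return A \code{\link{training_set}} with provenance
#'   \code{"surrogate"}.
#' @export
generate_training_set <- function(spec = feature_distribution_spec()) {
  stopifnot(inherits(spec, "feature_distribution_spec"))
  with_seed(spec$seed, {
    ua <- sample_truncated_bvn(spec$n_ua, spec$ua$max_hu, spec$ua$pp_lapl,
                               spec$correlation)
    nu <- sample_truncated_bvn(spec$n_nonua, spec$nonua$max_hu,
                               spec$nonua$pp_lapl, spec$correlation)
    training_set(max_hu = c(ua[, 1], nu[, 1]),
                 pp_lapl = c(ua[, 2], nu[, 2]),
                 label = c(rep(LBL_UA, spec$n_ua), rep(LBL_NONUA, spec$n_nonua)),
                 provenance = "surrogate")
  })
}

# peak-point Laplacian contrast ratio of a Gaussian core of imaged width
# w (mm) sampled at 1 mm spacing: 1 minus the weighted 26-neighbour mean
# of the unit core
core_lapl_ratio <- function(w, kernel = laplacian_kernel()) {
  d2 <- rowSums(kernel$offsets^2)
  vapply(w, function(wi) 1 - sum(kernel$weights * exp(-d2 / (2 * wi^2))),
         numeric(1))
}

# invert core_lapl_ratio: imaged core width achieving a target ratio,
# clamped to the attainable range
core_width_for_ratio <- function(ratio, w_min, w_max = 4,
                                 kernel = laplacian_kernel()) {
  vapply(ratio, function(rt) {
    if (rt >= core_lapl_ratio(w_min, kernel)) return(w_min)
    if (rt <= core_lapl_ratio(w_max, kernel)) return(w_max)
    stats::uniroot(function(w) core_lapl_ratio(w, kernel) - rt,
                   c(w_min, w_max), tol = 1e-6)$root
  }, numeric(1))
}

# truncated normal draw by rejection (scalar parameters, vector n)
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 16L, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate an end-to-end stone cohort
#'
#' Generates one phantom per stone, runs segmentation and feature
#' extraction on each noisy volume, and returns the labeled per-stone
#' feature table ready for classifier evaluation. Default cohort size is
#' 37 UA and 106 non-UA stones.
#'
#' Stone parameters come from the reference feature distributions: UA
#' stones draw a flat plateau attenuation from the UA maxHU model (their
#' ppLapl arises from image noise and, for small stones, edge partial
#' volume); non-UA stones draw a target (maxHU, ppLapl) pair from the
#' truncated bivariate-normal feature model and the Gaussian core width
#' that realises that ppLapl contrast is solved for per stone. Measured
#' features carry a small positive bias relative to the targets because
#' the peak voxel is selected as the maximum of the noisy field.
#'
#' @param correlation within-class correlation of the target feature
#'   pairs (default 0.6, as in \code{\link{feature_distribution_spec}}).
#' Each stone is seeded from the semi-automatic marking step it emulates:
#' the brightest voxel inside the ground-truth mask.
#'
#' @param n_ua,n_nonua class sizes (>= 1).
#' @param seed master RNG seed; fixes the whole cohort.
#' @param kernel Laplacian kernel for feature extraction.
#' @param threshold segmentation threshold, HU.
#' @param ... further arguments passed to \code{\link{stone_phantom_spec}}
#'   (e.g. \code{noise_sd_hu}).
#' @return data.frame with columns \code{stone_id}, \code{max_hu},
#'   \code{pp_lapl}, \code{peak_i/j/k} (1-based), \code{size_mm},
#'   \code{reference}.
#' @export
simulate_cohort <- function(n_ua = 37L, n_nonua = 106L, seed = NULL,
                            kernel = laplacian_kernel(), threshold = 130,
                            correlation = 0.6, ...) {
  if (!is_scalar_number(n_ua) || !is_scalar_number(n_nonua) ||
      n_ua < 1 || n_nonua < 1) {
    stop("both class sizes must be >= 1")
  }
  n_ua <- as.integer(n_ua); n_nonua <- as.integer(n_nonua)
  n <- n_ua + n_nonua
  mom <- stone_reference_moments()
  base <- stone_phantom_spec("UA", peak_hu = 500, diameter_mm = 8, ...)
  sigma_eff <- sqrt(base$blur_sigma_mm^2 + mean(base$spacing^2) / 12)
  params <- with_seed(seed, {
    comp <- c(rep(LBL_UA, n_ua), rep(LBL_NONUA, n_nonua))
    peak <- numeric(n); size <- numeric(n); tip <- rep(1.2, n)
    ua_i <- comp == LBL_UA
    peak[ua_i] <- rtruncnorm1(n_ua, mom$ua$max_hu$mean, mom$ua$max_hu$sd,
                              mom$ua$max_hu$range[1], mom$ua$max_hu$range[2])
    nonua_pairs <- sample_truncated_bvn(n_nonua, mom$nonua$max_hu,
                                        mom$nonua$pp_lapl, correlation)
    peak[!ua_i] <- nonua_pairs[, 1]
    # imaged core width realising the drawn ppLapl target at this peak
    ratio <- nonua_pairs[, 2] / ((1 - base$edge_fraction) * nonua_pairs[, 1])
    w <- core_width_for_ratio(ratio, w_min = sigma_eff + 0.05, kernel = kernel)
    tip[!ua_i] <- sqrt(pmax(w^2 - sigma_eff^2, 1e-4))
    size[ua_i] <- rtruncnorm1(n_ua, mom$ua$size_mm$mean, mom$ua$size_mm$sd,
                              mom$ua$size_mm$range[1], mom$ua$size_mm$range[2])
    size[!ua_i] <- rtruncnorm1(n_nonua, mom$nonua$size_mm$mean, mom$nonua$size_mm$sd,
                               mom$nonua$size_mm$range[1], mom$nonua$size_mm$range[2])
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    list(comp = comp, peak = peak, size = size, tip = tip, seeds = seeds)
  })
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- stone_phantom_spec(composition = params$comp[i],
                               peak_hu = params$peak[i],
                               diameter_mm = params$size[i],
                               tip_width_mm = params$tip[i],
                               seed = params$seeds[i], ...)
    ph <- generate_phantom(spec)
    # mark the stone at its brightest ground-truth voxel, then segment
    v <- ph$volume$values
    members <- which(ph$mask$membership, arr.ind = TRUE)
    vals <- v[coords_to_linear(members, dim(v))]
    mark <- members[which.max(vals), ]
    seg <- withCallingHandlers(
      segment_stone(ph$volume, mark, threshold = threshold),
      warning = function(w) invokeRestart("muffleWarning"))
    f <- extract_features(ph$volume, seg, kernel = kernel)
    rows[[i]] <- data.frame(
      stone_id = sprintf("stone_%03d", i),
      max_hu = f$max_hu, pp_lapl = f$pp_lapl,
      peak_i = f$peak_index[1], peak_j = f$peak_index[2],
      peak_k = f$peak_index[3],
      size_mm = f$size_mm,
      reference = ph$label,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
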