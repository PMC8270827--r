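# internal helpers shared across modules

# Canonical label tokens. "mixed" is only legal as a reference label.
LBL_UA <- "UA"
LBL_NONUA <- "non-UA"
LBL_MIXED <- "mixed"

#' Normalize stone composition labels
#'
#' Accepts common spellings (\code{"UA"}, \code{"NON_UA"}, \code{"non-UA"},
#' \code{"nonua"}, \code{"MIXED"}, case-insensitive) and maps them onto the
#' canonical tokens \code{"UA"}, \code{"non-UA"} and \code{"mixed"}.
#'
#' @param x character vector of labels.
#' @param allow_mixed logical; whether \code{"mixed"} is legal in this context
#'   (reference labels yes, predictor outputs no).
#' @return character vector of canonical labels.
#' @export
normalize_label <- function(x, allow_mixed = FALSE) {
  key <- gsub("[^a-z]", "", tolower(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[key == "ua"] <- LBL_UA
  out[key == "nonua"] <- LBL_NONUA
  out[key == "mixed"] <- LBL_MIXED
  if (anyNA(out)) {
    stop("unknown stone label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "),
         " (expected UA, non-UA or mixed)")
  }
  if (!allow_mixed && any(out == LBL_MIXED)) {
    stop("label 'mixed' is only valid as a reference label in this context")
  }
  out
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# Integer-percent rounding, half away from zero, applied only at the
# reporting layer. Small epsilon guards against 0.5 sitting just below
# representable due to binary floats (e.g. 90.49999999...).
round_percent <- function(p) {
  ifelse(is.na(p), NA_real_, floor(p * 100 + 0.5 + 1e-9))
}

# The 26 neighbour offsets of the 3x3x3 stencil (centre removed),
# ordered lexicographically by (slice, row, col).
neighbor_offsets_26 <- function() {
  g <- as.matrix(expand.grid(dk = -1:1, dj = -1:1, di = -1:1))
  g <- g[, c("di", "dj", "dk"), drop = FALSE]
  g <- g[order(g[, 1], g[, 2], g[, 3]), , drop = FALSE]
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), , drop = FALSE]
  dimnames(g) <- NULL
  g
}

clamp_index <- function(i, n) pmin(pmax(i, 1L), n)

# coords: m x 3 matrix of 1-based (slice,row,col); returns linear indices
coords_to_linear <- function(coords, d) {
  (coords[, 3] - 1L) * (d[1L] * d[2L]) + (coords[, 2] - 1L) * d[1L] + coords[, 1]
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
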