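#' Cutoff configuration for the rigid-cutoff and maxHU-only classifiers
#'
#' Defaults are the published cutoffs: a stone is non-UA when its maxHU is
#' at or above 1000 HU \emph{or} its ppLapl is at or above 195 HU; the
#' single-feature variant calls a stone UA when maxHU is strictly below
#' 745 HU. The UA region of the two-feature rule is the axis-aligned
#' rectangle [0, 1000) x [0, 195) in the (maxHU, ppLapl) plane.
#'
#' @param ppLapl_cut ppLapl cutoff, HU (default 195).
#' @param maxHU_cut maxHU cutoff for the two-feature rule, HU (default 1000).
#' @param maxHU_only_cut cutoff for the maxHU-only rule, HU (default 745).
#' @return An object of class \code{cutoff_config}.
#' @export
cutoff_config <- function(ppLapl_cut = 195, maxHU_cut = 1000,
                          maxHU_only_cut = 745) {
  for (v in list(ppLapl_cut, maxHU_cut, maxHU_only_cut)) {
    if (!is_scalar_number(v) || v <= 0) stop("all cutoffs must be strictly positive")
  }
  structure(list(ppLapl_cut = as.numeric(ppLapl_cut),
                 maxHU_cut = as.numeric(maxHU_cut),
                 maxHU_only_cut = as.numeric(maxHU_only_cut)),
            class = "cutoff_config")
}

#' Rigid-cutoff (ppLapl-maxHU) classifier
#'
#' @param features a \code{stone_features}, a data.frame with columns
#'   \code{max_hu} and \code{pp_lapl}, or a named numeric vector.
#' @param cfg a \code{\link{cutoff_config}}.
#' @return Character vector of labels, \code{"UA"} or \code{"non-UA"}
#'   (one per stone). Stones exactly on a cutoff line classify non-UA.
#' @examples
#' classify_cutoff(c(max_hu = 693, pp_lapl = 98))    # "UA"
#' classify_cutoff(c(max_hu = 1398, pp_lapl = 182))  # "non-UA"
#' @export
classify_cutoff <- function(features, cfg = cutoff_config()) {
  stopifnot(inherits(cfg, "cutoff_config"))
  fr <- check_finite_features(as_feature_frame(features))
  ifelse(fr$max_hu >= cfg$maxHU_cut | fr$pp_lapl >= cfg$ppLapl_cut,
         LBL_NONUA, LBL_UA)
}

#' maxHU-only classifier
#'
#' @inheritParams classify_cutoff
#' @return Character vector of labels; UA iff maxHU is strictly below the
#'   \code{maxHU_only_cut} (745 HU default), so a stone at exactly 745 HU
#'   classifies non-UA.
#' @export
classify_maxhu <- function(features, cfg = cutoff_config()) {
  stopifnot(inherits(cfg, "cutoff_config"))
  fr <- check_finite_features(as_feature_frame(features))
  ifelse(fr$max_hu < cfg$maxHU_only_cut, LBL_UA, LBL_NONUA)
}

#' Labeled training set for the kNN classifier
#'
#' Holds labeled (maxHU, ppLapl) points standing in for an annotated
#' reference stone dataset. Both classes must be present and mixed labels
#' are not allowed.
#'
#' @param max_hu,pp_lapl numeric feature vectors, HU.
#' @param label labels, coerced to \code{"UA"}/\code{"non-UA"}.
#' @param provenance \code{"surrogate"} (simulated) or
#'   \code{"user-supplied"}.
#' @return A data.frame of class \code{training_set}.
#' @export
training_set <- function(max_hu, pp_lapl, label,
                         provenance = c("user-supplied", "surrogate")) {
  provenance <- match.arg(provenance)
  n <- length(max_hu)
  if (length(pp_lapl) != n || length(label) != n || n < 1L) {
    stop("max_hu, pp_lapl and label must have equal, positive length")
  }
  if (!all(is.finite(max_hu)) || !all(is.finite(pp_lapl))) {
    stop("training features must be finite")
  }
  label <- normalize_label(label, allow_mixed = FALSE)
  if (length(unique(label)) < 2L) {
    stop("training set must contain both UA and non-UA stones")
  }
  structure(data.frame(max_hu = as.numeric(max_hu),
                       pp_lapl = as.numeric(pp_lapl),
                       label = label, stringsAsFactors = FALSE),
            provenance = provenance,
            class = c("training_set", "data.frame"))
}

#' Read / write a training set CSV
#'
#' Columns \code{max_hu, pp_lapl, label} with labels \code{UA}/\code{non-UA}
#' (common spellings such as \code{NON_UA} accepted on read).
#'
#' @param path CSV path.
#' @param provenance provenance tag attached on read.
#' @return \code{read_training_csv}: a \code{\link{training_set}}.
#' @export
read_training_csv <- function(path, provenance = "user-supplied") {
  if (!file.exists(path)) stop("training CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("max_hu", "pp_lapl", "label")
  if (!all(need %in% names(df))) {
    stop("training CSV '", path, "' must have columns: ", paste(need, collapse = ", "))
  }
  training_set(df$max_hu, df$pp_lapl, df$label, provenance = provenance)
}

#' @rdname read_training_csv
#' @param train a \code{training_set}.
#' @export
write_training_csv <- function(train, path) {
  stopifnot(inherits(train, "training_set"))
  utils::write.csv(as.data.frame(train)[, c("max_hu", "pp_lapl", "label")],
                   path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' kNN configuration
#'
#' @param k number of neighbours; must be odd (no vote ties with two
#'   classes) and positive. Default 9.
#' @param standardize z-score both features using training-set mean and SD
#'   before computing distances. Default \code{FALSE}: both features are in
#'   HU, so raw Euclidean distance is meaningful.
#' @return An object of class \code{knn_config}.
#' @export
knn_config <- function(k = 9L, standardize = FALSE) {
  if (!is_scalar_number(k) || k < 1 || k != round(k)) stop("'k' must be a positive integer")
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("'k' must be odd so that a binary majority vote cannot tie")
  structure(list(k = k, distance = "euclidean",
                 standardize = isTRUE(standardize)),
            class = "knn_config")
}

#' k-nearest-neighbour (kNN-ppLapl-maxHU) classifier
#'
#' Majority vote among the \code{k} training stones closest in Euclidean
#' distance over the (maxHU, ppLapl) plane. Distance ties at the k-th rank
#' are broken by training-point order (stable sort), making the prediction
#' deterministic.
#'
#' @inheritParams classify_cutoff
#' @param train a \code{\link{training_set}} with at least \code{k} points.
#' @param cfg a \code{\link{knn_config}}.
#' @param vote return the UA vote fraction among the k neighbours instead
#'   of the hard label (a score in [0, 1] usable for ROC analysis).
#' @return Character label vector, or numeric vote fractions when
#'   \code{vote = TRUE}.
#' @export
classify_knn <- function(features, train, cfg = knn_config(), vote = FALSE) {
  stopifnot(inherits(cfg, "knn_config"))
  if (!inherits(train, "training_set")) stop("'train' must be a training_set")
  if (nrow(train) < cfg$k) {
    stop(sprintf("training set has %d points but k = %d", nrow(train), cfg$k))
  }
  fr <- check_finite_features(as_feature_frame(features))
  tx <- train$max_hu; ty <- train$pp_lapl
  qx <- fr$max_hu; qy <- fr$pp_lapl
  if (cfg$standardize) {
    mx <- mean(tx); sx <- stats::sd(tx)
    my <- mean(ty); sy <- stats::sd(ty)
    if (sx == 0 || sy == 0) stop("cannot standardize: zero feature variance in training set")
    tx <- (tx - mx) / sx; ty <- (ty - my) / sy
    qx <- (qx - mx) / sx; qy <- (qy - my) / sy
  }
  is_ua <- train$label == LBL_UA
  frac <- vapply(seq_along(qx), function(i) {
    d2 <- (tx - qx[i])^2 + (ty - qy[i])^2
    nn <- order(d2)[seq_len(cfg$k)]   # stable: ties keep training order
    mean(is_ua[nn])
  }, numeric(1))
  if (vote) frac else ifelse(frac > 0.5, LBL_UA, LBL_NONUA)
}

#' Evaluate a classifier over a (maxHU, ppLapl) grid
#'
#' Renders the decision surface of any of the classifiers on a rectangular
#' grid, e.g. to plot the curved kNN boundary against the rigid-cutoff
#' rectangle.
#'
#' @param classifier a function mapping a feature data.frame (columns
#'   \code{max_hu}, \code{pp_lapl}) to a label vector, e.g.
#'   \code{\link{classify_cutoff}} or a closure over
#'   \code{\link{classify_knn}}.
#' @param max_hu,pp_lapl numeric vectors of grid coordinates (HU); both
#'   must be non-empty.
#' @return A data.frame with columns \code{max_hu}, \code{pp_lapl},
#'   \code{label}, one row per grid cell (maxHU varying fastest).
#' @export
decision_map <- function(classifier, max_hu, pp_lapl) {
  if (!is.function(classifier)) stop("'classifier' must be a function")
  if (length(max_hu) == 0L || length(pp_lapl) == 0L) stop("grid must be non-empty")
  grid <- expand.grid(max_hu = as.numeric(max_hu),
                      pp_lapl = as.numeric(pp_lapl),
                      KEEP.OUT.ATTRS = FALSE)
  lab <- normalize_label(classifier(grid), allow_mixed = FALSE)
  if (length(lab) != nrow(grid)) stop("classifier returned wrong number of labels")
  grid$label <- lab
  grid
}
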