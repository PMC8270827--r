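#' Run configuration
#'
#' Bundles every tunable of the pipeline: Laplacian kernel scheme, cutoff
#' and kNN settings, segmentation defaults, confidence level and seed.
#' Serializes to JSON and round-trips identically; unknown keys in a
#' config file are rejected.
#'
#' @param kernel_scheme \code{"inverse-distance"} or \code{"uniform"}.
#' @param cutoffs a \code{\link{cutoff_config}}.
#' @param knn a \code{\link{knn_config}}.
#' @param seg_threshold segmentation threshold, HU.
#' @param seg_max_extent segmentation clip cube side, mm.
#' @param confidence CI level for reports (default 0.95).
#' @param seed RNG seed used for any simulation the run performs.
#' @param training_csv optional path to a user-supplied training CSV; when
#'   \code{NULL} a surrogate training set is drawn from the defaults.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(kernel_scheme = "inverse-distance",
                       cutoffs = cutoff_config(), knn = knn_config(),
                       seg_threshold = 130, seg_max_extent = 40,
                       confidence = 0.95, seed = 1L, training_csv = NULL) {
  kernel_scheme <- match.arg(kernel_scheme, c("inverse-distance", "uniform"))
  stopifnot(inherits(cutoffs, "cutoff_config"), inherits(knn, "knn_config"))
  if (!is_scalar_number(confidence) || confidence <= 0 || confidence >= 1) {
    stop("'confidence' must be in (0, 1)")
  }
  structure(list(
    kernel_scheme = kernel_scheme,
    cutoffs = cutoffs,
    knn = knn,
    seg_threshold = as.numeric(seg_threshold),
    seg_max_extent = as.numeric(seg_max_extent),
    confidence = as.numeric(confidence),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    training_csv = if (is.null(training_csv)) NULL else as.character(training_csv)
  ), class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' @param config a \code{\link{run_config}}.
#' @param path JSON file path.
#' @return \code{write_run_config}: \code{path} invisibly;
#'   \code{read_run_config}: a \code{run_config} identical to the one
#'   written.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- list(
    kernel_scheme = config$kernel_scheme,
    cutoffs = list(ppLapl_cut = config$cutoffs$ppLapl_cut,
                   maxHU_cut = config$cutoffs$maxHU_cut,
                   maxHU_only_cut = config$cutoffs$maxHU_only_cut),
    knn = list(k = config$knn$k, standardize = config$knn$standardize),
    seg_threshold = config$seg_threshold,
    seg_max_extent = config$seg_max_extent,
    confidence = config$confidence,
    seed = config$seed,
    training_csv = config$training_csv
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("kernel_scheme", "cutoffs", "knn", "seg_threshold",
             "seg_max_extent", "confidence", "seed", "training_csv")
  extra <- setdiff(names(x), known)
  if (length(extra) > 0) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  }
  extra_cut <- setdiff(names(x$cutoffs), c("ppLapl_cut", "maxHU_cut", "maxHU_only_cut"))
  extra_knn <- setdiff(names(x$knn), c("k", "standardize"))
  if (length(extra_cut) > 0 || length(extra_knn) > 0) {
    stop("unknown config key(s): ", paste(c(extra_cut, extra_knn), collapse = ", "))
  }
  run_config(
    kernel_scheme = x$kernel_scheme %||% "inverse-distance",
    cutoffs = do.call(cutoff_config, as.list(x$cutoffs)),
    knn = do.call(knn_config, as.list(x$knn)),
    seg_threshold = x$seg_threshold %||% 130,
    seg_max_extent = x$seg_max_extent %||% 40,
    confidence = x$confidence %||% 0.95,
    seed = x$seed,
    training_csv = x$training_csv
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of the canonical JSON serialization, for provenance logging
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Extract features for every stone in a volume
#'
#' Reads a CT volume plus either a mask NIfTI (binary = one stone, integer
#' labels = several stones) or a seeds CSV (columns \code{stone_id, i, j,
#' k}, 0-based voxel indices triggering segmentation), extracts the
#' (maxHU, ppLapl) features per stone and writes a feature CSV. Rows are
#' ordered by stone id. The configuration hash and package version are
#' logged to the console for provenance.
#'
#' @param volume_path NIfTI or raw volume path.
#' @param mask_path optional mask NIfTI path.
#' @param seeds_path optional seeds CSV path (exactly one of
#'   \code{mask_path}/\code{seeds_path} is required).
#' @param config a \code{\link{run_config}}.
#' @param out_csv optional output CSV path.
#' @return The per-stone feature data.frame (peak indices 1-based),
#'   invisibly when \code{out_csv} is given.
#' @export
run_features <- function(volume_path, mask_path = NULL, seeds_path = NULL,
                         config = run_config(), out_csv = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(mask_path) == is.null(seeds_path)) {
    stop("supply exactly one of 'mask_path' or 'seeds_path'")
  }
  volume <- read_ct_volume(volume_path)
  kernel <- laplacian_kernel(config$kernel_scheme)
  masks <- list()
  if (!is.null(mask_path)) {
    m <- read_stone_mask(mask_path, volume)
    masks <- if (inherits(m, "stone_mask")) list(`1` = m) else m
    names(masks) <- sprintf("stone_%03d", as.integer(names(masks)))
  } else {
    if (!file.exists(seeds_path)) stop("seeds CSV not found: ", seeds_path)
    seeds <- utils::read.csv(seeds_path, stringsAsFactors = FALSE)
    need <- c("stone_id", "i", "j", "k")
    if (!all(need %in% names(seeds))) {
      stop("seeds CSV '", seeds_path, "' must have columns: ",
           paste(need, collapse = ", "))
    }
    for (r in seq_len(nrow(seeds))) {
      masks[[seeds$stone_id[r]]] <- segment_stone(
        volume, c(seeds$i[r], seeds$j[r], seeds$k[r]) + 1L,
        threshold = config$seg_threshold,
        max_extent = config$seg_max_extent)
    }
  }
  masks <- masks[order(names(masks))]
  rows <- lapply(names(masks), function(id) {
    f <- extract_features(volume, masks[[id]], kernel = kernel)
    data.frame(stone_id = id, max_hu = f$max_hu, pp_lapl = f$pp_lapl,
               peak_i = f$peak_index[1], peak_j = f$peak_index[2],
               peak_k = f$peak_index[3], size_mm = f$size_mm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  message(sprintf("peakstone %s | config %s | %d stone(s) from %s",
                  as.character(utils::packageVersion("peakstone")),
                  config_hash(config), nrow(out), volume_path))
  if (!is.null(out_csv)) {
    write_features_csv(out, out_csv)
    return(invisible(out))
  }
  out
}

#' Classify stones and evaluate against reference labels
#'
#' The evaluation layer of the pipeline: joins a per-stone feature table
#' with reference labels, applies the three classifiers (rigid cutoffs,
#' maxHU-only, kNN), excludes mixed-reference stones (logging the count),
#' and reports per-method confusion matrices, sensitivity/specificity/
#' accuracy with exact CIs, pairwise McNemar tests and AUCs for the two
#' score-based methods. Machine-readable JSON output is deterministic:
#' identical inputs give byte-identical files.
#'
#' @param features_csv per-stone feature CSV (from
#'   \code{\link{run_features}} or \code{\link{simulate_cohort}}).
#' @param labels_csv CSV with columns \code{stone_id, reference}
#'   (\code{UA}/\code{non-UA}/\code{mixed}).
#' @param config a \code{\link{run_config}}; its \code{training_csv} (or,
#'   when absent, a surrogate training set drawn with the config seed) is
#'   used for the kNN method.
#' @param out_json,out_txt optional output paths for the JSON report and
#'   the human-readable table rendering.
#' @return The report as a list (also written to \code{out_json}/
#'   \code{out_txt} when given).
#' @export
run_full_report <- function(features_csv, labels_csv, config = run_config(),
                            out_json = NULL, out_txt = NULL) {
  stopifnot(inherits(config, "run_config"))
  feats <- read_features_csv(features_csv)
  if (nrow(feats) == 0L) stop("feature table '", features_csv, "' is empty")
  if (!file.exists(labels_csv)) stop("labels CSV not found: ", labels_csv)
  labs <- utils::read.csv(labels_csv, stringsAsFactors = FALSE)
  if (!all(c("stone_id", "reference") %in% names(labs))) {
    stop("labels CSV '", labels_csv, "' must have columns stone_id, reference")
  }
  only_f <- setdiff(feats$stone_id, labs$stone_id)
  only_l <- setdiff(labs$stone_id, feats$stone_id)
  if (length(only_f) || length(only_l)) {
    stop("stone id mismatch between feature and label tables; ",
         "missing labels: [", paste(only_f, collapse = ", "), "], ",
         "missing features: [", paste(only_l, collapse = ", "), "]")
  }
  df <- merge(feats, labs, by = "stone_id", sort = TRUE)
  df$reference <- normalize_label(df$reference, allow_mixed = TRUE)

  train <- if (!is.null(config$training_csv)) {
    read_training_csv(config$training_csv)
  } else {
    generate_training_set(feature_distribution_spec(seed = config$seed))
  }
  kcfg <- config$knn
  ccfg <- config$cutoffs
  pred <- list(
    knn = classify_knn(df, train, kcfg),
    cutoff = classify_cutoff(df, ccfg),
    maxhu = classify_maxhu(df, ccfg)
  )
  n_mixed <- sum(df$reference == LBL_MIXED)
  if (n_mixed > 0) {
    message(sprintf("excluded %d mixed-reference stone(s) from evaluation", n_mixed))
  }

  methods <- names(pred)
  reports <- lapply(methods, function(m) {
    cm <- cross_tabulate(pred[[m]], df$reference)
    diagnostic_metrics(cm, conf = config$confidence)
  })
  names(reports) <- methods

  keep <- df$reference != LBL_MIXED
  correct <- lapply(pred, function(p) p[keep] == df$reference[keep])
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  mcn <- lapply(pairs, function(pr) {
    b <- sum(correct[[pr[1]]] & !correct[[pr[2]]])
    c_ <- sum(!correct[[pr[1]]] & correct[[pr[2]]])
    list(methods = pr, b = b, c = c_, p_value = mcnemar_exact(b, c_))
  })

  auc <- list(
    knn = suppressWarnings(roc_auc(classify_knn(df, train, kcfg, vote = TRUE),
                                   df$reference)),
    maxhu = suppressWarnings(roc_auc(df$max_hu, df$reference,
                                     direction = "lower"))
  )

  metric_json <- function(metric) {
    list(estimate = metric$estimate, numerator = metric$x,
         denominator = metric$n,
         ci_lower = unname(metric$ci[["lower"]]),
         ci_upper = unname(metric$ci[["upper"]]),
         percent = round_percent(metric$estimate),
         percent_ci = c(round_percent(metric$ci[["lower"]]),
                        round_percent(metric$ci[["upper"]])))
  }
  report <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    n_stones = nrow(df),
    n_mixed_excluded = n_mixed,
    training_provenance = attr(train, "provenance"),
    methods = lapply(reports, function(r) list(
      confusion = list(tp = r$cm$tp, fn = r$cm$fn, fp = r$cm$fp, tn = r$cm$tn),
      sensitivity = metric_json(r$sensitivity),
      specificity = metric_json(r$specificity),
      accuracy = metric_json(r$accuracy)
    )),
    mcnemar = mcn,
    auc = auc
  )
  if (!is.null(out_json)) {
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  txt <- render_report_text(reports, mcn, auc, n_mixed)
  if (!is.null(out_txt)) writeLines(txt, out_txt)
  report
}

# plain-text tables in the cross-tab / metrics layout
render_report_text <- function(reports, mcn, auc, n_mixed) {
  pretty <- c(knn = "kNN-ppLapl-maxHU", cutoff = "ppLapl-maxHU", maxhu = "maxHU")
  out <- c("Single-energy CT classification of UA vs non-UA stones", "")
  for (m in names(reports)) {
    r <- reports[[m]]
    out <- c(out,
      sprintf("%s", pretty[[m]]),
      sprintf("            reference UA   reference non-UA"),
      sprintf("  pred UA        %4d            %4d", r$cm$tp, r$cm$fp),
      sprintf("  pred non-UA    %4d            %4d", r$cm$fn, r$cm$tn),
      sprintf("  Sensitivity: %s", format_metric(r$sensitivity)),
      sprintf("  Specificity: %s", format_metric(r$specificity)),
      sprintf("  Accuracy:    %s", format_metric(r$accuracy)),
      "")
  }
  for (p in mcn) {
    out <- c(out, sprintf("McNemar %s vs %s: b=%d c=%d p=%.4f",
                          pretty[[p$methods[1]]], pretty[[p$methods[2]]],
                          p$b, p$c, p$p_value))
  }
  out <- c(out, sprintf("AUC kNN vote fraction: %s",
                        ifelse(is.na(auc$knn), "NA", sprintf("%.3f", auc$knn))),
           sprintf("AUC maxHU (lower = UA): %s",
                   ifelse(is.na(auc$maxhu), "NA", sprintf("%.3f", auc$maxhu))))
  if (n_mixed > 0) {
    out <- c(out, sprintf("Mixed-reference stones excluded: %d", n_mixed))
  }
  out
}
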