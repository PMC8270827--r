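# Independent brute-force oracles. Deliberately written as plain loops,
# sharing no code with the implementation they check.

# 26-term scaled Laplacian with replicate padding
oracle_laplacian <- function(v, scheme = "inverse-distance") {
  d <- dim(v)
  out <- array(NA_real_, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    s <- 0; wsum <- 0
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      w <- if (scheme == "uniform") 1 else 1 / sqrt(di^2 + dj^2 + dk^2)
      ii <- min(max(i + di, 1), d[1])
      jj <- min(max(j + dj, 1), d[2])
      kk <- min(max(k + dk, 1), d[3])
      s <- s + w * v[ii, jj, kk]
      wsum <- wsum + w
    }
    out[i, j, k] <- v[i, j, k] - s / wsum
  }
  out
}

# queue-based 26-connected flood fill of voxels >= threshold, within bounds
oracle_flood_fill <- function(v, seed, threshold, lo = c(1, 1, 1), hi = dim(v)) {
  d <- dim(v)
  visited <- array(FALSE, d)
  queue <- list(seed)
  visited[seed[1], seed[2], seed[3]] <- TRUE
  while (length(queue) > 0) {
    p <- queue[[1]]; queue <- queue[-1]
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      q <- p + c(di, dj, dk)
      if (any(q < lo) || any(q > hi)) next
      if (visited[q[1], q[2], q[3]]) next
      if (v[q[1], q[2], q[3]] >= threshold) {
        visited[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
  }
  visited
}

# full-sort kNN majority vote with stable ties
oracle_knn <- function(qx, qy, tx, ty, labels, k) {
  d <- sqrt((tx - qx)^2 + (ty - qy)^2)
  nn <- sort.list(d, method = "radix")[1:k]  # radix sort is stable
  votes <- table(labels[nn])
  names(votes)[which.max(votes)]
}

# exhaustive per-slice pairwise caliper measurement
oracle_size <- function(mask_arr, spacing) {
  sr <- spacing[2]; sc <- spacing[3]
  pts <- which(mask_arr, arr.ind = TRUE)
  best <- 0
  for (a in seq_len(nrow(pts))) for (b in seq_len(nrow(pts))) {
    if (pts[a, 1] != pts[b, 1]) next
    dr <- abs(pts[a, 2] - pts[b, 2]) * sr
    dc <- abs(pts[a, 3] - pts[b, 3]) * sc
    dd <- sqrt(dr^2 + dc^2)
    ext <- if (dd > 0) dd + (sr * dr + sc * dc) / dd else max(sr, sc)
    if (ext > best) best <- unname(ext)
  }
  best
}

# four explicit counting loops for the confusion matrix (UA positive)
oracle_counts <- function(pred, ref) {
  tp <- fn <- fp <- tn <- 0
  for (i in seq_along(pred)) {
    if (ref[i] == "mixed") next
    if (pred[i] == "UA" && ref[i] == "UA") tp <- tp + 1
    if (pred[i] == "non-UA" && ref[i] == "UA") fn <- fn + 1
    if (pred[i] == "UA" && ref[i] == "non-UA") fp <- fp + 1
    if (pred[i] == "non-UA" && ref[i] == "non-UA") tn <- tn + 1
  }
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

# all-pairs Mann-Whitney AUC with half credit for ties
oracle_auc <- function(scores, is_pos) {
  ps <- scores[is_pos]; ns <- scores[!is_pos]
  tot <- 0
  for (p in ps) for (q in ns) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(ps) * length(ns))
}

# binomial pmf summation for the exact two-sided McNemar p-value
oracle_mcnemar <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  m <- min(b, c)
  tail <- 0
  for (x in 0:m) tail <- tail + choose(n, x) * 0.5^n
  min(1, 2 * tail)
}
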