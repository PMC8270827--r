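# programmatic fixtures used across test files

# uniform background with one bright voxel at the centre
spike_volume <- function(dims = c(5, 5, 5), background = 100, peak = 700) {
  v <- array(background, dims)
  ctr <- (dims + 1) %/% 2
  v[ctr[1], ctr[2], ctr[3]] <- peak
  list(volume = ct_volume(v), centre = ctr)
}

# random integer-valued volume, reproducible
random_volume <- function(dims = c(7, 7, 7), seed = 1, lo = -1000, hi = 2000) {
  set.seed(seed)
  ct_volume(array(sample(lo:hi, prod(dims), replace = TRUE), dims))
}

# counts ratios of every printed interval of the published evaluation
# tables, with the printed integer-percent 95% CI bounds
printed_intervals <- function() {
  rbind(
    data.frame(x = 37,  n = 37,  lo = 91, hi = 100),
    data.frame(x = 103, n = 106, lo = 92, hi = 99),
    data.frame(x = 140, n = 143, lo = 94, hi = 100),
    data.frame(x = 35,  n = 37,  lo = 82, hi = 99),
    data.frame(x = 104, n = 106, lo = 93, hi = 100),
    data.frame(x = 139, n = 143, lo = 93, hi = 99),
    data.frame(x = 34,  n = 37,  lo = 78, hi = 98),
    data.frame(x = 100, n = 106, lo = 88, hi = 98),
    data.frame(x = 134, n = 143, lo = 88, hi = 97),
    data.frame(x = 24,  n = 24,  lo = 86, hi = 100),
    data.frame(x = 127, n = 130, lo = 93, hi = 100),
    data.frame(x = 22,  n = 24,  lo = 73, hi = 99),
    data.frame(x = 126, n = 130, lo = 92, hi = 99),
    data.frame(x = 21,  n = 24,  lo = 68, hi = 97),
    data.frame(x = 121, n = 130, lo = 87, hi = 97),
    data.frame(x = 18,  n = 18,  lo = 82, hi = 100),
    data.frame(x = 121, n = 124, lo = 93, hi = 100),
    data.frame(x = 17,  n = 18,  lo = 73, hi = 100),
    data.frame(x = 16,  n = 18,  lo = 65, hi = 99),
    data.frame(x = 116, n = 124, lo = 88, hi = 97)
  )
}

# the three published cross-tabulations (UA positive)
printed_crosstabs <- function() {
  list(
    knn = confusion_matrix(tp = 37, fn = 0, fp = 3, tn = 103),
    cutoff = confusion_matrix(tp = 35, fn = 2, fp = 2, tn = 104),
    maxhu = confusion_matrix(tp = 34, fn = 3, fp = 6, tn = 100)
  )
}
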