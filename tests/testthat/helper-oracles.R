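# Independent brute-force oracles. These are deliberately written as naive
# per-element scans, separate from the package's vectorized/kernel code paths.

# Nearest-seed scan: for every pixel, compute all L (or usable) distances and
# take the closest, lowest index first on ties.
oracle_nearest_assignment <- function(pattern, include_blind_spot = FALSE) {
  loc <- pattern$locations
  seeds <- if (include_blind_spot) seq_len(pattern$L) else which(!loc$blind_spot)
  out <- matrix(0L, 61, 61)
  for (i in 1:61) {
    for (j in 1:61) {
      x <- j - 31
      y <- 31 - i
      d <- (loc$x[seeds] - x)^2 + (loc$y[seeds] - y)^2
      out[i, j] <- seeds[which.min(d)]
    }
  }
  out
}

# Average precision via explicit confusion matrices at every unique threshold,
# descending, accumulating precision-weighted recall increments.
oracle_ap <- function(scores, labels) {
  y <- as.integer(labels)
  ts <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  ap <- 0
  for (t in ts) {
    pred <- scores >= t
    tp <- sum(pred & y == 1)
    fp <- sum(pred & y == 0)
    recall <- tp / sum(y == 1)
    precision <- tp / (tp + fp)
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# Region averaging by explicit per-region loops.
oracle_region_average <- function(values, assignment) {
  out <- values
  for (l in unique(as.vector(assignment))) {
    members <- assignment == l
    out[members] <- sum(values[members]) / sum(members)
  }
  out
}

# Exhaustive threshold scan for the F1-style objective.
oracle_f1_cutoff <- function(scores, labels) {
  y <- as.integer(labels)
  best_t <- NA_real_
  best_obj <- -Inf
  for (t in sort(unique(scores))) {
    pred <- scores >= t
    tp <- sum(pred & y == 1)
    ppv <- if (sum(pred) > 0) tp / sum(pred) else 0
    tpr <- tp / sum(y == 1)
    obj <- if (ppv + tpr > 0) ppv * tpr / (ppv + tpr) else 0
    if (obj > best_obj) {
      best_obj <- obj
      best_t <- t
    }
  }
  list(threshold = best_t, objective = best_obj)
}
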