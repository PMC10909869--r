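# Independent brute-force oracles, deliberately written with plain loops
# and none of the package's internals, so they can disagree with the
# implementation they check.

# Two-phase label-correction rule: false-negative repair evaluated on the
# original labels, then false-positive repair evaluated on that output.
oracle_correct_labels <- function(x) {
  n <- length(x)
  has <- function(v, i, val) {
    p <- FALSE; f <- FALSE
    if (i - 1 >= 1 && v[i - 1] == val) p <- TRUE
    if (i - 2 >= 1 && v[i - 2] == val) p <- TRUE
    if (i + 1 <= n && v[i + 1] == val) f <- TRUE
    if (i + 2 <= n && v[i + 2] == val) f <- TRUE
    c(p, f)
  }
  x1 <- x
  for (i in seq_len(n)) if (x[i] == 0) {
    ok <- has(x, i, 1)
    if (ok[1] && ok[2]) x1[i] <- 1L
  }
  out <- x1
  for (i in seq_len(n)) if (x1[i] == 1) {
    ok <- has(x1, i, 0)
    if (ok[1] && ok[2]) out[i] <- 0L
  }
  as.integer(out)
}

# Exhaustive Otsu: for every candidate split of a 256-bin histogram compute
# the between-class variance directly.
oracle_otsu <- function(x, n_bins = 256) {
  lo <- min(x); hi <- max(x)
  bin <- pmin(floor((x - lo) / (hi - lo) * n_bins), n_bins - 1)
  centers <- lo + (0:(n_bins - 1) + 0.5) * (hi - lo) / n_bins
  best_k <- NA; best_v <- -Inf
  for (k in 1:(n_bins - 1)) {          # class 0 = bins 0..k-1 (0-based)
    in0 <- bin < k
    w0 <- mean(in0); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- mean(centers[bin[in0] + 1]); mu1 <- mean(centers[bin[!in0] + 1])
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_v + 1e-15) { best_v <- v; best_k <- k }
  }
  lo + best_k * (hi - lo) / n_bins
}

# Trapezoidal ROC AUC.
oracle_auc_trapezoid <- function(y, s) {
  th <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  tpr <- sapply(th, function(t) mean(s[y == 1] >= t))
  fpr <- sapply(th, function(t) mean(s[y == 0] >= t))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Per-region mean by explicit voxel loop.
oracle_region_means <- function(rel, labels) {
  ids <- sort(unique(labels[labels > 0]))
  out <- numeric(length(ids))
  for (j in seq_along(ids)) {
    tot <- 0; cnt <- 0
    for (v in which(labels == ids[j])) { tot <- tot + rel[v]; cnt <- cnt + 1 }
    out[j] <- tot / cnt
  }
  names(out) <- ids
  out
}

rel_err <- function(a, b) abs(a - b) / pmax(1e-12, abs(a) + abs(b))
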