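#' Correct isolated label flips in a longitudinal diagnosis sequence
#'
#' Two-phase correction of one subject's time-ordered diagnosis events.
#' Phase 1 (false-negative repair, simultaneous over the original labels):
#' a negative at position i becomes positive iff at least one of the
#' up-to-two preceding labels is positive AND at least one of the up-to-two
#' following labels is positive. Phase 2 (false-positive repair,
#' simultaneous over the phase-1 output): a positive flanked on both sides
#' by at least one negative becomes negative. Within each phase
#' corrections do not cascade, so the result is order-independent and
#' deterministic; repairing false negatives first means an isolated
#' negative gap inside a positive run does not cause its true-positive
#' neighbours to be erased. With no neighbour on a side a condition fails,
#' so the first and last events are never corrected.
#'
#' @param events either a binary 0/1 vector of labels in time order, or a
#'   data.frame with columns `day` and `label` for one subject, sorted by
#'   `day`.
#' @return the corrected object of the same type; the input is not mutated.
#' @export
correct_labels <- function(events) {
  if (is.data.frame(events)) {
    if (nrow(events) == 0L) return(events)
    if (is.unsorted(events$day, strictly = TRUE))
      stop_nf("events must be sorted by strictly increasing day")
    events$label <- correct_labels(as.integer(events$label))
    return(events)
  }
  x <- as.integer(events)
  if (length(x) == 0L) return(x)
  if (!all(x %in% c(0L, 1L))) stop_nf("labels must be 0 or 1")
  n <- length(x)
  window <- function(v, i) {
    prev <- v[seq.int(max(1L, i - 2L), length.out = min(i - 1L, 2L))]
    foll <- if (i < n) v[seq.int(i + 1L, min(n, i + 2L))] else integer(0)
    list(prev = prev, foll = foll)
  }
  x1 <- x
  for (i in seq_len(n)) {                       # phase 1: 0 -> 1
    w <- window(x, i)
    if (x[i] == 0L && any(w$prev == 1L) && any(w$foll == 1L)) x1[i] <- 1L
  }
  out <- x1
  for (i in seq_len(n)) {                       # phase 2: 1 -> 0
    w <- window(x1, i)
    if (x1[i] == 1L && any(w$prev == 0L) && any(w$foll == 0L)) out[i] <- 0L
  }
  out
}

#' Link a scan to its temporally closest diagnosis
#'
#' Returns the label of the diagnosis event minimising `|event day - scan
#' day|`, regardless of whether the event is before or after the scan. On an
#' exact tie the earlier event wins.
#'
#' @param scan_day integer day of the scan.
#' @param events data.frame with columns `day`, `label` (one subject's
#'   corrected events); must be non-empty.
#' @return binary label.
#' @export
assign_scan_label <- function(scan_day, events) {
  if (is.null(events) || nrow(events) == 0L) stop_nf("events must be non-empty")
  ev <- events[order(events$day), , drop = FALSE]
  as.integer(ev$label[which.min(abs(ev$day - scan_day))])
}

#' Assign labels to all scans from corrected diagnosis timelines
#'
#' Convenience wrapper: corrects each subject's event sequence with
#' [correct_labels()] and labels every scan via [assign_scan_label()].
#'
#' @param scans list of scan records.
#' @param events cohort events data.frame (`subject_id`, `day`, `label`).
#' @return scans with `label` filled in.
#' @export
label_scans <- function(scans, events) {
  by_subj <- split(events, events$subject_id)
  by_subj <- lapply(by_subj, function(e) correct_labels(e[order(e$day), ]))
  lapply(scans, function(r) {
    r$label <- assign_scan_label(r$day, by_subj[[r$subject_id]])
    r
  })
}

#' Drop repeat positives from consecutive positive visits
#'
#' Per subject and modality, among each run of consecutive positive visits
#' only the earliest positive scan is kept; negative scans are always kept.
#' A positive following a negative visit starts a new run and is retained.
#'
#' @param scans list of labelled scan records.
#' @return filtered list.
#' @export
drop_repeat_positives <- function(scans) {
  if (!length(scans)) return(scans)
  key <- vapply(scans, function(r) paste(r$subject_id, r$modality), "")
  keep <- logical(length(scans))
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[order(vapply(scans[idx], `[[`, 0, "day"))]
    prev_pos <- FALSE
    for (i in idx) {
      lab <- scans[[i]]$label
      if (is.na(lab)) stop_nf("all scans must be labelled first")
      keep[i] <- (lab == 0L) || !prev_pos
      prev_pos <- lab == 1L
    }
  }
  scans[keep]
}

#' Randomly under-sample the negative class
#'
#' @param scans list of labelled scan records.
#' @param target_count number of negatives to keep (<= current count).
#' @param seed integer seed.
#' @return list with negatives uniformly down-sampled (original order
#'   preserved); positives untouched.
#' @export
undersample_negatives <- function(scans, target_count, seed) {
  labs <- vapply(scans, `[[`, 0L, "label")
  neg <- which(labs == 0L)
  if (target_count > length(neg))
    stop_nf("target_count (%d) exceeds number of negatives (%d)",
            target_count, length(neg))
  if (target_count == length(neg)) return(scans)
  keep_neg <- seeded(seed, sort(sample(neg, target_count)))
  scans[sort(c(which(labs == 1L), keep_neg))]
}

# Internal rigid in-plane transforms: 90-degree rotation of the first two
# axes and left-right mirroring of the second axis. Both permute voxels, so
# augmentation is lossless (the sorted voxel multiset is preserved).
rotate_inplane <- function(vol, k) {
  k <- k %% 4L
  for (i in seq_len(k)) {
    nd <- length(dim(vol))
    vol <- if (nd == 2L) t(vol[nrow(vol):1, , drop = FALSE]) else
      aperm(vol[dim(vol)[1]:1, , , drop = FALSE], c(2L, 1L, 3L))
  }
  vol
}

mirror_lr <- function(vol) {
  nd <- length(dim(vol))
  if (nd == 2L) vol[, ncol(vol):1, drop = FALSE] else
    vol[, dim(vol)[2]:1, , drop = FALSE]
}

#' Augment the positive class by rotation and mirroring
#'
#' Creates new positive records by applying a randomly chosen non-identity
#' composition of axis-aligned 90-degree in-plane rotations and left-right
#' mirroring to randomly selected positive volumes until `target_count`
#' positives exist. Each augmented record carries its source scan id and the
#' transform applied. Transforms are rigid voxel permutations, so no
#' intensity is invented or lost.
#'
#' @param scans list of labelled scan records (volumes in memory).
#' @param target_count desired total number of positive records.
#' @param seed integer seed.
#' @return scans plus augmented positive records appended.
#' @export
augment_positives <- function(scans, target_count, seed) {
  labs <- vapply(scans, `[[`, 0L, "label")
  pos <- which(labs == 1L)
  if (!length(pos)) stop_nf("at least one positive record required")
  if (target_count < length(pos))
    stop_nf("target_count (%d) below current positive count (%d)",
            target_count, length(pos))
  n_new <- target_count - length(pos)
  if (n_new == 0L) return(scans)
  # 7 non-identity combinations of (rotation k, mirror)
  combos <- expand.grid(rot = 0:3, mirror = c(FALSE, TRUE))[-1, ]
  picks <- seeded(seed, data.frame(
    src = pos[sample.int(length(pos), n_new, replace = TRUE)],
    tfm = sample.int(nrow(combos), n_new, replace = TRUE)))
  for (i in seq_len(n_new)) {
    src <- scans[[picks$src[i]]]
    k <- combos$rot[picks$tfm[i]]
    m <- combos$mirror[picks$tfm[i]]
    v <- rotate_inplane(src$volume, k)
    if (m) v <- mirror_lr(v)
    rec <- src
    rec$volume <- v
    rec$scan_id <- sprintf("%s_aug%d", src$scan_id, i)
    rec$augmented <- TRUE
    rec$transform <- list(rot = k, mirror = m, source = src$scan_id)
    scans[[length(scans) + 1L]] <- rec
  }
  scans
}

#' Patient-wise train/test split
#'
#' Partitions *subjects* (never scans) so no subject contributes to both
#' sides; augmented records follow their source subject. The number of test
#' subjects is `round(test_fraction * n_subjects)`, at least 1.
#'
#' @param scans list of scan records.
#' @param test_fraction fraction of subjects assigned to the test set.
#' @param seed integer seed.
#' @return list with elements `train` and `test` (lists of records) and
#'   `test_subjects` (character vector).
#' @export
patient_wise_split <- function(scans, test_fraction, seed) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_nf("test_fraction must be in (0, 1)")
  subj <- unique(vapply(scans, `[[`, "", "subject_id"))
  if (length(subj) < 2L) stop_nf("need at least 2 subjects to split")
  n_test <- max(1L, round(test_fraction * length(subj)))
  if (n_test >= length(subj)) n_test <- length(subj) - 1L
  test_subj <- seeded(seed, sample(subj, n_test))
  is_test <- vapply(scans, function(r) r$subject_id %in% test_subj, TRUE)
  list(train = scans[!is_test], test = scans[is_test],
       test_subjects = sort(test_subj))
}

#' Subject-level stratified cross-validation folds
#'
#' Assigns subjects (a subject counts as positive if any of its scans is
#' positive) to `k` folds so that per-fold class counts differ by at most
#' one subject from a perfectly proportional allocation, and no subject
#' appears in two folds.
#'
#' @param scans list of labelled scan records.
#' @param k number of folds (>= 2; at most the per-class subject count).
#' @param seed integer seed.
#' @return data.frame `subject_id`, `fold`.
#' @export
stratified_folds <- function(scans, k, seed) {
  if (k < 2L) stop_nf("k must be >= 2")
  tab <- scan_table(scans)
  subj_lab <- tapply(tab$label, tab$subject_id, function(l) as.integer(any(l == 1L)))
  pos <- names(subj_lab)[subj_lab == 1L]
  neg <- names(subj_lab)[subj_lab == 0L]
  if (length(pos) < k || length(neg) < k)
    stop_nf("k = %d exceeds subjects of one class (%d positive, %d negative)",
            k, length(pos), length(neg))
  seeded(seed, {
    pos <- sample(pos)
    neg <- sample(neg)
  })
  asg <- rbind(
    data.frame(subject_id = pos, fold = rep_len(seq_len(k), length(pos))),
    data.frame(subject_id = neg, fold = rep_len(seq_len(k), length(neg))))
  asg[order(asg$subject_id), ]
}
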