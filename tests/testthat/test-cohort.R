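test_that("label correction reproduces the hand-traced examples", {
  expect_identical(correct_labels(c(0L, 1L, 0L, 1L, 1L)), c(0L, 1L, 1L, 1L, 1L))
  expect_identical(correct_labels(c(0L, 0L, 0L, 0L)), c(0L, 0L, 0L, 0L))
  expect_identical(correct_labels(c(1L, 0L, 1L)), c(1L, 1L, 1L))
  expect_identical(correct_labels(c(0L, 1L, 0L)), c(0L, 0L, 0L))
  expect_identical(correct_labels(integer(0)), integer(0))
  expect_identical(correct_labels(c(1L)), c(1L))
})

test_that("label correction matches the brute-force rule on all short sequences", {
  for (n in 1:6) {
    for (code in 0:(2^n - 1)) {
      x <- as.integer(intToBits(code)[1:n])
      expect_identical(correct_labels(x), oracle_correct_labels(x),
                       label = paste("sequence", paste(x, collapse = "")))
    }
  }
})

test_that("label correction on data.frames validates ordering and keeps days", {
  df <- data.frame(day = c(0, 100, 200), label = c(1, 0, 1))
  out <- correct_labels(df)
  expect_identical(out$label, c(1L, 1L, 1L))
  expect_identical(out$day, df$day)
  expect_error(correct_labels(data.frame(day = c(100, 0), label = c(0, 1))),
               "sorted")
})

test_that("scans link to the temporally closest diagnosis, earlier on ties", {
  ev <- data.frame(day = c(90, 130), label = c(0L, 1L))
  expect_identical(assign_scan_label(100, ev), 0L)
  expect_identical(assign_scan_label(130, ev), 1L)
  ev2 <- data.frame(day = c(90, 110), label = c(1L, 0L))
  expect_identical(assign_scan_label(100, ev2), 1L)   # tie -> earlier event
  expect_error(assign_scan_label(1, ev[0, ]), "non-empty")
})

make_records <- function(days, labels, subject = "S1", modality = "MRI") {
  lapply(seq_along(days), function(i) list(
    subject_id = subject, modality = modality, day = days[i],
    volume = array(runif(8), c(2, 2, 2)), label = as.integer(labels[i]),
    true_label = as.integer(labels[i]),
    scan_id = sprintf("%s_v%d_%s", subject, i, modality)))
}

test_that("only the earliest positive of a consecutive positive run is kept", {
  r <- drop_repeat_positives(make_records(c(0, 100, 200), c(1, 1, 1)))
  expect_length(r, 1L)
  expect_identical(r[[1]]$day, 0)

  r2 <- drop_repeat_positives(make_records(c(0, 100), c(1, 0)))
  expect_length(r2, 2L)

  # positive, negative, positive: both positives retained (non-consecutive)
  r3 <- drop_repeat_positives(make_records(c(0, 100, 200), c(1, 0, 1)))
  expect_identical(vapply(r3, `[[`, 0L, "label"), c(1L, 0L, 1L))

  # runs are per subject and per modality
  mixed <- c(make_records(c(0, 10), c(1, 1), "A", "MRI"),
             make_records(c(0, 10), c(1, 1), "A", "PET"))
  expect_length(drop_repeat_positives(mixed), 2L)
})

test_that("under-sampling hits the target, keeps positives, and is seeded", {
  recs <- c(make_records(seq(0, 90, 10), rep(0, 10), "N1"),
            make_records(c(0, 10), c(1, 1), "P1"))
  out <- undersample_negatives(recs, 4, seed = 8)
  labs <- vapply(out, `[[`, 0L, "label")
  expect_identical(sum(labs == 0L), 4L)
  expect_identical(sum(labs == 1L), 2L)
  expect_identical(vapply(undersample_negatives(recs, 4, seed = 8), `[[`, "", "scan_id"),
                   vapply(out, `[[`, "", "scan_id"))
  expect_identical(undersample_negatives(recs, 10, seed = 1), recs)
  expect_error(undersample_negatives(recs, 11, seed = 1), "exceeds")
})

test_that("augmentation is lossless, tagged, involutive and seeded", {
  recs <- make_records(0, 1, "P1")
  out <- augment_positives(recs, 4, seed = 5)
  expect_length(out, 4L)
  src <- recs[[1]]$volume
  for (i in 2:4) {
    expect_true(isTRUE(out[[i]]$augmented))
    expect_identical(out[[i]]$transform$source, recs[[1]]$scan_id)
    expect_equal(sort(as.vector(out[[i]]$volume)), sort(as.vector(src)))
  }
  # mirroring twice restores the original
  expect_identical(neurofuse:::mirror_lr(neurofuse:::mirror_lr(src)), src)
  # four quarter-turns restore the original
  expect_equal(neurofuse:::rotate_inplane(src, 4L), src)
  out2 <- augment_positives(recs, 4, seed = 5)
  expect_identical(lapply(out2, `[[`, "transform"), lapply(out, `[[`, "transform"))
  expect_error(augment_positives(recs, 0, seed = 1), "below")
  expect_error(augment_positives(make_records(0, 0), 2, seed = 1), "positive record")
})

test_that("patient-wise splits never leak subjects and round as stated", {
  recs <- do.call(c, lapply(1:10, function(i)
    make_records(c(0, 10), c(0, i %% 2), sprintf("S%02d", i))))
  sp <- patient_wise_split(recs, 0.2, seed = 2)
  expect_length(sp$test_subjects, 2L)
  tr <- unique(vapply(sp$train, `[[`, "", "subject_id"))
  te <- unique(vapply(sp$test, `[[`, "", "subject_id"))
  expect_length(intersect(tr, te), 0L)
  expect_setequal(c(tr, te), sprintf("S%02d", 1:10))
  expect_identical(patient_wise_split(recs, 0.2, seed = 2)$test_subjects,
                   sp$test_subjects)
  expect_error(patient_wise_split(make_records(0, 1), 0.2, seed = 1),
               "2 subjects")
})

test_that("no subject leakage across many random splits", {
  recs <- do.call(c, lapply(1:12, function(i)
    make_records(0, i %% 2, sprintf("S%02d", i))))
  for (s in 1:200) {
    sp <- patient_wise_split(recs, 0.25, seed = s)
    tr <- vapply(sp$train, `[[`, "", "subject_id")
    te <- vapply(sp$test, `[[`, "", "subject_id")
    if (length(intersect(tr, te)) > 0)
      fail(sprintf("subject leak at seed %d", s))
  }
  succeed()
})

test_that("stratified folds balance classes at subject level", {
  recs <- do.call(c, lapply(1:20, function(i)
    make_records(0, as.integer(i <= 10), sprintf("S%02d", i))))
  f <- stratified_folds(recs, 10, seed = 3)
  expect_setequal(f$subject_id, sprintf("S%02d", 1:20))
  expect_identical(anyDuplicated(f$subject_id), 0L)
  lab <- as.integer(sub("S", "", f$subject_id) <= "10")
  per_fold <- table(f$fold, lab)
  expect_true(all(per_fold == 1))   # 10 folds x (1 positive + 1 negative)

  f2 <- stratified_folds(recs, 2, seed = 3)
  tabs <- table(f2$fold)
  expect_true(all(tabs == 10))
  expect_error(stratified_folds(recs, 11, seed = 1), "exceeds")
})
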