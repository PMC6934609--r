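test_that("cross-subject splits assign whole subjects per the cohort table", {
  man <- cohort_manifest(9L, 13L, 16L)  # subjects available per class
  sp <- split_cross_subject(man, seed = 1L)  # default 5/7/7, 1/2/2, 3/4/7
  tab <- table(unique(sp[, c("subject_id", "class_label", "split")])$class_label,
               unique(sp[, c("subject_id", "class_label", "split")])$split)
  expect_identical(unname(tab["healthy", c("train", "validation", "test")]),
                   c(5L, 1L, 3L))
  expect_identical(unname(tab["cancer", c("train", "validation", "test")]),
                   c(7L, 2L, 4L))
  expect_identical(unname(tab["inflammation", c("train", "validation", "test")]),
                   c(7L, 2L, 7L))
  # all frames of a subject share its split
  expect_true(all(tapply(sp$split, sp$subject_id,
                         function(s) length(unique(s))) == 1L))
  # train/test subject sets are disjoint
  expect_length(intersect(sp$subject_id[sp$split == "train"],
                          sp$subject_id[sp$split == "test"]), 0L)
  # re-seeding rotates subjects but keeps counts
  sp2 <- split_cross_subject(man, seed = 2L)
  expect_false(identical(sp$split, sp2$split))
  expect_identical(table(sp$split), table(sp2$split))
  expect_error(split_cross_subject(cohort_manifest(3L, 13L, 16L)), "healthy")
})

test_that("cross-sample splits are stratified frame splits without leakage", {
  man <- cohort_manifest(3L, 3L, 3L, frames_per_subject = 20L)  # 60 per class
  sp <- split_cross_sample(man, 0.75, seed = 3L)
  expect_identical(sum(sp$split == "train"), 135L)
  expect_identical(sum(sp$split == "test"), 45L)
  expect_true(all(table(sp$class_label[sp$split == "test"]) == 15L))
  key <- paste(sp$subject_id, sp$frame_index)
  expect_false(anyDuplicated(key) > 0L)
  expect_error(split_cross_sample(man, 1.0), "train_fraction")
})

test_that("the leakage guard rejects corrupted split assignments", {
  man <- cohort_manifest(2L, 2L, 2L)
  sp <- split_cross_subject(man, counts = list(healthy = c(1L, 0L, 1L),
                                               cancer = c(1L, 0L, 1L),
                                               inflammation = c(1L, 0L, 1L)),
                            seed = 1L)
  bad <- sp
  bad$split[bad$subject_id == bad$subject_id[1]][1] <- "test"
  bad$split[bad$subject_id == bad$subject_id[1]][2] <- "train"
  expect_error(check_split_integrity(bad, "cross_subject"), "leakage")
  bad2 <- rbind(sp, sp[1, ])  # the same frame in two rows
  bad2$split[nrow(bad2)] <- "test"
  bad2$split[1] <- "train"
  expect_error(check_split_integrity(bad2, "cross_sample"), "leakage")
})

test_that("stratified k-fold partitions frames with balanced fold sizes", {
  man <- cohort_manifest(2L, 2L, 2L, frames_per_subject = 11L)  # 22 per class
  kf <- kfold_cross_sample(man, k = 7L, seed = 4L)
  expect_false(anyNA(kf$fold))
  expect_true(all(kf$fold %in% 1:7))
  for (cls in cem_classes()) {
    sizes <- table(kf$fold[kf$class_label == cls])
    expect_lte(diff(range(sizes)), 1L)
  }
  # leave-one-out limit: each frame its own fold within a class
  man1 <- cohort_manifest(1L, 1L, 1L, frames_per_subject = 5L)
  loo <- kfold_cross_sample(man1, k = 5L, seed = 5L)
  expect_true(all(table(loo$fold, loo$class_label) == 1L))
  expect_error(kfold_cross_sample(man1, k = 6L), "smallest class")
})

test_that("evaluation reports accuracy consistent with the confusion matrix", {
  truth <- rep(cem_classes(), times = c(5L, 3L, 2L))
  perfect <- evaluation_report(truth, truth)
  expect_equal(perfect$accuracy, 100)
  expect_true(all(perfect$confusion[upper.tri(perfect$confusion)] == 0))
  expect_true(all(perfect$confusion[lower.tri(perfect$confusion)] == 0))
  constant <- evaluation_report(rep("cancer", 10L), truth)
  expect_equal(constant$accuracy, 50)  # cancer prevalence
  # orientation: rows predicted, columns true
  r <- evaluation_report(c("cancer", "healthy"), c("healthy", "healthy"))
  expect_identical(unname(r$confusion["cancer", "healthy"]), 1L)
  expect_identical(unname(r$confusion["healthy", "cancer"]), 0L)
  expect_equal(r$accuracy, 100 * sum(diag(r$confusion)) / r$n)
  expect_identical(sum(r$confusion), r$n)
  expect_error(evaluation_report(character(0), character(0)), "empty")
})

test_that("subject majority voting uses the severity tie-break", {
  pred <- c("cancer", "cancer", "healthy")
  expect_identical(unname(subject_majority_label(pred, rep("m1", 3L))), "cancer")
  expect_identical(unname(subject_majority_label(rep("healthy", 4L),
                                                 rep("m1", 4L))), "healthy")
  tie <- c("cancer", "healthy")
  expect_identical(unname(subject_majority_label(tie, rep("m1", 2L))), "cancer")
  tie2 <- c("inflammation", "healthy")
  expect_identical(unname(subject_majority_label(tie2, rep("m1", 2L))),
                   "inflammation")
  two <- subject_majority_label(c("cancer", "healthy", "healthy"),
                                c("m1", "m2", "m2"))
  expect_identical(two[["m1"]], "cancer")
  expect_identical(two[["m2"]], "healthy")
})

test_that("repeated_runs reports mean and sample standard deviation", {
  det <- repeated_runs(function(seed) 91.2, n_runs = 5L)
  expect_equal(det$sd, 0)
  expect_equal(det$mean, 91.2)
  two <- repeated_runs(function(seed) if (seed == 1L) 90 else 94, n_runs = 2L)
  expect_equal(two$sd, abs(90 - 94) / sqrt(2))
  expect_error(repeated_runs(function(seed) 1, n_runs = 1L), "n_runs")
})
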