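#' Verify that a split assignment leaks nothing between sets
#'
#' For subject-wise (cross-subject) splits, no subject may appear in more
#' than one of train/validation/test; for frame-wise (cross-sample) splits,
#' no frame may. An error is raised on violation.
#'
#' @param manifest Annotated manifest with a `split` column (and `fold`
#'   column for k-fold assignments, where each frame must sit in exactly one
#'   fold).
#' @param mode `"cross_subject"` or `"cross_sample"`.
#' @return Invisibly `TRUE` when the split is sound.
#' @export
check_split_integrity <- function(manifest, mode = c("cross_subject", "cross_sample")) {
  mode <- match.arg(mode)
  stopifnot("split" %in% names(manifest))
  used <- manifest[manifest$split %in% c("train", "validation", "test"), ]
  if (mode == "cross_subject") {
    tab <- unique(used[, c("subject_id", "split")])
    dup <- tab$subject_id[duplicated(tab$subject_id)]
    if (length(dup))
      stop("subject leakage across splits: ", paste(unique(dup), collapse = ", "))
  } else {
    key <- paste(used$subject_id, used$frame_index)
    if (anyDuplicated(key))
      stop("frame leakage: a frame is assigned to more than one split")
  }
  invisible(TRUE)
}

#' Cross-subject split: whole subjects assigned to train/validation/test
#'
#' Subjects are assigned whole -- every frame follows its subject -- so the
#' test set contains only subjects never seen in training. Re-seeding rotates
#' which subjects land in which set while keeping the per-class counts,
#' which is how cross-validation is simulated for this strategy.
#'
#' @param manifest Data frame with `subject_id` and `class_label` columns.
#' @param counts Named list: for each class, an integer vector
#'   `c(train, validation, test)` of subject counts. The default mirrors a
#'   typical unbalanced cohort layout (healthy 5/1/3, cancer 7/2/4,
#'   inflammation 7/2/7).
#' @param seed Integer seed for the subject assignment.
#' @return The manifest with a `split` column (`"train"`, `"validation"`,
#'   `"test"`, or `"unused"` for subjects beyond the requested counts).
#' @export
split_cross_subject <- function(manifest,
                                counts = list(healthy = c(5L, 1L, 3L),
                                              cancer = c(7L, 2L, 4L),
                                              inflammation = c(7L, 2L, 7L)),
                                seed = 1L) {
  stopifnot(all(c("subject_id", "class_label") %in% names(manifest)))
  manifest$split <- "unused"
  withr::with_seed(as.integer(seed), {
    for (cls in names(counts)) {
      subj <- unique(manifest$subject_id[manifest$class_label == cls])
      need <- sum(counts[[cls]])
      if (need > length(subj))
        stop("class ", cls, " has ", length(subj), " subjects; ", need,
             " requested")
      picked <- sample(subj, need)
      assign_to <- rep(c("train", "validation", "test"), counts[[cls]])
      for (i in seq_along(picked))
        manifest$split[manifest$subject_id == picked[i]] <- assign_to[i]
    }
  })
  check_split_integrity(manifest, "cross_subject")
  manifest
}

#' Cross-sample split: stratified random frame split
#'
#' Frames are split at random within each class, so frames from one subject
#' may appear in both training and test sets -- but never the same frame.
#' Per class, `floor(n * (1 - train_fraction))` frames go to test and the
#' remainder to train, so class proportions are preserved to within one
#' frame.
#'
#' @param manifest Data frame with `class_label` (one row per frame).
#' @param train_fraction Fraction of frames per class assigned to training
#'   (default 0.75).
#' @param seed Integer seed.
#' @return The manifest with a `split` column of `"train"`/`"test"`.
#' @export
split_cross_sample <- function(manifest, train_fraction = 0.75, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  manifest$split <- "train"
  withr::with_seed(as.integer(seed), {
    for (cls in unique(manifest$class_label)) {
      idx <- which(manifest$class_label == cls)
      n_test <- floor(length(idx) * (1 - train_fraction))
      manifest$split[sample(idx, n_test)] <- "test"
    }
  })
  check_split_integrity(manifest, "cross_sample")
  manifest
}

#' Stratified k-fold assignment of frames
#'
#' Partitions the frames into `k` folds, stratified by class: every frame
#' falls in exactly one fold and fold sizes differ by at most one within
#' each class. Fold i serves as the test set of trial i; the final figure is
#' the average performance over folds.
#'
#' @param manifest Data frame with `class_label`.
#' @param k Number of folds (default 7).
#' @param seed Integer seed.
#' @return The manifest with an integer `fold` column in `1..k`.
#' @export
kfold_cross_sample <- function(manifest, k = 7L, seed = 1L) {
  k <- as.integer(k)
  stopifnot(k >= 2L)
  if (k > min(table(manifest$class_label)))
    stop("k exceeds the number of frames of the smallest class")
  manifest$fold <- NA_integer_
  withr::with_seed(as.integer(seed), {
    for (cls in unique(manifest$class_label)) {
      idx <- which(manifest$class_label == cls)
      manifest$fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  manifest
}

#' Evaluation report: accuracy and confusion matrix
#'
#' Builds the frame-level report: accuracy in percent and the 3x3 confusion
#' matrix with rows = predicted class and columns = true class, ordered
#' cancer, inflammation, healthy (the clinical-severity layout).
#'
#' @param predicted Predicted class labels.
#' @param truth True class labels.
#' @return A `cem_report`: list with `accuracy` (percent), `confusion`
#'   (predicted x true counts), and `n` (test frames).
#' @export
evaluation_report <- function(predicted, truth) {
  if (length(truth) == 0L) stop("empty test set")
  stopifnot(length(predicted) == length(truth))
  lev <- CEM_CLASS_ORDER
  confusion <- table(predicted = factor(predicted, levels = lev),
                     true = factor(truth, levels = lev))
  structure(list(accuracy = 100 * sum(diag(confusion)) / length(truth),
                 confusion = unclass(confusion), n = length(truth)),
            class = "cem_report")
}

#' Evaluate a trained model on labeled test frames
#'
#' @param model A model handle with a `predict` method (`cem_svm` on feature
#'   matrices, `cem_cnn` on frames).
#' @param x Test inputs in the model's native form.
#' @param truth True class labels of the test frames.
#' @return A `cem_report`; see [evaluation_report()].
#' @export
evaluate_model <- function(model, x, truth) {
  evaluation_report(predict(model, x), truth)
}

#' @export
print.cem_report <- function(x, ...) {
  cat(sprintf("<cem_report> accuracy %.2f%% on %d frames\n", x$accuracy, x$n))
  cat("confusion (rows = predicted, cols = true):\n")
  print(x$confusion)
  invisible(x)
}

#' Majority-vote subject labeling
#'
#' Assigns each subject the modal predicted class over its frames. Exact
#' ties are broken by clinical severity: cancer over inflammation over
#' healthy (configurable through `severity_order`).
#'
#' @param predicted Predicted class per frame.
#' @param subjects Subject identifier per frame.
#' @param severity_order Tie-break preference, most severe first.
#' @return Named character vector: one class per subject.
#' @export
subject_majority_label <- function(predicted, subjects,
                                   severity_order = CEM_CLASS_ORDER) {
  stopifnot(length(predicted) == length(subjects), length(predicted) >= 1L)
  vapply(split(as.character(predicted), subjects), function(p) {
    counts <- table(factor(p, levels = severity_order))
    names(counts)[which.max(counts)]  # first max in severity order
  }, character(1))
}

#' Repeated seeded runs of a pipeline
#'
#' Runs a pipeline function under `n_runs` consecutive seeds (fresh splits
#' and initializations wherever the pipeline is seed-dependent) and reports
#' the per-run accuracies with their mean and sample standard deviation.
#'
#' @param run_fn Function of one argument (the run's seed) returning an
#'   accuracy.
#' @param n_runs Number of runs (default 10).
#' @param base_seed Seed of the first run; run i uses `base_seed + i - 1`.
#' @return List with `per_run`, `mean` and `sd`.
#' @export
repeated_runs <- function(run_fn, n_runs = 10L, base_seed = 1L) {
  stopifnot(n_runs >= 2L, is.function(run_fn))
  accs <- vapply(seq_len(n_runs), function(i) run_fn(base_seed + i - 1L),
                 numeric(1))
  list(per_run = accs, mean = mean(accs), sd = sd(accs))
}
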