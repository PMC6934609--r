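#' First-order statistics of a frame for sample selection
#'
#' The four statistics used to measure frame similarity for redundancy-aware
#' training-set selection: standard deviation, mean, variance and skewness of
#' the raw pixel values (population moments). Variance is kept alongside the
#' standard deviation it duplicates, as this is the stated feature set; its
#' only effect on clustering is a benign doubling of that direction's weight
#' after standardization. A constant frame has undefined skewness and is
#' flagged unusable for clustering.
#'
#' @param frame A [cem_frame] or intensity matrix.
#' @return A list with `std`, `mean`, `variance`, `skewness` (the latter
#'   `NA` for a constant frame).
#' @export
selection_features <- function(frame) {
  x <- as.numeric(frame_pixels(frame))
  if (length(x) == 0L) stop("empty frame")
  mu <- mean(x)
  v <- mean((x - mu)^2)
  list(std = sqrt(v), mean = mu, variance = v,
       skewness = if (v == 0) NA_real_ else mean((x - mu)^3) / v^1.5)
}

#' @rdname selection_features
#' @param frames List of frames.
#' @return `selection_feature_table()` returns a data frame with one row per
#'   frame and columns `std`, `mean`, `variance`, `skewness`.
#' @export
selection_feature_table <- function(frames) {
  do.call(rbind, lapply(frames, function(f)
    as.data.frame(selection_features(f))))
}

# Seeded k-means with bounded retries against empty-cluster failures.
kmeans_with_retry <- function(z, k, seed, retries = 5L) {
  for (attempt in seq_len(retries)) {
    km <- withr::with_seed(seed + attempt - 1L, try(
      kmeans(z, centers = k, nstart = 10L, iter.max = 50L), silent = TRUE))
    if (!inherits(km, "try-error")) return(km)
  }
  stop("k-means failed after ", retries, " seeded restarts: ",
       attr(km, "condition")$message)
}

#' Redundancy-aware selection of training frames by clustering
#'
#' Per class ("state") independently: the four first-order statistics of each
#' usable frame are standardized (z-score per dimension), clustered with
#' k-means into `k` clusters, and one uniformly random member of each
#' non-empty cluster is selected. Because consecutive video frames are
#' near-duplicates with nearly identical statistics, clusters align with
#' distinct base scenes and the selection covers the scene diversity of the
#' stream with far fewer frames. Constant frames (undefined skewness) are
#' excluded from clustering.
#'
#' @param features Data frame from [selection_feature_table()] (or a list of
#'   frames, which is featurized first).
#' @param classes Class label of each row of `features`.
#' @param k Number of clusters per class; between 1 and the number of usable
#'   frames of every class.
#' @param seed Integer seed for both the clustering initialization and the
#'   within-cluster draw.
#' @param standardize Standardize features before clustering (default TRUE;
#'   without it the variance, on a scale of ~1e3, dominates skewness, ~1).
#' @return Sorted integer indices (rows of `features`) of the selected
#'   frames: per class, one per non-empty cluster.
#' @export
select_by_clustering <- function(features, classes, k, seed = 1L,
                                 standardize = TRUE) {
  if (is.list(features) && !is.data.frame(features))
    features <- selection_feature_table(features)
  stopifnot(nrow(features) == length(classes), k >= 1L)
  fm <- as.matrix(features[, c("std", "mean", "variance", "skewness")])
  selected <- integer(0)
  for (cls in unique(classes)) {
    idx <- which(classes == cls)
    usable <- idx[apply(is.finite(fm[idx, , drop = FALSE]), 1L, all)]
    if (k > length(usable))
      stop("k = ", k, " exceeds the ", length(usable),
           " usable frames of class ", cls)
    if (k == length(usable)) {  # singleton clusters: everything is selected
      selected <- c(selected, usable)
      next
    }
    z <- fm[usable, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(z)
      s <- apply(z, 2L, sd)
      s[s == 0] <- 1
      z <- sweep(sweep(z, 2L, mu), 2L, s, "/")
    }
    cseed <- as.integer(seed) + match(cls, CEM_CLASS_ORDER, nomatch = 4L) * 1000L
    km <- kmeans_with_retry(z, k, cseed)
    picks <- withr::with_seed(cseed + 1L, vapply(
      sort(unique(km$cluster)), function(cl) {
        members <- usable[km$cluster == cl]
        if (length(members) == 1L) members else sample(members, 1L)
      }, integer(1)))
    selected <- c(selected, picks)
  }
  sort(selected)
}

#' Learning curve over training-set size for a selection strategy
#'
#' For each budget `k` and each of `n_trials` seeded trials, selects `k`
#' training frames per class from the training pool -- by k-means clustering
#' of first-order statistics ([select_by_clustering()]) or uniformly at
#' random -- trains the supplied classifier on the selection and evaluates it
#' on the fixed test set. The test set is never clustered or selected.
#'
#' @param features Selection-feature table for the *training pool* (rows
#'   align with `classes`).
#' @param classes Class labels of the training pool.
#' @param sizes Integer vector of budgets `k` (clusters per class).
#' @param strategy `"cluster"` or `"random"`.
#' @param n_trials Trials per budget (default 3).
#' @param classifier Function taking the selected training-pool row indices
#'   and returning test accuracy in percent.
#' @param seed Base seed; trial t of budget k uses a seed derived from it.
#' @return Data frame with columns `k`, `strategy`, `mean_accuracy`,
#'   `sd_accuracy`.
#' @export
learning_curve <- function(features, classes, sizes,
                           strategy = c("cluster", "random"), n_trials = 3L,
                           classifier, seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(all(sizes >= 1L), n_trials >= 1L, is.function(classifier))
  out <- lapply(sizes, function(k) {
    accs <- vapply(seq_len(n_trials), function(t) {
      tseed <- as.integer(seed) + 7919L * t + as.integer(k)
      sel <- if (strategy == "cluster") {
        select_by_clustering(features, classes, k, seed = tseed)
      } else {
        withr::with_seed(tseed, unlist(lapply(unique(classes), function(cls) {
          idx <- which(classes == cls)
          sample(idx, min(k, length(idx)))
        })))
      }
      classifier(sort(sel))
    }, numeric(1))
    data.frame(k = k, strategy = strategy, mean_accuracy = mean(accs),
               sd_accuracy = if (n_trials > 1L) sd(accs) else NA_real_)
  })
  do.call(rbind, out)
}
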