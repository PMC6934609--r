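test_that("generate_subject echoes the configuration", {
  cfg <- synth_config(frames_per_subject = 10L, seed = 1L)
  frames <- generate_subject("healthy", 1L, cfg)
  expect_length(frames, 10L)
  expect_true(all(vapply(frames, `[[`, character(1), "class_label") == "healthy"))
  expect_identical(dim(frames[[1]]$pixels), c(290L, 292L))
  expect_identical(vapply(frames, `[[`, integer(1), "frame_index"), 1:10)
  expect_true(all(vapply(frames, function(f)
    min(f$pixels) >= 0L && max(f$pixels) <= 255L, logical(1))))
})

test_that("identical seeds give bit-identical frames", {
  cfg <- synth_config(frames_per_subject = 6L, height = 64L, width = 66L)
  a <- generate_subject("cancer", 9L, cfg)
  b <- generate_subject("cancer", 9L, cfg)
  for (i in seq_along(a)) expect_identical(a[[i]]$pixels, b[[i]]$pixels)
  # and full datasets, file-hash equal on disk
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg2 <- synth_config(n_subjects_per_class = 1L, frames_per_subject = 4L,
                       height = 48L, width = 50L, seed = 5L)
  generate_dataset(cfg2, d1)
  generate_dataset(cfg2, d2)
  f1 <- list.files(d1, pattern = "\\.png$", full.names = TRUE)
  f2 <- list.files(d2, pattern = "\\.png$", full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("artifact frames sit in the stated intensity regimes", {
  sat <- generate_artifact_frame("saturated", 1L)
  expect_gte(mean(sat$pixels >= 250L), 0.95)
  expect_lt(histogram_skewness(sat), -5)
  expect_true(sat$is_artifact)
  und <- generate_artifact_frame("underexposed", 1L)
  expect_gte(mean(und$pixels <= 5L), 0.95)
  expect_gt(histogram_skewness(und), 0)
  # new seed: different pixels, same skewness sign
  sat2 <- generate_artifact_frame("saturated", 2L)
  expect_false(identical(sat$pixels, sat2$pixels))
  expect_lt(histogram_skewness(sat2), -5)
})

test_that("dataset manifests follow the configured arithmetic", {
  fs <- small_frame_set()  # 2 subjects/class, 10 frames, no artifacts
  expect_identical(nrow(fs$manifest), 60L)
  expect_identical(length(unique(fs$manifest$subject_id)), 6L)
  expect_false(any(fs$manifest$is_artifact))
  counts <- table(fs$manifest$class_label)
  expect_true(all(counts == 20L))
  # unbalanced cohort mirroring a 3/4/7 testing cohort
  cfg <- synth_config(n_subjects_per_class = c(healthy = 3L, cancer = 4L,
                                               inflammation = 7L),
                      frames_per_subject = 2L, height = 48L, width = 50L)
  fs2 <- generate_frame_set(cfg)
  expect_identical(length(unique(fs2$manifest$subject_id)), 14L)
  # artifacts are additional interleaved rows flagged in the manifest
  cfg3 <- synth_config(n_subjects_per_class = 1L, frames_per_subject = 10L,
                       height = 48L, width = 50L, artifact_fraction = 0.2)
  fs3 <- generate_frame_set(cfg3)
  expect_identical(sum(fs3$manifest$is_artifact), 3L * 2L)
  expect_true(all(is.na(fs3$manifest$scene_id[fs3$manifest$is_artifact])))
})

test_that("frames within a redundancy group are near-duplicates", {
  cfg <- synth_config(frames_per_subject = 20L, redundancy_group_size = 5L,
                      height = 96L, width = 96L)
  frames <- generate_subject("inflammation", 3L, cfg)
  scene <- vapply(frames, function(f) attr(f, "scene_id"), numeric(1))
  px <- lapply(frames, function(f) as.numeric(f$pixels))
  pairs_mad <- function(i, j) mean(abs(px[[i]] - px[[j]]))
  within <- c(); between <- c()
  for (i in 1:19) for (j in (i + 1):20) {
    if (scene[i] == scene[j]) within <- c(within, pairs_mad(i, j))
    else between <- c(between, pairs_mad(i, j))
  }
  expect_lt(mean(within), mean(between))
})

test_that("texture classes differ more between than within in LBP space", {
  cfg <- synth_config(frames_per_subject = 25L, height = 128L, width = 128L,
                      redundancy_group_size = 5L)
  lbp_hist <- function(f) tabulate(lbp_map(f$pixels) + 1L, nbins = 256L)
  hh <- vapply(c(10L, 20L), function(s)
    vapply(generate_subject("healthy", s, cfg), lbp_hist, numeric(256)),
    matrix(0, 256, 25))
  cc <- vapply(c(10L, 20L), function(s)
    vapply(generate_subject("cancer", s, cfg), lbp_hist, numeric(256)),
    matrix(0, 256, 25))
  hh <- matrix(hh, nrow = 256); cc <- matrix(cc, nrow = 256)
  l1 <- function(a, b) mean(abs(a - b))
  within <- mean(c(
    vapply(2:50, function(i) l1(hh[, 1], hh[, i]), numeric(1)),
    vapply(2:50, function(i) l1(cc[, 1], cc[, i]), numeric(1))))
  between <- mean(vapply(1:50, function(i) l1(hh[, i], cc[, i]), numeric(1)))
  expect_gt(between, within)
})

test_that("generate_dataset writes PNGs that round-trip exactly", {
  out <- withr::local_tempdir()
  cfg <- synth_config(n_subjects_per_class = 1L, frames_per_subject = 2L,
                      height = 48L, width = 50L, artifact_fraction = 0)
  man <- generate_dataset(cfg, out)
  expect_identical(nrow(man), 6L)
  csv <- read.csv(file.path(out, "manifest.csv"), stringsAsFactors = FALSE)
  expect_identical(names(csv), c("path", "subject_id", "class_label",
                                 "frame_index", "is_artifact"))
  fs <- generate_frame_set(cfg)
  rt <- read_frame_png(man$path[1])
  expect_identical(rt, fs$frames[[1]]$pixels)
})
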