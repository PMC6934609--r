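# Shared fixtures and independent oracles. Everything is generated in code;
# expensive objects are cached for the session.

fixture_env <- new.env(parent = emptyenv())

# Small frame set: 2 subjects/class, 10 frames each, 64 x 66 px.
small_frame_set <- function() {
  if (is.null(fixture_env$fs)) {
    fixture_env$fs <- generate_frame_set(synth_config(
      n_subjects_per_class = 2L, frames_per_subject = 10L,
      height = 64L, width = 66L, artifact_fraction = 0,
      redundancy_group_size = 5L, seed = 42L))
  }
  fixture_env$fs
}

rand_frame <- function(h, w, seed) {
  withr::with_seed(seed, matrix(sample(0L:255L, h * w, replace = TRUE), h, w))
}

# Naive double-loop LBP oracle built on the scalar lbp_code().
lbp_map_oracle <- function(px) {
  h <- nrow(px); w <- ncol(px)
  out <- matrix(NA_integer_, h - 2L, w - 2L)
  dr <- c(-1L, -1L, -1L, 0L, 1L, 1L, 1L, 0L)
  dc <- c(-1L, 0L, 1L, 1L, 1L, 0L, -1L, -1L)
  for (r in 2:(h - 1L)) {
    for (c in 2:(w - 1L)) {
      nb <- vapply(1:8, function(n) px[r + dr[n], c + dc[n]], integer(1))
      out[r - 1L, c - 1L] <- lbp_code(px[r, c], nb)
    }
  }
  out
}

# Population-moment skewness, written independently of the package.
skewness_oracle <- function(x) {
  x <- as.numeric(x)
  mu <- sum(x) / length(x)
  m2 <- sum((x - mu)^2) / length(x)
  m3 <- sum((x - mu)^3) / length(x)
  m3 / m2^(3 / 2)
}

# A random strictly increasing intensity lookup table over 0..255.
random_monotone_lut <- function(seed) {
  withr::with_seed(seed, cumsum(c(0L, sample(1L:3L, 255L, replace = TRUE))))
}

# Synthetic cohort manifest (no pixel data) for split tests.
cohort_manifest <- function(n_healthy, n_cancer, n_inflammation,
                            frames_per_subject = 2L) {
  mk <- function(cls, n) {
    do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(subject_id = sprintf("%s_%02d", cls, i), class_label = cls,
                 frame_index = seq_len(frames_per_subject),
                 stringsAsFactors = FALSE)))
  }
  rbind(mk("healthy", n_healthy), mk("cancer", n_cancer),
        mk("inflammation", n_inflammation))
}
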