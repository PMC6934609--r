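#' Configuration of the synthetic endomicroscopy simulator
#'
#' The simulator emulates the statistical structure of confocal laser
#' endomicroscopy frame streams of the colonic mucosa: three texture classes
#' built from a lattice of crypt lumens, systematic per-subject appearance
#' variation, strong temporal redundancy between consecutive frames, and
#' saturated/underexposed artifact frames. It is procedural (not a
#' photorealistic renderer): only the class-distinct micro-texture, subject
#' effects and redundancy matter for benchmarking the pipeline.
#'
#' @param n_subjects_per_class Subjects simulated per tissue class; either a
#'   single count or a named vector over `healthy`, `inflammation`, `cancer`
#'   for unbalanced cohorts.
#' @param frames_per_subject Informative frames per subject sequence.
#' @param height,width Frame size in pixels; the default 290 rows x 292
#'   columns matches the nominal acquisition matrix (row/column assignment is
#'   a convention of this package).
#' @param artifact_fraction Artifact frames interleaved into each subject's
#'   sequence, as a fraction of `frames_per_subject` (so
#'   `round(artifact_fraction * frames_per_subject)` extra frames). In
#'   `[0, 1)`.
#' @param redundancy_group_size Consecutive near-duplicate frames rendered
#'   from each base scene (video-rate redundancy).
#' @param jitter_px Maximum translation, in pixels, between frames of the
#'   same redundancy group.
#' @param noise_sd Standard deviation of the per-frame additive Gaussian
#'   intensity noise.
#' @param seed Integer master seed; identical configuration and seed give
#'   bit-identical output.
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects_per_class = 9L, frames_per_subject = 75L,
                         height = 290L, width = 292L, artifact_fraction = 0.05,
                         redundancy_group_size = 5L, jitter_px = 3L,
                         noise_sd = 8, seed = 1L) {
  nspc <- n_subjects_per_class
  if (length(nspc) == 1L && is.null(names(nspc)))
    nspc <- setNames(rep(as.integer(nspc), 3L),
                     c("healthy", "inflammation", "cancer"))
  if (!all(sort(names(nspc)) == sort(c("healthy", "inflammation", "cancer"))))
    stop("`n_subjects_per_class` must be a count or named over the 3 classes")
  stopifnot(all(nspc >= 1L), frames_per_subject >= 1L,
            height >= 16L, width >= 16L,
            artifact_fraction >= 0, artifact_fraction < 1,
            redundancy_group_size >= 1L, jitter_px >= 0L, noise_sd >= 0)
  structure(list(n_subjects_per_class = nspc,
                 frames_per_subject = as.integer(frames_per_subject),
                 height = as.integer(height), width = as.integer(width),
                 artifact_fraction = artifact_fraction,
                 redundancy_group_size = as.integer(redundancy_group_size),
                 jitter_px = as.integer(jitter_px), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Class-specific texture parameters. Healthy mucosa: a quasi-regular lattice
# of small round crypt lumens (dark) with bright rims; lumen spacing ~12 px
# so an 8x8 patch roughly covers one crypt. Inflammation: the same lattice
# with enlarged, irregular lumens and a raised background level. Cancer
# (dysplasia): disordered, elongated/fused structures with a broken lattice.
class_texture_params <- function(class_label) {
  switch(class_label,
    healthy = list(spacing = 12, pos_sd = 0.06, drop = 0.02, bg = 112),
    inflammation = list(spacing = 13, pos_sd = 0.12, drop = 0.05, bg = 142),
    cancer = list(spacing = 12, pos_sd = 0.45, drop = 0.25, bg = 108),
    stop("unknown class label: ", class_label))
}

draw_lumen_shapes <- function(class_label, n) {
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  switch(class_label,
    healthy = {
      r <- clamp(rnorm(n, 3.2, 0.25), 2.5, 4)
      list(a = r, b = r, phi = numeric(n))
    },
    inflammation = {
      r <- clamp(rnorm(n, 5.6, 1.1), 3.8, 8.5)
      ecc <- runif(n, 0, 0.3)
      list(a = r * (1 + ecc), b = r * (1 - 0.5 * ecc), phi = runif(n, 0, pi))
    },
    cancer = list(a = clamp(rnorm(n, 7.5, 1.6), 4, 11),
                  b = clamp(rnorm(n, 2.3, 0.5), 1.4, 3.5),
                  phi = runif(n, 0, pi)))
}

# Render one base scene as a float matrix (intensity units, pre-noise).
# `subj` carries the per-subject effects: brightness offset, lattice-spacing
# multiplier and lattice rotation.
render_scene <- function(class_label, subj, hc, wc) {
  p <- class_texture_params(class_label)
  s <- p$spacing * subj$spacing_mult
  # Hexagonal lattice covering the rotated canvas.
  rad <- sqrt((hc / 2)^2 + (wc / 2)^2) + 2 * s
  ii <- seq(-ceiling(rad / (0.866 * s)), ceiling(rad / (0.866 * s)))
  jj <- seq(-ceiling(rad / s), ceiling(rad / s))
  gy <- rep(ii * 0.866 * s, each = length(jj))
  gx <- rep(jj * s, length(ii)) + rep((ii %% 2) * s / 2, each = length(jj))
  th <- subj$rotation
  cy <- hc / 2 + gy * cos(th) - gx * sin(th)
  cx <- wc / 2 + gy * sin(th) + gx * cos(th)
  keep <- cy > -2 * s & cy < hc + 2 * s & cx > -2 * s & cx < wc + 2 * s
  keep <- keep & (runif(length(cy)) > p$drop)
  cy <- cy[keep] + rnorm(sum(keep), 0, p$pos_sd * s)
  cx <- cx[keep] + rnorm(sum(keep), 0, p$pos_sd * s)
  sh <- draw_lumen_shapes(class_label, length(cy))

  d <- matrix(99, hc, wc)  # normalized distance to the nearest lumen
  for (i in seq_along(cy)) {
    rb <- ceiling(1.7 * max(sh$a[i], sh$b[i])) + 1L
    r0 <- max(1L, floor(cy[i]) - rb); r1 <- min(hc, ceiling(cy[i]) + rb)
    c0 <- max(1L, floor(cx[i]) - rb); c1 <- min(wc, ceiling(cx[i]) + rb)
    if (r0 > r1 || c0 > c1) next
    du <- (r0:r1) - cy[i]; dv <- (c0:c1) - cx[i]
    u <- matrix(du, length(du), length(dv))
    v <- matrix(dv, length(du), length(dv), byrow = TRUE)
    co <- cos(sh$phi[i]); si <- sin(sh$phi[i])
    di <- sqrt(((u * co + v * si) / sh$a[i])^2 +
               ((-u * si + v * co) / sh$b[i])^2)
    d[r0:r1, c0:c1] <- pmin(d[r0:r1, c0:c1], di)
  }
  # Radial intensity profile: dark lumen, bright rim, background.
  prof <- stats::approx(x = c(0, 0.85, 1.05, 1.35, 1.6, 99),
                        y = c(48, 48, 200, 200, p$bg, p$bg),
                        xout = as.vector(d), rule = 2)$y
  scene <- matrix(prof, hc, wc)
  # Smooth illumination gradient across the field of view.
  gslope <- runif(2, -0.03, 0.03)
  scene <- scene + outer((seq_len(hc) - hc / 2) * gslope[1],
                         (seq_len(wc) - wc / 2) * gslope[2], `+`) * 30
  # Slow acquisition drift: contrast-agent concentration and probe coupling
  # change over the inspection, so distinct scenes of one subject differ
  # systematically in brightness and contrast (this is what makes first-order
  # statistics informative about scene identity). The drift is truncated so
  # that informative frames stay within the 8-bit gamut: clipping would
  # flatten texture and contaminate the class signal.
  drift <- max(-16, min(16, rnorm(1, 0, 8)))
  (scene - p$bg) * runif(1, 0.88, 1.12) + p$bg + drift
}

clamp_to_uint8 <- function(x) {
  m <- matrix(as.integer(pmin(pmax(round(x), 0), 255)), nrow(x), ncol(x))
  m
}

#' Generate one subject's informative frame sequence
#'
#' Renders `frames_per_subject` frames for one subject: base scenes are drawn
#' per redundancy group; frames within a group are the same scene translated
#' by at most `jitter_px` pixels with fresh additive noise, so consecutive
#' frames are near-duplicates. Subject-level effects (brightness offset,
#' lattice-spacing multiplier, lattice rotation) are drawn once from
#' `subject_seed`, so subjects differ systematically -- which is what makes
#' cross-subject generalization harder than cross-sample.
#'
#' @param class_label One of `"healthy"`, `"inflammation"`, `"cancer"`.
#' @param subject_seed Integer seed identifying the subject.
#' @param cfg A [synth_config()].
#' @param subject_id Identifier stored in the frames (defaults to a name
#'   derived from the seed).
#' @return List of [cem_frame] objects; each carries its base-scene index as
#'   attribute `"scene_id"`.
#' @export
generate_subject <- function(class_label, subject_seed, cfg = synth_config(),
                             subject_id = paste0("subj", subject_seed)) {
  if (!class_label %in% CEM_CLASS_ORDER)
    stop("`class_label` must be one of: ", paste(CEM_CLASS_ORDER, collapse = ", "))
  m <- cfg$jitter_px + 2L
  hc <- cfg$height + 2L * m
  wc <- cfg$width + 2L * m
  withr::with_seed(as.integer(subject_seed), {
    subj <- list(brightness = runif(1, -20, 20),
                 spacing_mult = runif(1, 0.85, 1.2),
                 rotation = runif(1, 0, 2 * pi))
    n_groups <- ceiling(cfg$frames_per_subject / cfg$redundancy_group_size)
    frames <- vector("list", cfg$frames_per_subject)
    fi <- 0L
    for (g in seq_len(n_groups)) {
      scene <- render_scene(class_label, subj, hc, wc)
      size <- min(cfg$redundancy_group_size, cfg$frames_per_subject - fi)
      for (t in seq_len(size)) {
        if (t == 1L || cfg$jitter_px == 0L) {
          dy <- 0L; dx <- 0L
        } else {
          dy <- sample(-cfg$jitter_px:cfg$jitter_px, 1L)
          dx <- sample(-cfg$jitter_px:cfg$jitter_px, 1L)
        }
        win <- scene[(m + 1L + dy):(m + cfg$height + dy),
                     (m + 1L + dx):(m + cfg$width + dx)]
        img <- win + subj$brightness +
          rnorm(length(win), 0, cfg$noise_sd)
        fi <- fi + 1L
        fr <- cem_frame(clamp_to_uint8(matrix(img, cfg$height, cfg$width)),
                        subject_id = subject_id, class_label = class_label,
                        frame_index = fi, is_artifact = FALSE)
        attr(fr, "scene_id") <- g
        frames[[fi]] <- fr
      }
    }
    frames
  })
}

#' Generate a saturated or underexposed artifact frame
#'
#' Saturated frames emulate sensor saturation from an excess of fluorescence:
#' at least 95% of pixels at intensity >= 250 with a small low-intensity
#' remainder, giving a strongly left-skewed gray-level histogram (skewness
#' well below -5). Underexposed frames are the mirror regime -- nearly all
#' pixels near 0 with a small bright remainder -- and have strongly
#' *positive* skewness.
#'
#' @param kind `"saturated"` or `"underexposed"`.
#' @param seed Integer seed (placement of the remainder blob varies with it;
#'   the intensity regime does not).
#' @param cfg A [synth_config()] supplying the frame geometry.
#' @param class_label,subject_id Metadata recorded in the frame (artifacts
#'   inherit the sequence they interrupt).
#' @return A [cem_frame] with `is_artifact = TRUE`.
#' @export
generate_artifact_frame <- function(kind = c("saturated", "underexposed"),
                                    seed = 1L, cfg = synth_config(),
                                    class_label = "healthy",
                                    subject_id = "artifact") {
  kind <- match.arg(kind)
  h <- cfg$height; w <- cfg$width
  withr::with_seed(as.integer(seed), {
    if (kind == "saturated") {
      base <- 255 - abs(rnorm(h * w, 0, 1.2))
      blob_val <- function(n) runif(n, 0, 30)
      # the unsaturated remainder covers ~1-2% of the frame
      rad <- sqrt(runif(1, 0.008, 0.018) * h * w / pi)
    } else {
      base <- abs(rnorm(h * w, 0, 1.5))
      blob_val <- function(n) runif(n, 120, 200)
      rad <- sqrt(runif(1, 0.006, 0.015) * h * w / pi)
    }
    img <- matrix(base, h, w)
    cy <- runif(1, rad, h - rad); cx <- runif(1, rad, w - rad)
    mask <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`) < rad^2
    img[mask] <- blob_val(sum(mask))
    fr <- cem_frame(clamp_to_uint8(img), subject_id = subject_id,
                    class_label = class_label, frame_index = 1L,
                    is_artifact = TRUE)
    fr
  })
}

#' Generate a full synthetic dataset in memory
#'
#' Simulates all subjects of all classes under `cfg`, interleaving
#' `round(artifact_fraction * frames_per_subject)` artifact frames into each
#' subject's sequence at random positions. Identical `cfg` (including its
#' seed) reproduces the dataset bit-identically.
#'
#' @param cfg A [synth_config()].
#' @return A list with `frames` (list of [cem_frame]) and `manifest`, a data
#'   frame with one row per frame: `subject_id`, `class_label`,
#'   `frame_index`, `is_artifact`, and `scene_id` (the ground-truth base
#'   scene for informative frames, `NA` for artifacts).
#' @export
generate_frame_set <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  gen_classes <- c("healthy", "inflammation", "cancer")
  n_art <- as.integer(round(cfg$artifact_fraction * cfg$frames_per_subject))
  withr::with_seed(cfg$seed, {
    all_frames <- list()
    rows <- list()
    for (cls in gen_classes) {
      for (k in seq_len(cfg$n_subjects_per_class[[cls]])) {
        sid <- sprintf("%s_%02d", cls, k)
        sseed <- sample.int(.Machine$integer.max - 1L, 1L)
        frames <- generate_subject(cls, sseed, cfg, subject_id = sid)
        scene_ids <- vapply(frames, function(f) attr(f, "scene_id"), numeric(1))
        if (n_art > 0L) {
          kinds <- sample(c("saturated", "underexposed"), n_art, replace = TRUE)
          aseeds <- sample.int(.Machine$integer.max - 1L, n_art)
          arts <- lapply(seq_len(n_art), function(i)
            generate_artifact_frame(kinds[i], aseeds[i], cfg,
                                    class_label = cls, subject_id = sid))
          n_tot <- cfg$frames_per_subject + n_art
          art_pos <- sort(sample.int(n_tot, n_art))
          combined <- vector("list", n_tot)
          combined[art_pos] <- arts
          combined[setdiff(seq_len(n_tot), art_pos)] <- frames
          sc <- rep(NA_real_, n_tot)
          sc[setdiff(seq_len(n_tot), art_pos)] <- scene_ids
          frames <- combined
          scene_ids <- sc
        }
        for (i in seq_along(frames)) frames[[i]]$frame_index <- i
        all_frames <- c(all_frames, frames)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, class_label = cls,
          frame_index = seq_along(frames),
          is_artifact = vapply(frames, `[[`, logical(1), "is_artifact"),
          scene_id = as.integer(scene_ids),
          stringsAsFactors = FALSE)
      }
    }
    list(frames = all_frames, manifest = do.call(rbind, rows))
  })
}

#' Write a synthetic dataset to disk
#'
#' Calls [generate_frame_set()] and writes each frame as an 8-bit grayscale
#' PNG plus a `manifest.csv` with header
#' `path,subject_id,class_label,frame_index,is_artifact`.
#'
#' @param cfg A [synth_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame (with the additional
#'   `scene_id` ground-truth column, which is not part of the CSV).
#' @export
generate_dataset <- function(cfg = synth_config(), out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  fs <- generate_frame_set(cfg)
  man <- fs$manifest
  man$path <- file.path(out_dir, sprintf("%s_f%04d.png", man$subject_id,
                                         man$frame_index))
  for (i in seq_along(fs$frames))
    write_frame_png(fs$frames[[i]]$pixels, man$path[i])
  csv <- man[, c("path", "subject_id", "class_label", "frame_index",
                 "is_artifact")]
  write.csv(csv, file.path(out_dir, "manifest.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(man)
}
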