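# Seeded generator of lesion-like images and PAD-UFES-20-schema metadata.
# Every output is a pure function of (config, seed): images show a darker,
# irregular, internally textured blob on a lighter skin-toned background with
# an illumination gradient, sensor noise and optional dark hair strokes (so
# the Black-Hat branch has structure to respond to); metadata rows follow the
# 26-column schema with class-conditional distributions and ~35% missingness
# on the lifestyle/demographic columns that real tables leave incomplete.

# Per-class image and clinical parameters at full signal strength. Contrasts
# and geometry differ by class so the planted image signal is linearly
# recoverable; clinical effects mirror the field's risk factors (malignant
# classes older, fairer-skinned, more often with a skin-cancer history).
SYNTH_CLASS_PARAMS <- list(
  contrast  = c(ACK = 62, BCC = 75, MEL = 95, NEV = 55, SCC = 68, SEK = 85),
  radius    = list(ACK = c(17, 21), BCC = c(21, 25), MEL = c(25, 30),
                   NEV = c(14, 18), SCC = c(19, 23), SEK = c(23, 27)),
  irregular = c(ACK = 0.10, BCC = 0.12, MEL = 0.25, NEV = 0.04, SCC = 0.18, SEK = 0.08),
  # chromatic signature of the pigment: per-channel multipliers on the
  # contrast (erythematous ACK/SCC lose less red, pearly BCC least of all,
  # MEL darkens all channels, NEV/SEK brown)
  tint      = list(ACK = c(0.90, 1.00, 1.05), BCC = c(0.60, 1.00, 1.25),
                   MEL = c(1.05, 1.00, 0.95), NEV = c(0.95, 1.10, 1.00),
                   SCC = c(0.75, 1.00, 1.15), SEK = c(1.00, 1.05, 0.90)),
  age_mu    = c(ACK = 68, BCC = 62, MEL = 54, NEV = 32, SCC = 72, SEK = 60),
  fitz_mu   = c(ACK = 2.0, BCC = 2.2, MEL = 1.4, NEV = 4.2, SCC = 1.6, SEK = 3.2),
  diam_mu   = c(ACK = 8, BCC = 12, MEL = 17, NEV = 5, SCC = 10, SEK = 14),
  p_history = c(ACK = 0.60, BCC = 0.65, MEL = 0.50, NEV = 0.10, SCC = 0.70, SEK = 0.30),
  p_itch    = c(ACK = 0.70, BCC = 0.35, MEL = 0.25, NEV = 0.08, SCC = 0.45, SEK = 0.60),
  p_grew    = c(ACK = 0.40, BCC = 0.65, MEL = 0.92, NEV = 0.05, SCC = 0.80, SEK = 0.30),
  p_hurt    = c(ACK = 0.25, BCC = 0.30, MEL = 0.20, NEV = 0.03, SCC = 0.70, SEK = 0.08),
  p_changed = c(ACK = 0.30, BCC = 0.50, MEL = 0.85, NEV = 0.05, SCC = 0.60, SEK = 0.20),
  p_bled    = c(ACK = 0.15, BCC = 0.60, MEL = 0.45, NEV = 0.03, SCC = 0.60, SEK = 0.08),
  p_elev    = c(ACK = 0.25, BCC = 0.60, MEL = 0.50, NEV = 0.75, SCC = 0.50, SEK = 0.85)
)

# Columns carrying ~35% missingness in the real table (the lifestyle,
# demographic and diameter attributes).
SYNTH_MISSING_COLS <- c("smoke", "drink", "background_father", "background_mother",
                        "age", "pesticide", "gender", "skin_cancer_history",
                        "cancer_history", "has_piped_water", "has_sewage_system",
                        "region", "diameter_1", "diameter_2")

SYNTH_REGIONS <- c("FACE", "FOREARM", "CHEST", "NECK", "BACK", "ARM", "HAND",
                   "EAR", "NOSE", "THIGH", "SCALP", "LIP", "FOOT", "ABDOMEN", "LEG")
SYNTH_BACKGROUNDS <- c("POMERANIA", "GERMANY", "BRAZIL", "ITALY", "NETHERLANDS",
                       "PORTUGAL", "SPAIN")

#' Synthetic-dataset configuration
#'
#' The defaults define the study conditions every test runs under: a class mix
#' qualitatively mirroring the real imbalance (ACK and BCC dominant, MEL
#' rare), 224-pixel images, moderate illumination gradient and sensor noise,
#' reticular dark texture inside the lesion (so adaptive thresholding
#' segments the interior), occasional hairs, and ~35% missingness on the
#' incomplete metadata columns.
#'
#' @param n_samples Number of paired samples.
#' @param class_mix Named length-6 proportions summing to 1.
#' @param image_side Image side in pixels.
#' @param signal Effect-size scale in `[0, 1]`: 1 = the full class-conditional
#'   separation above (the "strong signal" condition), 0 = identical
#'   distributions for all classes.
#' @param hair_range Integer range (min, max) of hair strokes per image.
#' @param hair_darkness Intensity drop along a hair stroke.
#' @param illumination Peak-to-centre amplitude of the linear illumination
#'   gradient.
#' @param noise_sigma Gaussian sensor-noise standard deviation.
#' @param gap_frac Fraction of lesion interior left as lighter texture gaps.
#' @param missing_rate Per-column missingness on [SYNTH_MISSING_COLS] columns.
#' @param seed Master seed; all randomness derives from it.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_samples = 600L,
                         class_mix = c(ACK = 0.32, BCC = 0.35, MEL = 0.04,
                                       NEV = 0.11, SCC = 0.08, SEK = 0.10),
                         image_side = 224L, signal = 1,
                         hair_range = c(0L, 2L), hair_darkness = 70,
                         illumination = 18, noise_sigma = 4,
                         gap_frac = 0.15, missing_rate = 0.35, seed = 1L) {
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0, 1]")
  if (signal < 0 || signal > 1) stop("signal must be in [0, 1]")
  structure(list(n_samples = as.integer(n_samples), class_mix = class_mix,
                 image_side = as.integer(image_side), signal = signal,
                 hair_range = as.integer(hair_range),
                 hair_darkness = hair_darkness, illumination = illumination,
                 noise_sigma = noise_sigma, gap_frac = gap_frac,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "synth_config")
}

# Interpolate a per-class parameter toward its across-class mean at low signal.
signal_mix <- function(value, s) mean(value) + s * (value - mean(value))

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

# Smooth random field on an n x n grid (blurred white noise, zero mean, unit sd).
smooth_field <- function(n, scale) {
  f <- gaussian_blur(matrix(stats::rnorm(n * n), n, n), scale)
  (f - mean(f)) / stats::sd(f)
}

#' Generate one synthetic lesion image
#'
#' Draws a skin-toned background with a linear illumination gradient, one
#' darker elliptical blob with a class-dependent contrast, size and boundary
#' irregularity, reticular lighter gaps inside the blob (pigment-network-like
#' texture), optional dark hair strokes, and Gaussian sensor noise. Byte-level
#' deterministic for a fixed `(cfg, cls, seed)`.
#'
#' @param cfg A [synth_config()].
#' @param cls Class code 0..5.
#' @param seed Per-image seed.
#' @return List with `image` (a [lesion_image()]), `lesion_mask` and
#'   `hair_mask` (logical matrices; the lesion mask is the blob interior
#'   eroded clear of the softened boundary band).
#' @export
generate_lesion_image <- function(cfg, cls, seed) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$image_side
  cname <- CLASS_NAMES[cls + 1L]
  s <- cfg$signal
  contrast <- signal_mix(SYNTH_CLASS_PARAMS$contrast, s)[cname]
  irr <- signal_mix(SYNTH_CLASS_PARAMS$irregular, s)[cname]
  rad_lo <- signal_mix(vapply(SYNTH_CLASS_PARAMS$radius, `[`, 1, 1), s)[cname]
  rad_hi <- signal_mix(vapply(SYNTH_CLASS_PARAMS$radius, `[`, 1, 2), s)[cname]
  tint_m <- do.call(rbind, SYNTH_CLASS_PARAMS$tint)
  tint <- drop(colMeans(tint_m) + s * (tint_m[cname, ] - colMeans(tint_m)))

  with_local_seed(seed, {
    # background skin tone, varied across captures
    r0 <- stats::runif(1, 175, 215)
    g0 <- r0 - stats::runif(1, 25, 45)
    b0 <- g0 - stats::runif(1, 25, 45)
    theta <- stats::runif(1, 0, 2 * pi)
    yy <- matrix(seq_len(n) - (n + 1) / 2, n, n)
    xx <- t(yy)
    illum <- cfg$illumination * (cos(theta) * xx + sin(theta) * yy) / (n / 2)

    # irregular blob boundary: radius modulated by low-order harmonics
    cy <- n / 2 + stats::runif(1, -n / 12, n / 12)
    cx <- n / 2 + stats::runif(1, -n / 12, n / 12)
    r0_les <- stats::runif(1, rad_lo, rad_hi)
    ph <- stats::runif(3, 0, 2 * pi)
    amp <- irr * c(1, 0.6, 0.4) / sum(c(1, 0.6, 0.4))
    ang <- atan2(yy - (cy - (n + 1) / 2), xx - (cx - (n + 1) / 2))
    rad_b <- r0_les * (1 + 3 * (amp[1] * sin(2 * ang + ph[1]) +
                                amp[2] * sin(3 * ang + ph[2]) +
                                amp[3] * sin(5 * ang + ph[3])))
    dist <- sqrt((xx - (cx - (n + 1) / 2))^2 + (yy - (cy - (n + 1) / 2))^2)
    inside <- dist < rad_b

    # mild reticular texture: slightly lighter gaps inside the blob
    field <- smooth_field(n, 3)
    gaps <- field > stats::quantile(field, 1 - cfg$gap_frac)
    darken <- matrix(0, n, n)
    darken[inside] <- contrast
    darken[inside & gaps] <- 0.75 * contrast
    darken <- gaussian_blur(darken, 1.5)   # soft lesion edge

    # hair strokes: dark thin segments across the frame
    hair <- matrix(FALSE, n, n)
    n_hair <- if (cfg$hair_range[2] > cfg$hair_range[1]) {
      sample(cfg$hair_range[1]:cfg$hair_range[2], 1)
    } else cfg$hair_range[1]
    if (n_hair > 0) {
      for (h in seq_len(n_hair)) {
        p0 <- stats::runif(2, 0.1 * n, 0.9 * n)
        a <- stats::runif(1, 0, pi)
        len <- stats::runif(1, 0.4 * n, 0.8 * n)
        p1 <- p0 + len * c(cos(a), sin(a))
        thick <- stats::runif(1, 1.2, 2.2)
        # distance from every pixel to the segment p0-p1
        vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
        tt <- ((xx + (n + 1) / 2 - p0[1]) * vx + (yy + (n + 1) / 2 - p0[2]) * vy) /
          (vx^2 + vy^2)
        tt <- pmin(pmax(tt, 0), 1)
        dseg <- sqrt((xx + (n + 1) / 2 - (p0[1] + tt * vx))^2 +
                     (yy + (n + 1) / 2 - (p0[2] + tt * vy))^2)
        hair <- hair | (dseg < thick)
      }
    }
    hair_drop <- ifelse(hair, cfg$hair_darkness, 0)

    img <- array(0, dim = c(n, n, 3L))
    base <- c(r0, g0, b0)
    for (ch in 1:3) {
      plane <- base[ch] + illum - tint[ch] * darken - hair_drop +
        stats::rnorm(n * n, sd = cfg$noise_sigma)
      img[, , ch] <- pmin(pmax(round(plane), 0), 255)
    }
    # interior mask eroded clear of the softened boundary band
    core <- morph_erode(ifelse(inside, 1, 0),
                        structuring_element("ellipse", 5)) > 0.5
    list(image = lesion_image(img), lesion_mask = core, hair_mask = hair)
  })
}

sample_bool <- function(n, p) stats::rbinom(n, 1, p) == 1

#' Generate synthetic clinical records
#'
#' Produces `length(cls)` rows of the 26-column metadata schema with
#' class-conditional distributions (age, Fitzpatrick type, diameters, symptom
#' and history booleans) scaled by the config's `signal`, then masks the
#' incomplete columns at the configured missingness rate. `diagnostic` and the
#' identifiers are never masked.
#'
#' @param cfg A [synth_config()].
#' @param cls Vector of class codes 0..5 (one row each).
#' @param seed Seed for the whole batch.
#' @return Data frame with the schema columns of [metadata_columns()].
#' @export
generate_clinical_records <- function(cfg, cls, seed) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- length(cls)
  cname <- CLASS_NAMES[cls + 1L]
  s <- cfg$signal
  P <- SYNTH_CLASS_PARAMS
  with_local_seed(seed, {
    age <- round(stats::rnorm(n, signal_mix(P$age_mu, s)[cname], 9))
    age <- pmin(pmax(age, 6), 94)
    fitz_mu <- signal_mix(P$fitz_mu, s)[cname]
    fitz <- vapply(fitz_mu, function(m) {
      sample(1:6, 1, prob = exp(-abs(1:6 - m)))
    }, 1L)
    d1 <- round(exp(stats::rnorm(n, log(signal_mix(P$diam_mu, s)[cname]), 0.25)), 1)
    d2 <- round(d1 * stats::runif(n, 0.7, 1.0), 1)
    pid <- sprintf("PAT_%04d", sample.int(9999, n, replace = TRUE))
    lid <- sample.int(999, n, replace = TRUE)
    df <- data.frame(
      patient_id = pid, lesion_id = lid,
      img_id = sprintf("%s_%d_%03d", pid, lid, seq_len(n)),
      smoke = sample_bool(n, 0.2), drink = sample_bool(n, 0.35),
      background_father = sample(SYNTH_BACKGROUNDS, n, replace = TRUE),
      background_mother = sample(SYNTH_BACKGROUNDS, n, replace = TRUE),
      age = age, pesticide = sample_bool(n, 0.3),
      gender = sample(c("MALE", "FEMALE"), n, replace = TRUE),
      skin_cancer_history = sample_bool(n, signal_mix(P$p_history, s)[cname]),
      cancer_history = sample_bool(n, 0.4 * signal_mix(P$p_history, s)[cname] + 0.15),
      has_piped_water = sample_bool(n, 0.85),
      has_sewage_system = sample_bool(n, 0.8),
      fitzpatrick = fitz,
      region = sample(SYNTH_REGIONS, n, replace = TRUE),
      diameter_1 = d1, diameter_2 = d2,
      diagnostic = cname,
      itch = sample_bool(n, signal_mix(P$p_itch, s)[cname]),
      grew = sample_bool(n, signal_mix(P$p_grew, s)[cname]),
      hurt = sample_bool(n, signal_mix(P$p_hurt, s)[cname]),
      changed = sample_bool(n, signal_mix(P$p_changed, s)[cname]),
      bled = sample_bool(n, signal_mix(P$p_bled, s)[cname]),
      elevation = sample_bool(n, signal_mix(P$p_elev, s)[cname]),
      biopsied = sample_bool(n, ifelse(cname %in% c("BCC", "MEL", "SCC"), 0.9, 0.3)),
      stringsAsFactors = FALSE
    )
    if (cfg$missing_rate > 0) {
      for (col in SYNTH_MISSING_COLS) {
        mask <- stats::runif(n) < cfg$missing_rate
        df[[col]][mask] <- NA
      }
    }
    df
  })
}

#' @rdname generate_clinical_records
#' @details `generate_clinical_record()` is the single-row convenience form.
#' @export
generate_clinical_record <- function(cfg, cls, seed) {
  generate_clinical_records(cfg, cls[1], seed)
}

#' Generate a paired synthetic dataset
#'
#' Draws class labels matching `class_mix` (largest-remainder rounding of the
#' proportions), one image and one metadata row per sample, with per-sample
#' seeds derived from the master seed. With `dir` set, writes
#' `images/<img_id>.png`, `metadata.csv` (empty cells for missing values) and
#' `labels.csv`; otherwise keeps images in memory.
#'
#' @param cfg A [synth_config()].
#' @param dir Optional output directory.
#' @return List with `images` (list of [lesion_image()] or file paths),
#'   `metadata` (data frame), `labels` (codes 0..5) and `img_id`.
#' @export
generate_dataset <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_samples
  exact <- cfg$class_mix * n
  counts <- floor(exact)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(exact - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
  }
  labels <- rep(0:5, times = counts)
  sample_seeds <- with_local_seed(cfg$seed, sample.int(2^31 - 2, n + 1))
  labels <- with_local_seed(sample_seeds[n + 1], sample(labels))
  metadata <- generate_clinical_records(cfg, labels, cfg$seed)
  images <- vector("list", n)
  for (i in seq_len(n)) {
    images[[i]] <- generate_lesion_image(cfg, labels[i], sample_seeds[i])$image
    attr(images[[i]], "img_id") <- metadata$img_id[i]
  }
  if (!is.null(dir)) {
    dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
    paths <- character(n)
    for (i in seq_len(n)) {
      paths[i] <- file.path(dir, "images", paste0(metadata$img_id[i], ".png"))
      write_image_png(images[[i]], paths[i])
    }
    utils::write.csv(metadata, file.path(dir, "metadata.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(data.frame(img_id = metadata$img_id, label = labels),
                     file.path(dir, "labels.csv"), row.names = FALSE)
    images <- paths
  }
  list(images = images, metadata = metadata, labels = labels,
       img_id = metadata$img_id)
}
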