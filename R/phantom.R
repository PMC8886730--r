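# Synthetic radiograph phantoms: two elliptical lung fields on a brighter
# mediastinum/body background, optional class-discriminative opacity blobs
# inside the lungs, paired binary lung masks, and a set of seeded
# distortion modes emulating the visual anomalies seen in public CXR
# collections (cropping/padding, intensity inversion, burned-in text,
# letterboxing).

#' Phantom generator specification
#'
#' Describes the geometry and intensity statistics of the synthetic
#' lung-field phantoms used throughout the package for testing and
#' desk-scale experiments.
#'
#' Pixel noise is uniform with the requested standard deviation. Bounded
#' support makes negative phantoms separable from positives by
#' construction: no lung-interior pixel of a lesion-free phantom can
#' exceed the background mean by more than `sqrt(3)` standard deviations,
#' comfortably below the smallest admissible lesion contrast
#' (`> 3 * background_noise_sd`).
#'
#' @param image_size Square image side in pixels.
#' @param lung_ellipses List of two ellipses, each `list(center = c(x, y),
#'   semi = c(a, b))` in fractions of the image side.
#' @param background_noise_sd Standard deviation of the additive pixel
#'   noise, in intensity units on the \[0, 1\] scale.
#' @param lesion_count_range Integer interval for the number of opacities
#'   in a positive phantom.
#' @param lesion_radius_range Pixel interval for the opacity radius.
#' @param lesion_contrast Peak intensity offset of an opacity; must exceed
#'   `3 * background_noise_sd`.
#' @param distractor_count_range Integer interval for the number of
#'   off-lung distractor artifacts (bright blobs emulating wires, text
#'   burn-ins and other acquisition anomalies). Drawn identically for
#'   both classes, so they carry no class information and the
#'   discriminative signal is confined to the lung fields.
#' @param lung_intensity,body_intensity Base intensities of the lung
#'   interiors and the surrounding body.
#' @param rng_seed Base seed mixed into every per-sample seed.
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(image_size = 64)
#' s <- generate_sample(spec, seed = 1, label = 1)
#' range(s$image)
phantom_spec <- function(image_size = 128L,
                         lung_ellipses = list(
                           list(center = c(0.33, 0.55), semi = c(0.15, 0.26)),
                           list(center = c(0.67, 0.55), semi = c(0.15, 0.26))),
                         background_noise_sd = 0.02,
                         lesion_count_range = c(2L, 4L),
                         lesion_radius_range = NULL,
                         lesion_contrast = 0.4,
                         distractor_count_range = c(1L, 3L),
                         lung_intensity = 0.25,
                         body_intensity = 0.55,
                         rng_seed = 0L) {
  if (is.null(lesion_radius_range)) {
    lesion_radius_range <- c(max(2L, round(image_size / 16)),
                             max(3L, round(image_size / 8)))
  }
  spec <- structure(list(
    image_size = as.integer(image_size),
    lung_ellipses = lung_ellipses,
    background_noise_sd = background_noise_sd,
    lesion_count_range = as.integer(lesion_count_range),
    lesion_radius_range = lesion_radius_range,
    lesion_contrast = lesion_contrast,
    distractor_count_range = as.integer(distractor_count_range),
    lung_intensity = lung_intensity,
    body_intensity = body_intensity,
    rng_seed = as.integer(rng_seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  for (e in spec$lung_ellipses) {
    lo <- e$center - e$semi
    hi <- e$center + e$semi
    if (any(lo < 0) || any(hi > 1)) {
      stop("phantom_spec: lung ellipse (center ", paste(e$center, collapse = ","),
           ") extends outside the image frame", call. = FALSE)
    }
  }
  if (spec$lesion_contrast <= 3 * spec$background_noise_sd) {
    stop("phantom_spec: lesion_contrast must exceed 3 * background_noise_sd",
         call. = FALSE)
  }
  min_semi_px <- min(vapply(spec$lung_ellipses,
                            function(e) min(e$semi), numeric(1))) * spec$image_size
  if (max(spec$lesion_radius_range) > min_semi_px) {
    stop("phantom_spec: maximum lesion radius (", max(spec$lesion_radius_range),
         " px) exceeds the smallest lung semi-axis (", round(min_semi_px, 1),
         " px)", call. = FALSE)
  }
  invisible(spec)
}

# 32-bit FNV-1a hash of a string; returned as an 8-hex-digit string.
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(enc2utf8(s))) {
    lo <- bitwXor(as.integer(h %% 65536), bitwAnd(as.integer(b), 255L))
    hi <- h %/% 65536
    # 32-bit modular multiply by the FNV prime, split to stay exact in doubles
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

spec_hash <- function(spec) {
  fnv1a(paste(unlist(spec), collapse = "|"))
}

# Evaluate both lung ellipses on the pixel grid -> logical mask matrix.
lung_mask_matrix <- function(spec) {
  n <- spec$image_size
  xs <- (seq_len(n) - 0.5) / n
  mask <- matrix(FALSE, n, n)
  for (e in spec$lung_ellipses) {
    dx <- outer(rep(1, n), (xs - e$center[1]) / e$semi[1])   # columns = x
    dy <- outer((xs - e$center[2]) / e$semi[2], rep(1, n))   # rows = y
    mask <- mask | (dx^2 + dy^2 <= 1)
  }
  mask
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate one synthetic lung phantom
#'
#' A deterministic function of `(spec, seed)`: the image, mask and label
#' are byte-identical across calls with the same arguments. Positive
#' phantoms (`label = 1`) carry 1 or more additive isotropic Gaussian
#' opacity blobs whose centers lie inside the lung mask; negative
#' phantoms carry none.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed for this sample.
#' @param label Optional class label in `{0, 1}`; `NULL` draws it from
#'   the seeded generator with probability 1/2.
#' @return A `phantom_sample`: list with `image` (h, w, 1) array in
#'   \[0, 1\], `lung_mask` binary matrix, `label`, `lesions`, and
#'   `provenance` (seed + spec hash).
#' @export
generate_sample <- function(spec, seed, label = NULL) {
  validate_phantom_spec(spec)
  n <- spec$image_size
  mix <- (spec$rng_seed * 7919 + as.integer(seed) * 104729) %% 2147483647
  with_local_seed(mix, {
    if (is.null(label)) label <- as.integer(stats::runif(1) < 0.5)
    mask <- lung_mask_matrix(spec)
    base <- matrix(spec$body_intensity, n, n)
    base[mask] <- spec$lung_intensity
    amp <- spec$background_noise_sd * sqrt(3)
    img <- base + matrix(stats::runif(n * n, -amp, amp), n, n)
    xs <- (seq_len(n) - 0.5) / n
    # additive isotropic Gaussian bump, hard-truncated at its radius so
    # off-lung artifacts contribute exactly zero inside the lung fields
    add_bump <- function(img, cx, cy, r, amp) {
      dx2 <- outer(rep(1, n), ((xs - cx) * n)^2)
      dy2 <- outer(((xs - cy) * n)^2, rep(1, n))
      d2 <- dx2 + dy2
      img + amp * exp(-d2 / (2 * (r / 3)^2)) * (d2 <= r^2)
    }
    lesions <- list()
    if (label == 1L) {
      k <- sample(seq(spec$lesion_count_range[1], spec$lesion_count_range[2]), 1)
      for (i in seq_len(k)) {
        r <- stats::runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
        e <- spec$lung_ellipses[[sample(length(spec$lung_ellipses), 1)]]
        # sample the center inside a shrunken ellipse so it stays in the lung
        shrink <- max(0.1, 1 - r / (min(e$semi) * n))
        th <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1))
        cx <- e$center[1] + cos(th) * rad * e$semi[1] * shrink
        cy <- e$center[2] + sin(th) * rad * e$semi[2] * shrink
        img <- add_bump(img, cx, cy, r, spec$lesion_contrast)
        lesions[[i]] <- list(center = c(cx, cy), radius = r)
      }
    }
    # class-independent off-lung distractors (both labels): their truncated
    # discs are rejected from a dilated lung ellipse, so the lung interior
    # is untouched and the class signal stays lung-confined
    kd <- sample(seq(spec$distractor_count_range[1],
                     spec$distractor_count_range[2]), 1)
    for (i in seq_len(kd)) {
      r <- stats::runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
      rf <- r / n
      for (try in 1:100) {
        cx <- stats::runif(1, rf, 1 - rf)
        cy <- stats::runif(1, rf, 1 - rf)
        clear <- all(vapply(spec$lung_ellipses, function(e) {
          ((cx - e$center[1]) / (e$semi[1] + rf))^2 +
            ((cy - e$center[2]) / (e$semi[2] + rf))^2 > 1
        }, logical(1)))
        if (clear) {
          img <- add_bump(img, cx, cy, r, spec$lesion_contrast)
          break
        }
      }
    }
    img <- pmin(pmax(img, 0), 1)
    structure(list(
      image = array(img, dim = c(n, n, 1L)),
      lung_mask = mask * 1L,
      label = as.integer(label),
      lesions = lesions,
      provenance = list(seed = as.integer(seed), spec_hash = spec_hash(spec))
    ), class = "phantom_sample")
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` phantom images and their lung masks as 8-bit grayscale PNGs
#' plus a CSV manifest with columns `path,mask_path,label,split`. Splits
#' are assigned 70/15/15 (train/val/test) by a deterministic hash of the
#' sample index and seed, so the split is reproducible without a stored
#' split file.
#'
#' @param n Number of samples (>= 2).
#' @param pos_fraction Fraction of positive (lesion-bearing) samples.
#' @param spec A [phantom_spec()].
#' @param seed Integer seed.
#' @param out_dir Output directory (created if missing).
#' @return The manifest as a data frame (invisibly also written to
#'   `file.path(out_dir, "manifest.csv")`), with attribute `dir`.
#' @export
generate_dataset <- function(n, pos_fraction, spec, seed, out_dir) {
  if (n < 2) stop("generate_dataset: n must be >= 2", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("generate_dataset: cannot create output directory ", out_dir, call. = FALSE)
  }
  n_pos <- round(n * pos_fraction)
  pos_idx <- with_local_seed(seed, sample(n, n_pos))
  labels <- integer(n)
  labels[pos_idx] <- 1L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- generate_sample(spec, seed = seed * 131071 %% 2147483647 + i,
                         label = labels[i])
    img_name <- sprintf("img_%04d.png", i)
    mask_name <- sprintf("mask_%04d.png", i)
    png::writePNG(round(s$image[, , 1] * 255) / 255,
                  file.path(out_dir, img_name))
    png::writePNG(s$lung_mask * 1.0, file.path(out_dir, mask_name))
    u <- strtoi(substr(fnv1a(paste0("split:", i, ":", seed)), 1, 7), 16L) / 16^7
    split <- if (u < 0.70) "train" else if (u < 0.85) "val" else "test"
    rows[[i]] <- data.frame(path = img_name, mask_path = mask_name,
                            label = labels[i], split = split,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  attr(manifest, "dir") <- out_dir
  manifest
}

#' Distort a phantom image
#'
#' Seed-deterministic distortion modes emulating acquisition anomalies in
#' public chest-radiograph collections: random crop re-padded with zeros,
#' intensity inversion, burned-in text-like blocks, and letterboxing.
#' Output dimensions always equal the input's and values stay in \[0, 1\].
#'
#' @param image Matrix or (h, w, 1) array in \[0, 1\].
#' @param kind One of `"crop_pad"`, `"invert"`, `"burned_text"`,
#'   `"letterbox"`.
#' @param seed Integer seed for the stochastic modes.
#' @return Distorted image with the same dimensions and class of layout.
#' @export
apply_distortion <- function(image, kind, seed = 0L) {
  kinds <- c("crop_pad", "invert", "burned_text", "letterbox")
  if (!kind %in% kinds) {
    stop("apply_distortion: unknown kind '", kind, "'; expected one of ",
         paste(kinds, collapse = ", "), call. = FALSE)
  }
  was_array <- length(dim(image)) == 3L
  img <- if (was_array) image[, , 1] else image
  h <- nrow(img); w <- ncol(img)
  out <- with_local_seed(as.integer(seed) + 17L, {
    switch(kind,
      invert = 1 - img,
      letterbox = {
        band <- max(1L, round(0.15 * h))
        r <- img
        r[seq_len(band), ] <- 0
        r[seq(h - band + 1L, h), ] <- 0
        r
      },
      crop_pad = {
        s <- stats::runif(1, 0.6, 0.9)
        ch <- max(2L, round(h * s)); cw <- max(2L, round(w * s))
        oy <- sample.int(h - ch + 1L, 1); ox <- sample.int(w - cw + 1L, 1)
        crop <- img[seq(oy, oy + ch - 1L), seq(ox, ox + cw - 1L)]
        py <- sample.int(h - ch + 1L, 1); px <- sample.int(w - cw + 1L, 1)
        r <- matrix(0, h, w)
        r[seq(py, py + ch - 1L), seq(px, px + cw - 1L)] <- crop
        r
      },
      burned_text = {
        r <- img
        gh <- max(2L, round(h / 24))          # glyph height
        gw <- max(1L, round(w / 40))          # glyph width
        y0 <- sample.int(max(1L, h - gh), 1)
        x0 <- sample.int(max(1L, w %/% 2), 1)
        for (g in seq_len(5L)) {              # a short burned-in string
          x <- x0 + (g - 1L) * (gw + max(1L, gw %/% 2))
          if (x + gw > w) break
          r[seq(y0, y0 + gh - 1L), seq(x, x + gw - 1L)] <- 1
        }
        r
      })
  })
  out <- pmin(pmax(out, 0), 1)
  if (was_array) array(out, dim = dim(image)) else out
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat("phantom_sample:", dim(x$image)[1], "x", dim(x$image)[2],
      "| label", x$label, "|", length(x$lesions), "lesion(s)",
      "| seed", x$provenance$seed, "\n")
  invisible(x)
}
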