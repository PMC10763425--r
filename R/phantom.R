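#' @title Synthetic chest-radiograph phantoms
#' @description
#' The phantom generator emits labeled, imbalanced, chest-radiograph-like
#' grayscale images so the whole classification pipeline (network, losses,
#' training, metrics) can be exercised without clinical data. A "normal"
#' sample is a lung-field phantom: a bright thorax ellipse on a dark
#' background, two darker elliptical lung fields, and periodic rib bands.
#' A "pneumonia" sample is the same phantom with additive bright structures
#' confined to the lung fields, mimicking the radiographic signs of
#' pneumonia: hazy infiltrates, small round nodules, lobar consolidation,
#' a diffuse lung-density lift, and pleural-line thickening.
#' @name phantom
NULL

pn_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pneumonet_error")))
}

# Run `expr` under a fixed RNG seed without clobbering the caller's RNG
# stream. `seed = NULL` draws from the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Lesion parameters for pneumonia-positive phantoms
#'
#' @param n_infiltrates number of hazy Gaussian infiltrate blobs.
#' @param n_nodules number of small bright discs.
#' @param consolidation_prob probability in `[0,1]` that one lobar region is
#'   uniformly brightened.
#' @param density_shift global lung-density lift in `[0,1]` (scaled to a
#'   maximum intensity lift of 0.12).
#' @param pleural_band_prob probability in `[0,1]` of a bright band along the
#'   lung boundary.
#' @return a `lesion_params` list.
#' @export
lesion_params <- function(n_infiltrates = 2L, n_nodules = 3L,
                          consolidation_prob = 0.3, density_shift = 0.3,
                          pleural_band_prob = 0.3) {
  lp <- list(n_infiltrates = as.integer(n_infiltrates),
             n_nodules = as.integer(n_nodules),
             consolidation_prob = consolidation_prob,
             density_shift = density_shift,
             pleural_band_prob = pleural_band_prob)
  if (lp$n_infiltrates < 0 || lp$n_nodules < 0)
    pn_stop("lesion counts must be non-negative", "pneumonet_spec_error")
  for (f in c("consolidation_prob", "density_shift", "pleural_band_prob"))
    if (lp[[f]] < 0 || lp[[f]] > 1)
      pn_stop(sprintf("lesion_params$%s must lie in [0,1]", f),
              "pneumonet_spec_error")
  class(lp) <- "lesion_params"
  lp
}

#' Specification of a synthetic radiograph dataset
#'
#' Defaults are the desk-scale preset: 64 px images, 270 pneumonia /
#' 100 normal samples (class ratio 2.70, matching the imbalance of the
#' pediatric chest X-ray collection the pipeline is designed around:
#' 4,273 pneumonia / 1,583 normal, ratio 2.70), Gaussian pixel noise with
#' sd 0.05.
#'
#' @param image_size pixels per side, at least 16.
#' @param channels 1 (grayscale) or 3 (grayscale replicated to RGB planes).
#' @param n_pneumonia,n_normal non-negative per-class sample counts.
#' @param lesion_params a [lesion_params()] record.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param seed integer RNG seed; identical spec + seed reproduces the
#'   dataset bit for bit.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(image_size = 64L, channels = 1L,
                         n_pneumonia = 270L, n_normal = 100L,
                         lesion_params = pneumonet::lesion_params(),
                         noise_sd = 0.05, seed = 1L) {
  spec <- list(image_size = as.integer(image_size),
               channels = as.integer(channels),
               n_pneumonia = as.integer(n_pneumonia),
               n_normal = as.integer(n_normal),
               lesion_params = lesion_params,
               noise_sd = noise_sd, seed = as.integer(seed))
  if (spec$image_size < 16L)
    pn_stop("image_size must be at least 16", "pneumonet_spec_error")
  if (!spec$channels %in% c(1L, 3L))
    pn_stop("channels must be 1 or 3", "pneumonet_spec_error")
  if (spec$n_pneumonia < 0L || spec$n_normal < 0L)
    pn_stop("class counts must be non-negative", "pneumonet_spec_error")
  if (spec$noise_sd < 0)
    pn_stop("noise_sd must be non-negative", "pneumonet_spec_error")
  class(spec) <- "phantom_spec"
  spec
}

#' The paper-scale dataset specification
#'
#' Full collection counts of the pediatric chest X-ray cohort the pipeline
#' targets: 4,273 pneumonia and 1,583 normal images (5,856 in total).
#' Image size defaults to a small value because only the bookkeeping, not
#' the pixel content, is of interest at this scale.
#'
#' @param image_size pixels per side.
#' @param seed RNG seed.
#' @param ... further arguments passed to [phantom_spec()].
#' @return a `phantom_spec`.
#' @export
paper_spec <- function(image_size = 16L, seed = 1L, ...) {
  phantom_spec(image_size = image_size, n_pneumonia = 4273L,
               n_normal = 1583L, seed = seed, ...)
}

# Ellipse membership on the pixel grid; cx/cy/rx/ry in pixel units.
ellipse_mask <- function(s, cx, cy, rx, ry) {
  x <- matrix(seq_len(s), s, s, byrow = TRUE) # column index
  y <- matrix(seq_len(s), s, s)               # row index
  ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
}

#' Generate a normal-appearance lung phantom
#'
#' Produces the shared background of every sample: a bright thorax field,
#' two darker elliptical lung fields at fixed fractional positions (with a
#' small per-sample geometric jitter), periodic rib bands across the
#' thorax, and additive Gaussian noise of sd `noise_sd`, clipped to
#' `[0,1]`. The lung-field mask is carried on the sample so that lesion
#' placement (and tests) can address the lung interior directly.
#'
#' @param spec a [phantom_spec()].
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return an `xray_sample` with `label = NA` (unlabeled phantom): a list
#'   with `pixels` (`image_size x image_size x channels` array in `[0,1]`),
#'   `lung_mask` (logical matrix), `lung_geom`, and `sample_id`.
#' @export
generate_lung_phantom <- function(spec, seed = NULL) {
  if (!inherits(spec, "phantom_spec"))
    spec <- do.call(phantom_spec, as.list(spec))
  s <- spec$image_size
  with_seed(seed, {
    jit <- function(x, frac) x * (1 + runif(1, -frac, frac))
    thorax <- list(cx = jit(0.50 * s, 0.02), cy = jit(0.52 * s, 0.02),
                   rx = jit(0.42 * s, 0.04), ry = jit(0.46 * s, 0.04))
    lungs <- list(
      list(cx = jit(0.33 * s, 0.04), cy = jit(0.48 * s, 0.04),
           rx = jit(0.155 * s, 0.08), ry = jit(0.27 * s, 0.08)),
      list(cx = jit(0.67 * s, 0.04), cy = jit(0.48 * s, 0.04),
           rx = jit(0.155 * s, 0.08), ry = jit(0.27 * s, 0.08)))
    img <- matrix(0.18, s, s)
    tmask <- ellipse_mask(s, thorax$cx, thorax$cy, thorax$rx, thorax$ry)
    img[tmask] <- runif(1, 0.70, 0.76)
    lmask <- ellipse_mask(s, lungs[[1]]$cx, lungs[[1]]$cy,
                          lungs[[1]]$rx, lungs[[1]]$ry) |
      ellipse_mask(s, lungs[[2]]$cx, lungs[[2]]$cy,
                   lungs[[2]]$rx, lungs[[2]]$ry)
    img[lmask] <- runif(1, 0.30, 0.38)
    # periodic rib bands across the thorax
    phase <- runif(1)
    period <- 0.12 * s
    ribs <- 0.06 * (0.5 + 0.5 * sin(2 * pi * (row(img) / period + phase)))
    img[tmask] <- img[tmask] + ribs[tmask]
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(s * s, 0, spec$noise_sd), s, s)
    img <- pmin(pmax(img, 0), 1)
    pixels <- array(img, dim = c(s, s, spec$channels))
    if (spec$channels == 3L) for (c in 2:3) pixels[, , c] <- img
    structure(list(pixels = pixels, label = NA_integer_,
                   sample_id = "phantom", lung_mask = lmask,
                   lung_geom = lungs,
                   lesions = list(n_infiltrates = 0L, n_nodules = 0L,
                                  consolidation = 0L, pleural_band = 0L,
                                  density_shift = 0),
                   added_brightness = 0),
              class = "xray_sample")
  })
}

# draw a pixel centre uniformly from the TRUE cells of a mask
sample_mask_point <- function(mask) {
  idx <- which(mask)
  i <- idx[sample.int(length(idx), 1L)]
  s <- nrow(mask)
  c(y = ((i - 1L) %% s) + 1L, x = ((i - 1L) %/% s) + 1L)
}

erode1 <- function(mask) {
  s <- nrow(mask)
  pad <- rbind(FALSE, cbind(FALSE, mask, FALSE), FALSE)
  out <- mask
  for (dy in -1:1) for (dx in -1:1)
    out <- out & pad[(2 + dy):(s + 1 + dy), (2 + dx):(s + 1 + dx)]
  out
}

#' Add pneumonia features to a lung phantom
#'
#' Superimposes, strictly inside the lung-field mask, the radiographic
#' signs of pneumonia: Gaussian-profile bright blobs (infiltrates), small
#' bright discs (nodules), with probability `consolidation_prob` a
#' contiguous lobar brightening, a uniform lung-density lift proportional
#' to `density_shift`, and with probability `pleural_band_prob` a bright
#' band along the lung boundary (pleural thickening). All contributions
#' are non-negative, pixels outside the lung mask are untouched, and the
#' result is clipped to `[0,1]`.
#'
#' @param sample an `xray_sample` produced by [generate_lung_phantom()].
#' @param lesion_params a [lesion_params()] record.
#' @param seed optional integer seed for lesion placement.
#' @return the sample with lesions applied, its `lesions` record filled in,
#'   and `added_brightness` set to the total intensity actually added
#'   (after clipping) inside the lung fields.
#' @export
add_pneumonia_features <- function(sample, lesion_params, seed = NULL) {
  if (!inherits(sample, "xray_sample") || is.null(sample$lung_mask))
    pn_stop("input must be a lung phantom carrying a lung-field mask",
            "pneumonet_contract_error")
  lp <- if (inherits(lesion_params, "lesion_params")) lesion_params
        else do.call(pneumonet::lesion_params, as.list(lesion_params))
  s <- nrow(sample$lung_mask)
  mask <- sample$lung_mask
  img <- sample$pixels[, , 1L]
  with_seed(seed, {
    add <- matrix(0, s, s)
    X <- matrix(seq_len(s), s, s, byrow = TRUE)
    Y <- matrix(seq_len(s), s, s)

    # diffuse density change across both lung fields
    if (lp$density_shift > 0) add[mask] <- add[mask] + 0.12 * lp$density_shift

    # hazy infiltrates: Gaussian intensity profiles
    if (lp$n_infiltrates > 0) for (i in seq_len(lp$n_infiltrates)) {
      ctr <- sample_mask_point(mask)
      sig <- runif(1, 0.05, 0.09) * s
      amp <- runif(1, 0.15, 0.30)
      blob <- amp * exp(-((X - ctr["x"])^2 + (Y - ctr["y"])^2) / (2 * sig^2))
      add[mask] <- add[mask] + blob[mask]
    }

    # nodules: small bright discs, kept mutually disjoint so each forms its
    # own connected component on the difference image
    if (lp$n_nodules > 0) {
      centers <- matrix(numeric(0), ncol = 2)
      radii <- numeric(0)
      for (i in seq_len(lp$n_nodules)) {
        r <- max(1.2, runif(1, 0.02, 0.04) * s)
        ok <- FALSE
        for (try in seq_len(200L)) {
          ctr <- sample_mask_point(mask)
          if (nrow(centers) == 0L ||
              all(sqrt((centers[, 1] - ctr["y"])^2 +
                       (centers[, 2] - ctr["x"])^2) > radii + r + 3)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) ctr <- sample_mask_point(mask) # fall back, overlap possible
        centers <- rbind(centers, c(ctr["y"], ctr["x"]))
        radii <- c(radii, r)
        amp <- runif(1, 0.25, 0.40)
        disc <- (X - ctr["x"])^2 + (Y - ctr["y"])^2 <= r^2
        add[mask & disc] <- add[mask & disc] + amp
      }
    }

    # lobar consolidation: brighten the upper or lower half of one lung
    consol <- 0L
    if (lp$consolidation_prob > 0 && runif(1) < lp$consolidation_prob) {
      consol <- 1L
      g <- sample$lung_geom[[sample.int(2L, 1L)]]
      lobe <- ellipse_mask(s, g$cx, g$cy, g$rx, g$ry)
      lobe <- lobe & (if (runif(1) < 0.5) Y <= g$cy else Y > g$cy)
      add[mask & lobe] <- add[mask & lobe] + 0.18
    }

    # pleural thickening: a bright band just inside the lung boundary
    pleur <- 0L
    if (lp$pleural_band_prob > 0 && runif(1) < lp$pleural_band_prob) {
      pleur <- 1L
      band <- mask & !erode1(erode1(mask))
      add[band] <- add[band] + 0.20
    }

    out <- pmin(img + add, 1)
    sample$added_brightness <- sum(out - img)
    for (c in seq_len(dim(sample$pixels)[3L])) sample$pixels[, , c] <- out
    sample$lesions <- list(n_infiltrates = lp$n_infiltrates,
                           n_nodules = lp$n_nodules,
                           consolidation = consol, pleural_band = pleur,
                           density_shift = lp$density_shift)
    sample
  })
}

#' Generate a labeled synthetic radiograph dataset
#'
#' Emits `n_pneumonia` pneumonia-positive samples (phantom + lesions,
#' label 1) and `n_normal` phantom-only samples (label 0), shuffled by the
#' spec's seed, together with a per-sample manifest. The whole dataset is
#' a pure function of `spec`: identical spec + seed reproduces it bit for
#' bit.
#'
#' @param spec a [phantom_spec()].
#' @return an `xray_dataset`: list with `samples` (list of `xray_sample`),
#'   `manifest` (data frame with sample_id, label, lesion record, and
#'   `added_brightness`), and the generating `spec`.
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    spec <- do.call(phantom_spec, as.list(spec))
  n <- spec$n_pneumonia + spec$n_normal
  if (n == 0L)
    pn_stop("dataset would be empty: both class counts are zero",
            "pneumonet_spec_error")
  with_seed(spec$seed, {
    samples <- vector("list", n)
    for (i in seq_len(spec$n_pneumonia)) {
      sm <- generate_lung_phantom(spec)
      sm <- add_pneumonia_features(sm, spec$lesion_params)
      sm$label <- 1L
      sm$sample_id <- sprintf("pneu_%05d", i)
      samples[[i]] <- sm
    }
    for (i in seq_len(spec$n_normal)) {
      sm <- generate_lung_phantom(spec)
      sm$label <- 0L
      sm$sample_id <- sprintf("norm_%05d", i)
      samples[[spec$n_pneumonia + i]] <- sm
    }
    samples <- samples[sample.int(n)]
    manifest <- data.frame(
      sample_id = vapply(samples, `[[`, "", "sample_id"),
      label = vapply(samples, `[[`, 0L, "label"),
      n_infiltrates = vapply(samples, function(x) x$lesions$n_infiltrates, 0L),
      n_nodules = vapply(samples, function(x) x$lesions$n_nodules, 0L),
      consolidation = vapply(samples, function(x) x$lesions$consolidation, 0L),
      pleural_band = vapply(samples, function(x) x$lesions$pleural_band, 0L),
      added_brightness = vapply(samples, `[[`, 0, "added_brightness"),
      stringsAsFactors = FALSE)
    structure(list(samples = samples, manifest = manifest, spec = spec),
              class = "xray_dataset")
  })
}

#' @export
length.xray_dataset <- function(x) length(x$samples)

#' @export
print.xray_dataset <- function(x, ...) {
  tab <- table(factor(x$manifest$label, levels = c(0, 1),
                      labels = c("normal", "pneumonia")))
  cat(sprintf("<xray_dataset> %d samples (%s), %dx%d px, %d channel(s)\n",
              length(x$samples),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              x$spec$image_size, x$spec$image_size, x$spec$channels))
  invisible(x)
}

#' Split a dataset into disjoint train and validation sets
#'
#' Draws exactly the requested per-class counts, without replacement, into
#' a training and a validation subset. The default counts mirror the
#' cohort split the pipeline targets: 4,160 pneumonia + 1,280 normal
#' training images and a balanced 208 + 208 validation set.
#'
#' @param dataset an `xray_dataset` (or plain list of `xray_sample`s).
#' @param train_counts,val_counts named numeric vectors
#'   `c(pneumonia = ..., normal = ...)`.
#' @param seed integer seed for the draw.
#' @return `list(train = , validation = )` of `xray_dataset` objects whose
#'   manifests carry a `split` column; the two subsets are disjoint by
#'   `sample_id`.
#' @export
split_dataset <- function(dataset,
                          train_counts = c(pneumonia = 4160, normal = 1280),
                          val_counts = c(pneumonia = 208, normal = 208),
                          seed = 1L) {
  samples <- if (inherits(dataset, "xray_dataset")) dataset$samples
             else dataset
  labels <- vapply(samples, `[[`, 0L, "label")
  want <- function(counts, cls)
    as.integer(counts[[if (cls == 1L) "pneumonia" else "normal"]])
  with_seed(seed, {
    idx <- list(train = integer(0), validation = integer(0))
    for (cls in c(1L, 0L)) {
      pool <- which(labels == cls)
      ntr <- want(train_counts, cls)
      nva <- want(val_counts, cls)
      if (length(pool) < ntr + nva)
        pn_stop(sprintf(
          "not enough %s samples: need %d (train %d + validation %d), have %d",
          if (cls == 1L) "pneumonia" else "normal",
          ntr + nva, ntr, nva, length(pool)), "pneumonet_split_error")
      pool <- pool[sample.int(length(pool))]
      idx$train <- c(idx$train, pool[seq_len(ntr)])
      idx$validation <- c(idx$validation, pool[ntr + seq_len(nva)])
    }
    subset_ds <- function(i, split) {
      ss <- samples[sort(i)]
      man <- data.frame(
        sample_id = vapply(ss, `[[`, "", "sample_id"),
        label = vapply(ss, `[[`, 0L, "label"),
        split = split, stringsAsFactors = FALSE)
      spec <- if (inherits(dataset, "xray_dataset")) dataset$spec else NULL
      structure(list(samples = ss, manifest = man, spec = spec),
                class = "xray_dataset")
    }
    list(train = subset_ds(idx$train, "train"),
         validation = subset_ds(idx$validation, "validation"))
  })
}

#' Stack a dataset into a batch array
#'
#' @param dataset an `xray_dataset`.
#' @return `list(x = H x W x C x N array, y = integer labels)`.
#' @export
as_batch_array <- function(dataset) {
  samples <- if (inherits(dataset, "xray_dataset")) dataset$samples
             else dataset
  d <- dim(samples[[1L]]$pixels)
  n <- length(samples)
  x <- array(0, dim = c(d[1L], d[2L], d[3L], n))
  for (i in seq_len(n)) x[, , , i] <- samples[[i]]$pixels
  list(x = x, y = vapply(samples, `[[`, 0L, "label"))
}
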