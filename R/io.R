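#' Write a dataset to class-labeled image folders
#'
#' Writes PNGs into `<out>/pneumonia/` and `<out>/normal/` subfolders and
#' a manifest CSV with header
#' `sample_id,label,split,n_infiltrates,n_nodules,consolidation,pleural_band`.
#'
#' @param dataset an `xray_dataset`.
#' @param out output directory (created if missing).
#' @param split split label written to the manifest.
#' @return the manifest data frame, invisibly.
#' @export
write_dataset <- function(dataset, out, split = "all") {
  dir.create(file.path(out, "pneumonia"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out, "normal"), recursive = TRUE, showWarnings = FALSE)
  for (sm in dataset$samples) {
    sub <- if (sm$label == 1L) "pneumonia" else "normal"
    img <- sm$pixels
    if (dim(img)[3L] == 1L) img <- img[, , 1L]
    png::writePNG(img, file.path(out, sub, paste0(sm$sample_id, ".png")))
  }
  man <- dataset$manifest
  man$split <- split
  cols <- c("sample_id", "label", "split", "n_infiltrates", "n_nodules",
            "consolidation", "pleural_band")
  for (cl in setdiff(cols, names(man))) man[[cl]] <- NA
  write.csv(man[, cols], file.path(out, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

# read one image file to an H x W grayscale matrix in [0,1] (min-max
# rescaled per image), or NULL if unreadable
read_image_gray <- function(path) {
  img <- tryCatch(suppressWarnings(EBImage::readImage(path)),
                  error = function(e) NULL)
  if (is.null(img)) return(NULL)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3L, dim(a)[3L]), drop = FALSE],
                                       c(1L, 2L), mean)
  m <- t(a) # EBImage stores x (width) first; transpose to rows = y
  rng <- range(m)
  if (rng[2L] > rng[1L]) m <- (m - rng[1L]) / (rng[2L] - rng[1L])
  else m <- m * 0
  m
}

#' Read an image-folder dataset
#'
#' Loads PNG/JPEG files from class subfolders (by default `pneumonia/`,
#' label 1, and `normal/`, label 0), min-max rescales each image to
#' `[0,1]`, bilinearly resizes to `image_size`, and replicates to
#' `channels` planes. Unreadable files are skipped with a warning (and
#' counted in attribute `"n_skipped"`); an empty class folder is an
#' error, mirroring an explicit low-quality/unreadable exclusion step.
#'
#' @param root dataset directory.
#' @param image_size target side length in pixels.
#' @param channels 1 or 3.
#' @param class_dirs named character vector mapping class folder names to
#'   the two classes.
#' @return an `xray_dataset` (samples carry no lung-mask metadata).
#' @export
read_image_folder <- function(root, image_size = 64L, channels = 1L,
                              class_dirs = c(pneumonia = "pneumonia",
                                             normal = "normal")) {
  if (!dir.exists(root))
    pn_stop(sprintf("dataset directory not found: %s", root),
            "pneumonet_io_error")
  samples <- list()
  n_skipped <- 0L
  for (cls in names(class_dirs)) {
    dir <- file.path(root, class_dirs[[cls]])
    files <- sort(list.files(dir, pattern = "\\.(png|jpe?g)$",
                             ignore.case = TRUE, full.names = TRUE))
    label <- if (cls == "pneumonia") 1L else 0L
    kept <- 0L
    for (f in files) {
      m <- read_image_gray(f)
      if (is.null(m)) {
        warning(sprintf("skipping unreadable image: %s", f), call. = FALSE)
        n_skipped <- n_skipped + 1L
        next
      }
      if (nrow(m) != image_size || ncol(m) != image_size) {
        img <- EBImage::resize(EBImage::Image(t(m)), w = image_size,
                               h = image_size)
        m <- t(EBImage::imageData(img))
        m <- pmin(pmax(m, 0), 1)
      }
      pixels <- array(m, dim = c(image_size, image_size, channels))
      if (channels == 3L) for (c in 2:3) pixels[, , c] <- m
      kept <- kept + 1L
      samples[[length(samples) + 1L]] <- structure(
        list(pixels = pixels, label = label,
             sample_id = sub("\\.[^.]+$", "", basename(f)),
             lung_mask = NULL, lung_geom = NULL,
             lesions = list(n_infiltrates = NA_integer_,
                            n_nodules = NA_integer_,
                            consolidation = NA_integer_,
                            pleural_band = NA_integer_,
                            density_shift = NA_real_),
             added_brightness = NA_real_),
        class = "xray_sample")
    }
    if (kept == 0L)
      pn_stop(sprintf("class folder '%s' contains no readable images",
                      class_dirs[[cls]]), "pneumonet_io_error")
  }
  manifest <- data.frame(
    sample_id = vapply(samples, `[[`, "", "sample_id"),
    label = vapply(samples, `[[`, 0L, "label"),
    stringsAsFactors = FALSE)
  structure(list(samples = samples, manifest = manifest,
                 spec = NULL, n_skipped = n_skipped),
            class = "xray_dataset")
}

config_schema <- list(
  model = c("input_size", "stem_channels", "n_blocks", "branch_reduction",
            "branch_stride", "fusion_mode", "use_channel_attention",
            "n_classes", "stem_stride", "stem_pool", "norm", "seed"),
  loss = c("name", "alpha", "gamma", "count_mapping"),
  train = c("batch_size", "lr0", "beta1", "weight_decay", "lr_step",
            "lr_gamma", "max_epochs", "seed", "loss_name", "device"),
  data = c("image_size", "channels", "n_pneumonia", "n_normal", "noise_sd",
           "seed", "n_infiltrates", "n_nodules", "consolidation_prob",
           "density_shift", "pleural_band_prob"))

#' Load and validate a YAML run configuration
#'
#' Recognized top-level keys: `model`, `loss`, `train`, `data`. Unknown
#' keys at any level are rejected; invalid values raise errors naming the
#' offending field (e.g. `loss.gamma`).
#'
#' @param path YAML file.
#' @return validated list of config records (`network_config`,
#'   `loss_config`, `train_config`, `phantom_spec` as present).
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    pn_stop(sprintf("config file not found: %s", path), "pneumonet_io_error")
  raw <- yaml::read_yaml(path)
  unknown_top <- setdiff(names(raw), names(config_schema))
  if (length(unknown_top))
    pn_stop(paste0("unknown config key(s): ",
                   paste(unknown_top, collapse = ", ")),
            "pneumonet_config_error")
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), config_schema[[sec]])
    if (length(bad))
      pn_stop(paste0("unknown config key(s): ",
                     paste(paste0(sec, ".", bad), collapse = ", ")),
              "pneumonet_config_error")
  }
  out <- list()
  if (!is.null(raw$model))
    out$model <- do.call(network_config, raw$model)
  if (!is.null(raw$loss)) {
    ls <- raw$loss
    if (!is.null(ls$gamma) && ls$gamma < 0)
      pn_stop("loss.gamma must be non-negative", "pneumonet_config_error")
    if (!is.null(ls$alpha) && (ls$alpha <= 0 || ls$alpha >= 1))
      pn_stop("loss.alpha must lie strictly in (0,1)",
              "pneumonet_config_error")
    out$loss <- ls
  }
  if (!is.null(raw$train))
    out$train <- do.call(train_config, raw$train)
  if (!is.null(raw$data)) {
    da <- raw$data
    lp_fields <- c("n_infiltrates", "n_nodules", "consolidation_prob",
                   "density_shift", "pleural_band_prob")
    lp <- da[intersect(lp_fields, names(da))]
    da <- da[setdiff(names(da), lp_fields)]
    if (length(lp)) da$lesion_params <- do.call(lesion_params, lp)
    out$data <- do.call(phantom_spec, da)
  }
  out
}

#' Write a run manifest
#'
#' Every run directory gets exactly one `run_manifest.json` recording the
#' configuration snapshot, seed, artifact paths, package version and
#' timestamp — enough to re-run the artifact bit-identically.
#'
#' @param out run directory.
#' @param config list of configuration records.
#' @param seed the run seed.
#' @param artifacts named character vector of artifact paths.
#' @return the manifest path, invisibly.
#' @export
write_run_manifest <- function(out, config, seed, artifacts = character(0)) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  man <- list(config = strip(config), seed = seed,
              artifacts = as.list(artifacts),
              package_version = as.character(packageVersion("pneumonet")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out, "run_manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
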