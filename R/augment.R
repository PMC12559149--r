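# Deterministic preprocessing and the default augmentation sampler.
#
# Preprocessing mirrors the conventional segmentation pipeline: crop to
# the non-zero region, z-score, resample to a target spacing with
# nearest-neighbour interpolation (the stacks are strongly anisotropic).
# The "default" sampler provides the general-purpose augmentations —
# rotation, rescaling, mirroring, noise, brightness/contrast, resolution
# reduction, gamma — as paired image/label transforms.

#' Crop, z-score, and resample an image/label pair
#'
#' Crops both volumes to the minimal bounding box of non-zero image
#' values, z-scores the image over the cropped region (mean 0, SD 1),
#' and resamples both to the target spacing with nearest-neighbour
#' interpolation. With the target equal to the input spacing the
#' geometry is unchanged.
#'
#' @param image an `image_stack`.
#' @param labels a congruent `label_stack`.
#' @param target_spacing (dz, dy, dx) in mm; default: the input spacing.
#' @return `list(image, labels)`.
#' @export
preprocess_stack <- function(image, labels, target_spacing = image$spacing) {
  check_congruent(image, labels)
  v <- image$values
  nz <- which(v != 0, arr.ind = TRUE)
  if (nrow(nz) == 0) abort("preprocess_stack: empty image")
  rngs <- lapply(1:3, function(ax) range(nz[, ax]))
  v <- v[rngs[[1]][1]:rngs[[1]][2], rngs[[2]][1]:rngs[[2]][2],
         rngs[[3]][1]:rngs[[3]][2], drop = FALSE]
  l <- labels$labels[rngs[[1]][1]:rngs[[1]][2], rngs[[2]][1]:rngs[[2]][2],
                     rngs[[3]][1]:rngs[[3]][2], drop = FALSE]
  v <- (v - mean(v)) / stats::sd(v)
  sp <- image$spacing
  target_spacing <- as.numeric(target_spacing)
  idx <- lapply(1:3, function(ax) {
    n_old <- dim(v)[ax]
    if (abs(target_spacing[ax] - sp[ax]) < 1e-12) return(seq_len(n_old))
    n_new <- max(1L, floor((n_old - 1) * sp[ax] / target_spacing[ax]) + 1L)
    pmin(pmax(round((seq_len(n_new) - 1) * target_spacing[ax] / sp[ax]) + 1, 1),
         n_old)
  })
  v <- v[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  l <- l[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  list(image = image_stack(v, target_spacing, image$joint, image$side),
       labels = label_stack(l, target_spacing, labels$joint, labels$side))
}

#' Configuration of the default augmentation sampler
#'
#' Probabilities and ranges for the general-purpose augmentations.
#' Defaults follow common practice for medical-image segmentation
#' training: in-plane rotation up to +/-15 degrees, isotropic rescaling
#' 0.85-1.15, mirroring of the left-right axis, additive Gaussian noise,
#' multiplicative brightness and contrast jitter, in-plane resolution
#' reduction, and gamma adjustment in 0.7-1.5.
#'
#' @param rotation,rescale,mirror,noise,brightness,contrast,lowres,gamma
#'   each a list with `p` (inclusion probability) and `range`.
#' @return an object of class `default_aug_config`.
#' @export
default_aug_config <- function(rotation = list(p = 0.5, range = c(-15, 15)),
                               rescale = list(p = 0.5, range = c(0.85, 1.15)),
                               mirror = list(p = 0.5),
                               noise = list(p = 0.5, range = c(0, 0.05)),
                               brightness = list(p = 0.5, range = c(0.75, 1.25)),
                               contrast = list(p = 0.5, range = c(0.75, 1.25)),
                               lowres = list(p = 0.25, range = c(1, 2)),
                               gamma = list(p = 0.3, range = c(0.7, 1.5))) {
  cfg <- list(rotation = rotation, rescale = rescale, mirror = mirror,
              noise = noise, brightness = brightness, contrast = contrast,
              lowres = lowres, gamma = gamma)
  for (nm in names(cfg)) {
    p <- cfg[[nm]]$p
    if (p < 0 || p > 1) abort("default_aug_config: probabilities must be in [0, 1]")
  }
  if (!is.null(gamma$range) && any(gamma$range <= 0)) {
    abort("default_aug_config: gamma must be > 0")
  }
  structure(cfg, class = "default_aug_config")
}

#' Sample one draw of the default augmentations
#'
#' Geometric transforms (rotation, rescaling, mirroring, resolution
#' reduction) are applied identically to image and labels
#' (nearest-neighbour for labels); intensity transforms (noise,
#' brightness/contrast, gamma) touch only the image. Deterministic for
#' a given seed; the returned `log` records every draw.
#'
#' @param image an `image_stack`.
#' @param labels a congruent `label_stack`.
#' @param config a [default_aug_config()].
#' @param seed integer seed.
#' @return `list(image, labels, log)`.
#' @export
sample_default_augmentation <- function(image, labels,
                                        config = default_aug_config(),
                                        seed = 1L) {
  check_congruent(image, labels)
  stopifnot(inherits(config, "default_aug_config"))
  v <- image$values
  l <- labels$labels
  log <- withr::with_seed(derive_seed(seed, "default-aug"), {
    lg <- list()
    draw <- function(nm) stats::runif(1) < config[[nm]]$p
    rng <- function(nm) stats::runif(1, config[[nm]]$range[1], config[[nm]]$range[2])
    if (draw("rotation")) lg$rotation <- rng("rotation")
    if (draw("rescale")) lg$rescale <- rng("rescale")
    if (draw("mirror")) lg$mirror <- "x"
    if (draw("noise")) lg$noise <- rng("noise")
    if (draw("brightness")) lg$brightness <- rng("brightness")
    if (draw("contrast")) lg$contrast <- rng("contrast")
    if (draw("lowres")) lg$lowres <- rng("lowres")
    if (draw("gamma")) lg$gamma <- rng("gamma")
    lg
  })
  if (!is.null(log$rotation) || !is.null(log$rescale)) {
    rot <- if (is.null(log$rotation)) 0 else log$rotation
    sc <- if (is.null(log$rescale)) 1 else log$rescale
    v <- warp_volume(v, rot, sc, pad = min(v))
    l <- warp_volume(l, rot, sc, interp = "nearest", pad = 0)
  }
  if (!is.null(log$mirror)) {
    rev_x <- rev(seq_len(dim(v)[3]))
    v <- v[, , rev_x, drop = FALSE]
    l <- l[, , rev_x, drop = FALSE]
  }
  if (!is.null(log$lowres)) {
    f <- log$lowres
    if (f > 1) {
      d <- dim(v)
      small_y <- pmin(round(seq(1, d[2], by = f)), d[2])
      small_x <- pmin(round(seq(1, d[3], by = f)), d[3])
      # nearest down, nearest back up (labels and image alike share geometry)
      up_y <- small_y[pmin(length(small_y), pmax(1, ceiling(seq_len(d[2]) / f)))]
      up_x <- small_x[pmin(length(small_x), pmax(1, ceiling(seq_len(d[3]) / f)))]
      up_y <- pmin(up_y, d[2]); up_x <- pmin(up_x, d[3])
      v <- v[, up_y, up_x, drop = FALSE]
      l <- l[, up_y, up_x, drop = FALSE]
    }
  }
  if (!is.null(log$noise)) {
    amp <- log$noise * diff(range(v))
    v <- v + withr::with_seed(derive_seed(seed, "aug-noise"),
                              array(stats::rnorm(length(v), 0, amp), dim(v)))
  }
  if (!is.null(log$brightness)) v <- v * log$brightness
  if (!is.null(log$contrast)) {
    mu <- mean(v)
    v <- (v - mu) * log$contrast + mu
  }
  if (!is.null(log$gamma)) {
    rg <- range(v)
    if (rg[2] > rg[1]) {
      v <- ((v - rg[1]) / (rg[2] - rg[1]))^log$gamma * (rg[2] - rg[1]) + rg[1]
    }
  }
  storage.mode(l) <- "integer"
  list(image = image_stack(v, image$spacing, image$joint, image$side),
       labels = label_stack(l, labels$spacing, labels$joint, labels$side),
       log = log)
}
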