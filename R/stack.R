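#' Image and label stack containers
#'
#' An `image_stack` holds a 3D axial grey-value volume indexed `(z, y, x)`
#' together with its voxel spacing and acquisition metadata; a
#' `label_stack` holds a congruent integer label volume with the coding
#' 0 = background, 1 = femur, 2 = tibia, 3 = fibula.
#'
#' Coordinate convention: arrays are indexed `(z, y, x)`; +x is the
#' patient's left, +y posterior; in-plane angles are measured
#' counterclockwise from +x in degrees. Spacing is `(dz, dy, dx)` in mm
#' and may be anisotropic (`dz` typically larger, emulating 2D TSE
#' stacks).
#'
#' @param values 3D numeric array indexed (z, y, x).
#' @param spacing numeric length-3 vector (dz, dy, dx) in mm, all > 0.
#' @param joint one of "hip", "knee", "ankle".
#' @param side one of "right", "left".
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(values, spacing, joint, side) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (!all(is.finite(values))) abort("image_stack: values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort("image_stack: spacing must be 3 positive numbers (dz, dy, dx)")
  }
  joint <- match.arg(joint, c("hip", "knee", "ankle"))
  side <- match.arg(side, c("right", "left"))
  structure(list(values = values, spacing = spacing,
                 joint = joint, side = side),
            class = "image_stack")
}

#' @rdname image_stack
#' @param labels 3D integer array with values in \{0, 1, 2, 3\}.
#' @export
label_stack <- function(labels, spacing, joint, side) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  if (!all(labels %in% 0:3)) {
    abort("label_stack: label codes must be in {0, 1, 2, 3}")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort("label_stack: spacing must be 3 positive numbers (dz, dy, dx)")
  }
  joint <- match.arg(joint, c("hip", "knee", "ankle"))
  side <- match.arg(side, c("right", "left"))
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = spacing,
                 joint = joint, side = side),
            class = "label_stack")
}

#' @exportS3Method base::print
print.image_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_stack> %s %s  %d x %d x %d (z,y,x)  spacing %.2f/%.2f/%.2f mm\n",
              x$side, x$joint, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @exportS3Method base::print
print.label_stack <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_stack> %s %s  %d x %d x %d (z,y,x)  labels {%s}\n",
              x$side, x$joint, d[1], d[2], d[3],
              paste(sort(unique(as.vector(x$labels))), collapse = ",")))
  invisible(x)
}

# internal: check two stacks are geometrically congruent
check_congruent <- function(a, b) {
  da <- dim(if (inherits(a, "label_stack")) a$labels else a$values)
  db <- dim(if (inherits(b, "label_stack")) b$labels else b$values)
  if (!identical(da, db)) abort("stacks are not congruent: shapes differ")
  if (max(abs(a$spacing - b$spacing)) > 1e-9) {
    abort("stacks are not congruent: spacings differ")
  }
  invisible(TRUE)
}

#' Read and write stacks as NIfTI-1
#'
#' Stacks are stored on disk in the conventional NIfTI (x, y, z) axis
#' order; the in-memory (z, y, x) arrays are permuted on the way in and
#' out. Joint level and side are carried in a JSON sidecar written next
#' to the volume (`<file>.meta.json`) because NIfTI-1 has no standard
#' field for them.
#'
#' @param stack an `image_stack` or `label_stack`.
#' @param path output path, conventionally ending in `.nii.gz`.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns
#'   the reconstructed stack.
#' @export
write_stack <- function(stack, path) {
  is_lab <- inherits(stack, "label_stack")
  vol <- if (is_lab) stack$labels else stack$values
  # (z, y, x) -> (x, y, z)
  vol <- aperm(vol, c(3L, 2L, 1L))
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- stack$spacing[c(3L, 2L, 1L)]
  RNifti::writeNifti(img, path)
  meta <- list(joint = stack$joint, side = stack$side,
               kind = if (is_lab) "labels" else "image")
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  vol <- aperm(as.array(img), c(3L, 2L, 1L))
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) abort("missing sidecar: %s", meta_path)
  meta <- jsonlite::read_json(meta_path)
  spacing <- pd[c(3L, 2L, 1L)]
  if (identical(meta$kind, "labels")) {
    label_stack(round(vol), spacing, meta$joint, meta$side)
  } else {
    image_stack(vol, spacing, meta$joint, meta$side)
  }
}
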