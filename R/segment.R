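# Stand-in segmenter and segmentation-quality metrics.
#
# The segmenter is a deterministic threshold + morphology + component
# rule chain. It is the integration point where a learned model would be
# substituted; everything downstream consumes only its LabelStack
# output.

#' Threshold-morphology stand-in segmenter
#'
#' Candidate bone is the bright class (marrow on T2-like contrast):
#' voxels above the midpoint between the median intensity (background)
#' and the `threshold_quantile` upper reference quantile. Per slice,
#' morphological opening removes noise specks, a dilation of the
#' configured cortical-shell width adds back the dark cortical rim,
#' holes are filled, and components below `min_component_voxels` are
#' discarded. Components are then assigned to bone codes by joint level,
#' expected component count, and in-plane position: a hip slice keeps
#' its largest component as femur; a knee slice keeps the two condylar
#' lobes proximally (femur) and the plateau lobes plus the
#' lateral fibular head distally; an ankle slice keeps the largest
#' component as tibia and the most lateral smaller component as fibula.
#' The fibula is identified side-aware as the component with less than
#' half the largest area whose centroid lies most lateral.
#'
#' @param image an `image_stack`.
#' @param params list: `threshold_quantile` (upper reference quantile of
#'   the bright class, default 0.995; the threshold is the midpoint
#'   between the median and this quantile, which is robust to the bone
#'   volume fraction varying between stacks), `min_component_voxels`
#'   (per-slice, default 30), `opening_radius` (pixels, default 1),
#'   `cortex_mm` (dilation recovering the dark cortical shell, default
#'   0.6).
#' @return a `label_stack`; attribute `status` is `"ok"`, or `"empty"`
#'   when no component survives (flagged, not an error).
#' @export
segment_stack <- function(image,
                          params = list()) {
  stopifnot(inherits(image, "image_stack"))
  p <- utils::modifyList(list(threshold_quantile = 0.995,
                              min_component_voxels = 30,
                              opening_radius = 1, cortex_mm = 0.6), params)
  v <- image$values
  if (!all(is.finite(v))) abort("segment_stack: image must be finite")
  d <- dim(v)
  out <- array(0L, d)
  rng <- range(v)
  comps_by_slice <- vector("list", d[1])
  if (rng[2] > rng[1]) {
    qs <- stats::quantile(v, c(0.5, p$threshold_quantile), names = FALSE)
    thr <- (qs[1] + qs[2]) / 2
    open_brush <- EBImage::makeBrush(2 * p$opening_radius + 1, "box")
    cortex_px <- if (p$cortex_mm > 0) {
      ceiling(p$cortex_mm / image$spacing[3] - 1e-9)
    } else 0L
    dil_brush <- if (cortex_px > 0) {
      EBImage::makeBrush(2 * cortex_px + 1, "disc")
    } else NULL
    for (iz in seq_len(d[1])) {
      m <- v[iz, , ] >= thr
      if (!any(m)) next
      m <- EBImage::opening(m + 0, open_brush) > 0.5
      if (!is.null(dil_brush) && any(m)) m <- EBImage::dilate(m + 0, dil_brush) > 0.5
      if (!any(m)) next
      m <- EBImage::fillHull(m + 0) > 0.5
      lab <- EBImage::bwlabel(m)
      sizes <- tabulate(lab[lab > 0])
      keep <- which(sizes >= p$min_component_voxels)
      if (length(keep) == 0) next
      cents <- vapply(keep, function(k) {
        mean(which(lab == k, arr.ind = TRUE)[, 2])
      }, numeric(1))
      ord <- order(sizes[keep], decreasing = TRUE)
      comps_by_slice[[iz]] <- list(lab = lab, ids = keep[ord],
                                   areas = sizes[keep][ord],
                                   cx = cents[ord])
    }
  }
  occ <- which(!vapply(comps_by_slice, is.null, logical(1)))
  lateral_sign <- if (image$side == "right") -1 else 1
  if (length(occ)) {
    split <- (min(occ) + max(occ)) / 2
    for (iz in occ) {
      cs <- comps_by_slice[[iz]]
      sl <- matrix(0L, d[2], d[3])
      if (image$joint == "hip") {
        sl[cs$lab == cs$ids[1]] <- 1L
      } else if (image$joint == "knee" && iz <= split) {
        for (k in cs$ids[seq_len(min(2, length(cs$ids)))]) sl[cs$lab == k] <- 1L
      } else {
        # tibia + fibula rule (distal knee and ankle slices)
        big <- cs$areas >= 0.5 * cs$areas[1]
        n_tib <- if (image$joint == "ankle") 1L else 2L
        tib <- which(big)[seq_len(min(n_tib, sum(big)))]
        rest <- setdiff(seq_along(cs$ids), tib)
        for (k in cs$ids[tib]) sl[cs$lab == k] <- 2L
        if (length(rest)) {
          fib <- rest[which.max(lateral_sign * cs$cx[rest])]
          sl[cs$lab == cs$ids[fib]] <- 3L
        }
      }
      out[iz, , ] <- sl
    }
  }
  status <- if (any(out > 0L)) "ok" else "empty"
  res <- label_stack(out, image$spacing, image$joint, image$side)
  attr(res, "status") <- status
  res
}

#' Dice similarity coefficient for one label code
#'
#' `DSC = 2|A intersect B| / (|A| + |B|)`. When both masks are empty the
#' coefficient is defined as 1 (agreement on absence); empty vs.
#' non-empty gives 0.
#'
#' @param a,b congruent `label_stack`s (or plain arrays).
#' @param label_code the bone code to compare (1 femur, 2 tibia,
#'   3 fibula).
#' @return a value in \[0, 1\].
#' @export
dice <- function(a, b, label_code = 1L) {
  va <- if (inherits(a, "label_stack")) a$labels else a
  vb <- if (inherits(b, "label_stack")) b$labels else b
  if (!identical(dim(va), dim(vb))) abort("dice: shape mismatch")
  ma <- va == label_code
  mb <- vb == label_code
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0) return(1.0)
  2 * sum(ma & mb) / (na + nb)
}
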