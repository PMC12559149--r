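# In-plane similarity resampling shared by the motion operator, the
# registration module, and the geometric augmentations.
#
# Forward model, pixel coordinates (y, x), rotation CCW from +x about the
# slice centre:  p' = s * R(theta) * (p - c) + c + t.
# Resampling is by inverse mapping; an exact identity short-circuit keeps
# zero-parameter transforms bit-exact.

warp_slice <- function(slice, rotation_deg = 0, scale = 1,
                       translation_px = c(0, 0),
                       interp = c("linear", "nearest"), pad = 0) {
  interp <- match.arg(interp)
  if (rotation_deg == 0 && scale == 1 && all(translation_px == 0)) {
    return(slice)
  }
  ny <- nrow(slice); nx <- ncol(slice)
  cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
  th <- deg2rad(rotation_deg)
  yy <- matrix(seq_len(ny) - 1, ny, nx) - cy
  xx <- matrix(seq_len(nx) - 1, ny, nx, byrow = TRUE) - cx
  # inverse map: source = R(-theta) ((p - c - t) / s) + c
  ys <- (yy - translation_px[1]) / scale
  xs <- (xx - translation_px[2]) / scale
  sx <- cos(th) * xs + sin(th) * ys + cx
  sy <- -sin(th) * xs + cos(th) * ys + cy
  if (interp == "nearest") {
    ix <- round(sx); iy <- round(sy)
    ok <- ix >= 0 & ix <= nx - 1 & iy >= 0 & iy <= ny - 1
    out <- matrix(pad, ny, nx)
    out[ok] <- slice[cbind(iy[ok] + 1, ix[ok] + 1)]
    return(out)
  }
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- as.vector(sx - x0); fy <- as.vector(sy - y0)
  ok <- as.vector(x0 >= 0 & x0 <= nx - 2 & y0 >= 0 & y0 <= ny - 2)
  # clamp indices so the gather is safe; masked afterwards
  x0c <- as.vector(pmin(pmax(x0, 0), nx - 2)) + 1
  y0c <- as.vector(pmin(pmax(y0, 0), ny - 2)) + 1
  g <- function(dy, dx) slice[cbind(y0c + dy, x0c + dx)]
  out <- (1 - fy) * ((1 - fx) * g(0, 0) + fx * g(0, 1)) +
    fy * ((1 - fx) * g(1, 0) + fx * g(1, 1))
  out[!ok] <- pad
  dim(out) <- c(ny, nx)
  out
}

# apply warp_slice to every slice of a (z, y, x) array
warp_volume <- function(vol, rotation_deg = 0, scale = 1,
                        translation_px = c(0, 0),
                        interp = "linear", pad = 0) {
  out <- vol
  for (iz in seq_len(dim(vol)[1])) {
    out[iz, , ] <- warp_slice(vol[iz, , ], rotation_deg, scale,
                              translation_px, interp, pad)
  }
  out
}
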