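#' RGB to HSV conversion on the half-degree working scale
#'
#' Converts an RGB frame (channels in [0, 255]) to HSV with hue on 0--180
#' (degrees halved), saturation and value on 0--255. RGB is first scaled to
#' [0, 1]; hue is then the usual hexcone angle in degrees -- 0 when
#' max = min, otherwise 60 * (G - B)/(max - min) when the maximum channel is
#' R, shifted by 120 for G and 240 for B -- wrapped into [0, 360) and
#' halved. Saturation is (max - min)/max (0 when max = 0) scaled to 0--255;
#' value is max scaled to 0--255. When two channels tie for the maximum the
#' branch is chosen in R, G, B order.
#'
#' @param frame an \code{\link{ImageFrame}} or a height x width x 3 RGB
#'   array with values in [0, 255]
#' @return a height x width x 3 numeric array; slabs named \code{h},
#'   \code{s}, \code{v}
#' @examples
#' px <- array(c(0, 255, 0), dim = c(1, 1, 3))   # pure green
#' rgbToHSV(px)[1, 1, ]                          # H = 60, S = 255, V = 255
#' @export
rgbToHSV <- function(frame) {
  p <- if (is(frame, "ImageFrame")) frame@pixels else frame
  stopifnot(length(dim(p)) == 3L, dim(p)[3] == 3L)
  nr <- dim(p)[1]; nc <- dim(p)[2]
  r <- matrix(p[, , 1] / 255, nr, nc)
  g <- matrix(p[, , 2] / 255, nr, nc)
  b <- matrix(p[, , 3] / 255, nr, nc)
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- matrix(0, nrow(mx), ncol(mx))
  chrom <- d > 0
  # branch precedence R, G, B for ties on the maximum
  isR <- chrom & (r >= g) & (r >= b)
  isG <- chrom & !isR & (g >= b)
  isB <- chrom & !isR & !isG
  h[isR] <- 60 * (g[isR] - b[isR]) / d[isR]
  h[isG] <- 60 * (b[isG] - r[isG]) / d[isG] + 120
  h[isB] <- 60 * (r[isB] - g[isB]) / d[isB] + 240
  h <- (h %% 360) / 2
  s <- matrix(0, nrow(mx), ncol(mx))
  nz <- mx > 0
  s[nz] <- d[nz] / mx[nz] * 255
  v <- mx * 255
  out <- array(c(h, s, v), dim = c(nr, nc, 3L))
  dimnames(out) <- list(NULL, NULL, c("h", "s", "v"))
  out
}

#' HSV to RGB conversion (inverse of the working scale)
#'
#' Maps an HSV raster on the package's working scale (H 0--180, S and V
#' 0--255) back to RGB in [0, 255]. Used by the synthetic renderer to paint
#' slices of known hue.
#'
#' @param hsv a height x width x 3 HSV array on the working scale, or a
#'   length-3 vector \code{c(h, s, v)}
#' @return an array (or vector) of RGB values in [0, 255]
#' @export
hsvToRGB <- function(hsv) {
  vec <- is.null(dim(hsv))
  if (vec) hsv <- array(hsv, dim = c(1, 1, 3))
  nr <- dim(hsv)[1]; nc <- dim(hsv)[2]
  h <- matrix((hsv[, , 1] * 2) %% 360, nr, nc)
  s <- matrix(hsv[, , 2] / 255, nr, nc)
  v <- matrix(hsv[, , 3] / 255, nr, nc)
  c_ <- v * s
  x <- c_ * (1 - abs((h / 60) %% 2 - 1))
  m <- v - c_
  sector <- pmin(floor(h / 60), 5)
  r <- g <- b <- matrix(0, nrow(h), ncol(h))
  pick <- function(sec, rr, gg, bb) {
    k <- sector == sec
    r[k] <<- rr[k]; g[k] <<- gg[k]; b[k] <<- bb[k]
  }
  zero <- matrix(0, nrow(h), ncol(h))
  pick(0, c_, x, zero); pick(1, x, c_, zero); pick(2, zero, c_, x)
  pick(3, zero, x, c_); pick(4, x, zero, c_); pick(5, c_, zero, x)
  out <- array(c(r + m, g + m, b + m) * 255, dim = dim(hsv))
  if (vec) out[1, 1, ] else out
}

#' Threshold an HSV raster into a foreground mask
#'
#' A pixel is foreground iff its hue, saturation and value all fall inside
#' the (inclusive) threshold window. With the default window the dark tray
#' background and desaturated glare drop out and the fruit flesh remains.
#'
#' @param hsv HSV raster from \code{\link{rgbToHSV}}
#' @param thresholds an \code{\link{HSVThresholds}} object
#' @return a logical height x width matrix, \code{TRUE} = foreground
#' @examples
#' px <- array(c(0, 255, 0), dim = c(1, 1, 3))
#' segmentHSV(rgbToHSV(px), hsvThresholds())   # green is inside the window
#' @export
segmentHSV <- function(hsv, thresholds = hsvThresholds()) {
  stopifnot(length(dim(hsv)) == 3L, dim(hsv)[3] == 3L)
  validObject(thresholds)
  nr <- dim(hsv)[1]; nc <- dim(hsv)[2]
  hh <- matrix(hsv[, , 1], nr, nc)
  ss <- matrix(hsv[, , 2], nr, nc)
  vv <- matrix(hsv[, , 3], nr, nc)
  (hh >= thresholds@hLo & hh <= thresholds@hHi &
   ss >= thresholds@sLo & ss <= thresholds@sHi &
   vv >= thresholds@vLo & vv <= thresholds@vHi)
}
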