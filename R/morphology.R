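## 3x3 grayscale erosion (8-connected min filter) with replicated borders
erode3x3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up    <- m[c(1L, seq_len(h - 1L)), , drop = FALSE]
  down  <- m[c(seq_len(h - 1L) + 1L, h), , drop = FALSE]
  r3 <- pmin(m, up, down)
  left  <- r3[, c(1L, seq_len(w - 1L)), drop = FALSE]
  right <- r3[, c(seq_len(w - 1L) + 1L, w), drop = FALSE]
  pmin(r3, left, right)
}

#' Grayscale reconstruction by erosion
#'
#' The largest image above `mask` reachable from `marker` by repeated
#' conditional 8-connected erosion (the fixed point of
#' \code{rec <- pmax(erode3x3(rec), mask)}). Requires
#' \code{marker >= mask} everywhere. Computed with alternating raster
#' sweeps in compiled code.
#'
#' @param marker,mask numeric matrices of equal shape.
#' @return The reconstructed matrix.
#' @export
reconstruct_by_erosion <- function(marker, mask) {
  stopifnot(identical(dim(marker), dim(mask)))
  if (any(marker < mask)) stop("marker must dominate mask")
  .reconstruct_erode_cpp(marker, mask)
}

#' H-minima transform
#'
#' Suppresses all regional minima of depth less than `h` (and reduces the
#' depth of the others by `h`) via reconstruction by erosion of
#' \code{plane + h} over \code{plane}.
#'
#' @param plane numeric matrix.
#' @param h minima depth threshold (same units as the plane).
#' @return The transformed matrix.
#' @export
hmin_transform <- function(plane, h) {
  stopifnot(h >= 0)
  reconstruct_by_erosion(plane + h, plane)
}

#' Extended regional minima
#'
#' Connected components where the image sits at least `h` below all
#' escape routes: the regional minima of the h-minima transform. The
#' plane is quantized to `levels` gray levels over its own range before
#' the morphological reconstruction (regional minima of a float image are
#' defined through its quantized level sets). A regional minimum must
#' have an external boundary of strictly greater values; when `h`
#' exceeds every basin depth the transform flattens and the candidate
#' "minimum" is the whole plane, which has no boundary and is therefore
#' rejected (no marks).
#'
#' @param plane numeric matrix.
#' @param h depth threshold on the plane's original scale.
#' @param levels quantization levels (default 1024).
#' @return Logical matrix marking the extended minima.
#' @export
extended_minima <- function(plane, h, levels = 1024L) {
  rng <- range(plane)
  if (!all(is.finite(rng)) || rng[2] - rng[1] <= 0)
    return(array(FALSE, dim(plane)))
  q <- round((plane - rng[1]) / (rng[2] - rng[1]) * (levels - 1L))
  hq <- round(h / (rng[2] - rng[1]) * (levels - 1L))
  if (hq < 1L) hq <- 1L
  g <- reconstruct_by_erosion(q + hq, q)          # h-minima transform
  rm <- reconstruct_by_erosion(g + 1, g) - g > 0  # regional minima of g
  if (all(rm)) rm[] <- FALSE                      # whole-plane: no boundary
  rm
}
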