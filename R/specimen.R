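## disc structuring element of given radius (EBImage brush)
disc_brush <- function(radius) EBImage::makeBrush(2L * as.integer(radius) + 1L, "disc")

#' Otsu threshold of a plane
#'
#' Gray-level threshold maximizing the between-class variance over all
#' split points of a `levels`-bin histogram of the plane (binned over its
#' own range; values at the upper range edge fall in the last bin). The
#' dark class is `plane < threshold`; the returned threshold is the upper
#' edge of the last dark bin, and ties take the lowest split. Returns
#' `NA` for a constant plane, where the threshold is undefined.
#'
#' @param plane numeric matrix.
#' @param levels number of histogram bins (default 256, 8-bit).
#' @return The threshold on the plane's original scale, or `NA`.
#' @export
otsu_threshold <- function(plane, levels = 256L) {
  rng <- range(plane)
  if (!all(is.finite(rng)) || rng[2] - rng[1] <= 0) return(NA_real_)
  b <- pmin(floor((as.numeric(plane) - rng[1]) / (rng[2] - rng[1]) * levels) + 1L,
            levels)
  p <- tabulate(b, nbins = levels) / length(b)
  idx <- seq_len(levels)
  w0 <- cumsum(p)[-levels]
  m0 <- cumsum(p * idx)[-levels]
  mt <- sum(p * idx)
  sb <- ifelse(w0 > 0 & w0 < 1, (mt * w0 - m0)^2 / (w0 * (1 - w0)), -Inf)
  k <- which.max(sb)
  rng[1] + k * (rng[2] - rng[1]) / levels
}

#' Opening-based brightness equalization
#'
#' Divides each RGB channel by a morphological background estimate
#' obtained with a large disk (default radius 100 px): the grayscale
#' opening of the absorbance image, i.e. the operation that removes dark
#' (absorbing, specimen-side) structures smaller than the disk while
#' following slow illumination trends. In transmitted-light polarity this
#' is a dilation followed by an erosion. After equalization, bright glass
#' sits near 1 and absorbing tissue below 1, independent of the global
#' illumination level (a multiplicative illumination change cancels).
#'
#' @param img an [rgb_image] at working resolution.
#' @param disk_radius structuring-element radius in pixels at this
#'   resolution (default 100).
#' @param eps floor applied to the background estimate before division.
#' @return A list of three real-valued matrices (`R`, `G`, `B`).
#' @export
brightness_equalize <- function(img, disk_radius = 100L, eps = 1e-6) {
  stopifnot(inherits(img, "rgb_image"))
  if (any(dim(img) <= 2L * disk_radius))
    stop("image smaller than the structuring element")
  brush <- disc_brush(disk_radius)
  eq <- lapply(1:3, function(k) {
    ch <- img$pixels[, , k] / 255
    bg <- EBImage::closing(ch, brush)
    ch / pmax(bg, eps)
  })
  names(eq) <- c("R", "G", "B")
  eq
}

#' Threshold equalized channels into a raw tissue mask
#'
#' Computes an Otsu threshold independently on the equalized B and R
#' channels; per channel, tissue is the below-threshold (darker than
#' glass) side. The final mask is the union of the two channel masks
#' (union maximizes tissue recall; downstream hemorrhage removal handles
#' false positives). A constant channel contributes an empty mask with a
#' warning.
#'
#' @param equalized list of equalized channel matrices from
#'   [brightness_equalize()].
#' @return Logical matrix (TRUE = tissue).
#' @export
tissue_threshold <- function(equalized) {
  one <- function(ch, name) {
    th <- otsu_threshold(ch)
    if (is.na(th)) {
      warning("channel ", name, " is constant; threshold undefined, contributing empty mask")
      return(array(FALSE, dim(ch)))
    }
    ch < th
  }
  one(equalized$B, "B") | one(equalized$R, "R")
}

#' Morphological cleanup of a binary mask
#'
#' Erosion, then dilation (both with small disks), then hole filling.
#' Components smaller than the erosion element vanish; enclosed holes are
#' filled.
#'
#' @param mask logical/0-1 matrix.
#' @param erosion_radius,dilation_radius disk radii in pixels (default 2).
#' @param fill_holes fill enclosed background holes (default TRUE).
#' @return Logical matrix.
#' @export
clean_mask <- function(mask, erosion_radius = 2L, dilation_radius = 2L,
                       fill_holes = TRUE) {
  m <- (mask > 0) * 1
  if (erosion_radius >= 1L) m <- EBImage::erode(m, disc_brush(erosion_radius))
  if (dilation_radius >= 1L) m <- EBImage::dilate(m, disc_brush(dilation_radius))
  if (fill_holes) m <- EBImage::fillHull(m)
  m > 0
}

#' Build the specimen map of a working-resolution slide image
#'
#' Composition of opening-based brightness equalization, Otsu thresholding
#' of the B and R channels, and morphological cleanup; yields the binary
#' tissue mask on which hot spots are sought.
#'
#' @param img an [rgb_image] at working (downsampled) resolution.
#' @param opening_radius equalization disk radius (default 100 px).
#' @param erosion_radius,dilation_radius cleanup disk radii (default 2 px).
#' @param fill_holes fill enclosed holes (default TRUE).
#' @return An object of class \code{specimen_map}: list with the logical
#'   `mask`, `working_downsample`, and the `provenance` of applied steps.
#' @export
build_specimen_map <- function(img, opening_radius = 100L,
                               erosion_radius = 2L, dilation_radius = 2L,
                               fill_holes = TRUE) {
  eq <- brightness_equalize(img, disk_radius = opening_radius)
  raw <- tissue_threshold(eq)
  mask <- clean_mask(raw, erosion_radius, dilation_radius, fill_holes)
  structure(list(mask = mask,
                 working_downsample = img$downsample,
                 provenance = c(
                   sprintf("brightness_equalize(disk_radius=%d)", opening_radius),
                   "tissue_threshold(otsu B|R, below-threshold)",
                   sprintf("clean_mask(erosion=%d, dilation=%d, fill_holes=%s)",
                           erosion_radius, dilation_radius, fill_holes))),
            class = "specimen_map")
}

#' @export
print.specimen_map <- function(x, ...) {
  cat(sprintf("<specimen_map> %d x %d at downsample %d; tissue fraction %.3f\n",
              nrow(x$mask), ncol(x$mask), x$working_downsample, mean(x$mask)))
  for (p in x$provenance) cat("  -", p, "\n")
  invisible(x)
}
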