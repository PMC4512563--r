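#' RGB image with physical resolution metadata
#'
#' Container for an 8-bit RGB raster together with its physical pixel size
#' and its downsample factor relative to the full-resolution (level-0)
#' scan. All package geometry is 0-based, (row, col), with half-open
#' rectangles \code{[row, row+h) x [col, col+w)} and the origin at the
#' top-left pixel.
#'
#' @param pixels numeric array of dimension \code{c(H, W, 3)}, values in
#'   \code{[0, 255]}.
#' @param mpp_x,mpp_y physical resolution in micrometers per pixel at
#'   level 0 (full resolution).
#' @param downsample integer >= 1; downsample factor of this raster
#'   relative to level 0.
#' @return An object of class \code{rgb_image}.
#' @export
rgb_image <- function(pixels, mpp_x = 0.279, mpp_y = mpp_x, downsample = 1L) {
  pixels <- as.array(pixels)
  if (length(dim(pixels)) == 2L) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L,
            mpp_x > 0, mpp_y > 0, downsample >= 1)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]")
  structure(list(pixels = pixels, mpp_x = mpp_x, mpp_y = mpp_y,
                 downsample = as.integer(downsample)),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image> %d x %d px, %.4g x %.4g um/px (level 0), downsample %d\n",
              d[1], d[2], x$mpp_x, x$mpp_y, x$downsample))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$pixels)[1:2]

#' Read a slide or tile image from disk
#'
#' Reads a plain RGB tile (PNG or TIFF). Plain tiles carry no embedded
#' physical resolution, so micrometers-per-pixel are supplied by the
#' caller (default 0.279 um/px, a common 400x brightfield scan
#' resolution).
#'
#' @param path file path to a PNG or TIFF image.
#' @param mpp_x,mpp_y physical resolution in um/px at level 0.
#' @param downsample downsample factor of the stored raster.
#' @return An [rgb_image].
#' @export
read_slide_image <- function(path, mpp_x = 0.279, mpp_y = mpp_x, downsample = 1L) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  ## EBImage stores (x = col, y = row); transpose to (row, col)
  a <- aperm(a, c(2L, 1L, 3L))
  rgb_image(round(a * 255), mpp_x = mpp_x, mpp_y = mpp_y, downsample = downsample)
}

#' Write an RGB image to disk
#'
#' @param img an [rgb_image].
#' @param path output path; format chosen from the file extension
#'   (PNG or TIFF).
#' @return `path`, invisibly.
#' @export
write_slide_image <- function(img, path) {
  a <- aperm(img$pixels / 255, c(2L, 1L, 3L))
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}

#' Axis-aligned field rectangle in level-0 pixel coordinates
#'
#' @param row,col 0-based origin (top-left corner) in level-0 pixels.
#' @param width,height extent in pixels at the target level.
#' @param level_downsample downsample factor of the level the width/height
#'   refer to (1 = full resolution).
#' @return An object of class \code{field_geometry}.
#' @export
field_geometry <- function(row, col, width, height, level_downsample = 1L) {
  stopifnot(width >= 1, height >= 1, row >= 0, col >= 0, level_downsample >= 1)
  structure(list(row = as.numeric(row), col = as.numeric(col),
                 width = as.integer(width), height = as.integer(height),
                 level_downsample = as.integer(level_downsample)),
            class = "field_geometry")
}

#' Extract a pixel block from an image
#'
#' Crops the rectangle described by `rect` out of `img`. The rectangle
#' origin is interpreted in level-0 pixels and converted to this raster's
#' resolution through its downsample factor; width/height are interpreted
#' at the raster's resolution when `rect$level_downsample` equals
#' `img$downsample`.
#'
#' @param img an [rgb_image].
#' @param rect a [field_geometry].
#' @return The cropped [rgb_image] (resolution metadata preserved).
#' @export
read_region <- function(img, rect) {
  stopifnot(inherits(img, "rgb_image"), inherits(rect, "field_geometry"))
  ds <- img$downsample
  r0 <- rect$row / ds
  c0 <- rect$col / ds
  if (abs(r0 - round(r0)) > 1e-9 || abs(c0 - round(c0)) > 1e-9)
    stop("rect origin does not fall on a pixel boundary at this level")
  r0 <- round(r0); c0 <- round(c0)
  scale <- rect$level_downsample / ds
  w <- rect$width * scale
  h <- rect$height * scale
  d <- dim(img$pixels)
  if (r0 < 0 || c0 < 0 || r0 + h > d[1] || c0 + w > d[2])
    stop("requested region lies outside the image bounds")
  rgb_image(img$pixels[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w), , drop = FALSE],
            mpp_x = img$mpp_x, mpp_y = img$mpp_y, downsample = ds)
}

## block-mean reduction of a matrix; ceil(dim/f) output, partial edge
## blocks averaged over the pixels they actually contain
block_reduce <- function(m, f) {
  if (f == 1L) return(m)
  h <- nrow(m); w <- ncol(m)
  ri <- ceiling(seq_len(h) / f)
  ci <- ceiling(seq_len(w) / f)
  sums <- rowsum(m, ri)                      # collapse rows
  sums <- t(rowsum(t(sums), ci))             # collapse cols
  cnt <- tcrossprod(tabulate(ri), tabulate(ci))
  sums / cnt
}

#' Downsample an image by block averaging
#'
#' Each output pixel is the mean of the corresponding `factor x factor`
#' block (anti-aliased reduction); partial blocks at the bottom/right edge
#' average over the pixels present. Output dimensions are
#' \code{ceiling(dim / factor)} and the stored downsample factor is scaled
#' accordingly.
#'
#' @param img an [rgb_image].
#' @param factor integer >= 1.
#' @return The reduced [rgb_image].
#' @export
downsample <- function(img, factor) {
  stopifnot(inherits(img, "rgb_image"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer")
  if (factor == 1L) return(img)
  px <- img$pixels
  out <- lapply(1:3, function(k) block_reduce(px[, , k], factor))
  rgb_image(array(unlist(out), c(dim(out[[1]]), 3L)),
            mpp_x = img$mpp_x, mpp_y = img$mpp_y,
            downsample = img$downsample * factor)
}

#' Extract one channel of an RGB image as a plane
#'
#' @param img an [rgb_image].
#' @param channel one of `"R"`, `"G"`, `"B"`, `"gray"`.
#' @return A numeric matrix on the 0--255 scale.
#' @export
channel_plane <- function(img, channel = c("R", "G", "B", "gray")) {
  channel <- match.arg(channel)
  px <- img$pixels
  d <- dim(px)
  m <- function(k) matrix(px[, , k], d[1], d[2])
  switch(channel,
         R = m(1), G = m(2), B = m(3),
         gray = (m(1) + m(2) + m(3)) / 3)
}

#' Convert RGB to naive CMYK planes
#'
#' Device-naive conversion on unit-scaled channels:
#' \eqn{K = 1 - \max(r, g, b)}, \eqn{C = (1 - r - K) / (1 - K)} and
#' analogously for M and Y; where \eqn{K = 1} (pure black) C, M and Y are
#' defined as 0. No ICC color management is attempted.
#'
#' @param img an [rgb_image].
#' @return A list of matrices `C`, `M`, `Y`, `K`, each in \code{[0, 1]}.
#' @export
rgb_to_cmyk <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  d <- dim(img$pixels)
  r <- matrix(img$pixels[, , 1], d[1], d[2]) / 255
  g <- matrix(img$pixels[, , 2], d[1], d[2]) / 255
  b <- matrix(img$pixels[, , 3], d[1], d[2]) / 255
  K <- 1 - pmax(r, g, b)
  denom <- 1 - K
  safe <- ifelse(denom > 0, denom, 1)
  C <- ifelse(denom > 0, (1 - r - K) / safe, 0)
  M <- ifelse(denom > 0, (1 - g - K) / safe, 0)
  Y <- ifelse(denom > 0, (1 - b - K) / safe, 0)
  list(C = C, M = M, Y = Y, K = K)
}

#' Extract the CIE Luv u* plane of an image
#'
#' Standard sRGB -> XYZ (D65) -> CIE Luv conversion; returns the u*
#' component, \eqn{u^* = 13 L^* (u' - u'_n)}. u* is strongly tied to
#' red/brown content, which makes it a convenient single channel for
#' locating DAB-stained (immunopositive) nuclei against hematoxylin blue.
#'
#' @param img an [rgb_image].
#' @return A numeric matrix (u* values; 0 for black and for neutral gray).
#' @export
rgb_to_luv_u <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  d <- dim(img$pixels)
  rgb <- matrix(img$pixels, ncol = 3L) / 255
  luv <- grDevices::convertColor(rgb, from = "sRGB", to = "Luv")
  matrix(luv[, 2], d[1], d[2])
}

## min-max normalize a plane to [0,1]; constant planes map to 0
minmax01 <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] <= 0) return(array(0, dim(m)))
  (m - rng[1]) / (rng[2] - rng[1])
}

#' Combined u (Luv) + C (CMYK) plane
#'
#' Min-max normalizes each input plane to \code{[0, 1]} over the whole
#' image and returns their sum (range \code{[0, 2]}); constant planes
#' normalize to 0. This composite channel accentuates DAB brown, which is
#' high in both u* and cyan-complement terms.
#'
#' @param u u* plane from [rgb_to_luv_u()].
#' @param c_plane C plane from [rgb_to_cmyk()].
#' @return A numeric matrix.
#' @export
combined_u_plus_c <- function(u, c_plane) {
  if (!identical(dim(u), dim(c_plane))) stop("u and C planes differ in shape")
  minmax01(u) + minmax01(c_plane)
}

#' Physical area of a field of view in square millimeters
#'
#' @param geom a [field_geometry] (width/height at its stated level).
#' @param mpp_x,mpp_y level-0 resolution in um/px.
#' @return Area in mm^2:
#'   \code{width * height * downsample^2 * mpp_x * mpp_y / 1e6}.
#' @examples
#' fov_area_mm2(field_geometry(0, 0, 1424, 1064), 0.279)   # ~0.12 mm^2
#' @export
fov_area_mm2 <- function(geom, mpp_x, mpp_y = mpp_x) {
  stopifnot(inherits(geom, "field_geometry"), mpp_x > 0, mpp_y > 0)
  ds <- geom$level_downsample
  geom$width * geom$height * ds^2 * mpp_x * mpp_y / 1e6
}

#' Read or write field-set tables
#'
#' Field sets are stored as CSV with columns
#' `slide_id, field_idx, row, col, width, height, ki67_pct`
#' (coordinates in level-0 pixels, 0-based origin).
#'
#' @param path CSV path.
#' @return `read_fieldsets`: a data.frame with the columns above.
#' @export
read_fieldsets <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("slide_id", "field_idx", "row", "col", "width", "height", "ki67_pct")
  if (!all(need %in% names(df)))
    stop("field-set CSV must contain columns: ", paste(need, collapse = ", "))
  df[need]
}

#' @rdname read_fieldsets
#' @param fields data.frame in the field-set layout.
#' @export
write_fieldsets <- function(fields, path) {
  utils::write.csv(fields, path, row.names = FALSE)
  invisible(path)
}
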