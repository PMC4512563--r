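#' Locate hot spots and select fields of quantification on a slide
#'
#' End-to-end pipeline: the slide is reduced to working resolution by
#' block averaging; the specimen map is built (brightness equalization,
#' Otsu thresholding of B and R, morphological cleanup); optionally a
#' trained texture classifier removes hemorrhage areas; immunopositive
#' marks are detected as extended regional minima of the negated u*
#' plane; the mark density map is formed; and fields are selected
#' greedily under the spatial dispersion penalty.
#'
#' @param slide a level-0 [rgb_image].
#' @param fov_width,fov_height field-of-view extent in level-0 pixels.
#' @param working_downsample resolution reduction factor (default 8).
#' @param n number of fields to select (default 20).
#' @param rho dispersion penalty strength (default 0.2).
#' @param classifier optional \code{texture_classifier} for hemorrhage
#'   exclusion (NULL skips the exclusion step).
#' @param opening_radius brightness-equalization disk radius at working
#'   resolution (default 100 px; scale down for small slides).
#' @param h_frac extended-minima depth fraction (default 0.1).
#' @param tumor_cover minimum tissue coverage of a field (default 0.8).
#' @param stride candidate grid stride at working resolution (default 1).
#' @param block classifier patch size at working resolution (default 32).
#' @return Object of class \code{hotspot_selection}: the `selection`
#'   (\code{field_selection}), `specimen_map`, `density` map, `marks`,
#'   the `working_image`, and the call parameters.
#' @export
find_hotspots <- function(slide, fov_width, fov_height = fov_width,
                          working_downsample = 8L, n = 20L, rho = 0.2,
                          classifier = NULL, opening_radius = 100L,
                          h_frac = 0.1, tumor_cover = 0.8, stride = 1L,
                          block = 32L) {
  stopifnot(inherits(slide, "rgb_image"))
  wimg <- downsample(slide, working_downsample)
  map <- build_specimen_map(wimg, opening_radius = opening_radius)
  hem_frac <- 0
  if (!is.null(classifier)) {
    stack <- build_feature_bank(wimg)
    hemmask <- classify_map(stack, map, classifier, block = block)
    hem_frac <- if (any(map$mask)) sum(hemmask) / sum(map$mask) else 0
    map <- exclude_hemorrhage(map, hemmask)
  }
  u <- rgb_to_luv_u(wimg)
  marks <- immunopositive_marks(u, map, h_frac = h_frac)
  fw <- fov_width / working_downsample
  fh <- fov_height / working_downsample
  dmap <- density_map(marks, fov_width = fw, fov_height = fh)
  sel <- select_fields(dmap, map, n = n, rho = rho, fov_width = fw,
                       fov_height = fh, tumor_cover = tumor_cover,
                       stride = stride)
  structure(list(selection = sel, specimen_map = map, density = dmap,
                 marks = marks, working_image = wimg,
                 hemorrhage_fraction = hem_frac,
                 params = list(fov_width = fov_width, fov_height = fov_height,
                               working_downsample = working_downsample,
                               n = n, rho = rho, opening_radius = opening_radius,
                               h_frac = h_frac, tumor_cover = tumor_cover,
                               stride = stride)),
            class = "hotspot_selection")
}

#' @export
print.hotspot_selection <- function(x, ...) {
  cat(sprintf("<hotspot_selection> %d field(s) on a %d x %d working raster\n",
              nrow(x$selection$fields), nrow(x$specimen_map$mask),
              ncol(x$specimen_map$mask)))
  cat(sprintf("  tissue fraction %.3f | %d immunopositive mark(s) | rho = %.3g\n",
              mean(x$specimen_map$mask), x$marks$mark_count, x$params$rho))
  invisible(x)
}

#' @export
summary.hotspot_selection <- function(object, ...) {
  f <- object$selection$fields
  cat("Hot-spot field selection\n")
  cat(sprintf("  working downsample : %d\n", object$params$working_downsample))
  cat(sprintf("  FOV (level 0)      : %d x %d px\n",
              object$params$fov_width, object$params$fov_height))
  cat(sprintf("  rho                : %.3g\n", object$params$rho))
  cat(sprintf("  tissue fraction    : %.3f\n", mean(object$specimen_map$mask)))
  cat(sprintf("  hemorrhage excluded: %.1f%% of tissue\n",
              100 * object$hemorrhage_fraction))
  cat(sprintf("  marks / fields     : %d / %d\n",
              object$marks$mark_count, nrow(f)))
  if (nrow(f)) {
    cat("  density score range:",
        sprintf("%.4g .. %.4g\n", min(f$density_score), max(f$density_score)))
  }
  invisible(object)
}

#' Plot a hot-spot selection
#'
#' Renders the working-resolution image with the selected field
#' rectangles outlined.
#'
#' @param x a \code{hotspot_selection}.
#' @param ... passed to [graphics::rasterImage()] setup (unused).
#' @export
plot.hotspot_selection <- function(x, ...) {
  px <- x$working_image$pixels / 255
  h <- dim(px)[1]; w <- dim(px)[2]
  ras <- grDevices::as.raster(px)
  graphics::plot(c(0, w), c(0, h), type = "n", asp = 1,
                 xlab = "col (working px)", ylab = "row (working px)",
                 xaxs = "i", yaxs = "i")
  graphics::rasterImage(ras, 0, 0, w, h)
  f <- x$selection$fields
  fw <- x$params$fov_width / x$params$working_downsample
  fh <- x$params$fov_height / x$params$working_downsample
  if (nrow(f))
    graphics::rect(f$center_col - fw / 2, h - (f$center_row + fh / 2),
                   f$center_col + fw / 2, h - (f$center_row - fh / 2),
                   border = "black", lwd = 2)
  invisible(x)
}
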