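## Ruifrok-Johnston H-DAB optical-density stain vectors (rows, unit norm)
hdab_stain_matrix <- function() {
  H <- c(0.650, 0.704, 0.286)
  D <- c(0.269, 0.568, 0.778)
  R <- c(H[2] * D[3] - H[3] * D[2],
         H[3] * D[1] - H[1] * D[3],
         H[1] * D[2] - H[2] * D[1])
  rbind(H = H / sqrt(sum(H^2)),
        DAB = D / sqrt(sum(D^2)),
        Res = R / sqrt(sum(R^2)))
}

#' Color-deconvolve an RGB field into H and DAB stain channels
#'
#' Converts pixels to optical density (\eqn{-\log_{10}((v + 1)/256)}) and
#' unmixes with the published hematoxylin/DAB stain vectors.
#'
#' @param img an [rgb_image] (full-resolution field).
#' @return List of matrices `H`, `DAB` (stain concentrations, >= 0
#'   clipped).
#' @export
stain_deconvolve <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  d <- dim(img$pixels)
  od <- -log10((matrix(img$pixels, ncol = 3L) + 1) / 256)
  conc <- od %*% solve(hdab_stain_matrix())
  list(H = matrix(pmax(conc[, 1], 0), d[1], d[2]),
       DAB = matrix(pmax(conc[, 2], 0), d[1], d[2]))
}

## segment one stain channel: smooth, Otsu, fill, watershed-split, count
segment_channel <- function(conc, min_area, min_signal, sigma = 1) {
  if (max(conc) < min_signal)
    return(list(mask = array(FALSE, dim(conc)), labels = array(0, dim(conc)), n = 0L))
  sm <- EBImage::gblur(conc, sigma = sigma)
  th <- otsu_threshold(sm)
  ## sparse stain: Otsu may split the background; never threshold below
  ## the minimum stain concentration
  th <- max(if (is.na(th)) -Inf else th, min_signal)
  mask <- sm > th
  mask <- EBImage::fillHull(mask * 1) > 0
  dm <- EBImage::distmap(mask * 1)
  lab <- EBImage::watershed(dm, tolerance = 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  labs <- array(0, dim(lab))
  n <- 0L
  for (k in keep) { n <- n + 1L; labs[lab == k] <- n }
  list(mask = labs > 0, labels = labs, n = n)
}

#' Count immunopositive and immunonegative nuclei in a field
#'
#' A self-contained nucleus counter used to score selected fields: the
#' field is color-deconvolved into DAB and hematoxylin concentration
#' channels; each channel is smoothed, Otsu-thresholded, hole-filled and
#' split by a distance-transform watershed; components above a minimum
#' area are counted. DAB components are immunopositive; hematoxylin
#' components that do not substantially overlap the DAB mask are
#' immunonegative. Staining intensity is deliberately not graded. Any
#' counter with the same contract (field image in, positive/negative
#' counts out) can be substituted in [score_slide()].
#'
#' @param field_img full-resolution [rgb_image] of one field.
#' @param min_area minimum nucleus area in pixels (default 16).
#' @param min_signal minimum stain concentration (optical density) for a
#'   channel to be considered present (default 0.4).
#' @return List of class \code{nucleus_count} with integers `positive`,
#'   `negative`, `total`.
#' @export
segment_and_classify <- function(field_img, min_area = 16L, min_signal = 0.4) {
  stopifnot(inherits(field_img, "rgb_image"))
  dec <- stain_deconvolve(field_img)
  dab <- segment_channel(dec$DAB, min_area, min_signal)
  hem <- segment_channel(dec$H, min_area, min_signal)
  pos <- dab$n
  neg <- 0L
  if (hem$n > 0L) {
    for (k in seq_len(hem$n)) {
      px <- hem$labels == k
      if (mean(dab$mask[px]) < 0.5) neg <- neg + 1L
    }
  }
  structure(list(positive = as.integer(pos), negative = as.integer(neg),
                 total = as.integer(pos + neg)),
            class = "nucleus_count")
}

#' Ki-67 index of a nucleus count
#'
#' \eqn{100 \cdot positive / (positive + negative)}: the percentage of
#' immunopositive nuclei among all counted nuclei.
#'
#' @param count a \code{nucleus_count} (or list with `positive`,
#'   `negative`).
#' @return Percent in \code{[0, 100]}; `NA` with a warning when no nuclei
#'   were counted.
#' @export
ki67_index <- function(count) {
  pos <- count$positive; neg <- count$negative
  stopifnot(pos >= 0, neg >= 0)
  if (pos + neg == 0L) {
    warning("no nuclei counted; Ki-67 index undefined")
    return(NA_real_)
  }
  100 * pos / (pos + neg)
}

#' Score every selected field and aggregate to a slide Ki-67 index
#'
#' Maps each selected field to full-resolution coordinates, crops it from
#' the slide, counts nuclei with `counter`, writes the per-field index
#' back into the selection, and averages the per-field indices into the
#' slide score. Fields that cannot be read or contain no nuclei are
#' recorded as missing and excluded from the mean with a warning.
#'
#' @param selection a \code{field_selection}.
#' @param slide the level-0 [rgb_image] the selection refers to.
#' @param counter function(field [rgb_image]) -> \code{nucleus_count};
#'   default [segment_and_classify()].
#' @param ... passed to `counter`.
#' @return List of class \code{ki67_score}: data.frame `per_field`
#'   (field rank, counts, index) and `slide_mean_pct`.
#' @export
score_slide <- function(selection, slide, counter = segment_and_classify, ...) {
  stopifnot(inherits(selection, "field_selection"), inherits(slide, "rgb_image"))
  lv0 <- selection_to_level0(selection)
  if (!nrow(lv0)) stop("selection contains no fields")
  per <- data.frame(rank = lv0$rank, positive = NA_integer_,
                    negative = NA_integer_, index_pct = NA_real_)
  for (i in seq_len(nrow(lv0))) {
    cnt <- tryCatch({
      geom <- field_geometry(max(lv0$row[i], 0), max(lv0$col[i], 0),
                             lv0$width[i], lv0$height[i])
      counter(read_region(slide, geom), ...)
    }, error = function(e) NULL)
    if (is.null(cnt)) next
    per$positive[i] <- cnt$positive
    per$negative[i] <- cnt$negative
    per$index_pct[i] <- suppressWarnings(ki67_index(cnt))
  }
  ok <- is.finite(per$index_pct)
  if (!all(ok)) warning(sum(!ok), " field(s) unscorable; excluded from the slide mean")
  structure(list(per_field = per,
                 slide_mean_pct = if (any(ok)) mean(per$index_pct[ok]) else NA_real_),
            class = "ki67_score")
}

#' @export
print.ki67_score <- function(x, ...) {
  cat(sprintf("<ki67_score> %d field(s); slide mean Ki-67 = %.2f%%\n",
              nrow(x$per_field), x$slide_mean_pct))
  invisible(x)
}
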