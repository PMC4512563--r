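#' Detect immunopositive-cell marks on the u channel
#'
#' DAB-brown nuclei carry the highest u* (red-associated) values in the
#' slide, so the brownness plane is taken as negated u* and its extended
#' regional minima --- pits of depth at least \code{h_frac} times the
#' dynamic range of the plane within tissue --- mark the stained objects.
#' Marks are restricted to the specimen map; each connected component is
#' one mark.
#'
#' @param u u* plane from [rgb_to_luv_u()] at working resolution.
#' @param map a \code{specimen_map} of the same shape.
#' @param h_frac minima depth as a fraction of the within-tissue dynamic
#'   range (default 0.1).
#' @return List with the logical `marks` raster, the labeled `labels`
#'   matrix, a `centroids` matrix (row, col, 0-based), and `mark_count`.
#' @export
immunopositive_marks <- function(u, map, h_frac = 0.1) {
  stopifnot(inherits(map, "specimen_map"), identical(dim(u), dim(map$mask)))
  msk <- map$mask
  empty <- list(marks = array(FALSE, dim(u)),
                labels = array(0, dim(u)),
                centroids = matrix(numeric(0), 0, 2,
                                   dimnames = list(NULL, c("row", "col"))),
                mark_count = 0L)
  if (!any(msk)) return(empty)
  brown <- -u
  rng <- range(brown[msk])
  if (rng[2] - rng[1] <= 0) return(empty)
  ## clamp to the within-tissue range (keeps natural pixel noise, which
  ## bounds reconstruction propagation); marks are intersected with the
  ## specimen map afterwards, so out-of-tissue minima never survive
  brown <- pmin(pmax(brown, rng[1]), rng[2])
  h <- h_frac * (rng[2] - rng[1])
  em <- extended_minima(brown, h) & msk
  lab <- EBImage::bwlabel(em * 1)
  n <- max(lab)
  if (n == 0L) return(empty)
  idx <- which(lab > 0, arr.ind = TRUE)
  cen <- cbind(row = tapply(idx[, 1] - 1, lab[lab > 0], mean),
               col = tapply(idx[, 2] - 1, lab[lab > 0], mean))
  list(marks = em, labels = lab, centroids = cen, mark_count = as.integer(n))
}

#' Immunopositive-cell density map
#'
#' Places a unit impulse at each mark centroid and convolves with a
#' normalized disk kernel of radius half the field-of-view diagonal at
#' working resolution. Impulses near the image border are re-weighted by
#' the in-bounds kernel mass so that every mark contributes exactly 1 and
#' the map sums to the mark count.
#'
#' @param marks result of [immunopositive_marks()] (or any list with a
#'   `centroids` matrix).
#' @param fov_width,fov_height field-of-view extent in working-resolution
#'   pixels.
#' @param shape output raster dimension \code{c(H, W)}.
#' @return List of class \code{density_map}: `values` matrix,
#'   `kernel_radius`, `mark_count`.
#' @export
density_map <- function(marks, fov_width, fov_height = fov_width, shape = NULL) {
  cen <- marks$centroids
  if (is.null(shape)) shape <- dim(marks$marks)
  radius <- max(1L, round(sqrt(fov_width^2 + fov_height^2) / 2))
  vals <- array(0, shape)
  n <- nrow(cen)
  if (n > 0L) {
    imp <- array(0, shape)
    ri <- pmin(pmax(round(cen[, 1]) + 1L, 1L), shape[1])
    ci <- pmin(pmax(round(cen[, 2]) + 1L, 1L), shape[2])
    for (i in seq_len(n)) imp[ri[i], ci[i]] <- imp[ri[i], ci[i]] + 1
    K <- disk_mask(radius)
    K <- K / sum(K)
    covered <- EBImage::filter2(array(1, shape), K, boundary = 0)
    w <- imp / pmax(covered, 1e-12)     # border re-weighting, kernel symmetric
    vals <- EBImage::filter2(w, K, boundary = 0)
    vals[vals < 0] <- 0
  }
  structure(list(values = vals, kernel_radius = radius, mark_count = n),
            class = "density_map")
}

#' Spatial dispersion penalty for a candidate field
#'
#' \deqn{penalty = 1 - \rho \sum_i \frac{1}{\sqrt{(x - x_i)^2 + (y - y_i)^2}}}
#' with distances measured in field-of-view widths, clipped below at 0.
#' With no selected fields the penalty is 1; it decreases as selected
#' fields crowd the candidate, which spreads successive selections across
#' hot spots while still letting a dominant hot spot host several fields.
#'
#' @param candidate numeric pair (row, col) of the candidate center.
#' @param selected matrix/list of previously selected centers (rows of
#'   (row, col)); may be empty.
#' @param rho dispersion strength (default 0.2, dimensionless).
#' @param fov_width field width in the same pixel units as the centers.
#' @return Penalty in \code{[0, 1]}.
#' @export
dispersion_penalty <- function(candidate, selected, rho = 0.2, fov_width = 1) {
  stopifnot(rho >= 0, fov_width > 0)
  if (is.null(selected) || NROW(selected) == 0L) return(1)
  selected <- matrix(as.numeric(unlist(selected)), ncol = 2, byrow = is.list(selected))
  d <- sqrt((candidate[1] - selected[, 1])^2 + (candidate[2] - selected[, 2])^2) / fov_width
  if (any(d == 0)) stop("candidate coincides with an already-selected center")
  max(0, 1 - rho * sum(1 / d))
}

## overlap fraction of two equal axis-aligned rectangles given center offsets
rect_overlap_frac <- function(dr, dc, h, w) {
  pmax(0, h - abs(dr)) * pmax(0, w - abs(dc)) / (h * w)
}

#' Greedy selection of fields of quantification
#'
#' Repeatedly picks the candidate center maximizing
#' \code{density x penalty} given the fields already selected. Candidates
#' are working-resolution pixel centers (optionally strided) whose field
#' rectangle lies inside the slide, is covered by the (hemorrhage-
#' excluded) specimen map at least `tumor_cover`, and overlaps no selected
#' field by more than `max_overlap`. Selection stops at `n` fields or when
#' no candidate has a positive adjusted score.
#'
#' @param dmap a \code{density_map}.
#' @param map a \code{specimen_map} aligned with it.
#' @param n maximum number of fields (default 20).
#' @param rho dispersion penalty strength (default 0.2).
#' @param fov_width,fov_height field extent in working-resolution pixels.
#' @param tumor_cover minimum tissue coverage of a field (default 0.8).
#' @param max_overlap maximum pairwise field overlap fraction
#'   (default 0.5).
#' @param stride candidate grid stride in pixels (default 1).
#' @return An object of class \code{field_selection}: data.frame `fields`
#'   (rank, center_row, center_col in working pixels, density_score) plus
#'   the selection parameters.
#' @export
select_fields <- function(dmap, map, n = 20L, rho = 0.2,
                          fov_width, fov_height = fov_width,
                          tumor_cover = 0.8, max_overlap = 0.5, stride = 1L) {
  stopifnot(inherits(dmap, "density_map"), inherits(map, "specimen_map"),
            identical(dim(dmap$values), dim(map$mask)))
  d <- dim(dmap$values)
  h2 <- fov_height / 2; w2 <- fov_width / 2

  ## tissue coverage of the field centered at each pixel: the rectangle
  ## spans offsets [-h/2, h/2) around the center. filter2 convolves
  ## (kernel flipped), so the box is placed to land on those offsets
  ## after the flip, embedded in an odd canvas as filter2 requires.
  kh <- fov_height + 1L - fov_height %% 2L
  kw <- fov_width + 1L - fov_width %% 2L
  ch <- (kh + 1L) %/% 2L; cw <- (kw + 1L) %/% 2L
  box <- matrix(0, kh, kw)
  ## offsets -floor(h/2) .. ceiling(h/2)-1 => flipped kernel rows
  ro <- ch - (ceiling(fov_height / 2) - 1L):(-floor(fov_height / 2))
  co <- cw - (ceiling(fov_width / 2) - 1L):(-floor(fov_width / 2))
  box[ro, co] <- 1 / (fov_height * fov_width)
  cov <- EBImage::filter2(map$mask * 1, box, boundary = 0)

  rows <- seq(ceiling(h2), floor(d[1] - h2), by = stride)
  cols <- seq(ceiling(w2), floor(d[2] - w2), by = stride)
  if (!length(rows) || !length(cols))
    return(empty_selection(rho, fov_width, fov_height, map$working_downsample,
                           warn = "field of view larger than the slide"))
  cr <- rep(rows, times = length(cols))
  cc <- rep(cols, each = length(rows))
  dens <- dmap$values[cbind(cr, cc)]
  eligible <- cov[cbind(cr, cc)] >= tumor_cover

  sel_r <- numeric(0); sel_c <- numeric(0); sel_s <- numeric(0)
  invd <- rep(0, length(cr))    # running sum of 1/distance to selected fields
  for (step in seq_len(n)) {
    if (!any(eligible)) break
    score <- dens * pmax(0, 1 - rho * invd)
    score[!eligible] <- -Inf
    best <- which.max(score)
    if (!is.finite(score[best]) || score[best] <= 0) break
    sel_r <- c(sel_r, cr[best]); sel_c <- c(sel_c, cc[best])
    sel_s <- c(sel_s, dens[best])
    dd <- sqrt((cr - cr[best])^2 + (cc - cc[best])^2) / fov_width
    invd <- invd + ifelse(dd > 0, 1 / dd, Inf)
    ov <- rect_overlap_frac(cr - cr[best], cc - cc[best], fov_height, fov_width)
    eligible <- eligible & ov <= max_overlap
  }
  if (!length(sel_r))
    return(empty_selection(rho, fov_width, fov_height, map$working_downsample,
                           warn = "no eligible candidate field"))
  fields <- data.frame(rank = seq_along(sel_r),
                       center_row = sel_r - 1, center_col = sel_c - 1,
                       density_score = sel_s, ki67_pct = NA_real_)
  structure(list(fields = fields, rho = rho,
                 fov_width = fov_width, fov_height = fov_height,
                 tumor_cover = tumor_cover, max_overlap = max_overlap,
                 working_downsample = map$working_downsample),
            class = "field_selection")
}

empty_selection <- function(rho, fov_width, fov_height, downsample, warn = NULL) {
  if (!is.null(warn)) warning(warn)
  structure(list(fields = data.frame(rank = integer(0), center_row = numeric(0),
                                     center_col = numeric(0),
                                     density_score = numeric(0),
                                     ki67_pct = numeric(0)),
                 rho = rho, fov_width = fov_width, fov_height = fov_height,
                 tumor_cover = NA_real_, max_overlap = NA_real_,
                 working_downsample = downsample),
            class = "field_selection")
}

#' @export
print.field_selection <- function(x, ...) {
  cat(sprintf("<field_selection> %d field(s), rho = %.3g, FOV %g x %g working px (downsample %d)\n",
              nrow(x$fields), x$rho, x$fov_width, x$fov_height,
              x$working_downsample))
  if (nrow(x$fields)) print(utils::head(x$fields, 10L))
  invisible(x)
}

#' Convert selected fields to level-0 geometry
#'
#' @param sel a \code{field_selection}.
#' @return data.frame with level-0 `row`, `col` origins and `width`,
#'   `height` extents alongside the selection columns.
#' @export
selection_to_level0 <- function(sel) {
  stopifnot(inherits(sel, "field_selection"))
  ds <- sel$working_downsample
  f <- sel$fields
  data.frame(rank = f$rank,
             row = round((f$center_row - sel$fov_height / 2) * ds),
             col = round((f$center_col - sel$fov_width / 2) * ds),
             width = round(sel$fov_width * ds),
             height = round(sel$fov_height * ds),
             density_score = f$density_score,
             ki67_pct = f$ki67_pct)
}

#' Calibrate the dispersion strength against reference selections
#'
#' Runs [select_fields()] for every value of `rho_grid` on each slide and
#' scores the result against that slide's reference field set with the
#' localization concordance measure ([lcm()]); returns the grid value
#' minimizing the mean LCM (ties broken by the smaller rho) together with
#' the full curve.
#'
#' @param slides list; each element a list with components `dmap`
#'   (\code{density_map}), `map` (\code{specimen_map}) and `reference`
#'   (an [observer_fieldset()]); optionally `ki67_fun`, a function mapping
#'   a matrix of selected centers (row, col working pixels) to per-field
#'   Ki-67 percentages, used for the curve's mean-Ki-67 column.
#' @param rho_grid numeric grid (default \code{seq(0.1, 0.5, by = 0.05)}).
#' @param fov_width,fov_height field extent in working pixels.
#' @param n fields per selection (default 20).
#' @param stride candidate stride passed to [select_fields()].
#' @param ... further arguments to [select_fields()].
#' @return List with `rho_star` and a data.frame `curve`
#'   (rho, mean_lcm, mean_ki67).
#' @export
calibrate_rho <- function(slides, rho_grid = seq(0.1, 0.5, by = 0.05),
                          fov_width, fov_height = fov_width, n = 20L,
                          stride = 1L, ...) {
  if (!length(rho_grid)) stop("rho grid is empty")
  if (!length(slides)) stop("need at least one slide with a reference field set")
  curve <- data.frame(rho = rho_grid, mean_lcm = NA_real_, mean_ki67 = NA_real_)
  for (i in seq_along(rho_grid)) {
    lcms <- numeric(0); kis <- numeric(0)
    for (sl in slides) {
      sel <- select_fields(sl$dmap, sl$map, n = n, rho = rho_grid[i],
                           fov_width = fov_width, fov_height = fov_height,
                           stride = stride, ...)
      if (!nrow(sel$fields)) next
      test <- observer_fieldset(centers = as.matrix(sel$fields[, c("center_row", "center_col")]),
                                ki67_pct = rep(NA_real_, nrow(sel$fields)),
                                observer_id = "auto", slide_id = sl$reference$slide_id)
      lcms <- c(lcms, lcm(sl$reference, test, fov_width = fov_width))
      if (!is.null(sl$ki67_fun))
        kis <- c(kis, mean(sl$ki67_fun(as.matrix(sel$fields[, c("center_row", "center_col")]))))
    }
    curve$mean_lcm[i] <- mean(lcms)
    curve$mean_ki67[i] <- if (length(kis)) mean(kis) else NA_real_
  }
  best <- which.min(curve$mean_lcm)   # which.min takes the first (smallest rho) tie
  list(rho_star = rho_grid[best], curve = curve)
}
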