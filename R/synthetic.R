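## run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

#' Named color palette of the synthetic stain rendering
#'
#' Fixed RGB anchors: DAB brown for immunopositive nuclei, hematoxylin
#' blue for immunonegative nuclei, bright glass background, pale
#' counterstained stroma, and hemorrhage red.
#'
#' @return Named list of RGB triplets (0--255).
#' @export
synth_palette <- function() {
  list(dab = c(120, 80, 40), hematoxylin = c(60, 70, 140),
       glass = c(235, 235, 240), stroma = c(216, 196, 208),
       hemorrhage = c(170, 60, 60))
}

#' Parameters of the synthetic slide generator
#'
#' Defaults describe a scaled-down study slide: a 1600 x 1600 px scan
#' (nominal 1 um/px) holding a few tissue sections with blue and brown
#' nucleus-like blobs, localized high-density hot spots, hemorrhage-
#' textured distractor patches without nuclei, and bright glass
#' background. Fields of quantification on this proxy are 128 x 128 px.
#'
#' @param slide_size c(H, W) in pixels.
#' @param mpp nominal micrometers per pixel at level 0.
#' @param fov c(height, width) of a quantification field, level-0 px.
#' @param working_downsample the analysis downsample that brings this
#'   proxy to the physical working resolution of a real 8x-reduced
#'   brightfield scan (~2.2 um/px); 2 for the 1 um/px default.
#' @param tissue_blob_count,tissue_radius number of tissue sections and
#'   their radius range in pixels.
#' @param nucleus_radius nucleus radius range in pixels.
#' @param base_density expected nuclei per field-of-view area outside hot
#'   spots.
#' @param hotspot_count,hotspot_multiplier,hotspot_radius number of hot
#'   spots, their density multiplier (>= 1) and radius in pixels.
#' @param ki67_background_pct,ki67_hotspot_pct planted immunopositive
#'   fractions (percent) outside and inside hot spots.
#' @param hemorrhage_count,hemorrhage_radius hemorrhage patch count and
#'   radius in pixels.
#' @param noise_sigma Gaussian pixel noise standard deviation (0--255
#'   scale).
#' @param seed integer seed; the slide and its ground truth are fully
#'   determined by it.
#' @return Named list of class \code{synth_params}.
#' @export
synth_params <- function(slide_size = c(1600L, 1600L), mpp = 1.0,
                         fov = c(128L, 128L), working_downsample = 2L,
                         tissue_blob_count = 3L, tissue_radius = c(300, 450),
                         nucleus_radius = c(2.5, 3.5), base_density = 100,
                         hotspot_count = 4L, hotspot_multiplier = 3,
                         hotspot_radius = 150,
                         ki67_background_pct = 5, ki67_hotspot_pct = 15,
                         hemorrhage_count = 2L, hemorrhage_radius = 90,
                         noise_sigma = 3, seed = 1L) {
  stopifnot(base_density > 0, hotspot_multiplier >= 1,
            ki67_background_pct >= 0, ki67_background_pct <= 100,
            ki67_hotspot_pct >= 0, ki67_hotspot_pct <= 100,
            noise_sigma >= 0)
  structure(as.list(environment()), class = "synth_params")
}

## disk raster helper: TRUE inside the disk (cr, cc, r), 1-based centers
fill_disk <- function(mask, cr, cc, r, value = TRUE) {
  d <- dim(mask)
  rr <- max(1L, floor(cr - r)):min(d[1], ceiling(cr + r))
  cc2 <- max(1L, floor(cc - r)):min(d[2], ceiling(cc + r))
  sub <- outer((rr - cr)^2, (cc2 - cc)^2, "+") <= r^2
  mask[rr, cc2][sub] <- value
  mask
}

## paint soft-edged nucleus disks onto three channel matrices; the whole
## loop lives in one frame so channel subassignment stays in place
render_nuclei <- function(chR, chG, chB, rows, cols, radii, colmat) {
  d <- dim(chR)
  for (i in seq_along(rows)) {
    cr <- rows[i]; cc <- cols[i]; r <- radii[i]
    rr <- max(1L, floor(cr - r - 1)):min(d[1], ceiling(cr + r + 1))
    cc2 <- max(1L, floor(cc - r - 1)):min(d[2], ceiling(cc + r + 1))
    w <- pmin(pmax(r + 0.5 - sqrt(outer((rr - cr)^2, (cc2 - cc)^2, "+")), 0), 1)
    chR[rr, cc2] <- (1 - w) * chR[rr, cc2] + w * colmat[i, 1]
    chG[rr, cc2] <- (1 - w) * chG[rr, cc2] + w * colmat[i, 2]
    chB[rr, cc2] <- (1 - w) * chB[rr, cc2] + w * colmat[i, 3]
  }
  list(chR, chG, chB)
}

## per-nucleus jittered palette colors as an n x 3 matrix
nucleus_colors <- function(cls, pal, sd = 6) {
  base <- rbind(pos = pal$dab, neg = pal$hematoxylin)[cls, , drop = FALSE]
  pmin(pmax(base + matrix(stats::rnorm(3L * length(cls), 0, sd), ncol = 3L), 0), 255)
}

## stroma brightness modulation: absorbing micro-texture (0.60-0.85 of
## the stroma tint) with sparse near-glass bright gaps
stroma_texture <- function(h, w) {
  tex <- 0.60 + 0.25 * (blotch_noise(h, w, sigma = 2) + 1) / 2
  g <- blotch_noise(h, w, sigma = 5)
  tex[g > stats::quantile(g, 0.96)] <- 1.08
  tex
}

## coarse blotchy field in [-1, 1]: smoothed white noise, per-image scaled
blotch_noise <- function(h, w, sigma = 4) {
  n <- EBImage::gblur(matrix(stats::runif(h * w), h, w), sigma = sigma)
  rng <- range(n)
  if (rng[2] - rng[1] <= 0) return(matrix(0, h, w))
  2 * (n - rng[1]) / (rng[2] - rng[1]) - 1
}

## hard-core dart throwing: keep proposals no closer than `spacing` to an
## accepted point, using an occupancy grid of cell size `spacing`
hardcore_thin <- function(pr, pc, spacing, accept_first = TRUE) {
  n <- length(pr)
  if (!n) return(logical(0))
  cell <- max(spacing, 1)
  gr <- floor(pr / cell); gc <- floor(pc / cell)
  occ <- new.env(hash = TRUE, parent = emptyenv())
  keep <- logical(n)
  for (i in seq_len(n)) {
    ok <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      key <- paste(gr[i] + dr, gc[i] + dc)
      pts <- occ[[key]]
      if (!is.null(pts) &&
          any((pts[, 1] - pr[i])^2 + (pts[, 2] - pc[i])^2 < spacing^2)) {
        ok <- FALSE; break
      }
    }
    if (ok) {
      key <- paste(gr[i], gc[i])
      occ[[key]] <- rbind(occ[[key]], c(pr[i], pc[i]))
      keep[i] <- TRUE
    }
  }
  keep
}

#' Generate a synthetic IHC-like slide with ground truth
#'
#' Renders bright glass background, pale tissue sections carrying blue
#' (hematoxylin-like, immunonegative) and brown (DAB-like,
#' immunopositive) soft-edged nuclei placed by a hard-core spatial
#' Poisson process, localized hot spots where the nucleus rate is
#' multiplied and the immunopositive fraction raised, hemorrhage patches
#' rendered as coarse red blotch texture without nuclei, and Gaussian
#' pixel noise. Fully determined by the seed.
#'
#' @param params a [synth_params()] object.
#' @return List with `image` (an [rgb_image]) and `truth`: tissue and
#'   hemorrhage masks, hot-spot centers/radius, the per-nucleus table
#'   (row, col, radius, class), planted fractions, and the params.
#' @export
generate_slide <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  with_seed(params$seed, {
    pal <- synth_palette()
    H <- params$slide_size[1]; W <- params$slide_size[2]

    ## tissue sections
    tissue <- matrix(FALSE, H, W)
    for (b in seq_len(params$tissue_blob_count)) {
      r <- stats::runif(1, params$tissue_radius[1], params$tissue_radius[2])
      cr <- stats::runif(1, r * 0.8, H - r * 0.8)
      cc <- stats::runif(1, r * 0.8, W - r * 0.8)
      tissue <- fill_disk(tissue, cr, cc, r)
    }

    ## hot spots: disks fully inside tissue, mutually separated
    hs <- matrix(numeric(0), 0, 2)
    hr <- params$hotspot_radius
    if (params$hotspot_count > 0L) {
      tries <- 0L
      while (nrow(hs) < params$hotspot_count && tries < 1000L) {
        tries <- tries + 1L
        ## relax the mutual-separation requirement if placement is hard
        sep <- if (tries <= 500L) 2.5 * hr else 1.6 * hr
        cr <- stats::runif(1, hr + 1, H - hr - 1)
        cc <- stats::runif(1, hr + 1, W - hr - 1)
        probe <- cbind(cr + c(0, hr, -hr, 0, 0), cc + c(0, 0, 0, hr, -hr))
        inside <- all(tissue[cbind(pmin(pmax(round(probe[, 1]), 1), H),
                                   pmin(pmax(round(probe[, 2]), 1), W))])
        farenough <- !nrow(hs) ||
          all((hs[, 1] - cr)^2 + (hs[, 2] - cc)^2 >= sep^2)
        if (inside && farenough) hs <- rbind(hs, c(cr, cc))
      }
      if (nrow(hs) < params$hotspot_count)
        stop("could not place the requested hot spots inside tissue")
    }
    hotmask <- matrix(FALSE, H, W)
    for (i in seq_len(nrow(hs))) hotmask <- fill_disk(hotmask, hs[i, 1], hs[i, 2], hr)

    ## hemorrhage patches: inside tissue, away from hot spots
    hem <- matrix(FALSE, H, W)
    hemr <- params$hemorrhage_radius
    hcent <- matrix(numeric(0), 0, 2)
    if (params$hemorrhage_count > 0L) {
      tries <- 0L
      while (nrow(hcent) < params$hemorrhage_count && tries < 500L) {
        tries <- tries + 1L
        cr <- stats::runif(1, hemr + 1, H - hemr - 1)
        cc <- stats::runif(1, hemr + 1, W - hemr - 1)
        inside <- tissue[round(cr), round(cc)]
        awayhs <- !nrow(hs) ||
          all((hs[, 1] - cr)^2 + (hs[, 2] - cc)^2 >= (hr + hemr + 20)^2)
        awayhem <- !nrow(hcent) ||
          all((hcent[, 1] - cr)^2 + (hcent[, 2] - cc)^2 >= (2 * hemr + 10)^2)
        if (inside && awayhs && awayhem) hcent <- rbind(hcent, c(cr, cc))
      }
      for (i in seq_len(nrow(hcent)))
        hem <- fill_disk(hem, hcent[i, 1], hcent[i, 2], hemr)
      hem <- hem & tissue
    }

    ## nucleus placement: base rate over tissue, extra rate in hot spots
    fov_area <- prod(params$fov)
    lambda <- params$base_density / fov_area
    placeable <- tissue & !hem
    place_points <- function(region, rate) {
      idx <- which(region)
      n <- stats::rpois(1, rate * length(idx))
      if (!n) return(matrix(numeric(0), 0, 2))
      pick <- sample(idx, n, replace = TRUE)
      cbind((pick - 1) %% H + 1 + stats::runif(n, -0.5, 0.5),
            (pick - 1) %/% H + 1 + stats::runif(n, -0.5, 0.5))
    }
    pts <- place_points(placeable, lambda)
    if (params$hotspot_multiplier > 1 && any(hotmask))
      pts <- rbind(pts, place_points(placeable & hotmask,
                                     lambda * (params$hotspot_multiplier - 1)))
    if (nrow(pts)) {
      ## hard-core spacing of two radii: nuclei pack tangentially (dense
      ## tissue) without interpenetrating, so counts stay well defined
      spacing <- 2 * mean(params$nucleus_radius)
      pts <- pts[sample.int(nrow(pts)), , drop = FALSE]
      pts <- pts[hardcore_thin(pts[, 1], pts[, 2], spacing), , drop = FALSE]
    }

    ## class labels from the locally planted Ki-67 fraction
    nuclei <- data.frame(row = numeric(0), col = numeric(0),
                         radius = numeric(0), class = character(0))
    if (nrow(pts)) {
      inhot <- hotmask[cbind(pmin(pmax(round(pts[, 1]), 1), H),
                             pmin(pmax(round(pts[, 2]), 1), W))]
      p <- ifelse(inhot, params$ki67_hotspot_pct, params$ki67_background_pct) / 100
      cls <- ifelse(stats::runif(nrow(pts)) < p, "pos", "neg")
      rad <- stats::runif(nrow(pts), params$nucleus_radius[1], params$nucleus_radius[2])
      nuclei <- data.frame(row = pts[, 1] - 1, col = pts[, 2] - 1,
                           radius = rad, class = cls,
                           stringsAsFactors = FALSE)
    }

    ## render; stroma carries absorbance micro-texture (cytoplasm,
    ## collagen) plus sparse bright gaps (vessels, clefts) that anchor
    ## the local background estimate near glass level
    tex <- stroma_texture(H, W)
    chans <- lapply(1:3, function(k) {
      ch <- matrix(pal$glass[k], H, W)
      ch[tissue] <- pmin(pal$stroma[k] * tex[tissue], 255)
      ch
    })
    if (any(hem)) {
      ## each patch gets its own full-contrast blotch texture
      mod <- c(35, 15, 15)
      for (i in seq_len(nrow(hcent))) {
        rr <- max(1L, floor(hcent[i, 1] - hemr)):min(H, ceiling(hcent[i, 1] + hemr))
        cc <- max(1L, floor(hcent[i, 2] - hemr)):min(W, ceiling(hcent[i, 2] + hemr))
        bl <- blotch_noise(length(rr), length(cc), sigma = 6)
        inpatch <- hem[rr, cc]
        for (k in 1:3) {
          sub <- chans[[k]][rr, cc]
          sub[inpatch] <- pmin(pmax(pal$hemorrhage[k] + mod[k] * bl[inpatch], 0), 255)
          chans[[k]][rr, cc] <- sub
        }
      }
    }
    if (nrow(nuclei)) {
      cols <- nucleus_colors(nuclei$class, pal)
      chans <- render_nuclei(chans[[1]], chans[[2]], chans[[3]],
                             nuclei$row + 1, nuclei$col + 1, nuclei$radius, cols)
    }
    px <- array(0, c(H, W, 3))
    for (k in 1:3) px[, , k] <- chans[[k]]
    if (params$noise_sigma > 0)
      px <- px + array(stats::rnorm(length(px), 0, params$noise_sigma), dim(px))
    px <- round(pmin(pmax(px, 0), 255))

    list(image = rgb_image(px, mpp_x = params$mpp, mpp_y = params$mpp),
         truth = list(tissue_mask = tissue, hemorrhage_mask = hem,
                      hotspot_centers = hs, hotspot_radius = hr,
                      nuclei = nuclei,
                      ki67_background_pct = params$ki67_background_pct,
                      ki67_hotspot_pct = params$ki67_hotspot_pct,
                      params = params))
  })
}

#' Planted local Ki-67 fraction at given working-resolution centers
#'
#' @param truth ground truth from [generate_slide()].
#' @param centers matrix of (row, col) centers in working-resolution
#'   pixels.
#' @param working_downsample downsample factor of the centers' frame.
#' @return Numeric vector of planted percentages (hot-spot value inside a
#'   hot spot, background value elsewhere).
#' @export
planted_local_ki67 <- function(truth, centers, working_downsample) {
  centers <- matrix(as.numeric(centers), ncol = 2)
  r0 <- centers[, 1] * working_downsample
  c0 <- centers[, 2] * working_downsample
  hs <- truth$hotspot_centers
  inhot <- rep(FALSE, nrow(centers))
  for (i in seq_len(nrow(hs)))
    inhot <- inhot | ((r0 - hs[i, 1])^2 + (c0 - hs[i, 2])^2 <= truth$hotspot_radius^2)
  ifelse(inhot, truth$ki67_hotspot_pct, truth$ki67_background_pct)
}

#' Generate a single full-resolution field with exact nucleus counts
#'
#' Dart-throwing placement of exactly `n_pos` brown and `n_neg` blue
#' non-overlapping nuclei on a stroma-tinted tile; errors if the counts
#' cannot be placed at the given radius and tile size.
#'
#' @param width,height tile size in pixels.
#' @param n_pos,n_neg requested immunopositive / immunonegative counts.
#' @param nucleus_radius radius range in pixels.
#' @param noise_sigma Gaussian pixel noise sd (default 2).
#' @param mpp nominal resolution.
#' @param seed integer seed.
#' @return List with `image` (an [rgb_image]) and `count`
#'   (\code{nucleus_count} ground truth).
#' @export
generate_field <- function(width = 128L, height = 128L, n_pos = 0L, n_neg = 0L,
                           nucleus_radius = c(2.5, 3.5), noise_sigma = 2,
                           mpp = 1.0, seed = 1L) {
  stopifnot(n_pos >= 0, n_neg >= 0)
  with_seed(seed, {
    pal <- synth_palette()
    n <- n_pos + n_neg
    spacing <- 2 * max(nucleus_radius) + 2
    margin <- max(nucleus_radius) + 1
    pts <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(pts) < n && tries < 200L * max(n, 1L)) {
      tries <- tries + 1L
      cand <- c(stats::runif(1, margin, height - margin),
                stats::runif(1, margin, width - margin))
      if (!nrow(pts) ||
          all((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2 >= spacing^2))
        pts <- rbind(pts, cand)
    }
    if (nrow(pts) < n)
      stop("cannot place ", n, " non-overlapping nuclei in a ",
           height, "x", width, " tile")
    tex <- stroma_texture(height, width)
    chans <- lapply(1:3, function(k) pmin(pal$stroma[k] * tex, 255))
    cls <- c(rep("pos", n_pos), rep("neg", n_neg))
    if (n > 0) {
      cols <- nucleus_colors(cls, pal, sd = 5)
      radii <- stats::runif(n, nucleus_radius[1], nucleus_radius[2])
      chans <- render_nuclei(chans[[1]], chans[[2]], chans[[3]],
                             pts[, 1], pts[, 2], radii, cols)
    }
    px <- array(0, c(height, width, 3))
    for (k in 1:3) px[, , k] <- chans[[k]]
    if (noise_sigma > 0)
      px <- px + array(stats::rnorm(length(px), 0, noise_sigma), dim(px))
    px <- round(pmin(pmax(px, 0), 255))
    list(image = rgb_image(px, mpp_x = mpp),
         count = structure(list(positive = as.integer(n_pos),
                                negative = as.integer(n_neg),
                                total = as.integer(n)),
                           class = "nucleus_count"))
  })
}

#' Generate a full-resolution texture patch for classifier teaching
#'
#' `"tumor"` patches are stroma tiles carrying blue/brown nuclei at
#' hot-spot-like density; `"hemorrhage"` patches are coarse red blotch
#' texture without nuclei. Used to build the teaching set of the
#' hemorrhage texture classifier.
#'
#' @param type `"tumor"` or `"hemorrhage"`.
#' @param size patch edge length in level-0 pixels (default 256).
#' @param params a [synth_params()] (palette/density source).
#' @param seed integer seed.
#' @param density_factor multiplier on the base nucleus density for tumor
#'   patches (default 1; hot-spot-like patches use the hot-spot
#'   multiplier).
#' @return An [rgb_image].
#' @export
generate_texture_patch <- function(type = c("tumor", "hemorrhage"),
                                   size = 256L, params = synth_params(),
                                   seed = 1L, density_factor = 1) {
  type <- match.arg(type)
  with_seed(seed, {
    pal <- synth_palette()
    if (type == "hemorrhage") {
      bl <- blotch_noise(size, size, sigma = 6)
      mod <- c(35, 15, 15)
      chans <- lapply(1:3, function(k)
        pmin(pmax(pal$hemorrhage[k] + mod[k] * bl, 0), 255))
    } else {
      tex <- stroma_texture(size, size)
      chans <- lapply(1:3, function(k) pmin(pal$stroma[k] * tex, 255))
      lam <- params$base_density * density_factor / prod(params$fov)
      n <- stats::rpois(1, lam * size * size)
      if (n > 0) {
        pr <- stats::runif(n, 1, size); pc <- stats::runif(n, 1, size)
        keep <- hardcore_thin(pr, pc, 2 * mean(params$nucleus_radius))
        pr <- pr[keep]; pc <- pc[keep]
        cls <- ifelse(stats::runif(length(pr)) < params$ki67_hotspot_pct / 100,
                      "pos", "neg")
        cols <- nucleus_colors(cls, pal)
        radii <- stats::runif(length(pr), params$nucleus_radius[1],
                              params$nucleus_radius[2])
        chans <- render_nuclei(chans[[1]], chans[[2]], chans[[3]],
                               pr, pc, radii, cols)
      }
    }
    px <- array(0, c(size, size, 3))
    for (k in 1:3) px[, , k] <- chans[[k]]
    px <- px + array(stats::rnorm(length(px), 0, params$noise_sigma), dim(px))
    rgb_image(round(pmin(pmax(px, 0), 255)), mpp_x = params$mpp)
  })
}

#' Simulated pathologist field selections for concordance experiments
#'
#' Centers fields on the ground-truth hot spots with Gaussian positional
#' jitter and random dropout; per-field Ki-67 is the planted local index
#' plus bounded noise. Serves as an expert proxy when exercising the LCM
#' and the dispersion-strength calibration.
#'
#' @param truth ground truth from [generate_slide()].
#' @param working_downsample downsample factor of the output frame.
#' @param jitter_px Gaussian positional jitter sd in working pixels.
#' @param dropout_frac probability of dropping each field (in \code{[0, 1)}).
#' @param ki67_noise_sd sd of the additive Ki-67 noise (percent points).
#' @param seed integer seed.
#' @param observer_id,slide_id identifiers.
#' @return An [observer_fieldset()].
#' @export
generate_observer_proxy <- function(truth, working_downsample = 8L,
                                    jitter_px = 0, dropout_frac = 0,
                                    ki67_noise_sd = 0.5, seed = 1L,
                                    observer_id = "proxy", slide_id = "synthetic") {
  stopifnot(jitter_px >= 0, dropout_frac >= 0, dropout_frac < 1)
  with_seed(seed, {
    cen <- truth$hotspot_centers / working_downsample
    keep <- stats::runif(nrow(cen)) >= dropout_frac
    if (!any(keep)) stop("all proxy fields were dropped")
    cen <- cen[keep, , drop = FALSE]
    cen <- cen + matrix(stats::rnorm(length(cen), 0, jitter_px), ncol = 2)
    ki <- planted_local_ki67(truth, truth$hotspot_centers[keep, , drop = FALSE] /
                               working_downsample, working_downsample)
    ki <- pmin(pmax(ki + stats::rnorm(length(ki), 0, ki67_noise_sd), 0), 100)
    observer_fieldset(cen, ki, observer_id = observer_id, slide_id = slide_id)
  })
}

#' Train the hemorrhage classifier on a synthetic teaching set
#'
#' Generates `n_per_class` full-resolution tumor and hemorrhage texture
#' patches, reduces each to working resolution, pools its 64-layer
#' feature bank, and fits the texture classifier. Reproducible under the
#' seed.
#'
#' @param params a [synth_params()] (palette and density source).
#' @param n_per_class patches per class (default 25).
#' @param patch_size level-0 patch edge (default 256 px).
#' @param working_downsample reduction factor (default 8).
#' @param seed integer seed.
#' @param ... passed to [train_texture_classifier()].
#' @return A fitted \code{texture_classifier}.
#' @export
train_synthetic_classifier <- function(params = synth_params(), n_per_class = 25L,
                                       patch_size = 256L, working_downsample = 8L,
                                       seed = 1L, ...) {
  types <- rep(c("tumor", "hemorrhage"), each = n_per_class)
  ## tumor patches span the density range seen on a slide (base rate up to
  ## the hot-spot rate)
  dens <- seq(1, params$hotspot_multiplier, length.out = n_per_class)
  dens <- c(dens, rep(1, n_per_class))
  feats <- matrix(NA_real_, length(types), 64L)
  for (i in seq_along(types)) {
    patch <- generate_texture_patch(types[i], size = patch_size, params = params,
                                    seed = seed * 10000L + i,
                                    density_factor = dens[i])
    wp <- downsample(patch, working_downsample)
    stack <- build_feature_bank(wp)
    feats[i, ] <- pool_region_features(stack, matrix(TRUE, nrow(wp$pixels), ncol(wp$pixels)))
  }
  train_texture_classifier(feats, types, ...)
}

#' Ground-truth density map of immunopositive nuclei
#'
#' Builds the density map directly from the planted immunopositive
#' nucleus coordinates, bypassing the image pipeline entirely. Serves as
#' an independent route to hot-spot density for validation and
#' calibration experiments.
#'
#' @param truth ground truth from [generate_slide()].
#' @param working_downsample downsample factor of the output frame.
#' @param fov_width,fov_height field extent in working pixels.
#' @return A \code{density_map}.
#' @export
truth_density_map <- function(truth, working_downsample, fov_width,
                              fov_height = fov_width) {
  shape <- ceiling(dim(truth$tissue_mask) / working_downsample)
  pos <- truth$nuclei[truth$nuclei$class == "pos", , drop = FALSE]
  marks <- list(centroids = cbind(row = pos$row / working_downsample,
                                  col = pos$col / working_downsample),
                marks = array(FALSE, shape))
  density_map(marks, fov_width = fov_width, fov_height = fov_height,
              shape = shape)
}

#' Ground-truth specimen map
#'
#' Block-reduces the planted tissue mask (minus hemorrhage) to working
#' resolution, as an independent reference for the image-derived map.
#'
#' @param truth ground truth from [generate_slide()].
#' @param working_downsample downsample factor.
#' @return A \code{specimen_map}.
#' @export
truth_specimen_map <- function(truth, working_downsample) {
  m <- block_reduce((truth$tissue_mask & !truth$hemorrhage_mask) * 1,
                    working_downsample) > 0.5
  structure(list(mask = m, working_downsample = as.integer(working_downsample),
                 provenance = "ground truth (synthetic)"),
            class = "specimen_map")
}

#' Reference field selection from ground truth
#'
#' Runs the dispersion-penalized greedy selection on the ground-truth
#' density and tissue maps (no image processing involved) and returns the
#' result as an observer field set carrying the planted local Ki-67
#' levels. Used as the expert-proxy reference when calibrating the
#' dispersion strength.
#'
#' @param truth ground truth from [generate_slide()].
#' @param working_downsample downsample factor.
#' @param fov_width,fov_height field extent in working pixels.
#' @param n fields (default 20).
#' @param rho dispersion strength embodied by the reference (default 0.2).
#' @param stride candidate stride (default 2).
#' @param slide_id identifier.
#' @return An [observer_fieldset()].
#' @export
truth_reference_selection <- function(truth, working_downsample, fov_width,
                                      fov_height = fov_width, n = 20L,
                                      rho = 0.2, stride = 2L,
                                      slide_id = "synthetic") {
  dmap <- truth_density_map(truth, working_downsample, fov_width, fov_height)
  map <- truth_specimen_map(truth, working_downsample)
  sel <- select_fields(dmap, map, n = n, rho = rho, fov_width = fov_width,
                       fov_height = fov_height, stride = stride)
  cen <- as.matrix(sel$fields[, c("center_row", "center_col")])
  observer_fieldset(cen, planted_local_ki67(truth, cen, working_downsample),
                    observer_id = "truth", slide_id = slide_id)
}
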