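#' Pool texture features over a region
#'
#' Summarizes a 64-layer feature bank into one vector by taking the mean
#' of every feature map over the region mask.
#'
#' @param stack a \code{feature_stack} from [build_feature_bank()].
#' @param region_mask logical/0-1 matrix, same shape as the maps.
#' @return Numeric 64-vector (one entry per bank layer).
#' @export
pool_region_features <- function(stack, region_mask) {
  stopifnot(inherits(stack, "feature_stack"))
  region_mask <- region_mask > 0
  if (!identical(dim(region_mask), dim(stack$maps[[1]])))
    stop("region mask shape does not match the feature maps")
  if (!any(region_mask)) stop("region is empty")
  vapply(stack$maps, function(m) mean(m[region_mask]), numeric(1))
}

#' Train the hemorrhage texture classifier
#'
#' Z-scores the feature columns on training statistics, ranks them with
#' the Fisher discriminant, keeps the top `k`, and fits a Gaussian-kernel
#' (RBF) support vector machine separating hemorrhage texture from tumor
#' tissue texture. Deterministic given a fixed sample order.
#'
#' @param samples numeric matrix, one row per region, 64 feature columns.
#' @param labels factor/character with levels `"tumor"` and
#'   `"hemorrhage"` (any two labels accepted; the second sorted level is
#'   reported as hemorrhage unless `positive` is given).
#' @param k number of features retained by Fisher selection (default 25).
#' @param cost SVM cost parameter C (default 1).
#' @param gamma RBF kernel width; default \code{1 / (k * median feature
#'   variance)} computed on the z-scored retained features.
#' @param positive the label treated as hemorrhage (default
#'   `"hemorrhage"` if present, else the second level).
#' @return An object of class \code{texture_classifier}.
#' @export
train_texture_classifier <- function(samples, labels, k = 25L, cost = 1,
                                     gamma = NULL, positive = NULL) {
  samples <- as.matrix(samples)
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) != 2L) stop("labels must contain exactly two classes")
  if (min(table(labels)) < 5L) stop("need at least 5 samples per class")
  if (is.null(positive))
    positive <- if ("hemorrhage" %in% levels(labels)) "hemorrhage" else levels(labels)[2]

  ctr <- colMeans(samples)
  scl <- apply(samples, 2, stats::sd)
  scl[scl <= 0] <- 1
  z <- sweep(sweep(samples, 2, ctr), 2, scl, "/")

  ranked <- fisher_rank(z, labels)
  sel <- sort(select_features(ranked, k = min(k, ncol(z))))
  zs <- z[, sel, drop = FALSE]
  if (is.null(gamma)) {
    mv <- stats::median(apply(zs, 2, stats::var))
    gamma <- 1 / (length(sel) * max(mv, 1e-8))
  }
  fit <- e1071::svm(x = zs, y = labels, kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
  structure(list(fit = fit, center = ctr, scale = scl,
                 selected_features = sel, ranking = ranked,
                 cost = cost, gamma = gamma, positive = positive,
                 levels = levels(labels)),
            class = "texture_classifier")
}

#' @export
print.texture_classifier <- function(x, ...) {
  cat(sprintf("<texture_classifier> RBF SVM on %d/%d features (C=%.3g, gamma=%.3g); positive class '%s'\n",
              length(x$selected_features), length(x$center),
              x$cost, x$gamma, x$positive))
  invisible(x)
}

#' Predict texture class for pooled feature vectors
#'
#' @param object a \code{texture_classifier}.
#' @param newdata numeric matrix with 64 feature columns (or a single
#'   vector).
#' @param ... unused.
#' @return Factor of predicted labels.
#' @export
predict.texture_classifier <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  z <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  stats::predict(object$fit, z[, object$selected_features, drop = FALSE])
}

#' Classify the specimen map into tumor and hemorrhage blocks
#'
#' Tiles the working-resolution image into `block x block` patches,
#' pools the feature bank over the tissue pixels of each patch, predicts
#' with the trained classifier, and returns the union of
#' hemorrhage-predicted patches intersected with the specimen map.
#' Patches whose tissue coverage is below `min_tissue_frac` are left
#' unclassified (treated as tumor).
#'
#' @param stack \code{feature_stack} of the working image.
#' @param map a \code{specimen_map}.
#' @param clf a fitted \code{texture_classifier}.
#' @param block patch edge length in working-resolution pixels
#'   (default 32).
#' @param min_tissue_frac minimum tissue fraction for a patch to be
#'   classified (default 0.25).
#' @param grow_radius dilation radius applied to the detected mask
#'   before intersection (default: the feature-bank disk radius).
#'   Texture features within one neighborhood radius of a hemorrhage
#'   boundary are contaminated by it, so detection cores are grown by
#'   that radius to cover the full area.
#' @return Logical hemorrhage mask (subset of the specimen map).
#' @export
classify_map <- function(stack, map, clf, block = 32L, min_tissue_frac = 0.25,
                         grow_radius = stack$radius) {
  stopifnot(inherits(stack, "feature_stack"), inherits(map, "specimen_map"))
  if (!inherits(clf, "texture_classifier")) stop("classifier is not fitted")
  msk <- map$mask
  d <- dim(msk)
  hem <- array(FALSE, d)
  rb <- seq(1L, d[1], by = block)
  cb <- seq(1L, d[2], by = block)
  feats <- list(); spans <- list()
  for (r0 in rb) for (c0 in cb) {
    rr <- r0:min(r0 + block - 1L, d[1])
    cc <- c0:min(c0 + block - 1L, d[2])
    sub <- msk[rr, cc, drop = FALSE]
    if (mean(sub) < min_tissue_frac) next
    ## pool on the cropped block (mean over its tissue pixels)
    feats[[length(feats) + 1L]] <-
      vapply(stack$maps, function(m) mean(m[rr, cc][sub]), numeric(1))
    spans[[length(spans) + 1L]] <- list(rr = rr, cc = cc)
  }
  if (length(feats)) {
    pred <- predict(clf, do.call(rbind, feats))
    for (i in which(as.character(pred) == clf$positive)) {
      sp <- spans[[i]]
      hem[sp$rr, sp$cc] <- TRUE
    }
  }
  if (any(hem) && grow_radius >= 1L)
    hem <- EBImage::dilate(hem * 1, disc_brush(grow_radius)) > 0
  hem & msk
}

#' Remove hemorrhage areas from a specimen map
#'
#' @param map a \code{specimen_map}.
#' @param hem logical hemorrhage mask, same shape.
#' @return The \code{specimen_map} with `mask & !hem` and provenance
#'   appended.
#' @export
exclude_hemorrhage <- function(map, hem) {
  stopifnot(inherits(map, "specimen_map"))
  if (!identical(dim(hem), dim(map$mask))) stop("mask shapes differ")
  map$mask <- map$mask & !(hem > 0)
  map$provenance <- c(map$provenance,
                      sprintf("exclude_hemorrhage(area=%d px)", sum(hem > 0)))
  map
}
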