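#' Euclidean disk mask
#'
#' Binary structuring element \eqn{\{(dx, dy) : dx^2 + dy^2 \le r^2\}} of
#' dimension \code{(2r+1) x (2r+1)}. Used as the texture neighborhood
#' \eqn{\Omega}; its pixel count is \eqn{N_\Omega} (317 at the default
#' radius of 10).
#'
#' @param radius integer >= 1.
#' @return A 0/1 numeric matrix.
#' @export
disk_mask <- function(radius) {
  stopifnot(radius >= 1)
  d <- -radius:radius
  m <- outer(d^2, d^2, "+") <= radius^2
  storage.mode(m) <- "double"
  m
}

## shift a plane by (d1, d2) with edge replication:
## out[k, l] = m[clamp(k + d1), clamp(l + d2)]
shift_replicate <- function(m, d1, d2) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) + d1, 1L), h)
  ci <- pmin(pmax(seq_len(w) + d2, 1L), w)
  m[ri, ci, drop = FALSE]
}

#' Sum and difference images under a fixed displacement
#'
#' Forms \eqn{s_{k,l} = f_{k,l} + f_{k+d_1, l+d_2}} and
#' \eqn{d_{k,l} = f_{k,l} - f_{k+d_1, l+d_2}}. Border pixels whose
#' translated partner falls outside the plane use edge replication, so
#' both outputs keep the input shape.
#'
#' @param plane numeric matrix (one color channel).
#' @param displacement integer pair \code{(d1, d2)} in (row, col) pixels;
#'   default \code{c(3, 3)}.
#' @return A list of class \code{sumdiff_pair} with matrices `S`, `D` and
#'   the `displacement`.
#' @export
sum_difference_images <- function(plane, displacement = c(3L, 3L)) {
  stopifnot(is.matrix(plane), length(displacement) == 2L)
  d1 <- as.integer(displacement[1]); d2 <- as.integer(displacement[2])
  if (abs(d1) >= nrow(plane) || abs(d2) >= ncol(plane))
    stop("displacement exceeds the image extent")
  fs <- shift_replicate(plane, d1, d2)
  structure(list(S = plane + fs, D = plane - fs, displacement = c(d1, d2)),
            class = "sumdiff_pair")
}

#' Normalized sum/difference histograms over a region
#'
#' Integer-binned counts of the sum and difference values inside a region,
#' each normalized by the region pixel count N, giving the empirical
#' probabilities \eqn{\hat P_s(i) = h_s(i)/N} and
#' \eqn{\hat P_d(i) = h_d(i)/N}.
#'
#' @param pair a \code{sumdiff_pair}.
#' @param region logical/0-1 matrix selecting the pixels; default: all.
#' @return List with named probability vectors `probs_sum`, `probs_diff`
#'   (names are the integer bin values) and the count `N`.
#' @export
local_histograms <- function(pair, region = NULL) {
  stopifnot(inherits(pair, "sumdiff_pair"))
  if (is.null(region)) region <- array(TRUE, dim(pair$S))
  region <- region > 0
  N <- sum(region)
  if (N == 0L) stop("region is empty")
  tab <- function(v) {
    t <- table(round(v))
    p <- as.numeric(t) / N
    names(p) <- names(t)
    p
  }
  list(probs_sum = tab(pair$S[region]), probs_diff = tab(pair$D[region]), N = N)
}

## disk-neighborhood raw sums via linear filtering, replicate borders
disk_sums <- function(m, kernel) {
  EBImage::filter2(m, kernel, boundary = "replicate")
}

#' Modified Unser texture feature maps
#'
#' Computes, for every pixel, texture features over the disk neighborhood
#' \eqn{\Omega} centered there, from the sum image s and difference image
#' d. With \eqn{\mu_\Omega = \sum_\Omega s / (2 N_\Omega)}, the features
#' are the modified definitions:
#' \enumerate{
#'   \item Mean (PSM): \eqn{\sum s / (2 N_\Omega) = \mu_\Omega}
#'   \item Variance: \eqn{\frac12 (\sum (s - 2\mu_\Omega)^2 + \sum d^2) / N_\Omega}
#'   \item Energy: \eqn{(\sum s^2)(\sum d^2) / N_\Omega^2}
#'   \item Correlation: \eqn{\frac12 (\sum (s - 2\mu_\Omega)^2 - \sum d^2) / N_\Omega}
#'   \item Contrast: \eqn{\sum d^2 / N_\Omega}
#'   \item Homogeneity: \eqn{\sum 1/(1 + d^2) / N_\Omega}
#'   \item Cluster shade: \eqn{\sum (s - 2\mu_\Omega)^3 / N_\Omega}
#'   \item Cluster prominence: \eqn{\sum (s - 2\mu_\Omega)^4 / N_\Omega}
#' }
#' (Energy is deliberately the printed product-of-sums form, not the
#' classic sum-histogram energy.) The implementation expands the centered
#' powers into raw disk sums of element-wise transformed planes and
#' evaluates each as one linear filter pass, which is algebraically
#' identical to the naive per-pixel definition. Borders use edge
#' replication.
#'
#' @param pair a \code{sumdiff_pair} from [sum_difference_images()].
#' @param radius disk radius in pixels (default 10).
#' @param features integer subset of 1:8.
#' @return Named list of feature matrices (`f1` ... `f8` as requested).
#' @export
unser_feature_maps <- function(pair, radius = 10L, features = 1:8) {
  stopifnot(inherits(pair, "sumdiff_pair"), radius >= 1)
  features <- as.integer(features)
  if (any(is.na(features)) || any(features < 1L) || any(features > 8L))
    stop("feature ids must be in 1..8")
  S <- pair$S; D <- pair$D
  if (any(dim(S) <= 2L * radius))
    stop("plane must be larger than the disk diameter")
  K <- disk_mask(radius)
  N <- sum(K)

  s1 <- disk_sums(S, K)            # sum s
  mu <- s1 / (2 * N)
  ## central sums of (s - 2 mu)^p are invariant to a global shift of S;
  ## working on the centered plane keeps the expanded-filter form well
  ## conditioned (no large-term cancellation)
  cshift <- mean(S)
  Sc <- S - cshift
  sc1 <- s1 - cshift * N
  muc <- sc1 / (2 * N)
  needc <- any(features %in% c(2L, 4L, 7L, 8L))
  sc2 <- if (needc) disk_sums(Sc^2, K)
  sc3 <- if (any(features %in% c(7L, 8L))) disk_sums(Sc^3, K)
  sc4 <- if (8L %in% features) disk_sums(Sc^4, K)
  s2 <- if (3L %in% features) disk_sums(S^2, K)
  d2 <- if (any(features %in% c(2L, 3L, 4L, 5L))) disk_sums(D^2, K)
  hom <- if (6L %in% features) disk_sums(1 / (1 + D^2), K)

  cs2 <- if (any(features %in% c(2L, 4L)))
    sc2 - 4 * muc * sc1 + 4 * muc^2 * N
  out <- list()
  for (f in sort(unique(features))) {
    out[[paste0("f", f)]] <- switch(as.character(f),
      "1" = mu,
      "2" = 0.5 * (cs2 + d2) / N,
      "3" = (s2 * d2) / N^2,
      "4" = 0.5 * (cs2 - d2) / N,
      "5" = d2 / N,
      "6" = hom / N,
      "7" = (sc3 - 6 * muc * sc2 + 12 * muc^2 * sc1 - 8 * muc^3 * N) / N,
      "8" = (sc4 - 8 * muc * sc3 + 24 * muc^2 * sc2 - 32 * muc^3 * sc1 +
               16 * muc^4 * N) / N)
  }
  out
}

## channel-block order of the 64-layer bank: 8 features x 8 planes
bank_channels <- function() c("R", "G", "B", "uC", "C", "M", "Y", "K")

unser_feature_names <- function()
  c("Mean", "Variance", "Energy", "Correlation", "Contrast",
    "Homogeneity", "Cluster shade", "Cluster prominence")

#' Build the 64-layer texture feature bank
#'
#' Computes all 8 modified Unser features for each of 8 color planes ---
#' R, G, B, u(Luv)+C(CMYK), C, M, Y, K --- of the input image. Layers are
#' indexed \code{(channel_block - 1) * 8 + feature_id} with blocks
#' R(1--8), G(9--16), B(17--24), u+C(25--32), C(33--40), M(41--48),
#' Y(49--56), K(57--64).
#'
#' @param img an [rgb_image] (typically at working resolution).
#' @param displacement sum/difference displacement, default \code{c(3, 3)}.
#' @param radius disk neighborhood radius, default 10.
#' @return An object of class \code{feature_stack}: list with `maps`
#'   (64 matrices) and `index` (data.frame layer/channel/feature).
#' @export
build_feature_bank <- function(img, displacement = c(3L, 3L), radius = 10L) {
  stopifnot(inherits(img, "rgb_image"))
  if (any(dim(img) <= 2L * radius))
    stop("image too small for the requested disk radius")
  cmyk <- rgb_to_cmyk(img)
  u <- rgb_to_luv_u(img)
  planes <- list(R = channel_plane(img, "R"),
                 G = channel_plane(img, "G"),
                 B = channel_plane(img, "B"),
                 uC = combined_u_plus_c(u, cmyk$C),
                 C = cmyk$C, M = cmyk$M, Y = cmyk$Y, K = cmyk$K)
  maps <- vector("list", 64L)
  for (b in seq_along(planes)) {
    pr <- sum_difference_images(planes[[b]], displacement)
    fm <- unser_feature_maps(pr, radius = radius, features = 1:8)
    for (f in 1:8) maps[[(b - 1L) * 8L + f]] <- fm[[paste0("f", f)]]
  }
  idx <- data.frame(layer = 1:64,
                    channel = rep(bank_channels(), each = 8L),
                    feature_id = rep(1:8, times = 8L),
                    feature = rep(unser_feature_names(), times = 8L),
                    stringsAsFactors = FALSE)
  structure(list(maps = maps, index = idx,
                 displacement = displacement, radius = radius),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack> %d layers of %d x %d (displacement %d,%d; radius %d)\n",
              length(x$maps), nrow(x$maps[[1]]), ncol(x$maps[[1]]),
              x$displacement[1], x$displacement[2], x$radius))
  invisible(x)
}

#' Default retained texture features
#'
#' The 25 bank indices retained by Fisher selection in the shipped
#' configuration: energy/contrast of R and G; six features (PSM, variance,
#' energy, contrast, homogeneity, cluster prominence) of each of u+C, C
#' and M; PSM and homogeneity of Y; cluster shade of K.
#'
#' @return Integer vector of 25 layer indices into the 64-layer bank.
#' @export
default_selected_features <- function() {
  c(3L, 5L, 11L, 13L,
    25L, 26L, 27L, 29L, 30L, 32L,
    33L, 34L, 35L, 37L, 38L, 40L,
    41L, 42L, 43L, 45L, 46L, 48L,
    49L, 54L, 63L)
}

#' Rank features by Fisher discriminant score
#'
#' Per-feature two-class Fisher score
#' \eqn{J = (\mu_1 - \mu_2)^2 / (\sigma_1^2 + \sigma_2^2)}; features with
#' zero variance in both classes score 0. Ranking is descending with ties
#' broken by lower feature index.
#'
#' @param samples numeric matrix, one row per region sample, one column
#'   per feature.
#' @param labels binary vector/factor of length \code{nrow(samples)}.
#' @return data.frame with columns `feature`, `score`, ordered by rank.
#' @export
fisher_rank <- function(samples, labels) {
  samples <- as.matrix(samples)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must contain exactly two classes")
  if (min(table(labels)) < 2L) stop("need at least 2 samples per class")
  a <- samples[labels == levels(labels)[1], , drop = FALSE]
  b <- samples[labels == levels(labels)[2], , drop = FALSE]
  num <- (colMeans(a) - colMeans(b))^2
  den <- apply(a, 2, stats::var) + apply(b, 2, stats::var)
  score <- ifelse(den > 0, num / den, 0)
  ord <- order(-score, seq_along(score))
  data.frame(feature = ord, score = score[ord])
}

#' Select the top-ranked features
#'
#' @param ranked data.frame from [fisher_rank()].
#' @param k number of features to keep (default 25).
#' @return Integer vector of the first `k` feature indices (stable,
#'   deterministic).
#' @export
select_features <- function(ranked, k = 25L) {
  if (k > nrow(ranked)) stop("k exceeds the number of ranked features")
  if (k == 0L) return(integer(0))
  ranked$feature[seq_len(k)]
}
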