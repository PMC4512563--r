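## Independent brute-force oracles used to pin expected values.

## naive per-pixel Unser features over the exact Euclidean disk,
## replicate borders; mirrors the printed definitions literally
naive_unser <- function(S, D, radius, features = 1:8) {
  h <- nrow(S); w <- ncol(S)
  offs <- which(ki67hotspot::disk_mask(radius) > 0, arr.ind = TRUE) - radius - 1L
  N <- nrow(offs)
  out <- lapply(features, function(f) matrix(NA_real_, h, w))
  names(out) <- paste0("f", features)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ri <- pmin(pmax(i + offs[, 1], 1L), h)
    ci <- pmin(pmax(j + offs[, 2], 1L), w)
    s <- S[cbind(ri, ci)]
    d <- D[cbind(ri, ci)]
    mu <- sum(s) / (2 * N)
    for (f in features) {
      v <- switch(as.character(f),
        "1" = mu,
        "2" = 0.5 * (sum((s - 2 * mu)^2) + sum(d^2)) / N,
        "3" = sum(s^2) * sum(d^2) / N^2,
        "4" = 0.5 * (sum((s - 2 * mu)^2) - sum(d^2)) / N,
        "5" = sum(d^2) / N,
        "6" = sum(1 / (1 + d^2)) / N,
        "7" = sum((s - 2 * mu)^3) / N,
        "8" = sum((s - 2 * mu)^4) / N)
      out[[paste0("f", f)]][i, j] <- v
    }
  }
  out
}

## exhaustive Otsu: explicit per-split between-class variance search on
## the floor-binned histogram (bin k spans [rng1 + (k-1)w, rng1 + kw),
## last bin right-closed; threshold = upper edge of the last dark bin)
otsu_exhaustive <- function(plane, levels = 256L) {
  rng <- range(plane)
  if (rng[2] - rng[1] <= 0) return(NA_real_)
  b <- pmin(floor((as.numeric(plane) - rng[1]) / (rng[2] - rng[1]) * levels) + 1L,
            levels)
  cnt <- tabulate(b, nbins = levels)
  n <- sum(cnt)
  best <- -Inf; bestk <- 1L
  for (k in seq_len(levels - 1L)) {
    dark <- b <= k
    w0 <- sum(dark) / n
    if (w0 <= 0 || w0 >= 1) next
    mu0 <- mean(b[dark]); mu1 <- mean(b[!dark])
    sb <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (sb > best) { best <- sb; bestk <- k }
  }
  rng[1] + bestk * (rng[2] - rng[1]) / levels
}

## O(n^2) pair-counting Kendall tau-b
tau_oracle <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[i] - x[j]); b <- sign(y[i] - y[j])
    if (a == 0) tx <- tx + 1
    if (b == 0) ty <- ty + 1
    if (a * b > 0) C <- C + 1
    if (a * b < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  den <- sqrt((n0 - tx) * (n0 - ty))
  if (den == 0) return(NA_real_)
  (C - D) / den
}

## naive fixed-point grayscale reconstruction by erosion (8-connected)
naive_reconstruct_erode <- function(marker, mask) {
  erode3 <- function(m) {
    h <- nrow(m); w <- ncol(m)
    up <- m[c(1, seq_len(h - 1)), , drop = FALSE]
    dn <- m[c(seq_len(h - 1) + 1, h), , drop = FALSE]
    r <- pmin(m, up, dn)
    lf <- r[, c(1, seq_len(w - 1)), drop = FALSE]
    rt <- r[, c(seq_len(w - 1) + 1, w), drop = FALSE]
    pmin(r, lf, rt)
  }
  rec <- marker
  repeat {
    nxt <- pmax(erode3(rec), mask)
    if (identical(nxt, rec)) return(rec)
    rec <- nxt
  }
}

## small rgb_image with all channels equal to `value`
flat_image <- function(h, w, value, mpp = 1) {
  ki67hotspot::rgb_image(array(value, c(h, w, 3)), mpp_x = mpp)
}
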