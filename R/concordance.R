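#' Observer field set
#'
#' One observer's (or one method's) set of selected quantification fields
#' on one slide: field centers in working-resolution pixels plus the
#' per-field Ki-67 index.
#'
#' @param centers numeric matrix with columns (row, col) in
#'   working-resolution pixels.
#' @param ki67_pct per-field Ki-67 percentages (may be NA).
#' @param observer_id,slide_id identifiers.
#' @return An object of class \code{observer_fieldset}.
#' @export
observer_fieldset <- function(centers, ki67_pct, observer_id = "obs",
                              slide_id = "slide") {
  centers <- matrix(as.numeric(centers), ncol = 2,
                    dimnames = list(NULL, c("row", "col")))
  if (nrow(centers) < 1L) stop("a field set needs at least one field")
  ki67_pct <- rep_len(as.numeric(ki67_pct), nrow(centers))
  if (any(ki67_pct < 0 | ki67_pct > 100, na.rm = TRUE))
    stop("ki67_pct must lie in [0, 100]")
  structure(list(fields = data.frame(row = centers[, 1], col = centers[, 2],
                                     ki67_pct = ki67_pct),
                 observer_id = observer_id, slide_id = slide_id),
            class = "observer_fieldset")
}

## scaled logistic: 0 at 0, 1 at infinity, strictly monotone
sigm_scaled <- function(x) 2 / (1 + exp(-x)) - 1

#' Localization concordance measure (LCM)
#'
#' For each reference field i, let \eqn{d_i} be the distance to the
#' nearest test field. The measure is
#' \deqn{LCM = \sum_i w_i \, sigm\!\left(\frac{d_i}{4\,FOV_{size}}\right)}
#' with \eqn{sigm(x) = 2/(1 + e^{-x}) - 1} and weights
#' \eqn{w_i = L_{E,i} / \bar L_E}, the reference field's Ki-67 level
#' relative to the mean reference level (weights average 1; fields with
#' missing levels get weight 1). Identical selections score 0; selections
#' in disjoint slide areas approach the number of reference fields. Low
#' values mean concordant localization.
#'
#' @param reference,test [observer_fieldset()] objects on the same slide.
#' @param fov_width field-of-view width in the same pixel units as the
#'   centers (the distance scale is \code{4 * fov_width}).
#' @return The LCM value (>= 0).
#' @export
lcm <- function(reference, test, fov_width) {
  stopifnot(inherits(reference, "observer_fieldset"),
            inherits(test, "observer_fieldset"), fov_width > 0)
  rf <- reference$fields; tf <- test$fields
  d <- vapply(seq_len(nrow(rf)), function(i)
    min(sqrt((rf$row[i] - tf$row)^2 + (rf$col[i] - tf$col)^2)), numeric(1))
  L <- rf$ki67_pct
  if (all(is.na(L)) || mean(L, na.rm = TRUE) <= 0) {
    w <- rep(1, nrow(rf))
  } else {
    w <- L / mean(L, na.rm = TRUE)
    w[is.na(w)] <- 1
  }
  sum(w * sigm_scaled(d / (4 * fov_width)))
}

#' Kendall's tau-b rank correlation
#'
#' Tie-corrected rank correlation
#' \eqn{\tau_b = (C - D) / \sqrt{(n_0 - n_1)(n_0 - n_2)}} where C and D
#' count concordant and discordant pairs, \eqn{n_0 = n(n-1)/2}, and
#' \eqn{n_1}, \eqn{n_2} count tied pairs within each variable. Returns
#' `NA` when either variable is constant (undefined denominator).
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return tau-b in \code{[-1, 1]}, or `NA`.
#' @export
kendall_tau_b <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("need at least two paired observations")
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  up <- upper.tri(sx)
  cd <- sum(sx[up] * sy[up])             # C - D
  n0 <- n * (n - 1) / 2
  n1 <- sum(sx[up] == 0)
  n2 <- sum(sy[up] == 0)
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) return(NA_real_)
  cd / den
}

#' Percentile bootstrap confidence interval for tau-b
#'
#' Resamples the pairs with replacement `B` times, recomputes tau-b, and
#' returns the percentile interval at the requested level. Degenerate
#' resamples (either variable constant, tau-b undefined) are skipped.
#' Deterministic under a fixed seed.
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @param B bootstrap replicates (default 100).
#' @param level confidence level (default 0.95).
#' @param seed integer seed (required).
#' @return Numeric \code{c(low, high)}.
#' @export
bootstrap_ci <- function(x, y, B = 100L, level = 0.95, seed) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 3L) stop("need at least three pairs for a bootstrap interval")
  if (missing(seed)) stop("a seed is required")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  taus <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    taus[b] <- kendall_tau_b(x[idx], y[idx])
  }
  taus <- taus[is.finite(taus)]
  if (!length(taus)) return(c(NA_real_, NA_real_))
  alpha <- (1 - level) / 2
  unname(stats::quantile(taus, c(alpha, 1 - alpha)))
}

#' Pairwise agreement table of Ki-67 scores
#'
#' Computes Kendall's tau-b with bootstrap confidence intervals for every
#' pair of scoring methods, optionally split by a grade grouping. Slides
#' missing a score in either method of a pair are dropped pairwise;
#' cells with fewer than 3 shared slides are marked not computable (NA).
#'
#' @param scores data.frame with columns `slide_id`, `method`,
#'   `ki67_pct` and optionally `grade`.
#' @param by_grade split by the `grade` column (default FALSE).
#' @param B,level,seed bootstrap parameters (see [bootstrap_ci()]).
#' @return data.frame of class \code{agreement_table} with columns
#'   `group`, `method_a`, `method_b`, `n`, `tau_b`, `ci_low`, `ci_high`.
#' @export
agreement_table <- function(scores, by_grade = FALSE, B = 100L,
                            level = 0.95, seed = 1L) {
  need <- c("slide_id", "method", "ki67_pct")
  if (!all(need %in% names(scores)))
    stop("scores must contain columns: ", paste(need, collapse = ", "))
  methods <- sort(unique(scores$method))
  if (length(methods) < 2L) stop("need at least two methods")
  groups <- if (by_grade) {
    if (!"grade" %in% names(scores)) stop("by_grade = TRUE needs a grade column")
    sort(unique(scores$grade))
  } else "all"
  out <- list()
  for (g in groups) {
    sub <- if (identical(g, "all")) scores else scores[scores$grade == g, ]
    for (i in seq_along(methods)) for (j in seq_along(methods)) {
      if (j <= i) next
      a <- sub[sub$method == methods[i], c("slide_id", "ki67_pct")]
      b <- sub[sub$method == methods[j], c("slide_id", "ki67_pct")]
      m <- merge(a, b, by = "slide_id")
      m <- m[is.finite(m$ki67_pct.x) & is.finite(m$ki67_pct.y), ]
      row <- data.frame(group = as.character(g), method_a = methods[i],
                        method_b = methods[j], n = nrow(m),
                        tau_b = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
      if (nrow(m) >= 3L) {
        row$tau_b <- kendall_tau_b(m$ki67_pct.x, m$ki67_pct.y)
        ci <- bootstrap_ci(m$ki67_pct.x, m$ki67_pct.y, B = B, level = level,
                           seed = seed)
        row$ci_low <- ci[1]; row$ci_high <- ci[2]
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("agreement_table", class(res))
  res
}
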