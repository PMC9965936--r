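#' Sliding-window median filter
#'
#' Replaces each pixel with the median of the `window` x `window`
#' neighborhood centered on it, the standard impulse-noise (salt-and-pepper)
#' remover. Borders are handled by edge replication, so interior pixels see
#' exactly their neighborhood and edge pixels see clamped coordinates.
#' Because the window holds an odd number of values, the output pixel is
#' always a member of its input window multiset.
#'
#' @param img Intensity matrix in `[0, levels - 1]`.
#' @param window Odd window side length, at least 3.
#' @param threshold Optional detection threshold: when given, a pixel is
#'   replaced by its window median only if it deviates from that median by
#'   more than `threshold` gray levels; by default the median is applied
#'   unconditionally.
#' @return Filtered image of the same dimensions.
#' @examples
#' img <- matrix(0, 8, 8); img[4, 4] <- 255  # one salt impulse
#' all(median_filter(img, 3) == 0)
#' @export
median_filter <- function(img, window = 3L, threshold = NULL) {
  assert_gray_image(img, levels = 256L)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` side must be odd and >= 3", call. = FALSE)
  h <- nrow(img); w <- ncol(img)
  k <- (window - 1L) %/% 2L
  pad <- edge_pad(img, k)
  stack <- matrix(0, h * w, window^2)
  j <- 0L
  for (dc in 0:(window - 1L)) {
    for (dr in 0:(window - 1L)) {
      j <- j + 1L
      stack[, j] <- as.vector(pad[dr + seq_len(h), dc + seq_len(w)])
    }
  }
  med <- apply(stack, 1L, stats::median)
  out <- matrix(med, h, w)
  if (!is.null(threshold)) {
    keep <- abs(img - out) <= threshold
    out[keep] <- img[keep]
  }
  out
}

#' Gray-level histogram with density and cumulative distribution
#'
#' Tabulates intensities over all gray levels and derives the probability
#' density `PDF(h) = n_h / n` and its cumulative sum, the quantities driving
#' both the mean-split point selection and the per-segment equalization.
#'
#' @param img Intensity matrix in `[0, levels - 1]`.
#' @param levels Number of gray levels (default 256).
#' @return An object of class `gray_histogram`: list with `counts`, `pdf`,
#'   `cdf` (each of length `levels`, indexed by gray level + 1), `n` and
#'   `levels`.
#' @export
compute_histogram <- function(img, levels = 256L) {
  assert_gray_image(img, levels = levels)
  counts <- tabulate(as.integer(img) + 1L, nbins = levels)
  n <- sum(counts)
  pdf <- counts / n
  structure(list(counts = counts, pdf = pdf, cdf = cumsum(pdf),
                 n = n, levels = as.integer(levels)),
            class = "gray_histogram")
}

# CDF-weighted mean split of the interval [a, b]; weights are the global
# cumulative distribution evaluated at the occupied levels in (a, b]
weighted_mean_split <- function(hist, a, b) {
  occ <- which(hist$counts > 0L) - 1L
  occ_ab <- occ[occ >= a & occ <= b]
  lv <- occ_ab[occ_ab > a]
  if (length(lv) == 0L) lv <- occ_ab
  wts <- hist$cdf[lv + 1L]
  x <- sum(lv * wts) / sum(wts)
  # both children must retain an occupied level
  clamp(floor(x), min(occ_ab), max(occ_ab) - 1L)
}

#' Recursive mean-split points of a histogram
#'
#' Splits the full gray range into `t` sub-intervals by recursively placing
#' a split at the CDF-weighted mean gray level of the interval being split.
#' The interval holding the most pixels is split next (ties broken toward
#' the lower interval), so any `t` up to the number of occupied levels is
#' supported; `t = 2` gives the classical brightness-preserving
#' bi-histogram split.
#'
#' @param hist A [compute_histogram()] result.
#' @param t Number of sub-intervals, at least 1 and at most the number of
#'   occupied gray levels.
#' @return Integer vector of `t - 1` strictly increasing interior split
#'   points; attribute `"intervals"` holds the `t x 2` matrix of inclusive
#'   sub-interval bounds partitioning `[0, levels - 1]`.
#' @export
split_points <- function(hist, t) {
  stopifnot(inherits(hist, "gray_histogram"))
  t <- as.integer(t)
  if (t < 1L) stop("`t` must be at least 1", call. = FALSE)
  n_occ <- sum(hist$counts > 0L)
  if (t > n_occ)
    stop("`t` exceeds the number of occupied gray levels (", n_occ, ")",
         call. = FALSE)
  leaves <- list(c(0L, hist$levels - 1L))
  occ <- which(hist$counts > 0L) - 1L
  count_in <- function(iv) sum(hist$counts[(iv[1]:iv[2]) + 1L])
  occ_in <- function(iv) sum(occ >= iv[1] & occ <= iv[2])
  while (length(leaves) < t) {
    splittable <- vapply(leaves, occ_in, integer(1)) >= 2L
    if (!any(splittable))
      stop("histogram cannot be split into ", t, " sub-intervals", call. = FALSE)
    wt <- vapply(leaves, count_in, numeric(1))
    wt[!splittable] <- -Inf
    lo <- vapply(leaves, `[`, integer(1), 1L)
    pick <- order(-wt, lo)[1]
    iv <- leaves[[pick]]
    s <- weighted_mean_split(hist, iv[1], iv[2])
    leaves[[pick]] <- c(iv[1], as.integer(s))
    leaves <- append(leaves, list(c(as.integer(s) + 1L, iv[2])),
                     after = pick)
  }
  bounds <- do.call(rbind, leaves)
  bounds <- bounds[order(bounds[, 1]), , drop = FALSE]
  pts <- bounds[-nrow(bounds), 2L]
  structure(as.integer(pts), intervals = bounds)
}

#' Mean-split sub-histogram equalization
#'
#' Splits the intensity range at the recursive CDF-weighted mean points
#' ([split_points()]), then equalizes each sub-image independently: within
#' sub-interval `[a_k, b_k]` an occupied level `l` maps to
#' `round(a_k + (CDF_k(l) - CDF_k(l_min)) / (1 - CDF_k(l_min)) * (b_k - a_k))`,
#' where `CDF_k` is the sub-image's own cumulative distribution. Each segment
#' is therefore stretched over its own input interval only, which limits the
#' global brightness shift and preserves intensity ordering between
#' segments. A sub-interval holding a single occupied level is left
#' unchanged (so a constant image is a fixed point). If the image has fewer
#' occupied levels than `t`, the number of segments is capped accordingly.
#'
#' @param img Intensity matrix in `[0, levels - 1]`.
#' @param t Requested number of sub-intervals (default 2).
#' @param levels Number of gray levels.
#' @return Equalized image of the same dimensions, values in
#'   `[0, levels - 1]`.
#' @export
equalize <- function(img, t = 2L, levels = 256L) {
  assert_gray_image(img, levels = levels)
  hist <- compute_histogram(img, levels)
  t_eff <- min(as.integer(t), sum(hist$counts > 0L))
  if (t_eff < 1L) stop("`t` must be at least 1", call. = FALSE)
  bounds <- if (t_eff == 1L) {
    matrix(c(0L, levels - 1L), 1L)
  } else {
    attr(split_points(hist, t_eff), "intervals")
  }
  lut <- 0:(levels - 1L)
  for (k in seq_len(nrow(bounds))) {
    a <- bounds[k, 1L]; b <- bounds[k, 2L]
    lv <- which(hist$counts > 0L) - 1L
    lv <- lv[lv >= a & lv <= b]
    if (length(lv) <= 1L) next  # single-level segment: identity
    p <- hist$counts[lv + 1L] / sum(hist$counts[lv + 1L])
    cdf <- cumsum(p)
    lut[lv + 1L] <- round(a + (cdf - cdf[1]) / (1 - cdf[1]) * (b - a))
  }
  matrix(lut[as.integer(img) + 1L], nrow(img), ncol(img))
}
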