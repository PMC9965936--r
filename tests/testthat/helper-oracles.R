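# Independent brute-force oracles. Each one recomputes an operation by the
# most literal method available (explicit loops, exhaustive enumeration) and
# shares no code with the implementation it checks.

# median filter: per-pixel window gather with clamped (edge-replicated)
# coordinates, explicit sort, middle order statistic
oracle_median_filter <- function(img, window) {
  h <- nrow(img); w <- ncol(img)
  k <- (window - 1) / 2
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      vals <- numeric(0)
      for (dr in -k:k) {
        for (dc in -k:k) {
          rr <- min(max(r + dr, 1), h)
          cc <- min(max(c + dc, 1), w)
          vals <- c(vals, img[rr, cc])
        }
      }
      out[r, c] <- sort(vals)[(window^2 + 1) / 2]
    }
  }
  out
}

# stack-based flood fill from one seed: admits 4-connected pixels whose
# value is within tau of the seed value
oracle_flood_fill <- function(img, seed, tau = 0) {
  h <- nrow(img); w <- ncol(img)
  ref <- img[seed[1], seed[2]]
  visited <- matrix(FALSE, h, w)
  stack <- list(seed)
  while (length(stack) > 0) {
    px <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    r <- px[1]; c <- px[2]
    if (r < 1 || r > h || c < 1 || c > w) next
    if (visited[r, c]) next
    if (abs(img[r, c] - ref) > tau) next
    visited[r, c] <- TRUE
    stack <- c(stack, list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1)))
  }
  visited
}

# co-occurrence features by explicit enumeration of every pixel pair at
# every offset (both directions), quantizing exactly as documented
oracle_glcm_features <- function(img, mask, offsets, levels = 16,
                                 gray_levels = 256) {
  h <- nrow(img); w <- ncol(img)
  q <- pmin(floor(img * levels / gray_levels), levels - 1)
  P <- matrix(0, levels, levels)
  for (o in seq_len(nrow(offsets))) {
    dr <- offsets[o, 1]; dc <- offsets[o, 2]
    for (r in seq_len(h)) {
      for (c in seq_len(w)) {
        r2 <- r + dr; c2 <- c + dc
        if (r2 < 1 || r2 > h || c2 < 1 || c2 > w) next
        if (!mask[r, c] || !mask[r2, c2]) next
        i <- q[r, c] + 1; j <- q[r2, c2] + 1
        P[i, j] <- P[i, j] + 1
        P[j, i] <- P[j, i] + 1  # symmetric count
      }
    }
  }
  P <- P / sum(P)
  iv <- matrix(0:(levels - 1), levels, levels)
  jv <- t(iv)
  mi <- sum(iv * P); mj <- sum(jv * P)
  si <- sqrt(sum((iv - mi)^2 * P)); sj <- sqrt(sum((jv - mj)^2 * P))
  c(glcm_contrast = sum(P * (iv - jv)^2),
    glcm_correlation = if (si > 0 && sj > 0)
      sum((iv - mi) * (jv - mj) * P) / (si * sj) else 0,
    glcm_energy = sum(P^2),
    glcm_homogeneity = sum(P / (1 + (iv - jv)^2)))
}

# valid-mode single-channel cross-correlation by explicit window loops
oracle_conv <- function(input, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  oh <- nrow(input) - kh + 1; ow <- ncol(input) - kw + 1
  out <- matrix(0, oh, ow)
  for (r in seq_len(oh)) {
    for (c in seq_len(ow)) {
      s <- 0
      for (m in seq_len(kh)) {
        for (n in seq_len(kw)) {
          s <- s + kernel[m, n] * input[r + m - 1, c + n - 1]
        }
      }
      out[r, c] <- s
    }
  }
  out
}

# AUC as the all-pairs concordance count (ties worth 1/2)
oracle_auc <- function(truth, prob) {
  pos <- prob[truth == 1]; neg <- prob[truth == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# classical global histogram equalization with the cdf-min convention,
# evaluated level by level
oracle_global_he <- function(img, levels = 256) {
  counts <- tabulate(as.integer(img) + 1, nbins = levels)
  occ <- which(counts > 0) - 1
  cdf <- cumsum(counts[occ + 1]) / sum(counts)
  m <- round((cdf - cdf[1]) / (1 - cdf[1]) * (levels - 1))
  lut <- 0:(levels - 1)
  lut[occ + 1] <- m
  matrix(lut[as.integer(img) + 1], nrow(img), ncol(img))
}

# per-level intensity mapping realized by an image transform (for order
# checks): value each sorted occupied input level maps to
level_mapping <- function(img, out) {
  lv <- sort(unique(as.vector(img)))
  vapply(lv, function(l) out[img == l][1], numeric(1))
}

random_gray_image <- function(h, w, levels = 256) {
  matrix(sample(0:(levels - 1), h * w, replace = TRUE), h, w)
}
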