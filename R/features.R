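#' Statistical moment features of a pixel multiset
#'
#' Population moments of the intensities in a region: mean, standard
#' deviation (square root of the second central moment), moment skewness
#' `m3 / m2^(3/2)` and kurtosis `m4 / m2^2` (subtract 3 via `excess = TRUE`
#' for the Fisher convention), plus the raw central moments and the pixel
#' count. A zero-variance region reports skewness and kurtosis 0 by
#' convention so that constant regions never yield undefined values.
#'
#' @param x Numeric vector of pixel intensities, at least one value.
#' @param excess Report excess kurtosis (minus 3)?
#' @return Named numeric vector: `mean`, `sd`, `skewness`, `kurtosis`,
#'   `m2`, `m3`, `m4`, `n`.
#' @examples
#' statistical_features(c(1, 2, 3))["skewness"]  # symmetric: 0
#' @export
statistical_features <- function(x, excess = FALSE) {
  if (length(x) < 1L) stop("at least one pixel is required", call. = FALSE)
  if (!is.numeric(x) || !all(is.finite(x)))
    stop("`x` must be numeric and finite", call. = FALSE)
  n <- length(x)
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2); m3 <- mean(d^3); m4 <- mean(d^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 - if (excess) 3 else 0 else 0
  c(mean = mu, sd = sqrt(m2), skewness = skew, kurtosis = kurt,
    m2 = m2, m3 = m3, m4 = m4, n = n)
}

default_glcm_offsets <- function() {
  rbind(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
}

#' Gray-level co-occurrence matrix
#'
#' Quantizes the image to `levels` gray bins and accumulates, over the given
#' pixel offsets, the counts of co-occurring bin pairs whose both endpoints
#' lie inside the region mask. The matrix is symmetrized (each pair counted
#' in both directions) and normalized to sum to 1.
#'
#' @param img Intensity matrix in `[0, gray_levels - 1]`.
#' @param mask Optional logical region mask (default: whole image).
#' @param offsets Integer matrix of `(row, col)` displacements; default
#'   distance-1 offsets in the four standard directions (0, 90, 45, 135
#'   degrees).
#' @param levels Number of quantization bins (default 16).
#' @param gray_levels Input gray range (default 256).
#' @return `levels x levels` normalized co-occurrence matrix of class
#'   `glcm`.
#' @export
glcm <- function(img, mask = NULL, offsets = default_glcm_offsets(),
                 levels = 16L, gray_levels = 256L) {
  assert_gray_image(img, levels = gray_levels)
  h <- nrow(img); w <- ncol(img)
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  if (!identical(dim(mask), dim(img)))
    stop("mask shape does not match the image", call. = FALSE)
  q <- pmin(floor(img * levels / gray_levels), levels - 1L)
  counts <- numeric(levels * levels)
  for (o in seq_len(nrow(offsets))) {
    dr <- offsets[o, 1]; dc <- offsets[o, 2]
    r_lo <- max(1L, 1L - dr); r_hi <- min(h, h - dr)
    c_lo <- max(1L, 1L - dc); c_hi <- min(w, w - dc)
    if (r_lo > r_hi || c_lo > c_hi) next
    ri <- r_lo:r_hi
    ci <- c_lo:c_hi
    a <- q[ri, ci, drop = FALSE]
    b <- q[ri + dr, ci + dc, drop = FALSE]
    sel <- mask[ri, ci, drop = FALSE] & mask[ri + dr, ci + dc, drop = FALSE]
    if (!any(sel)) next
    idx <- a[sel] * levels + b[sel] + 1L
    counts <- counts + tabulate(idx, nbins = levels * levels)
  }
  P <- matrix(counts, levels, levels, byrow = TRUE)  # row = first pixel's bin
  P <- P + t(P)
  tot <- sum(P)
  if (tot == 0) stop("no valid pixel pairs in the region", call. = FALSE)
  structure(P / tot, class = "glcm", levels = levels)
}

#' Haralick-style texture features from a co-occurrence matrix
#'
#' Computes contrast `sum P(i,j) (i-j)^2`, correlation
#' `sum (i-mu_i)(j-mu_j) P(i,j) / (sigma_i sigma_j)` (0 when either marginal
#' variance vanishes), energy `sum P^2` and homogeneity
#' `sum P / (1 + (i-j)^2)` over the normalized, symmetrized GLCM.
#'
#' @inheritParams glcm
#' @return Named numeric vector: `glcm_contrast`, `glcm_correlation`,
#'   `glcm_energy`, `glcm_homogeneity`.
#' @export
glcm_features <- function(img, mask = NULL, offsets = default_glcm_offsets(),
                          levels = 16L, gray_levels = 256L) {
  P <- glcm(img, mask, offsets, levels, gray_levels)
  lv <- seq_len(nrow(P)) - 1
  I <- matrix(lv, length(lv), length(lv))
  J <- t(I)
  mu_i <- sum(I * P); mu_j <- sum(J * P)
  s_i <- sqrt(sum((I - mu_i)^2 * P)); s_j <- sqrt(sum((J - mu_j)^2 * P))
  corr <- if (s_i > 0 && s_j > 0)
    sum((I - mu_i) * (J - mu_j) * P) / (s_i * s_j) else 0
  c(glcm_contrast = sum(P * (I - J)^2),
    glcm_correlation = corr,
    glcm_energy = sum(P^2),
    glcm_homogeneity = sum(P / (1 + (I - J)^2)))
}

feature_table_columns <- function() {
  c("mean", "sd", "skewness", "kurtosis", "m2", "m3", "m4", "area",
    "glcm_contrast", "glcm_correlation", "glcm_energy", "glcm_homogeneity",
    "whole_image", "label")
}

#' Build the per-image feature table
#'
#' One row per image: the statistical moments and GLCM texture features of
#' each image's candidate region, plus the region area and the class label.
#' When an image has no candidate region (or the region is too small for
#' co-occurrence pairs), whole-image features are used instead and the
#' `whole_image` flag is set.
#'
#' @param dataset A `labeled_dataset`.
#' @param candidates Optional list of [select_candidate()] results (or
#'   `NULL` entries), one per image.
#' @param images Optional list of processed intensity matrices to measure
#'   (default: the dataset's images).
#' @param glcm_levels Number of GLCM quantization bins.
#' @return A `data.frame` with the fixed column schema of
#'   `feature_table_columns()`, ending in `label`.
#' @export
build_feature_table <- function(dataset, candidates = NULL, images = NULL,
                                glcm_levels = 16L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (is.null(images)) images <- dataset$images
  n <- length(images)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    img <- images[[i]]
    mask <- NULL
    if (!is.null(candidates) && !is.null(candidates[[i]]))
      mask <- candidates[[i]]$mask
    whole <- is.null(mask) || sum(mask) < 2L
    if (whole) mask <- matrix(TRUE, nrow(img), ncol(img))
    sf <- statistical_features(img[mask])
    gf <- glcm_features(img, mask, levels = glcm_levels)
    rows[[i]] <- data.frame(mean = sf[["mean"]], sd = sf[["sd"]],
                            skewness = sf[["skewness"]],
                            kurtosis = sf[["kurtosis"]],
                            m2 = sf[["m2"]], m3 = sf[["m3"]], m4 = sf[["m4"]],
                            area = as.numeric(sum(mask)),
                            glcm_contrast = gf[["glcm_contrast"]],
                            glcm_correlation = gf[["glcm_correlation"]],
                            glcm_energy = gf[["glcm_energy"]],
                            glcm_homogeneity = gf[["glcm_homogeneity"]],
                            whole_image = whole,
                            label = dataset$labels[i])
  }
  do.call(rbind, rows)
}

#' Write / read a feature table losslessly
#'
#' Numeric columns are serialized with 17 significant digits so the CSV
#' round trip reproduces every double exactly.
#'
#' @param table A feature table from [build_feature_table()].
#' @param path CSV path.
#' @return `path` invisibly; `read_feature_table()` returns the table.
#' @export
write_feature_table <- function(table, path) {
  out <- table
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$whole_image <- as.logical(tab$whole_image)
  tab$label <- as.integer(tab$label)
  for (j in setdiff(names(tab), c("whole_image", "label")))
    tab[[j]] <- as.numeric(tab[[j]])
  tab
}
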