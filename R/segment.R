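#' Fuzzy c-means clustering
#'
#' Alternating-update fuzzy c-means: cluster centers are the
#' membership-weighted means of the data (weights raised to the fuzziness
#' exponent `m`) and memberships are the inverse-distance ratios
#' `mu_ij = 1 / sum_k (d_ij / d_ik)^(2/(m-1))`. Iteration stops when the
#' maximum center displacement falls below `tol` or `max_iter` cycles have
#' run. Memberships are initialized uniformly at random from `seed`; since
#' the objective is nonconvex and a single run can settle in a degenerate
#' local minimum (e.g. splitting one broad intensity mode while merging a
#' small one), `restarts` independent seeded initializations are run and
#' the partition with the lowest final objective is kept. The fit is fully
#' reproducible given `seed`. A point coinciding with a center receives
#' membership 1 there and 0 elsewhere.
#'
#' @param x Numeric vector (1-D intensities) or matrix of points by rows.
#' @param centers Number of clusters `c`, between 1 and `nrow(x)`.
#' @param m Fuzziness exponent, greater than 1 (2 is the conventional
#'   choice; values near 1 approach hard k-means).
#' @param tol Positive convergence tolerance on center displacement.
#' @param max_iter Maximum number of update cycles.
#' @param seed Integer seed for the membership initialization.
#' @param restarts Number of independent initializations (best objective
#'   wins; restart seeds are derived from `seed`).
#' @return An object of class `fcm_partition`: `centers` (c x p matrix),
#'   `membership` (n x c, rows summing to 1), `cluster` (hard assignment),
#'   `objective` (value of `sum mu^m d^2` after each cycle, nonincreasing),
#'   `iterations`, `converged`, plus the call parameters.
#' @examples
#' fit <- fcm_fit(c(0, 0, 10, 10), centers = 2, seed = 1)
#' sort(drop(fit$centers))
#' @export
fcm_fit <- function(x, centers = 3L, m = 2, tol = 1e-4, max_iter = 100L,
                    seed = 1L, restarts = 5L) {
  if (restarts > 1L) {
    fits <- lapply(seq_len(restarts), function(r) {
      fcm_fit(x, centers, m, tol, max_iter, seed = derive_seed(seed, r),
              restarts = 1L)
    })
    objs <- vapply(fits, function(f) f$objective[f$iterations], numeric(1))
    best <- fits[[which.min(objs)]]
    best$seed <- as.integer(seed)
    best$restarts <- as.integer(restarts)
    return(best)
  }
  X <- as.matrix(x)
  if (!is.numeric(X) || !all(is.finite(X)))
    stop("`x` must be numeric and finite", call. = FALSE)
  n <- nrow(X); cc <- as.integer(centers)
  if (cc < 1L) stop("`centers` must be at least 1", call. = FALSE)
  if (cc > n) stop("more clusters than data points", call. = FALSE)
  if (m <= 1) stop("fuzziness `m` must exceed 1", call. = FALSE)
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)

  U <- with_local_seed(seed, {
    u <- matrix(stats::runif(n * cc), n, cc)
    u / rowSums(u)
  })
  V <- matrix(0, cc, ncol(X))
  obj <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Um <- U^m
    V_old <- V
    V <- (t(Um) %*% X) / colSums(Um)
    D2 <- matrix(rowSums(X^2), n, cc) - 2 * X %*% t(V) +
      matrix(rowSums(V^2), n, cc, byrow = TRUE)
    D2 <- pmax(D2, 0)
    zero <- D2 == 0
    W <- D2^(-1 / (m - 1))  # (d^2)^{-1/(m-1)} = d^{-2/(m-1)}
    U <- W / rowSums(W)
    zr <- which(rowSums(zero) > 0L)
    if (length(zr)) {
      U[zr, ] <- 0
      U[zr, ] <- zero[zr, , drop = FALSE] / rowSums(zero[zr, , drop = FALSE])
    }
    obj <- c(obj, sum(U^m * D2))
    if (it > 1L && max(abs(V - V_old)) < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(centers = V, membership = U,
                 cluster = max.col(U, ties.method = "first"),
                 objective = obj, iterations = it, converged = converged,
                 m = m, c = cc, tol = tol, seed = as.integer(seed)),
            class = "fcm_partition")
}

#' @export
print.fcm_partition <- function(x, ...) {
  cat(sprintf("fcm_partition: %d clusters, m = %g, %d iterations (%s)\n",
              x$c, x$m, x$iterations,
              if (x$converged) "converged" else "max_iter reached"))
  cat("centers:\n"); print(x$centers)
  invisible(x)
}

#' Select region-growing seed pixels from a fuzzy partition
#'
#' The cluster center of an intensity-space partition is a gray value, not a
#' location; to anchor region growing spatially, each cluster's seed is the
#' pixel with maximal membership to that cluster, ties broken by row-major
#' pixel order (row 1 left-to-right first). The partition must have been
#' fitted on the image's intensities in row-major order
#' (`as.numeric(t(img))`). Clusters to which no pixel is assigned are
#' skipped with a warning.
#'
#' @param partition An [fcm_fit()] result over the image's pixels.
#' @param img The intensity matrix the partition was fitted on.
#' @return Integer matrix with one row per retained cluster and columns
#'   `row`, `col`; attribute `"cluster"` gives the originating cluster index
#'   and `"center"` its center intensity.
#' @export
select_seeds <- function(partition, img) {
  stopifnot(inherits(partition, "fcm_partition"))
  assert_gray_image(img)
  w <- ncol(img)
  if (nrow(partition$membership) != length(img))
    stop("partition size does not match the image", call. = FALSE)
  keep <- integer(0)
  seeds <- NULL
  for (j in seq_len(partition$c)) {
    if (!any(partition$cluster == j)) {
      warning("cluster ", j, " is empty; skipped", call. = FALSE)
      next
    }
    colj <- partition$membership[, j]
    cand <- which(colj == max(colj))   # row-major indices
    seeds <- rbind(seeds, rm_index_to_rc(min(cand), w))
    keep <- c(keep, j)
  }
  structure(seeds, cluster = keep,
            center = partition$centers[keep, 1L])
}

#' Seeded region growing
#'
#' Grows one region per seed by sweep-synchronous expansion: in every sweep
#' each region (in seed order) admits the unlabeled neighbors, under the
#' declared connectivity, whose intensity lies within `tau` gray levels of
#' the region's reference value. The reference is by default the running
#' mean of the intensities admitted so far (`"seed"` keeps the seed's
#' value). A pixel is claimed by the first region to reach it, so regions
#' stay pairwise disjoint and connected; growth terminates on the first
#' sweep in which no region changes.
#'
#' @param img Intensity matrix.
#' @param seeds Integer matrix of seed coordinates, one `(row, col)` per
#'   region, e.g. from [select_seeds()].
#' @param tau Nonnegative similarity threshold in gray levels; a scalar
#'   shared by all regions or one value per seed.
#' @param connectivity 4 or 8.
#' @param reference `"mean"` (running region mean, default) or `"seed"`.
#' @return An object of class `region_map`: `labels` (integer matrix, 0 =
#'   unassigned), `seeds`, `tau`, `connectivity`, `n_regions`, `sweeps` and
#'   `region_sizes`.
#' @export
region_grow <- function(img, seeds, tau, connectivity = 4L,
                        reference = c("mean", "seed")) {
  assert_gray_image(img)
  reference <- match.arg(reference)
  if (!is.matrix(seeds)) seeds <- matrix(seeds, ncol = 2L)
  if (nrow(seeds) < 1L) stop("at least one seed is required", call. = FALSE)
  if (any(tau < 0)) stop("`tau` must be nonnegative", call. = FALSE)
  tau <- rep_len(tau, nrow(seeds))
  if (!connectivity %in% c(4L, 8L))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  h <- nrow(img); w <- ncol(img)
  if (any(seeds[, 1] < 1L | seeds[, 1] > h | seeds[, 2] < 1L | seeds[, 2] > w))
    stop("seed out of image bounds", call. = FALSE)

  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8L)
    offs <- rbind(offs, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))

  k <- nrow(seeds)
  labels <- matrix(0L, h, w)
  sums <- numeric(k); counts <- integer(k); seedval <- numeric(k)
  for (i in seq_len(k)) {
    r <- seeds[i, 1]; c <- seeds[i, 2]
    seedval[i] <- img[r, c]
    if (labels[r, c] == 0L) {
      labels[r, c] <- i
      sums[i] <- img[r, c]; counts[i] <- 1L
    } else {
      warning("seed ", i, " falls on an already-claimed pixel; region empty",
              call. = FALSE)
    }
  }
  sweeps <- 0L
  repeat {
    changed <- 0L
    for (i in seq_len(k)) {
      if (counts[i] == 0L) next
      maski <- labels == i
      nb <- matrix(FALSE, h, w)
      for (o in seq_len(nrow(offs)))
        nb <- nb | shift_mat(maski, offs[o, 1], offs[o, 2], FALSE)
      nb <- nb & labels == 0L
      if (!any(nb)) next
      ref <- if (reference == "mean") sums[i] / counts[i] else seedval[i]
      adm <- nb & abs(img - ref) <= tau[i]
      nadm <- sum(adm)
      if (nadm > 0L) {
        labels[adm] <- i
        sums[i] <- sums[i] + sum(img[adm])
        counts[i] <- counts[i] + nadm
        changed <- changed + nadm
      }
    }
    sweeps <- sweeps + 1L
    if (changed == 0L) break
  }
  structure(list(labels = labels, seeds = seeds, tau = tau,
                 connectivity = as.integer(connectivity),
                 n_regions = k, sweeps = sweeps, region_sizes = counts),
            class = "region_map")
}

# boundary pixels: region pixels with at least one 4-neighbor outside the
# region (image-edge pixels count as boundary)
region_boundary <- function(mask) {
  inner <- shift_mat(mask, 1, 0, FALSE) & shift_mat(mask, -1, 0, FALSE) &
    shift_mat(mask, 0, 1, FALSE) & shift_mat(mask, 0, -1, FALSE)
  mask & !inner
}

# central-difference gradient magnitude with edge replication
gradient_magnitude <- function(img) {
  p <- edge_pad(img, 1L)
  h <- nrow(img); w <- ncol(img)
  gx <- (p[1 + seq_len(h), 2 + seq_len(w)] - p[1 + seq_len(h), seq_len(w)]) / 2
  gy <- (p[2 + seq_len(h), 1 + seq_len(w)] - p[seq_len(h), 1 + seq_len(w)]) / 2
  sqrt(gx^2 + gy^2)
}

#' Select the candidate tumor region
#'
#' Ranks grown regions by how much they look like a compact, edge-supported
#' blob: the score is circularity (`4 * pi * area / perimeter^2`, with the
#' perimeter taken as the boundary pixel count) multiplied by edge support
#' (the fraction of boundary pixels whose gradient magnitude exceeds the
#' image's median gradient). The highest-scoring region is returned; ties go
#' to the larger region, then the lower region id. Regions smaller than
#' `min_area` are excluded (unless no region reaches it): the discrete
#' circularity measure degenerates for few-pixel blobs, which would let
#' residual impulse specks outscore any anatomically plausible region.
#'
#' @param regions A [region_grow()] result.
#' @param img The intensity matrix the regions were grown on.
#' @param min_area Smallest region size (pixels) eligible for selection.
#' @param exclude Region ids never eligible (e.g. the region grown from the
#'   background cluster's seed); ignored if it would leave no region.
#' @return An object of class `candidate_region`: `id`, logical `mask` and
#'   `boundary`, `area`, `circularity`, `edge_support`, `score` and a
#'   per-region score `table`.
#' @export
select_candidate <- function(regions, img, min_area = 8L, exclude = integer(0)) {
  stopifnot(inherits(regions, "region_map"))
  assert_gray_image(img)
  ids <- which(regions$region_sizes > 0L)
  if (length(ids) == 0L) stop("no nonbackground regions", call. = FALSE)
  kept <- setdiff(ids, exclude)
  if (length(kept) > 0L) ids <- kept
  big <- ids[regions$region_sizes[ids] >= min_area]
  if (length(big) > 0L) ids <- big
  gm <- gradient_magnitude(img)
  medg <- stats::median(gm)
  tab <- data.frame(id = ids, area = NA_real_, perimeter = NA_real_,
                    circularity = NA_real_, edge_support = NA_real_,
                    score = NA_real_)
  for (r in seq_along(ids)) {
    mask <- regions$labels == ids[r]
    bnd <- region_boundary(mask)
    area <- sum(mask); per <- sum(bnd)
    circ <- 4 * pi * area / per^2
    edge <- mean(gm[bnd] > medg)
    tab[r, -1] <- c(area, per, circ, edge, circ * edge)
  }
  pick <- order(-tab$score, -tab$area, tab$id)[1]
  id <- tab$id[pick]
  mask <- regions$labels == id
  structure(list(id = id, mask = mask, boundary = region_boundary(mask),
                 area = tab$area[pick], circularity = tab$circularity[pick],
                 edge_support = tab$edge_support[pick],
                 score = tab$score[pick], table = tab),
            class = "candidate_region")
}

#' Pixel accuracy and Dice overlap between two masks
#'
#' @param predicted,truth Logical (or 0/1) matrices of identical shape.
#' @return List with `pixel_accuracy` (fraction of matching pixels) and
#'   `dice` (`2|A n B| / (|A| + |B|)`; two empty masks give 1).
#' @export
segmentation_metrics <- function(predicted, truth) {
  if (!identical(dim(predicted), dim(truth)))
    stop("mask shapes differ", call. = FALSE)
  p <- predicted > 0; t <- truth > 0
  inter <- sum(p & t)
  denom <- sum(p) + sum(t)
  list(pixel_accuracy = mean(p == t),
       dice = if (denom == 0L) 1 else 2 * inter / denom)
}
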