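#' Specify a synthetic brain phantom
#'
#' A phantom is a square 8-bit image holding an elliptical "brain" on a dark
#' background, optionally carrying a brighter circular "tumor" blob, with
#' additive Gaussian noise followed by salt-and-pepper impulses. It emulates
#' the two-class (tumor / no tumor) axial MR slice layout that the pipeline
#' classifies, and carries exact ground truth (tumor mask and binary label)
#' so every downstream stage can be validated.
#'
#' @param size Image side in pixels (square image).
#' @param brain_axes Length-2 numeric, horizontal and vertical semi-axes of
#'   the brain ellipse in pixels.
#' @param brain_intensity,background_intensity,tumor_intensity Gray levels in
#'   `[0, levels - 1]`.
#' @param tumor Logical; is a tumor present (label 1)?
#' @param tumor_center Length-2 `(row, col)` center of the tumor disk;
#'   default places it slightly off the brain center.
#' @param tumor_radius Tumor disk radius in pixels.
#' @param noise_sigma Standard deviation of the additive Gaussian noise, in
#'   gray levels.
#' @param salt_pepper Fraction of pixels replaced by extreme impulses
#'   (0 or `levels - 1`), in `[0, 0.5]`.
#' @param levels Number of gray levels (default 256, i.e. 8-bit).
#' @param seed Integer seed making the rendered phantom fully reproducible.
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(tumor = TRUE, noise_sigma = 0, salt_pepper = 0)
#' ph <- generate_phantom(spec)
#' table(ph$image)  # three intensity plateaus
#' @export
phantom_spec <- function(size = 64L,
                         brain_axes = c(24, 20),
                         brain_intensity = 120,
                         background_intensity = 20,
                         tumor = TRUE,
                         tumor_center = NULL,
                         tumor_radius = 6,
                         tumor_intensity = 220,
                         noise_sigma = 5,
                         salt_pepper = 0.02,
                         levels = 256L,
                         seed = 1L) {
  size <- as.integer(size)
  if (size < 8L) stop("`size` must be at least 8 pixels", call. = FALSE)
  if (length(brain_axes) != 2L || any(brain_axes <= 0))
    stop("`brain_axes` must be two positive semi-axes", call. = FALSE)
  if (any(brain_axes >= size / 2))
    stop("brain ellipse must fit inside the image", call. = FALSE)
  ints <- c(brain_intensity, background_intensity, tumor_intensity)
  if (any(ints < 0) || any(ints > levels - 1))
    stop("intensities must lie in [0, ", levels - 1L, "]", call. = FALSE)
  if (salt_pepper < 0 || salt_pepper > 0.5)
    stop("`salt_pepper` must lie in [0, 0.5]", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (is.null(tumor_center))
    tumor_center <- round(c(size / 2 - 4, size / 2 + 5))
  if (tumor) {
    if (tumor_radius <= 0) stop("`tumor_radius` must be positive", call. = FALSE)
    cy <- (size + 1) / 2; cx <- (size + 1) / 2
    ax <- brain_axes[1] - tumor_radius
    ay <- brain_axes[2] - tumor_radius
    if (ax <= 0 || ay <= 0 ||
        ((tumor_center[2] - cx) / ax)^2 + ((tumor_center[1] - cy) / ay)^2 > 1)
      stop("tumor disk must lie fully inside the brain ellipse", call. = FALSE)
  }
  structure(list(size = size, brain_axes = brain_axes,
                 brain_intensity = brain_intensity,
                 background_intensity = background_intensity,
                 tumor = isTRUE(tumor), tumor_center = tumor_center,
                 tumor_radius = tumor_radius, tumor_intensity = tumor_intensity,
                 noise_sigma = noise_sigma, salt_pepper = salt_pepper,
                 levels = as.integer(levels), seed = as.integer(seed)),
            class = "phantom_spec")
}

# noiseless template: background / brain ellipse / tumor disk
phantom_template <- function(spec) {
  n <- spec$size
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  cy <- (n + 1) / 2; cx <- (n + 1) / 2
  brain <- ((cols - cx) / spec$brain_axes[1])^2 +
           ((rows - cy) / spec$brain_axes[2])^2 <= 1
  img <- matrix(spec$background_intensity, n, n)
  img[brain] <- spec$brain_intensity
  mask <- matrix(FALSE, n, n)
  if (spec$tumor) {
    mask <- (rows - spec$tumor_center[1])^2 + (cols - spec$tumor_center[2])^2 <=
      spec$tumor_radius^2
    img[mask] <- spec$tumor_intensity
  }
  list(image = img, mask = mask)
}

#' Render a brain phantom with ground truth
#'
#' Renders the noiseless template described by a [phantom_spec()] (background,
#' brain ellipse, optional tumor disk), then adds Gaussian noise (rounded and
#' clamped to the gray range) and finally replaces a fixed fraction of pixels
#' with salt-and-pepper impulses. The tumor mask always marks exactly the
#' noiseless tumor disk, regardless of noise.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom` with elements `image` (intensity
#'   matrix), `mask` (logical tumor mask) and `label` (1 if a tumor is
#'   present, else 0).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  tmpl <- phantom_template(spec)
  img <- tmpl$image
  n2 <- length(img)
  with_local_seed(spec$seed, {
    if (spec$noise_sigma > 0) {
      img <- round(img + stats::rnorm(n2, 0, spec$noise_sigma))
      img <- clamp(img, 0, spec$levels - 1)
    }
    if (spec$salt_pepper > 0) {
      k <- round(spec$salt_pepper * n2)
      if (k > 0) {
        idx <- sample.int(n2, k)
        img[idx] <- sample(c(0, spec$levels - 1), k, replace = TRUE)
      }
    }
  })
  structure(list(image = img, mask = tmpl$mask,
                 label = as.integer(spec$tumor)),
            class = "phantom")
}

#' Generate a labeled phantom dataset
#'
#' Draws `n` phantoms whose geometry, intensities and noise realizations are
#' jittered deterministically from `seed`, with a fixed class balance. The
#' per-image jitter varies tumor position and radius, brain axes and tissue
#' intensities around the template values so that images are not trivially
#' identical within a class.
#'
#' @param n Number of images (at least 2).
#' @param balance Proportion of tumor (label 1) images, strictly in (0, 1);
#'   both classes are always represented.
#' @param template A [phantom_spec()] providing baseline parameters.
#' @param seed Integer seed; the same seed reproduces the dataset bit for bit.
#' @param jitter Logical; disable to render every image from the unmodified
#'   template (aside from its per-image noise seed).
#' @return A list of class `labeled_dataset` with elements `images`, `masks`
#'   (`NULL` entries for tumor-free images), `labels`, `specs` and `split`
#'   (filled by [split_dataset()]).
#' @export
generate_dataset <- function(n = 100L, balance = 0.5,
                             template = phantom_spec(), seed = 1L,
                             jitter = TRUE) {
  n <- as.integer(n)
  if (n < 2L) stop("`n` must be at least 2", call. = FALSE)
  if (balance <= 0 || balance >= 1)
    stop("`balance` must be strictly between 0 and 1", call. = FALSE)
  n_pos <- clamp(round(n * balance), 1L, n - 1L)
  labels <- with_local_seed(seed,
    sample(rep(c(1L, 0L), c(n_pos, n - n_pos))))
  img_seeds <- with_local_seed(derive_seed(seed, 1L),
    sample.int(.Machine$integer.max - 1L, n))
  specs <- vector("list", n)
  images <- vector("list", n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- template
    sp$tumor <- labels[i] == 1L
    sp$seed <- img_seeds[i]
    if (jitter) {
      sp <- with_local_seed(derive_seed(seed, 100L + i), jitter_spec(sp))
    }
    sp <- do.call(phantom_spec, unclass(sp))  # re-validate
    ph <- generate_phantom(sp)
    specs[[i]] <- sp
    images[[i]] <- ph$image
    if (ph$label == 1L) masks[[i]] <- ph$mask
  }
  structure(list(images = images, masks = masks, labels = labels,
                 specs = specs, split = rep(NA_character_, n)),
            class = "labeled_dataset")
}

# deterministic per-image variation around the template spec
jitter_spec <- function(sp) {
  sp$brain_axes <- sp$brain_axes + sample(-2:2, 2, replace = TRUE)
  sp$brain_intensity <- clamp(sp$brain_intensity + sample(-10:10, 1),
                              0, sp$levels - 1)
  sp$tumor_intensity <- clamp(sp$tumor_intensity + sample(-10:10, 1),
                              0, sp$levels - 1)
  if (sp$tumor) {
    sp$tumor_radius <- sample(4:8, 1)
    sp$tumor_center <- round(sp$size / 2) + sample(-5:5, 2, replace = TRUE)
  }
  sp
}

#' Assign a stratified train/test split
#'
#' @param dataset A `labeled_dataset`.
#' @param train_frac Proportion of each class assigned to the training split.
#' @param seed Integer seed for the stratified draw.
#' @return The dataset with its `split` element filled with `"train"` /
#'   `"test"`.
#' @export
split_dataset <- function(dataset, train_frac = 0.8, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (train_frac <= 0 || train_frac >= 1)
    stop("`train_frac` must be strictly between 0 and 1", call. = FALSE)
  split <- rep("test", length(dataset$labels))
  with_local_seed(seed, {
    for (cl in unique(dataset$labels)) {
      idx <- which(dataset$labels == cl)
      k <- clamp(round(train_frac * length(idx)), 1L, length(idx) - 1L)
      split[sample(idx, k)] <- "train"
    }
  })
  dataset$split <- split
  dataset
}

#' Export a dataset in the two-folder layout
#'
#' Writes `root/yes/*.png` and `root/no/*.png` (tumor and tumor-free images),
#' ground-truth masks under `root/masks/` mirrored by filename, and a
#' `manifest.csv` with columns `filename`, `label`, `split`, `seed` that
#' preserves the original image order for a lossless round trip with
#' [read_image_folder()].
#'
#' @param dataset A `labeled_dataset`.
#' @param dir Output root directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  for (d in file.path(dir, c("yes", "no", "masks")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset$images)
  fn <- sprintf("img_%04d.png", seq_len(n))
  for (i in seq_len(n)) {
    sub <- if (dataset$labels[i] == 1L) "yes" else "no"
    write_gray_image(dataset$images[[i]], file.path(dir, sub, fn[i]))
    if (!is.null(dataset$masks[[i]]))
      write_gray_image(dataset$masks[[i]] * 255, file.path(dir, "masks", fn[i]))
  }
  seeds <- vapply(dataset$specs, function(s) if (is.null(s)) NA_integer_ else s$seed,
                  integer(1))
  utils::write.csv(
    data.frame(filename = fn, label = dataset$labels,
               split = dataset$split, seed = seeds,
               stringsAsFactors = FALSE),
    file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an image dataset in the two-folder layout
#'
#' Reads `root/yes` (label 1) and `root/no` (label 0), converting color
#' inputs to grayscale with the fixed BT.601 luminance rule. Masks under
#' `root/masks/` with matching filenames are attached when present. If a
#' `manifest.csv` written by [write_dataset()] exists, its row order, labels
#' and split assignment are used, making the export/import round trip exact;
#' otherwise files are taken in sorted order, `yes` before `no`.
#'
#' @param path Dataset root directory.
#' @return A `labeled_dataset`.
#' @export
read_image_folder <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  manifest <- file.path(path, "manifest.csv")
  if (file.exists(manifest)) {
    man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    fn <- man$filename
    labels <- as.integer(man$label)
    split <- as.character(man$split)
  } else {
    yes <- sort(list.files(file.path(path, "yes"), pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE))
    no <- sort(list.files(file.path(path, "no"), pattern = "\\.(png|tif|tiff)$",
                          ignore.case = TRUE))
    fn <- c(yes, no)
    labels <- rep(c(1L, 0L), c(length(yes), length(no)))
    split <- rep(NA_character_, length(fn))
  }
  if (length(fn) == 0L)
    stop("no images found under ", path, call. = FALSE)
  images <- vector("list", length(fn))
  masks <- vector("list", length(fn))
  for (i in seq_along(fn)) {
    sub <- if (labels[i] == 1L) "yes" else "no"
    images[[i]] <- read_gray_image(file.path(path, sub, fn[i]))
    mp <- file.path(path, "masks", fn[i])
    if (file.exists(mp)) masks[[i]] <- read_gray_image(mp) > 0
  }
  structure(list(images = images, masks = masks, labels = labels,
                 specs = vector("list", length(fn)), split = split),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d images (%d tumor, %d tumor-free)\n",
              length(x$images), sum(x$labels == 1L), sum(x$labels == 0L)))
  if (!all(is.na(x$split)))
    cat(sprintf("  split: %d train / %d test\n",
                sum(x$split == "train", na.rm = TRUE),
                sum(x$split == "test", na.rm = TRUE)))
  invisible(x)
}
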