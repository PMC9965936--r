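#' Pipeline configuration
#'
#' Collects and validates every stage's parameters before any work starts.
#' Defaults reflect the standard study conditions: 64 x 64 phantoms with a
#' high-contrast tumor, mild Gaussian noise (sigma 5) and 2% impulse
#' noise; 3 x 3 median window; bi-histogram equalization (`t = 2`); three
#' intensity clusters (background, brain, tumor) with fuzziness 2; automatic
#' growth threshold (twice the pooled within-cluster standard deviation);
#' an 80/20 stratified split; and a small conv net trained by gradient
#' descent then refined on its output layer.
#'
#' @param n_images Dataset size when generating phantoms.
#' @param balance Tumor class proportion.
#' @param template [phantom_spec()] template for generation.
#' @param data_dir Optional existing dataset root ([read_image_folder()]
#'   layout); when given, generation parameters are ignored.
#' @param train_frac Training fraction of the stratified split.
#' @param window Median filter window side (odd).
#' @param subhist Number of equalization sub-histograms `t`.
#' @param clusters,fuzziness Fuzzy c-means cluster count and exponent.
#' @param tau Growth threshold in gray levels, or `"auto"`.
#' @param connectivity 4 or 8.
#' @param grow_on Which preprocessed image segmentation operates on:
#'   `"denoised"` (default) or `"equalized"`. Clustering relies on the
#'   intensity-plateau structure that equalization deliberately flattens,
#'   so the denoised image is the stabler substrate; the equalized image is
#'   still used for feature extraction and the classifier input.
#' @param glcm_levels GLCM quantization bins.
#' @param input_side,n_filters,kernel,pool Network architecture.
#' @param learning_rate,epochs,batch_size Gradient-descent stage.
#' @param refine_pop,refine_iters Metaheuristic refinement budget (either 0
#'   disables refinement).
#' @param seed Global seed; every stage seed is derived from it.
#' @param out_dir Optional artifact directory; when set, the run writes
#'   metrics, ROC table, manifest, feature table and model files.
#' @param write_images Also write processed images and label maps (slower).
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_images = 100L, balance = 0.5,
                            template = phantom_spec(), data_dir = NULL,
                            train_frac = 0.8,
                            window = 3L, subhist = 2L,
                            clusters = 3L, fuzziness = 2, tau = "auto",
                            connectivity = 4L, grow_on = c("denoised", "equalized"),
                            glcm_levels = 16L,
                            input_side = 64L, n_filters = 8L, kernel = 3L,
                            pool = 2L,
                            learning_rate = 0.5, epochs = 30L, batch_size = 16L,
                            refine_pop = 20L, refine_iters = 30L,
                            seed = 1L, out_dir = NULL, write_images = FALSE) {
  grow_on <- match.arg(grow_on)
  stopifnot(inherits(template, "phantom_spec"))
  if (is.null(data_dir)) {
    if (n_images < 2L) stop("`n_images` must be at least 2", call. = FALSE)
    if (balance <= 0 || balance >= 1)
      stop("`balance` must be strictly between 0 and 1", call. = FALSE)
  }
  if (train_frac <= 0 || train_frac >= 1)
    stop("`train_frac` must be strictly between 0 and 1", call. = FALSE)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be odd and >= 3", call. = FALSE)
  if (subhist < 1L) stop("`subhist` must be at least 1", call. = FALSE)
  if (clusters < 1L) stop("`clusters` must be at least 1", call. = FALSE)
  if (fuzziness <= 1) stop("`fuzziness` must exceed 1", call. = FALSE)
  if (!identical(tau, "auto") && (!is.numeric(tau) || tau < 0))
    stop("`tau` must be \"auto\" or a nonnegative number", call. = FALSE)
  if (!connectivity %in% c(4L, 8L))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  if (learning_rate < 0) stop("`learning_rate` must be >= 0", call. = FALSE)
  if (epochs < 1L) stop("`epochs` must be at least 1", call. = FALSE)
  if (input_side - kernel + 1L < pool)
    stop("network dimensions are inconsistent", call. = FALSE)
  structure(list(n_images = as.integer(n_images), balance = balance,
                 template = template, data_dir = data_dir,
                 train_frac = train_frac, window = as.integer(window),
                 subhist = as.integer(subhist), clusters = as.integer(clusters),
                 fuzziness = fuzziness, tau = tau,
                 connectivity = as.integer(connectivity), grow_on = grow_on,
                 glcm_levels = as.integer(glcm_levels),
                 input_side = as.integer(input_side),
                 n_filters = as.integer(n_filters), kernel = as.integer(kernel),
                 pool = as.integer(pool), learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 refine_pop = as.integer(refine_pop),
                 refine_iters = as.integer(refine_iters),
                 seed = as.integer(seed), out_dir = out_dir,
                 write_images = isTRUE(write_images)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key/value document mirroring the [pipeline_config()] arguments; a
#' `template:` block holds [phantom_spec()] arguments. Unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$template)) raw$template <- do.call(phantom_spec, raw$template)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, raw)
}

# fuzzy-weighted within-cluster intensity standard deviations: the
# variance companion of the membership-weighted center, so boundary pixels
# with partial membership widen the estimate appropriately
within_cluster_sd <- function(x, partition) {
  V <- partition$centers[, 1L]
  Um <- partition$membership^partition$m
  vapply(seq_len(partition$c), function(j) {
    sqrt(sum(Um[, j] * (x - V[j])^2) / sum(Um[, j]))
  }, numeric(1))
}

# denoise, equalize, segment and mask every image of a dataset; the
# classifier input is the candidate-masked image on the segmentation
# substrate (absolute intensities stay comparable across images, unlike
# per-image equalized ones)
pipeline_inputs <- function(dataset, config, seed) {
  n <- length(dataset$images)
  denoised <- lapply(dataset$images, median_filter, window = config$window)
  equalized <- lapply(denoised, equalize, t = config$subhist)
  base_imgs <- if (config$grow_on == "equalized") equalized else denoised
  seg <- vector("list", n)
  for (i in seq_len(n))
    seg[[i]] <- segment_image(base_imgs[[i]], config, derive_seed(seed, i))
  candidates <- lapply(seg, `[[`, "candidate")
  inputs <- vector("list", n)
  for (i in seq_len(n)) {
    img <- base_imgs[[i]]
    if (!is.null(candidates[[i]])) img <- img * candidates[[i]]$mask
    inputs[[i]] <- resize_image(img, config$input_side)
  }
  list(denoised = denoised, equalized = equalized, base = base_imgs,
       seg = seg, candidates = candidates, inputs = inputs)
}

# preprocess + segment a single image; returns NULL candidate when no
# region can be selected
segment_image <- function(base, config, seed) {
  x <- rm_order_values(base)
  part <- fcm_fit(x, centers = config$clusters, m = config$fuzziness,
                  seed = seed)
  seeds <- suppressWarnings(select_seeds(part, base))
  tau <- if (identical(config$tau, "auto")) {
    2 * within_cluster_sd(x, part)[attr(seeds, "cluster")]
  } else config$tau
  map <- region_grow(base, seeds, tau, config$connectivity)
  # the darkest cluster is background by construction; its region is not a
  # plausible lesion candidate
  darkest <- which.min(attr(seeds, "center"))
  cand <- tryCatch(select_candidate(map, base, exclude = darkest),
                   error = function(e) NULL)
  list(partition = part, map = map, candidate = cand, tau = tau)
}

#' Run the full tumor-classification pipeline
#'
#' Executes generate (or load) -> denoise -> equalize -> segment ->
#' extract features -> train -> refine -> predict -> evaluate, with every
#' stage seed derived from the global seed so two runs with the same
#' configuration are identical down to the bytes of the metrics JSON.
#' Segmentation quality (Dice of the candidate region against the ground
#' truth mask) is reported over the images that carry a mask; the classifier
#' is trained on the masked preprocessed images of the training split and
#' evaluated on the held-out test split.
#'
#' @param config A [pipeline_config()].
#' @return List of class `hhocnn_run`: `metrics` (test-set
#'   [compute_metrics()] report), `segmentation` (`dice` per masked image,
#'   `mean_dice_tumor`, `mean_pixel_accuracy`), `predictions`,
#'   `feature_table`, `model`, `refinement`, `loss_history`, `dataset`
#'   (with split), `config` and, when `out_dir` is set, `paths` of written
#'   artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- with_local_seed(config$seed, sample.int(2^31 - 2, 8L))

  # 1. data
  dataset <- if (is.null(config$data_dir)) {
    generate_dataset(config$n_images, config$balance, config$template,
                     seed = seeds[1])
  } else {
    read_image_folder(config$data_dir)
  }
  if (all(is.na(dataset$split)))
    dataset <- split_dataset(dataset, config$train_frac, seeds[2])
  n <- length(dataset$images)

  # 2-5. preprocessing, segmentation, features, classifier inputs
  prep <- pipeline_inputs(dataset, config, seeds[3])
  candidates <- prep$candidates
  dice <- pixacc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.null(dataset$masks[[i]]) || is.null(candidates[[i]])) next
    sm <- segmentation_metrics(candidates[[i]]$mask, dataset$masks[[i]])
    dice[i] <- sm$dice; pixacc[i] <- sm$pixel_accuracy
  }
  feats <- build_feature_table(dataset, candidates, images = prep$equalized,
                               glcm_levels = config$glcm_levels)
  inputs <- prep$inputs
  tr <- which(dataset$split == "train")
  te <- which(dataset$split == "test")

  model <- cnn_init(config$input_side, config$n_filters, config$kernel,
                    config$pool, seed = seeds[4])
  fit <- train_gd(model, inputs[tr], dataset$labels[tr],
                  learning_rate = config$learning_rate,
                  epochs = config$epochs, batch_size = config$batch_size,
                  seed = seeds[5])
  refinement <- refine_hho(fit$model, inputs[tr], dataset$labels[tr],
                           pop_size = config$refine_pop,
                           iterations = config$refine_iters, seed = seeds[6])
  model <- refinement$model

  # 6. evaluation
  pred <- cnn_predict(model, inputs[te])
  metrics <- compute_metrics(dataset$labels[te], pred$label, pred$prob)

  run <- structure(
    list(metrics = metrics,
         segmentation = list(dice = dice,
                             mean_dice_tumor = mean(dice, na.rm = TRUE),
                             mean_pixel_accuracy = mean(pixacc, na.rm = TRUE)),
         predictions = data.frame(index = te, truth = dataset$labels[te],
                                  prob = pred$prob, label = pred$label),
         feature_table = feats, model = model, refinement = refinement,
         loss_history = fit$loss_history, dataset = dataset,
         config = config),
    class = "hhocnn_run")
  if (!is.null(config$out_dir)) run$paths <- write_run_artifacts(run)
  run
}

# write metrics/manifest/feature/model artifacts for a finished run
write_run_artifacts <- function(run) {
  config <- run$config
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_report(run$metrics, config$out_dir)
  write_feature_table(run$feature_table, file.path(config$out_dir, "features.csv"))
  save_cnn(run$model, file.path(config$out_dir, "model"))
  manifest <- unclass(config)
  manifest$template <- unclass(manifest$template)
  manifest$segmentation <- run$segmentation[c("mean_dice_tumor",
                                              "mean_pixel_accuracy")]
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  paths <- c(metrics = file.path(config$out_dir, "metrics.json"),
             roc = file.path(config$out_dir, "roc.csv"),
             features = file.path(config$out_dir, "features.csv"),
             manifest = file.path(config$out_dir, "manifest.json"),
             model = file.path(config$out_dir, "model.json"))
  if (config$write_images) {
    img_dir <- file.path(config$out_dir, "processed")
    dir.create(img_dir, showWarnings = FALSE)
    for (i in seq_along(run$dataset$images)) {
      img <- run$dataset$images[[i]]
      eq <- equalize(median_filter(img, run$config$window), run$config$subhist)
      write_gray_image(eq, file.path(img_dir, sprintf("img_%04d.png", i)))
    }
    paths <- c(paths, processed = img_dir)
  }
  paths
}

#' @export
print.hhocnn_run <- function(x, ...) {
  cat("hhocnn_run\n")
  cat(sprintf("  segmentation: mean tumor Dice %.3f\n",
              x$segmentation$mean_dice_tumor))
  print(x$metrics)
  invisible(x)
}
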