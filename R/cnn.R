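sigmoid <- function(z) 1 / (1 + exp(-z))

#' Bilinear image resize
#'
#' Resizes an intensity matrix to `side x side` with bilinear interpolation
#' (half-pixel-centered sampling) and rounds back to integer gray levels.
#'
#' @param img Intensity matrix.
#' @param side Output side in pixels.
#' @return `side x side` intensity matrix.
#' @export
resize_image <- function(img, side) {
  assert_gray_image(img)
  h <- nrow(img); w <- ncol(img)
  if (h == side && w == side) return(img)
  src <- function(n_in, n_out) {
    s <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    s <- clamp(s, 1, n_in)
    i0 <- clamp(floor(s), 1, n_in)
    i1 <- clamp(i0 + 1, 1, n_in)
    list(i0 = i0, i1 = i1, f = s - i0)
  }
  ry <- src(h, side); rx <- src(w, side)
  a <- img[ry$i0, rx$i0, drop = FALSE]; b <- img[ry$i0, rx$i1, drop = FALSE]
  c_ <- img[ry$i1, rx$i0, drop = FALSE]; d <- img[ry$i1, rx$i1, drop = FALSE]
  fy <- matrix(ry$f, side, side); fx <- matrix(rx$f, side, side, byrow = TRUE)
  top <- a * (1 - fx) + b * fx
  bot <- c_ * (1 - fx) + d * fx
  clamp(round(top * (1 - fy) + bot * fy), 0, 255)
}

#' 2-D convolution (cross-correlation) forward pass
#'
#' Computes the pre-activation plane
#' `S(f) = sum_p sum_m sum_n V[m, n, p, f] * T[m, n, p]` over sliding
#' kernel windows, using the cross-correlation convention (no kernel flip)
#' common to CNN implementations. Supports multi-channel inputs, filter
#' banks, stride and zero padding; output sizes follow the standard
#' `floor((H + 2*pad - kh) / stride) + 1` formula.
#'
#' @param input `H x W` matrix or `H x W x P` array.
#' @param kernel `kh x kw` matrix, `kh x kw x P` array, or
#'   `kh x kw x P x F` filter bank.
#' @param stride Positive integer stride.
#' @param padding Nonnegative integer zero-padding on every side.
#' @return An `oh x ow` matrix (single filter) or `oh x ow x F` array.
#' @examples
#' conv_forward(diag(3), matrix(1, 1, 1))  # 1x1 identity kernel
#' @export
conv_forward <- function(input, kernel, stride = 1L, padding = 0L) {
  if (is.matrix(input)) input <- array(input, c(dim(input), 1L))
  kd <- dim(kernel)
  if (is.matrix(kernel)) kernel <- array(kernel, c(kd, 1L, 1L))
  if (length(dim(kernel)) == 3L) kernel <- array(kernel, c(dim(kernel), 1L))
  kh <- dim(kernel)[1]; kw <- dim(kernel)[2]
  P <- dim(kernel)[3]; FF <- dim(kernel)[4]
  if (dim(input)[3] != P)
    stop("kernel channel count does not match the input", call. = FALSE)
  stride <- as.integer(stride); padding <- as.integer(padding)
  if (stride < 1L || padding < 0L) stop("invalid stride/padding", call. = FALSE)
  h <- dim(input)[1] + 2L * padding
  w <- dim(input)[2] + 2L * padding
  if (kh > h || kw > w)
    stop("kernel does not fit the (padded) input", call. = FALSE)
  if (padding > 0L) {
    padded <- array(0, c(h, w, P))
    padded[padding + seq_len(dim(input)[1]),
           padding + seq_len(dim(input)[2]), ] <- input
    input <- padded
  }
  oh <- (h - kh) %/% stride + 1L
  ow <- (w - kw) %/% stride + 1L
  r0 <- (seq_len(oh) - 1L) * stride
  c0 <- (seq_len(ow) - 1L) * stride
  Xc <- matrix(0, oh * ow, kh * kw * P)
  col <- 0L
  for (p in seq_len(P)) {
    for (n in seq_len(kw)) {
      for (m in seq_len(kh)) {
        col <- col + 1L
        Xc[, col] <- as.vector(input[r0 + m, c0 + n, p])
      }
    }
  }
  Wm <- matrix(kernel, kh * kw * P, FF)
  out <- Xc %*% Wm
  if (FF == 1L) matrix(out, oh, ow) else array(out, c(oh, ow, FF))
}

#' Initialize a small convolutional classifier
#'
#' The smallest network matching the pipeline's layer list: input
#' (`input_side` square, intensities scaled to `[0, 1]`) -> one valid
#' convolution layer (`n_filters` kernels of side `kernel`) -> ReLU -> max
#' pooling (`pool` square, non-overlapping) -> fully connected layer ->
#' sigmoid class probability. Conv weights start from small Gaussian draws,
#' the fully connected layer from Gaussian draws scaled by `1/sqrt(D)`;
#' biases start at zero. Sliding-window and pooling index tables are
#' precomputed once.
#'
#' @param input_side Input image side after resizing (default 64).
#' @param n_filters Number of convolution filters.
#' @param kernel Convolution kernel side.
#' @param pool Pooling window side.
#' @param seed Integer seed for the weight initialization.
#' @param levels Gray levels of the input images.
#' @return An object of class `cnn_model`.
#' @export
cnn_init <- function(input_side = 64L, n_filters = 8L, kernel = 3L,
                     pool = 2L, seed = 1L, levels = 256L) {
  input_side <- as.integer(input_side); kernel <- as.integer(kernel)
  n_filters <- as.integer(n_filters); pool <- as.integer(pool)
  conv_out <- input_side - kernel + 1L
  if (conv_out < pool)
    stop("network dimensions are inconsistent", call. = FALSE)
  pool_out <- conv_out %/% pool
  D <- pool_out^2 * n_filters

  # im2col index table: rows = conv output cells (column-major), columns =
  # kernel taps (m fastest, then n)
  r0 <- rep(seq_len(conv_out), times = conv_out)
  c0 <- rep(seq_len(conv_out), each = conv_out)
  conv_idx <- matrix(0L, conv_out^2, kernel^2)
  col <- 0L
  for (n in seq_len(kernel)) {
    for (m in seq_len(kernel)) {
      col <- col + 1L
      conv_idx[, col] <- (c0 + n - 2L) * input_side + (r0 + m - 1L)
    }
  }
  # pooling index table: rows = pooled cells (column-major), columns = the
  # pool^2 conv cells they cover
  pr <- rep(seq_len(pool_out), times = pool_out)
  pc <- rep(seq_len(pool_out), each = pool_out)
  pool_idx <- matrix(0L, pool_out^2, pool^2)
  col <- 0L
  for (n in seq_len(pool)) {
    for (m in seq_len(pool)) {
      col <- col + 1L
      pool_idx[, col] <- ((pc - 1L) * pool + n - 1L) * conv_out +
        (pr - 1L) * pool + m
    }
  }

  w <- with_local_seed(seed, list(
    Wc = matrix(stats::rnorm(kernel^2 * n_filters, 0, 0.1),
                kernel^2, n_filters),
    bc = numeric(n_filters),
    wf = stats::rnorm(D, 0, 1 / sqrt(D)),
    bf = 0
  ))
  structure(list(input_side = input_side, n_filters = n_filters,
                 kernel = kernel, pool = pool, conv_out = conv_out,
                 pool_out = pool_out, D = D, levels = as.integer(levels),
                 Wc = w$Wc, bc = w$bc, wf = w$wf, bf = w$bf,
                 conv_idx = conv_idx, pool_idx = pool_idx,
                 seed = as.integer(seed)),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(
    "cnn_model: %dx%d input -> conv %dx%d (%d filters) -> ReLU -> %dx%d max-pool -> FC(%d) -> sigmoid\n",
    x$input_side, x$input_side, x$kernel, x$kernel, x$n_filters,
    x$pool, x$pool, x$D))
  invisible(x)
}

#' Forward pass of the convolutional classifier
#'
#' conv -> ReLU -> max-pool -> flatten -> fully connected -> sigmoid. The
#' pass is pure: the same weights and input always give the same
#' probability. The class label is obtained by thresholding at 0.5 (see
#' [cnn_predict()]).
#'
#' @param model A [cnn_init()] model.
#' @param img Intensity matrix of side `input_side` (resize first with
#'   [resize_image()] if needed).
#' @param cache Return the intermediate activations needed for
#'   backpropagation?
#' @return Class probability in `[0, 1]`, or (with `cache = TRUE`) a list
#'   with `p`, `z`, `flat`, `Xc`, `relu_mask` and `amax`.
#' @export
cnn_forward <- function(model, img, cache = FALSE) {
  stopifnot(inherits(model, "cnn_model"))
  if (!is.matrix(img) || nrow(img) != model$input_side ||
      ncol(img) != model$input_side)
    stop("wrong input size: expected ", model$input_side, "x",
         model$input_side, call. = FALSE)
  x <- img / (model$levels - 1)
  Xc <- matrix(x[model$conv_idx], nrow(model$conv_idx), ncol(model$conv_idx))
  S <- Xc %*% model$Wc
  S <- sweep(S, 2L, model$bc, "+")
  R <- pmax(S, 0)
  npool <- nrow(model$pool_idx)
  M <- R[model$pool_idx[, 1L], , drop = FALSE]
  amax <- matrix(1L, npool, model$n_filters)
  for (l in 2:ncol(model$pool_idx)) {
    Pl <- R[model$pool_idx[, l], , drop = FALSE]
    upd <- Pl > M
    amax[upd] <- l
    M[upd] <- Pl[upd]
  }
  flat <- as.vector(M)
  z <- sum(model$wf * flat) + model$bf
  p <- sigmoid(z)
  if (!cache) return(p)
  list(p = p, z = z, flat = flat, Xc = Xc, relu_mask = S > 0, amax = amax)
}

# gradients of the batch MSE loss w.r.t. all weights
cnn_loss_grad <- function(model, images, labels) {
  B <- length(images)
  dWc <- matrix(0, nrow(model$Wc), ncol(model$Wc))
  dbc <- numeric(model$n_filters)
  dwf <- numeric(model$D)
  dbf <- 0
  loss <- 0
  probs <- numeric(B)
  npool <- nrow(model$pool_idx)
  for (i in seq_len(B)) {
    cc <- cnn_forward(model, images[[i]], cache = TRUE)
    probs[i] <- cc$p
    y <- labels[i]
    loss <- loss + (cc$p - y)^2 / B
    dz <- (2 * (cc$p - y) / B) * cc$p * (1 - cc$p)
    dwf <- dwf + dz * cc$flat
    dbf <- dbf + dz
    dM <- matrix(dz * model$wf, npool, model$n_filters)
    dS <- matrix(0, nrow(cc$Xc), model$n_filters)
    for (f in seq_len(model$n_filters)) {
      cells <- model$pool_idx[cbind(seq_len(npool), cc$amax[, f])]
      dS[cells, f] <- dM[, f]
    }
    dS <- dS * cc$relu_mask
    dWc <- dWc + crossprod(cc$Xc, dS)
    dbc <- dbc + colSums(dS)
  }
  list(loss = loss, probs = probs,
       grads = list(Wc = dWc, bc = dbc, wf = dwf, bf = dbf))
}

# full-dataset MSE loss at the current weights
cnn_loss <- function(model, images, labels) {
  p <- vapply(images, function(im) cnn_forward(model, im), numeric(1))
  mse_loss(labels, p)
}

#' Train the classifier by mini-batch gradient descent
#'
#' Minimizes the MSE loss between the sigmoid output and the 0/1 labels by
#' mini-batch gradient descent. The epoch shuffling is seeded, so training
#' is fully reproducible; the per-epoch loss over the whole training set is
#' recorded.
#'
#' @param model A [cnn_init()] model.
#' @param images List of intensity matrices of side `input_side`.
#' @param labels Integer 0/1 labels; both classes must be present.
#' @param learning_rate Nonnegative step size (0 leaves weights unchanged).
#' @param epochs Number of passes over the training set.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed for shuffling.
#' @return List of class `cnn_fit`: `model` (trained weights) and
#'   `loss_history` (training loss after each epoch).
#' @export
train_gd <- function(model, images, labels, learning_rate = 0.5,
                     epochs = 30L, batch_size = 16L, seed = 1L) {
  stopifnot(inherits(model, "cnn_model"))
  n <- length(images)
  if (n != length(labels)) stop("images/labels length mismatch", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("training set must contain both classes", call. = FALSE)
  if (learning_rate < 0) stop("`learning_rate` must be >= 0", call. = FALSE)
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("`epochs` must be at least 1", call. = FALSE)
  history <- numeric(epochs)
  with_local_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        g <- cnn_loss_grad(model, images[idx], labels[idx])
        model$Wc <- model$Wc - learning_rate * g$grads$Wc
        model$bc <- model$bc - learning_rate * g$grads$bc
        model$wf <- model$wf - learning_rate * g$grads$wf
        model$bf <- model$bf - learning_rate * g$grads$bf
      }
      history[ep] <- cnn_loss(model, images, labels)
    }
  })
  structure(list(model = model, loss_history = history), class = "cnn_fit")
}

# pack/unpack model weights into a flat position vector
pack_weights <- function(model, scope) {
  if (scope == "fc") c(model$wf, model$bf)
  else c(as.vector(model$Wc), model$bc, model$wf, model$bf)
}

unpack_weights <- function(model, w, scope) {
  if (scope == "fc") {
    model$wf <- w[seq_len(model$D)]
    model$bf <- w[model$D + 1L]
  } else {
    nWc <- length(model$Wc)
    model$Wc <- matrix(w[seq_len(nWc)], nrow(model$Wc), ncol(model$Wc))
    ofs <- nWc
    model$bc <- w[ofs + seq_len(model$n_filters)]; ofs <- ofs + model$n_filters
    model$wf <- w[ofs + seq_len(model$D)]; ofs <- ofs + model$D
    model$bf <- w[ofs + 1L]
  }
  model
}

#' Refine classifier weights with the population metaheuristic
#'
#' Packs the output-layer weights (default scope; `"all"` packs the whole
#' network) into a position vector and minimizes the training MSE with
#' [hho_optimize()], searching the box `current weight +/- radius` and
#' warm-starting the population at the current weights. The refined weights
#' are accepted only if the training loss does not increase (model-level
#' elitism), so refinement can never hurt the fit. With the final
#' convolution weights fixed, the flattened pooled features are precomputed
#' once and each candidate evaluation is a single affine-sigmoid pass.
#'
#' @param model A trained (or initialized) [cnn_init()] model.
#' @param images,labels Training images and 0/1 labels.
#' @param pop_size,iterations Optimizer budget; a zero budget returns the
#'   model unchanged.
#' @param seed Integer seed for the search.
#' @param scope `"fc"` (output layer only, default) or `"all"`.
#' @param radius Half-width of the search box around each current weight.
#' @return List of class `hho_refinement`: `model`, `loss_before`,
#'   `loss_after`, `accepted` and the optimizer `trace`.
#' @export
refine_hho <- function(model, images, labels, pop_size = 20L,
                       iterations = 30L, seed = 1L,
                       scope = c("fc", "all"), radius = 1) {
  stopifnot(inherits(model, "cnn_model"))
  scope <- match.arg(scope)
  loss0 <- cnn_loss(model, images, labels)
  if (pop_size <= 0L || iterations <= 0L) {
    return(structure(list(model = model, loss_before = loss0,
                          loss_after = loss0, accepted = FALSE,
                          trace = numeric(0)),
                     class = "hho_refinement"))
  }
  w0 <- pack_weights(model, scope)
  if (scope == "fc") {
    Fm <- t(vapply(images, function(im) cnn_forward(model, im, cache = TRUE)$flat,
                   numeric(model$D)))
    objective <- function(w) {
      p <- sigmoid(drop(Fm %*% w[seq_len(model$D)]) + w[model$D + 1L])
      mse_loss(labels, p)
    }
  } else {
    objective <- function(w) cnn_loss(unpack_weights(model, w, scope),
                                      images, labels)
  }
  res <- hho_optimize(objective, dim = length(w0),
                      lower = w0 - radius, upper = w0 + radius,
                      pop_size = pop_size, iterations = iterations,
                      seed = seed, init = w0)
  accepted <- res$best_fitness <= loss0
  out <- if (accepted) unpack_weights(model, res$best, scope) else model
  structure(list(model = out, loss_before = loss0,
                 loss_after = if (accepted) res$best_fitness else loss0,
                 accepted = accepted, trace = res$trace),
            class = "hho_refinement")
}

#' Predict class labels and probabilities
#'
#' Runs the forward pass on each image and thresholds the sigmoid output at
#' 0.5; a probability of exactly 0.5 is labeled 1 (documented tie rule).
#' Input order is preserved; an empty input gives an empty result.
#'
#' @param model A `cnn_model`.
#' @param images List of intensity matrices of side `input_side`.
#' @return `data.frame` with columns `prob` and `label`.
#' @export
cnn_predict <- function(model, images) {
  stopifnot(inherits(model, "cnn_model"))
  if (length(images) == 0L)
    return(data.frame(prob = numeric(0), label = integer(0)))
  p <- vapply(images, function(im) cnn_forward(model, im), numeric(1))
  data.frame(prob = p, label = as.integer(p >= 0.5))
}

#' Save / load a model (JSON header + flat weight file)
#'
#' `save_cnn()` writes `<path>.json` (architecture and seed) and
#' `<path>.weights` (one weight per line at 17 significant digits, in the
#' order conv kernels, conv biases, FC weights, FC bias). The round trip
#' through `load_cnn()` reproduces every weight exactly.
#'
#' @param model A `cnn_model`.
#' @param path Base path without extension.
#' @return `path` invisibly; `load_cnn()` returns the model.
#' @export
save_cnn <- function(model, path) {
  stopifnot(inherits(model, "cnn_model"))
  header <- list(input_side = model$input_side, n_filters = model$n_filters,
                 kernel = model$kernel, pool = model$pool,
                 levels = model$levels, seed = model$seed)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE)
  w <- pack_weights(model, "all")
  writeLines(sprintf("%.17g", w), paste0(path, ".weights"))
  invisible(path)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  model <- cnn_init(input_side = header$input_side,
                    n_filters = header$n_filters, kernel = header$kernel,
                    pool = header$pool, seed = header$seed,
                    levels = header$levels)
  w <- as.numeric(readLines(paste0(path, ".weights")))
  unpack_weights(model, w, "all")
}
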