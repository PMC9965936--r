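# finite-difference gradient of the dataset loss over all packed weights
numeric_grads <- function(model, imgs, labels, eps = 1e-5) {
  w0 <- hhocnn:::pack_weights(model, "all")
  g <- numeric(length(w0))
  for (i in seq_along(w0)) {
    wp <- w0; wp[i] <- w0[i] + eps
    wm <- w0; wm[i] <- w0[i] - eps
    g[i] <- (hhocnn:::cnn_loss(hhocnn:::unpack_weights(model, wp, "all"), imgs, labels) -
             hhocnn:::cnn_loss(hhocnn:::unpack_weights(model, wm, "all"), imgs, labels)) /
      (2 * eps)
  }
  g
}

analytic_grads <- function(model, imgs, labels) {
  g <- hhocnn:::cnn_loss_grad(model, imgs, labels)$grads
  c(as.vector(g$Wc), g$bc, g$wf, g$bf)
}

tiny_model <- function(seed = 5) {
  cnn_init(input_side = 8, n_filters = 2, kernel = 3, pool = 2, seed = seed)
}
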