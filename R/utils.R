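# internal helpers shared across stages

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream (the package's only entry point to the RNG).
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# derive a bounded child seed from a parent seed (R seeds are 32-bit)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k)) %% (2^31 - 2) + 1)
}

assert_gray_image <- function(img, levels = 256L, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop(sprintf("`%s` must have at least one row and column", arg), call. = FALSE)
  if (!all(is.finite(img)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  if (any(img < 0) || any(img > levels - 1))
    stop(sprintf("`%s` has values outside [0, %d]", arg, levels - 1L), call. = FALSE)
  invisible(img)
}

# shift a matrix by (dr, dc); vacated cells take `fill`
shift_mat <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- seq_len(h) - dr
  cs <- seq_len(w) - dc
  rok <- rs >= 1L & rs <= h
  cok <- cs >= 1L & cs <= w
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# replicate-pad a matrix by k pixels on every side
edge_pad <- function(m, k) {
  ri <- clamp(seq_len(nrow(m) + 2L * k) - k, 1L, nrow(m))
  ci <- clamp(seq_len(ncol(m) + 2L * k) - k, 1L, ncol(m))
  m[ri, ci, drop = FALSE]
}

# row-major pixel ordering (row 1 left-to-right, then row 2, ...) used for
# deterministic tie-breaks and for the FCM point ordering
rm_order_values <- function(img) as.numeric(t(img))

rm_index_to_rc <- function(i, width) {
  cbind(row = (i - 1L) %/% width + 1L, col = (i - 1L) %% width + 1L)
}

rc_to_rm_index <- function(r, c, width) (r - 1L) * width + c
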