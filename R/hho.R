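#' Mean squared error between expected and predicted outputs
#'
#' `MSE = (1/g) * sum (F - F*)^2`, the training loss minimized by both the
#' gradient-descent and metaheuristic refinement stages.
#'
#' @param expected,predicted Equal-length numeric vectors.
#' @return Scalar loss.
#' @examples
#' mse_loss(c(1, 0), c(0.5, 0.5))  # 0.25
#' @export
mse_loss <- function(expected, predicted) {
  if (length(expected) != length(predicted))
    stop("`expected` and `predicted` lengths differ", call. = FALSE)
  if (length(expected) < 1L) stop("empty input", call. = FALSE)
  mean((expected - predicted)^2)
}

#' Single hawk position update
#'
#' The two position-update branches of the population search. Exploration
#' moves a solution relative to a randomly chosen population member:
#' `A' = A_rand - v1 * |A_rand - 2 * v2 * A|`. Exploitation contracts
#' toward that member: `A' = A_rand - v1 * A_rand + 2 * v1 * v2 * A`.
#' With `v1 = 0` both branches collapse to `A_rand` (a pure restart at the
#' chosen member). The result is clamped to the feasible box.
#'
#' @param current Current position vector `A`.
#' @param rand_pos Position `A_rand` of a randomly chosen population member.
#' @param v1,v2 Control scalars in `[0, 1]`.
#' @param mode `"exploration"` or `"exploitation"`.
#' @param lower,upper Bounds (scalars or vectors), clamped after the update.
#' @return Updated position vector.
#' @export
hho_update_position <- function(current, rand_pos, v1, v2,
                                mode = c("exploration", "exploitation"),
                                lower = -Inf, upper = Inf) {
  mode <- match.arg(mode)
  if (length(current) != length(rand_pos))
    stop("position dimensions differ", call. = FALSE)
  new <- if (mode == "exploration") {
    rand_pos - v1 * abs(rand_pos - 2 * v2 * current)
  } else {
    rand_pos - v1 * rand_pos + 2 * v1 * v2 * current
  }
  clamp(new, lower, upper)
}

#' Population metaheuristic minimization
#'
#' Hawks-style population search: `pop_size` candidate solutions are
#' initialized uniformly in the feasible box and evaluated (iteration 1);
#' each subsequent iteration updates every solution with
#' [hho_update_position()], choosing the exploration or exploitation branch
#' by a uniform draw against 0.5 and taking `A_rand` as a uniformly chosen
#' population member. `v1` is a uniform draw scaled by a linear decay from 1
#' to 0 over the budget (late iterations exploit), `v2` is uniform per
#' update. A new position replaces its solution only if its fitness is no
#' worse (greedy selection), and the best-so-far solution is tracked
#' separately, so the best-fitness trace is monotone nonincreasing. The run
#' is fully determined by `seed`.
#'
#' @param fn Objective function mapping a length-`dim` vector to a finite
#'   scalar cost.
#' @param dim Problem dimension.
#' @param lower,upper Box bounds, scalars or length-`dim` vectors.
#' @param pop_size Population size `f`, at least 2.
#' @param iterations Evaluation sweeps, at least 1 (iteration 1 evaluates
#'   the initial population).
#' @param seed Integer seed.
#' @param init Optional matrix (or vector) of starting positions injected
#'   into the initial population (clamped to bounds); used to warm-start
#'   refinement from current model weights.
#' @param decay Apply the linear `v1` decay (default) or keep the full
#'   `[0, 1]` draw throughout.
#' @param v1_scale Extra multiplier on `v1`; 0 turns every update into a
#'   restart at `A_rand`.
#' @param p_random_jump Probability of replacing an update with the optional
#'   coefficient-vector jump `A_rand + B * C`, where `B` is uniform in
#'   `[0, 2]` per dimension and `C = |best - A|`; off (0) by default.
#' @return List of class `hho_result`: `best`, `best_fitness`, `trace`
#'   (best fitness per iteration), `evaluations`, `population`, `fitness`,
#'   and the call parameters.
#' @examples
#' r <- hho_optimize(function(x) sum(x^2), dim = 2, lower = -5, upper = 5,
#'                   pop_size = 10, iterations = 50, seed = 1)
#' r$best_fitness < 1e-2
#' @export
hho_optimize <- function(fn, dim, lower, upper, pop_size = 30L,
                         iterations = 500L, seed = 1L, init = NULL,
                         decay = TRUE, v1_scale = 1, p_random_jump = 0) {
  dim <- as.integer(dim)
  pop_size <- as.integer(pop_size)
  iterations <- as.integer(iterations)
  if (pop_size < 2L) stop("`pop_size` must be at least 2", call. = FALSE)
  if (iterations < 1L) stop("`iterations` must be at least 1", call. = FALSE)
  lower <- rep_len(lower, dim); upper <- rep_len(upper, dim)
  if (any(lower > upper)) stop("invalid bounds", call. = FALSE)

  eval_fn <- function(x) {
    v <- fn(x)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("objective returned a non-finite value at position (",
           paste(signif(x, 6), collapse = ", "), ")", call. = FALSE)
    v
  }

  with_local_seed(seed, {
    X <- matrix(stats::runif(pop_size * dim, rep(lower, each = pop_size),
                             rep(upper, each = pop_size)),
                pop_size, dim)
    if (!is.null(init)) {
      init <- matrix(init, ncol = dim)
      kk <- min(nrow(init), pop_size)
      for (i in seq_len(kk))
        X[i, ] <- clamp(init[i, ], lower, upper)
    }
    fit <- apply(X, 1L, eval_fn)
    evals <- pop_size
    best_i <- which.min(fit)
    best <- X[best_i, ]; best_f <- fit[best_i]
    trace <- numeric(iterations)
    trace[1] <- best_f
    if (iterations > 1L) {
      for (b in 2:iterations) {
        dec <- if (decay) 1 - (b - 1) / iterations else 1
        for (e in seq_len(pop_size)) {
          A_rand <- X[sample.int(pop_size, 1L), ]
          v1 <- stats::runif(1) * dec * v1_scale
          v2 <- stats::runif(1)
          if (p_random_jump > 0 && stats::runif(1) < p_random_jump) {
            B <- stats::runif(dim, 0, 2)
            newx <- clamp(A_rand + B * abs(best - X[e, ]), lower, upper)
          } else {
            mode <- if (stats::runif(1) >= 0.5) "exploitation" else "exploration"
            newx <- hho_update_position(X[e, ], A_rand, v1, v2, mode,
                                        lower, upper)
          }
          nf <- eval_fn(newx)
          evals <- evals + 1L
          if (nf <= fit[e]) { X[e, ] <- newx; fit[e] <- nf }
          if (nf < best_f) { best <- newx; best_f <- nf }
        }
        trace[b] <- best_f
      }
    }
    structure(list(best = best, best_fitness = best_f, trace = trace,
                   evaluations = evals, population = X, fitness = fit,
                   pop_size = pop_size, iterations = iterations,
                   seed = as.integer(seed)),
              class = "hho_result")
  })
}

#' @export
print.hho_result <- function(x, ...) {
  cat(sprintf("hho_result: best fitness %.6g after %d iterations (%d evaluations)\n",
              x$best_fitness, x$iterations, x$evaluations))
  invisible(x)
}
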