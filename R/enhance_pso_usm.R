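## Particle-swarm optimised unsharp masking: a 3x3 eight-fold-symmetric edge
## kernel (center / edge / corner weights) plus a gain factor are searched by
## global-best PSO to maximise the Shannon entropy of the enhanced image,
## penalised by the fraction of pixels pushed outside [0, 1].

#' Symmetric 3x3 unsharp kernel specification
#'
#' Three free weights expand to a kernel with 8-fold symmetry; together with
#' the gain they form the 4-dimensional PSO search space.
#'
#' @param center center weight.
#' @param edge weight shared by the four edge-adjacent cells.
#' @param corner weight shared by the four corners.
#' @param gain scalar gain on the extracted edge.
#' @return an object of class `kernel_spec`.
#' @export
kernel_spec <- function(center = 1, edge = 0, corner = 0, gain = 0) {
  structure(list(center = center, edge = edge, corner = corner, gain = gain),
            class = "kernel_spec")
}

#' Expand a kernel specification to its 3x3 matrix
#'
#' @param spec a [kernel_spec].
#' @return 3x3 numeric matrix, equal to its transpose and 90-degree
#'   rotation by construction.
#' @export
expand_kernel <- function(spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  matrix(c(spec$corner, spec$edge, spec$corner,
           spec$edge, spec$center, spec$edge,
           spec$corner, spec$edge, spec$corner), 3L, 3L)
}

#' Apply an unsharp kernel with gain
#'
#' `edge = conv(img, kernel)` (reflect padding); `raw = img + gain * edge`;
#' the over-range ratio is the fraction of `raw` outside `[0, 1]` before
#' clipping.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param spec a [kernel_spec].
#' @return list with `enhanced` (clipped matrix) and `over_range_ratio`.
#' @export
usm_apply <- function(img, spec) {
  assert_gray(img)
  edge <- conv3x3_reflect(img, expand_kernel(spec))
  raw <- img + spec$gain * edge
  ratio <- mean(raw < 0 | raw > 1)
  list(enhanced = clip01(raw), over_range_ratio = ratio)
}

#' PSO configuration
#'
#' Canonical global-best particle swarm with constriction-equivalent
#' defaults (`w = 0.729`, `c1 = c2 = 1.49445`). Positions are clamped to
#' `bounds` after every update. Fully seeded: identical seeds give
#' bit-identical traces.
#'
#' @param swarm_size particles (default 30).
#' @param max_iterations iterations (default 100).
#' @param inertia inertia weight `w` (default 0.729).
#' @param cognitive,social acceleration constants `c1`, `c2`
#'   (default 1.49445).
#' @param bounds 2-column matrix of per-parameter (lower, upper) bounds;
#'   default: kernel weights in `[-2, 2]`, gain in `[0, 2]`.
#' @param penalty_beta weight of the over-range penalty (default 10).
#' @param seed RNG seed (default 1).
#' @return an object of class `pso_config`.
#' @export
pso_config <- function(swarm_size = 30L, max_iterations = 100L,
                       inertia = 0.729, cognitive = 1.49445,
                       social = 1.49445, bounds = NULL,
                       penalty_beta = 10, seed = 1L) {
  stopifnot(swarm_size >= 2, max_iterations >= 1, cognitive >= 0, social >= 0)
  if (is.null(bounds)) {
    bounds <- cbind(c(-2, -2, -2, 0), c(2, 2, 2, 2))
  }
  stopifnot(is.matrix(bounds), ncol(bounds) == 2, all(bounds[, 2] > bounds[, 1]))
  structure(list(swarm_size = as.integer(swarm_size),
                 max_iterations = as.integer(max_iterations),
                 inertia = inertia, cognitive = cognitive, social = social,
                 bounds = bounds, penalty_beta = penalty_beta,
                 seed = as.integer(seed)),
            class = "pso_config")
}

#' Entropy-minus-penalty fitness of a kernel specification
#'
#' Shannon entropy (bits, 256 bins on the 8-bit quantized enhanced image)
#' minus `penalty_beta` times the over-range ratio. Maximising it favours
#' information-rich enhancements that keep pixels representable.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param spec a [kernel_spec].
#' @param config a [pso_config] (only `penalty_beta` is used).
#' @return scalar fitness.
#' @export
pso_fitness <- function(img, spec, config = pso_config()) {
  res <- usm_apply(img, spec)
  image_entropy(res$enhanced) - config$penalty_beta * res$over_range_ratio
}

#' Maximise an arbitrary objective by global-best PSO
#'
#' The generic engine behind [pso_optimize]: velocities follow
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`, positions are clamped
#' to the bounds, and the best-so-far trace is non-decreasing by
#' construction.
#'
#' @param objective function taking a parameter vector, returning a scalar
#'   to maximise.
#' @param bounds 2-column matrix of (lower, upper) bounds, one row per
#'   parameter.
#' @param config a [pso_config] (`bounds` in the config are ignored in
#'   favour of the argument).
#' @return list with `position` (best parameter vector), `fitness`, and
#'   `trace` (best fitness after each iteration).
#' @export
pso_maximize <- function(objective, bounds, config = pso_config()) {
  d <- nrow(bounds)
  lo <- bounds[, 1]; hi <- bounds[, 2]; span <- hi - lo
  withr::with_seed(config$seed, {
    n <- config$swarm_size
    x <- t(lo + t(matrix(stats::runif(n * d), n, d)) * span)
    v <- t(t(matrix(stats::runif(n * d), n, d)) * span * 2 - span)
    fit <- apply(x, 1L, objective)
    pbest <- x; pfit <- fit
    gi <- which.max(pfit)
    gbest <- pbest[gi, ]; gfit <- pfit[gi]
    trace <- numeric(config$max_iterations)
    for (it in seq_len(config$max_iterations)) {
      r1 <- matrix(stats::runif(n * d), n, d)
      r2 <- matrix(stats::runif(n * d), n, d)
      v <- config$inertia * v +
        config$cognitive * r1 * (pbest - x) +
        config$social * r2 * sweep(x, 2L, gbest, function(a, b) b - a)
      x <- x + v
      x <- t(pmin(pmax(t(x), lo), hi))
      fit <- apply(x, 1L, objective)
      upd <- fit > pfit
      pbest[upd, ] <- x[upd, , drop = FALSE]
      pfit[upd] <- fit[upd]
      gi <- which.max(pfit)
      if (pfit[gi] > gfit) {
        gbest <- pbest[gi, ]; gfit <- pfit[gi]
      }
      trace[it] <- gfit
    }
    list(position = gbest, fitness = gfit, trace = trace)
  })
}

#' Optimise the unsharp kernel and gain for one image
#'
#' Runs [pso_maximize] over (center, edge, corner, gain) with the
#' entropy-minus-penalty fitness.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param config a [pso_config].
#' @return list with `best` (a [kernel_spec]), `fitness` and `trace`.
#' @export
pso_optimize <- function(img, config = pso_config()) {
  assert_gray(img)
  obj <- function(p) {
    pso_fitness(img, kernel_spec(p[1], p[2], p[3], p[4]), config)
  }
  res <- pso_maximize(obj, config$bounds, config)
  list(best = kernel_spec(res$position[1], res$position[2],
                          res$position[3], res$position[4]),
       fitness = res$fitness, trace = res$trace)
}

#' PSO-optimised unsharp enhancement of one channel
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param config a [pso_config].
#' @return enhanced matrix in `[0, 1]`.
#' @export
pso_usm_enhance <- function(img, config = pso_config()) {
  opt <- pso_optimize(img, config)
  usm_apply(img, opt$best)$enhanced
}

# numeric HSV -> RGB (grDevices::hsv returns hex strings, not numerics)
hsv_to_rgb_numeric <- function(h, s, v) {
  i <- floor(h * 6) %% 6
  f <- h * 6 - floor(h * 6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

#' PSO-optimised unsharp enhancement of a colour image
#'
#' Converts RGB to HSV, enhances the value channel with the optimised
#' unsharp mask, and converts back. Standalone entry point; the
#' segmentation pipeline applies [pso_usm_enhance] to the green channel
#' directly.
#'
#' @param img an [rgb_image].
#' @param config a [pso_config].
#' @return an enhanced [rgb_image].
#' @export
pso_usm_enhance_rgb <- function(img, config = pso_config()) {
  stopifnot(is_rgb_image(img))
  d <- dim(img)
  hsv <- grDevices::rgb2hsv(rbind(as.vector(img$red), as.vector(img$green),
                                  as.vector(img$blue)), maxColorValue = 1)
  v2 <- pso_usm_enhance(matrix(hsv[3L, ], d[1], d[2]), config)
  res <- hsv_to_rgb_numeric(hsv[1L, ], hsv[2L, ], as.vector(v2))
  rgb_image(matrix(res$r, d[1], d[2]), matrix(res$g, d[1], d[2]),
            matrix(res$b, d[1], d[2]))
}
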