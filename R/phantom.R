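## Seeded synthetic fundus phantoms: dark branching curvilinear vessels on a
## reddish background with radial illumination falloff and additive noise,
## inside a circular field of view, with exact ground-truth masks. They let
## every pipeline stage be exercised and scored without external datasets.

#' Phantom generator configuration
#'
#' @param height,width image size in pixels (default 256 x 256).
#' @param n_trees number of vessel trees (default 3).
#' @param branch_depth branching levels per tree (default 4).
#' @param width_root root vessel width in pixels (default 4).
#' @param width_decay per-level width multiplier (default 0.8).
#' @param vessel_contrast green/red-channel depression of vessel pixels
#'   (default 0.25).
#' @param vignette_strength radial illumination falloff amplitude
#'   (default 0.3).
#' @param noise_sd additive Gaussian noise sigma (default 0.02).
#' @param fov_radius_frac FOV radius as a fraction of the minimum dimension
#'   (default 0.48).
#' @param seed RNG seed (default 1).
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(height = 256L, width = 256L, n_trees = 3L,
                           branch_depth = 4L, width_root = 4,
                           width_decay = 0.8, vessel_contrast = 0.25,
                           vignette_strength = 0.3, noise_sd = 0.02,
                           fov_radius_frac = 0.48, seed = 1L) {
  stopifnot(height >= 64, width >= 64, n_trees >= 1, branch_depth >= 1,
            width_root > 0, width_decay > 0, width_decay < 1,
            vessel_contrast > 0, vessel_contrast < 1,
            vignette_strength > 0, vignette_strength < 1,
            noise_sd > 0, noise_sd < 1,
            fov_radius_frac > 0, fov_radius_frac < 1)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_trees = as.integer(n_trees),
                 branch_depth = as.integer(branch_depth),
                 width_root = width_root, width_decay = width_decay,
                 vessel_contrast = vessel_contrast,
                 vignette_strength = vignette_strength, noise_sd = noise_sd,
                 fov_radius_frac = fov_radius_frac, seed = as.integer(seed)),
            class = "phantom_config")
}

# Stamp a filled disc onto a logical mask (in place via return).
stamp_disc <- function(mask, r0, c0, radius) {
  H <- nrow(mask); W <- ncol(mask)
  ir <- max(1L, floor(r0 - radius)):min(H, ceiling(r0 + radius))
  ic <- max(1L, floor(c0 - radius)):min(W, ceiling(c0 + radius))
  if (length(ir) == 0L || length(ic) == 0L) return(mask)
  dd <- outer((ir - r0)^2, (ic - c0)^2, "+")
  mask[ir, ic] <- mask[ir, ic] | (dd <= radius^2)
  mask
}

# Rasterize one branch as a random-walk polyline; returns the updated mask.
# Recurses into two children until branch_depth is reached or the walk
# leaves the FOV.
draw_branch <- function(mask, pos, heading, width, depth, config, center, R) {
  step <- 1.5
  seg_len <- 0.35 * R * 0.85^(depth - 1)
  n_steps <- max(4L, round(seg_len / step))
  alive <- TRUE
  for (s in seq_len(n_steps)) {
    heading <- heading + stats::rnorm(1L, 0, 0.12)
    pos <- pos + step * c(cos(heading), sin(heading))
    if (sqrt(sum((pos - center)^2)) > R - 2) {
      alive <- FALSE
      break
    }
    mask <- stamp_disc(mask, pos[1L], pos[2L], max(width / 2, 0.6))
  }
  if (alive && depth < config$branch_depth) {
    split <- stats::runif(1L, 0.3, 0.7)
    for (sgn in c(-1, 1)) {
      mask <- draw_branch(mask, pos, heading + sgn * split,
                          width * config$width_decay, depth + 1L,
                          config, center, R)
    }
  }
  mask
}

#' Generate one synthetic fundus phantom
#'
#' The background is reddish (R, G, B about 0.75, 0.45, 0.25) multiplied by
#' a radial vignette; vessels are recursively branching random-walk curves
#' rasterized at their widths and drawn by depressing the green and red
#' channels; Gaussian noise is added and clipped. The vessel mask is the
#' exact rasterization before noise, restricted to the FOV disc. Identical
#' seeds give bit-identical triples.
#'
#' @param config a [phantom_config].
#' @return list with elements `image` (an [rgb_image]), `vessels` and
#'   `fov` (logical masks).
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  H <- config$height; W <- config$width
  center <- c((H + 1) / 2, (W + 1) / 2)
  R <- config$fov_radius_frac * min(H, W)
  rr <- matrix(seq_len(H), H, W) - center[1L]
  cc <- matrix(seq_len(W), H, W, byrow = TRUE) - center[2L]
  dist <- sqrt(rr^2 + cc^2)
  fov <- dist <= R
  withr::with_seed(config$seed, {
    vessels <- array(FALSE, c(H, W))
    for (t in seq_len(config$n_trees)) {
      a <- stats::runif(1L, 0, 2 * pi)
      pos <- center + 0.8 * R * c(cos(a), sin(a))
      # heading angle in (row, col) space: cos along rows, sin along columns
      heading <- atan2(center[2L] - pos[2L], center[1L] - pos[1L]) +
        stats::runif(1L, -0.4, 0.4)
      vessels <- draw_branch(vessels, pos, heading, config$width_root, 1L,
                             config, center, R)
    }
    vessels <- vessels & fov
    vignette <- 1 - config$vignette_strength * pmin(dist / R, 1)^2
    base <- c(red = 0.75, green = 0.45, blue = 0.25)
    chans <- lapply(base, function(v) v * vignette)
    chans$red[vessels] <- chans$red[vessels] - config$vessel_contrast
    chans$green[vessels] <- chans$green[vessels] - config$vessel_contrast
    for (nm in names(chans)) {
      chans[[nm]][!fov] <- 0.02
      chans[[nm]] <- clip01(chans[[nm]] +
        matrix(stats::rnorm(H * W, 0, config$noise_sd), H, W))
    }
    list(image = rgb_image(chans$red, chans$green, chans$blue),
         vessels = vessels, fov = fov)
  })
}

#' Generate a set of phantoms
#'
#' Phantom `i` (1-based position `i` in the list) uses seed
#' `config$seed + i - 1`, so the first element reproduces
#' [generate_phantom] at the base configuration and every element is
#' reproducible in isolation.
#'
#' @param n number of phantoms, `>= 1`.
#' @param base_config a [phantom_config].
#' @return list of `n` phantom triples.
#' @export
generate_phantom_set <- function(n, base_config = phantom_config()) {
  stopifnot(n >= 1)
  lapply(seq_len(n) - 1L, function(i) {
    cfg <- base_config
    cfg$seed <- base_config$seed + i
    generate_phantom(cfg)
  })
}
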