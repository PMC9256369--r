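## Hysteresis thresholding of the Gabor response, connected-component
## cleaning, and the end-to-end enhancement -> Gabor -> threshold pipeline.

# Connected-component labelling. EBImage::bwlabel is 4-connected; for
# 8-connectivity, labels touching diagonally are merged with a small
# union-find pass over label pairs.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), connectivity %in% c(4L, 8L))
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 4L || max(lab) <= 1L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  a1 <- lab[-H, -W]; b1 <- lab[-1L, -1L]  # \ diagonal pairs
  a2 <- lab[-1L, -W]; b2 <- lab[-H, -1L]  # / diagonal pairs
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]),
                        cbind(a2[keep2], b2[keep2])))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(max(lab))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1L]); rb <- find(pairs[r, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_along(parent), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

#' Hysteresis thresholding
#'
#' A pixel is vessel iff its response is at least `low` and it is connected,
#' through pixels at least `low`, to some pixel at least `high`. Weak
#' ridges attached to a confident detection survive; isolated weak blobs do
#' not.
#'
#' @param response numeric matrix in `[0, 1]`.
#' @param low,high thresholds, `low <= high`.
#' @param connectivity 4 or 8 (default 8).
#' @param fov optional logical matrix; pixels outside it are excluded from
#'   both thresholds and the output.
#' @return logical mask.
#' @export
hysteresis_threshold <- function(response, low, high, connectivity = 8L,
                                 fov = NULL) {
  assert_gray(response, "response")
  if (low > high) stop("low threshold exceeds high threshold", call. = FALSE)
  weak <- response >= low
  strong <- response >= high
  if (!is.null(fov)) {
    weak <- weak & fov
    strong <- strong & fov
  }
  if (!any(strong)) return(array(FALSE, dim(response)))
  lab <- label_components(weak, connectivity)
  keep <- unique(lab[strong])
  matrix(lab %in% keep[keep > 0L], nrow(response), ncol(response)) & weak
}

#' Remove small connected components
#'
#' Components with fewer than `min_component_area` pixels are deleted;
#' components at or above the threshold are kept intact. Idempotent.
#'
#' @param mask logical matrix.
#' @param min_component_area minimum surviving area in pixels (default 30).
#' @param connectivity 4 or 8 (default 8).
#' @return cleaned logical mask.
#' @export
morphological_clean <- function(mask, min_component_area = 30L,
                                connectivity = 8L) {
  stopifnot(is.logical(mask), min_component_area >= 1)
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask)
  areas <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(areas >= min_component_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Segmentation pipeline configuration
#'
#' @param method enhancement applied to the green channel before the Gabor
#'   bank: one of `"none"`, `"gcadw"`, `"homomorphic"`, `"jeh"`, `"usm"`,
#'   `"adaptive_usm"`, `"pso_usm"`.
#' @param high_percentile upper hysteresis threshold as a percentile of the
#'   in-FOV Gabor response (default 92).
#' @param low_percentile lower threshold percentile (default 75).
#' @param min_component_area cleaning threshold in pixels (default 30).
#' @param connectivity 4 or 8 (default 8).
#' @param gabor a [gabor_bank_config].
#' @param gcadw a [gcadw_config].
#' @param homomorphic a [homomorphic_config].
#' @param jeh_window JEH neighbourhood size (default 3).
#' @param usm an [unsharp_config].
#' @param adaptive_usm an [adaptive_usm_config].
#' @param pso a [pso_config]; its seed is overridden by the `seed` argument
#'   of [segment_vessels].
#' @return an object of class `segmentation_config`.
#' @export
segmentation_config <- function(method = c("none", "gcadw", "homomorphic",
                                           "jeh", "usm", "adaptive_usm",
                                           "pso_usm"),
                                high_percentile = 92, low_percentile = 75,
                                min_component_area = 30L, connectivity = 8L,
                                gabor = gabor_bank_config(),
                                gcadw = gcadw_config(),
                                homomorphic = homomorphic_config(),
                                jeh_window = 3L,
                                usm = unsharp_config(),
                                adaptive_usm = adaptive_usm_config(),
                                pso = pso_config()) {
  method <- match.arg(method)
  stopifnot(low_percentile > 0, low_percentile < high_percentile,
            high_percentile < 100, min_component_area >= 1,
            connectivity %in% c(4L, 8L))
  structure(list(method = method, high_percentile = high_percentile,
                 low_percentile = low_percentile,
                 min_component_area = as.integer(min_component_area),
                 connectivity = as.integer(connectivity), gabor = gabor,
                 gcadw = gcadw, homomorphic = homomorphic,
                 jeh_window = as.integer(jeh_window), usm = usm,
                 adaptive_usm = adaptive_usm, pso = pso),
            class = "segmentation_config")
}

# Dispatch the configured enhancement on one channel.
apply_enhancement <- function(channel, config, seed = NULL) {
  switch(config$method,
    none = channel,
    gcadw = gcadw_enhance(channel, config$gcadw),
    homomorphic = homomorphic_enhance(channel, config$homomorphic),
    jeh = jeh_equalize(channel, config$jeh_window),
    usm = unsharp_enhance(channel, config$usm),
    adaptive_usm = adaptive_usm_enhance_gray(channel, config$adaptive_usm),
    pso_usm = {
      if (is.null(seed)) {
        stop("method 'pso_usm' requires a seed", call. = FALSE)
      }
      pc <- config$pso
      pc$seed <- as.integer(seed)
      pso_usm_enhance(channel, pc)
    },
    stop(sprintf("unknown enhancement method '%s'", config$method),
         call. = FALSE))
}

#' Segment retinal vessels
#'
#' End-to-end pipeline: green channel, selected enhancement, maximum
#' multi-orientation Gabor response, hysteresis thresholds at the
#' configured percentiles of the in-FOV response, then small-component
#' cleaning. The output never marks pixels outside the FOV.
#'
#' When a FOV mask is given, pixels outside it are replaced by the mean
#' in-FOV value of the enhanced channel before the Gabor stage: the sharp
#' edge of the black surround otherwise excites a strong spurious Gabor
#' ring just inside the FOV that dominates the threshold percentiles and
#' survives component cleaning. The fill happens after enhancement (the
#' enhancers see the full raw frame, as they would on a fundus photograph)
#' and identically for every method.
#'
#' @param img an [rgb_image] (or a numeric matrix treated as the channel
#'   directly).
#' @param fov optional logical field-of-view mask.
#' @param config a [segmentation_config].
#' @param seed integer seed, required for (and only used by) the
#'   `pso_usm` method; identical seeds give identical masks.
#' @return logical vessel mask.
#' @export
segment_vessels <- function(img, fov = NULL,
                            config = segmentation_config(), seed = NULL) {
  channel <- if (is_rgb_image(img)) extract_green_channel(img) else img
  assert_gray(channel)
  if (!is.null(fov)) stopifnot(identical(dim(fov), dim(channel)))
  enhanced <- apply_enhancement(channel, config, seed)
  if (!is.null(fov)) enhanced[!fov] <- mean(enhanced[fov])
  resp <- gabor_max_response(enhanced, config$gabor, fov = fov)
  vals <- if (is.null(fov)) resp else resp[fov]
  hi <- stats::quantile(vals, config$high_percentile / 100, names = FALSE)
  lo <- stats::quantile(vals, config$low_percentile / 100, names = FALSE)
  mask <- hysteresis_threshold(resp, lo, hi, config$connectivity, fov = fov)
  morphological_clean(mask, config$min_component_area, config$connectivity)
}
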