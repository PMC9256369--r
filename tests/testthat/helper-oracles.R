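# Independent brute-force oracles, kept deliberately naive: plain loops and
# breadth-first searches that share no code path with the implementation.

# 'Same'-size true convolution by explicit summation, odd kernels only,
# reflect (mirror-with-edge) extension.
oracle_conv2_direct <- function(img, k) {
  h <- (nrow(k) - 1) / 2
  H <- nrow(img); W <- ncol(img)
  ext <- function(r, c) {
    r <- ifelse(r < 1, 1 - r, ifelse(r > H, 2 * H + 1 - r, r))
    c <- ifelse(c < 1, 1 - c, ifelse(c > W, 2 * W + 1 - c, c))
    img[cbind(r, c)]
  }
  out <- matrix(0 + 0i, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      s <- 0 + 0i
      for (a in -h:h) {
        for (b in -h:h) {
          s <- s + k[h + 1 + a, h + 1 + b] * ext(r - a, c - b)
        }
      }
      out[r, c] <- s
    }
  }
  if (is.complex(k)) out else Re(out)
}

# Breadth-first connected-component labelling.
oracle_label_bfs <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  nb <- if (connectivity == 8L) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0L) {
      p <- queue[1L]; queue <- queue[-1L]
      r <- (p - 1L) %% H + 1L; c <- (p - 1L) %/% H + 1L
      for (j in seq_len(nrow(nb))) {
        rr <- r + nb[j, 1L]; cc <- c + nb[j, 2L]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W) {
          q <- (cc - 1L) * H + rr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- nxt
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

# Hysteresis by flood fill from every strong pixel across the weak field.
oracle_hysteresis <- function(response, low, high, connectivity = 8L) {
  weak <- response >= low
  lab <- oracle_label_bfs(weak, connectivity)
  strong_labels <- unique(lab[response >= high])
  strong_labels <- strong_labels[strong_labels > 0L]
  matrix(lab %in% strong_labels, nrow(response), ncol(response))
}

# Area filter through the BFS labelling.
oracle_clean <- function(mask, min_area, connectivity = 8L) {
  lab <- oracle_label_bfs(mask, connectivity)
  if (max(lab) == 0L) return(mask)
  keep <- which(tabulate(lab[lab > 0L]) >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# Joint equalization by explicit pair enumeration: per-pixel 2-D CDF sums
# over the full 256 x 256 pair table.
oracle_jeh <- function(img, window_z = 3L) {
  k <- (window_z - 1L) / 2L
  H <- nrow(img); W <- ncol(img)
  g <- matrix(0, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      rr <- pmin(pmax((r - k):(r + k), 1L), H)
      cc <- pmin(pmax((c - k):(c + k), 1L), W)
      g[r, c] <- mean(img[rr, cc])
    }
  }
  f8 <- floor(img * 255 + 0.5)
  g8 <- floor(pmin(pmax(g, 0), 1) * 255 + 0.5)
  h <- matrix(0L, 256, 256)
  for (i in seq_along(f8)) {
    h[f8[i] + 1, g8[i] + 1] <- h[f8[i] + 1, g8[i] + 1] + 1L
  }
  cdf_of <- function(a, b) sum(h[seq_len(a + 1), seq_len(b + 1)])
  occ <- which(h > 0, arr.ind = TRUE)
  cdf_min <- min(apply(occ, 1L, function(p) cdf_of(p[1] - 1L, p[2] - 1L)))
  mn <- length(img)
  out <- matrix(0, H, W)
  for (i in seq_along(f8)) {
    out[i] <- trunc(255 / (mn - 1) * (cdf_of(f8[i], g8[i]) - cdf_min)) / 255
  }
  out
}

# Small test phantom shared by the pipeline tests.
small_phantom <- function(seed = 1L) {
  generate_phantom(phantom_config(height = 128L, width = 128L, seed = seed))
}
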