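# analytic test geometries and independent oracles

# horizontal line of `len` pixels in a square canvas
line_mask <- function(canvas = 21L, row = (canvas + 1L) %/% 2L,
                      cols = 6:16, pixel_size = 1) {
  m <- matrix(FALSE, canvas, canvas)
  m[row, cols] <- TRUE
  binary_mask(m, pixel_size)
}

# 45-degree diagonal of n pixels
diag_mask <- function(n = 11L, canvas = n + 10L, pixel_size = 1) {
  m <- matrix(FALSE, canvas, canvas)
  for (i in seq_len(n)) m[5L + i, 5L + i] <- TRUE
  binary_mask(m, pixel_size)
}

# symmetric Y: one horizontal arm and two diagonal arms meeting at a pixel
y_mask <- function(arm = 11L, pixel_size = 1) {
  n <- 4L * arm
  m <- matrix(FALSE, n, n)
  cy <- 2L * arm
  m[cy, cy:(cy + arm - 1L)] <- TRUE
  for (i in 0:(arm - 1L)) {
    m[cy - i, cy - i] <- TRUE
    m[cy + i, cy - i] <- TRUE
  }
  binary_mask(m, pixel_size)
}

# X: two crossing 21-px diagonal lines sharing the centre pixel
x_mask <- function(pixel_size = 1) {
  m <- matrix(FALSE, 25L, 25L)
  for (i in -10:10) {
    m[13L + i, 13L + i] <- TRUE
    m[13L - i, 13L + i] <- TRUE
  }
  binary_mask(m, pixel_size)
}

# 8-connected component count (independent BFS labelling)
n_components8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (i in which(m)) {
    if (lab[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      r <- ((q - 1L) %% nr) + 1L
      cc <- ((q - 1L) %/% nr) + 1L
      for (dy in -1:1) for (dx in -1:1) {
        rr <- r + dy; c2 <- cc + dx
        if (rr >= 1L && rr <= nr && c2 >= 1L && c2 <= nc) {
          j <- (c2 - 1L) * nr + rr
          if (m[j] && lab[j] == 0L) {
            lab[j] <- cur
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  cur
}

# brute-force skeleton length: sum over all 8-adjacent pixel pairs,
# orthogonal pairs x pixel_size, diagonal pairs x sqrt(2) * pixel_size
pair_sum_length <- function(m, pixel_size = 1) {
  orth <- sum(m[-nrow(m), ] & m[-1L, ]) + sum(m[, -ncol(m)] & m[, -1L])
  diag1 <- sum(m[-nrow(m), -ncol(m)] & m[-1L, -1L])
  diag2 <- sum(m[-1L, -ncol(m)] & m[-nrow(m), -1L])
  orth * pixel_size + (diag1 + diag2) * sqrt(2) * pixel_size
}

# random blob mask: union of seeded random disks, reproducible
blob_mask <- function(seed, n = 48L, n_disks = 6L, r_max = 7) {
  set.seed(seed)
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n_disks)) {
    ctr <- runif(2, 8, n - 8)
    m <- m | disk_roi(c(n, n), ctr, runif(1, 2, r_max))
  }
  binary_mask(m, 1)
}

# skeleton_graph stub with given segment centroids, for NND arithmetic
graph_from_centroids <- function(xy) {
  segs <- tibble::tibble(
    segment_id = seq_len(nrow(xy)),
    n_px = 5L,
    length_um = 4,
    centroid_x_um = xy[, 1],
    centroid_y_um = xy[, 2],
    closed = FALSE,
    kind = "path"
  )
  structure(list(pixels = tibble::tibble(), segments = segs,
                 junctions = tibble::tibble(), pixel_size = 1,
                 dim = c(100L, 100L)),
            class = "skeleton_graph")
}
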