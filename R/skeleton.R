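# Neighbour offsets in the fixed scan order N, NE, E, SE, S, SW, W, NW.
# This order is the deterministic tie-break for all tracing.
NB_DY <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
NB_DX <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)

# shift a matrix by (dy, dx), filling vacated cells with `fill`
shift_mat <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dy):min(nr, nr + dy)
  cs <- max(1L, 1L + dx):min(nc, nc + dx)
  out[rs, cs] <- m[rs - dy, cs - dx]
  out
}

# number of 0->1 transitions around the 8-neighbour cycle, per pixel
transition_count <- function(nb) {
  a <- matrix(0L, nrow(nb[[1]]), ncol(nb[[1]]))
  for (k in 1:8) {
    nxt <- if (k == 8L) 1L else k + 1L
    a <- a + (nb[[k]] == 0L & nb[[nxt]] == 1L)
  }
  a
}

#' Skeletonize a binary mask to 1-pixel-wide centrelines
#'
#' Topology-preserving parallel thinning with two alternating
#' sub-iterations (Guo-Hall scheme). A foreground pixel is deleted when
#' its 8-neighbourhood contains exactly one connected foreground arc
#' (crossing number 1, so removal cannot split the network or create a
#' hole), its local foreground count is 2 or 3 (line interiors and
#' endpoints are kept), and a direction condition met in only one of the
#' two sub-iterations holds (so opposite borders are peeled alternately
#' and strokes thin towards their medial line instead of retracting from
#' the ends). Iterated to a fixed point, this yields 8-connected 1-px-wide
#' centrelines with the same connected-component count as the input; a
#' 2-px diagonal staircase resolves into a clean 1-px diagonal.
#'
#' @param mask A [binary_mask()].
#'
#' @return A [binary_mask()] containing the skeleton.
#' @export
skeletonize <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- mask$pixels * 1L
  repeat {
    changed <- FALSE
    for (iter in 0:1) {
      # p2..p9 clockwise from north
      p2 <- shift_mat(m, 1L, 0L);  p3 <- shift_mat(m, 1L, -1L)
      p4 <- shift_mat(m, 0L, -1L); p5 <- shift_mat(m, -1L, -1L)
      p6 <- shift_mat(m, -1L, 0L); p7 <- shift_mat(m, -1L, 1L)
      p8 <- shift_mat(m, 0L, 1L);  p9 <- shift_mat(m, 1L, 1L)
      cnum <- (p2 == 0L & (p3 == 1L | p4 == 1L)) +
        (p4 == 0L & (p5 == 1L | p6 == 1L)) +
        (p6 == 0L & (p7 == 1L | p8 == 1L)) +
        (p8 == 0L & (p9 == 1L | p2 == 1L))
      n1 <- (p9 == 1L | p2 == 1L) + (p3 == 1L | p4 == 1L) +
        (p5 == 1L | p6 == 1L) + (p7 == 1L | p8 == 1L)
      n2 <- (p2 == 1L | p3 == 1L) + (p4 == 1L | p5 == 1L) +
        (p6 == 1L | p7 == 1L) + (p8 == 1L | p9 == 1L)
      nmin <- pmin(n1, n2)
      dcond <- if (iter == 0L) {
        ((p2 == 1L | p3 == 1L | p5 == 0L) & p4 == 1L) == 0L
      } else {
        ((p6 == 1L | p7 == 1L | p9 == 0L) & p8 == 1L) == 0L
      }
      del <- m == 1L & cnum == 1L & nmin >= 2L & nmin <= 3L & dcond
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  mask$pixels <- m == 1L
  mask
}

#' Build a classified skeleton graph
#'
#' Classifies every skeleton pixel by its number of 8-neighbours among
#' skeleton pixels (fewer than 2: endpoint; exactly 2: slab; 3 or more:
#' junction), merges 8-adjacent junction pixels into junction clusters, and
#' traces segments between terminals (endpoints or junction clusters).
#' Every 8-adjacency step between skeleton pixels is assigned to exactly
#' one segment: maximal slab runs together with their terminal attachment
#' steps, direct terminal-terminal contacts as 2-pixel bridge segments, and
#' closed slab rings as cyclic segments. Orthogonal steps measure
#' `pixel_size` micrometres, diagonal steps `sqrt(2) * pixel_size`, so the
#' summed segment lengths equal the total skeleton length with no step
#' counted twice. Isolated pixels become zero-length single-pixel segments.
#'
#' @param skeleton A [binary_mask()] holding a 1-px-wide skeleton, as
#'   produced by [skeletonize()]. A warning is raised if the input is not
#'   thin (contains a solid 2x2 block).
#'
#' @return An object of class `skeleton_graph`: a list with
#'   \describe{
#'     \item{pixels}{tibble of skeleton pixels: `y`, `x` (1-based),
#'       `class` (`"endpoint"`, `"slab"`, `"junction"`).}
#'     \item{segments}{tibble: `segment_id`, `n_px`, `length_um`,
#'       `centroid_x_um`, `centroid_y_um`, `closed`.}
#'     \item{junctions}{tibble of junction clusters: `cluster_id`, `n_px`,
#'       `centroid_x_um`, `centroid_y_um`.}
#'     \item{pixel_size}{micrometres per pixel.}
#'     \item{dim}{image dimensions.}
#'   }
#' @export
build_graph <- function(skeleton) {
  stopifnot(inherits(skeleton, "binary_mask"))
  m <- skeleton$pixels
  psz <- skeleton$pixel_size
  nr <- nrow(m); nc <- ncol(m)
  if (nr >= 2L && nc >= 2L) {
    solid22 <- m[-nr, -nc] & m[-1L, -nc] & m[-nr, -1L] & m[-1L, -1L]
    if (any(solid22)) {
      warn("skeleton is not 1 px wide everywhere (solid 2x2 block found)")
    }
  }
  idx <- which(m)
  n <- length(idx)
  if (n == 0L) {
    return(empty_skeleton_graph(psz, dim(m)))
  }
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  id_map <- matrix(0L, nr, nc)
  id_map[idx] <- seq_len(n)
  nb <- matrix(0L, n, 8L)
  for (k in 1:8) {
    r2 <- rr + NB_DY[k]; c2 <- cc + NB_DX[k]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    v <- integer(n)
    v[ok] <- id_map[cbind(r2[ok], c2[ok])]
    nb[, k] <- v
  }
  deg <- rowSums(nb > 0L)
  cls <- ifelse(deg < 2L, "endpoint", ifelse(deg == 2L, "slab", "junction"))
  is_term <- cls != "slab"

  # junction clusters: 8-connected components of junction pixels
  cluster_of <- integer(n)
  jn <- which(cls == "junction")
  cl_id <- 0L
  for (j in jn) {
    if (cluster_of[j] > 0L) next
    cl_id <- cl_id + 1L
    queue <- j
    cluster_of[j] <- cl_id
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (q in nb[p, ]) {
        if (q > 0L && cls[q] == "junction" && cluster_of[q] == 0L) {
          cluster_of[q] <- cl_id
          queue <- c(queue, q)
        }
      }
    }
  }

  step_um <- function(a, b) {
    if (rr[a] != rr[b] && cc[a] != cc[b]) sqrt(2) * psz else psz
  }
  path_length <- function(path, closed = FALSE) {
    if (length(path) < 2L) return(0)
    tot <- 0
    for (i in seq_len(length(path) - 1L)) {
      tot <- tot + step_um(path[i], path[i + 1L])
    }
    if (closed) tot <- tot + step_um(path[length(path)], path[1L])
    tot
  }

  segs <- list()
  consumed <- logical(n)  # slab pixels assigned to a segment
  terms <- which(is_term)
  for (t in terms) {
    for (k in 1:8) {
      s <- nb[t, k]
      if (s == 0L || is_term[s] || consumed[s]) next
      path <- c(t, s)
      consumed[s] <- TRUE
      prev <- t; cur <- s
      repeat {
        nbs <- nb[cur, ]
        nbs <- nbs[nbs > 0L]
        nxt <- nbs[nbs != prev][1]
        if (is.na(nxt)) break  # dangling slab (cannot occur in valid input)
        path <- c(path, nxt)
        if (is_term[nxt]) break
        consumed[nxt] <- TRUE
        prev <- cur; cur <- nxt
      }
      segs[[length(segs) + 1L]] <- list(path = path, closed = FALSE,
                                        kind = "path")
    }
  }
  # direct terminal-terminal contacts: 2-px bridges; a bridge whose two
  # pixels are junction pixels of the same cluster is internal wiring of
  # one branch point, not a vessel
  for (t in terms) {
    for (k in 1:8) {
      u <- nb[t, k]
      if (u > t && is_term[u]) {
        internal <- cls[t] == "junction" && cls[u] == "junction" &&
          cluster_of[t] == cluster_of[u]
        segs[[length(segs) + 1L]] <- list(
          path = c(t, u), closed = FALSE,
          kind = if (internal) "cluster_internal" else "bridge")
      }
    }
  }
  # isolated pixels: zero-length segments
  for (t in which(deg == 0L)) {
    segs[[length(segs) + 1L]] <- list(path = t, closed = FALSE,
                                      kind = "isolated")
  }
  # closed slab rings with no terminal
  leftover <- which(cls == "slab" & !consumed)
  while (length(leftover)) {
    s0 <- leftover[[1]]
    path <- s0
    consumed[s0] <- TRUE
    prev <- s0
    cur <- nb[s0, nb[s0, ] > 0L][1]
    while (cur != s0) {
      path <- c(path, cur)
      consumed[cur] <- TRUE
      nbs <- nb[cur, ]
      nbs <- nbs[nbs > 0L]
      nxt <- nbs[nbs != prev][1]
      prev <- cur; cur <- nxt
    }
    segs[[length(segs) + 1L]] <- list(path = path, closed = TRUE,
                                      kind = "path")
    leftover <- which(cls == "slab" & !consumed)
  }

  x_um <- (cc - 1) * psz
  y_um <- (rr - 1) * psz
  seg_tbl <- purrr::imap_dfr(segs, function(s, i) {
    tibble::tibble(
      segment_id = i,
      n_px = length(s$path),
      length_um = path_length(s$path, s$closed),
      centroid_x_um = mean(x_um[s$path]),
      centroid_y_um = mean(y_um[s$path]),
      closed = s$closed,
      kind = s$kind
    )
  })
  if (nrow(seg_tbl) == 0L) {
    seg_tbl <- tibble::tibble(segment_id = integer(), n_px = integer(),
                              length_um = numeric(), centroid_x_um = numeric(),
                              centroid_y_um = numeric(), closed = logical())
  }
  jn_tbl <- if (cl_id > 0L) {
    tibble::tibble(pix = seq_len(n), cluster = cluster_of,
                   x = x_um, y = y_um) |>
      dplyr::filter(.data$cluster > 0L) |>
      dplyr::group_by(cluster_id = .data$cluster) |>
      dplyr::summarise(n_px = dplyr::n(),
                       centroid_x_um = mean(.data$x),
                       centroid_y_um = mean(.data$y),
                       .groups = "drop")
  } else {
    tibble::tibble(cluster_id = integer(), n_px = integer(),
                   centroid_x_um = numeric(), centroid_y_um = numeric())
  }
  structure(
    list(
      pixels = tibble::tibble(y = rr, x = cc, class = cls,
                              cluster_id = ifelse(cluster_of > 0L,
                                                  cluster_of, NA_integer_)),
      segments = seg_tbl,
      junctions = jn_tbl,
      pixel_size = psz,
      dim = dim(m)
    ),
    class = "skeleton_graph"
  )
}

empty_skeleton_graph <- function(psz, d) {
  structure(
    list(
      pixels = tibble::tibble(y = integer(), x = integer(),
                              class = character(), cluster_id = integer()),
      segments = tibble::tibble(segment_id = integer(), n_px = integer(),
                                length_um = numeric(),
                                centroid_x_um = numeric(),
                                centroid_y_um = numeric(), closed = logical(),
                                kind = character()),
      junctions = tibble::tibble(cluster_id = integer(), n_px = integer(),
                                 centroid_x_um = numeric(),
                                 centroid_y_um = numeric()),
      pixel_size = psz,
      dim = d
    ),
    class = "skeleton_graph"
  )
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf(
    "<skeleton_graph> %d px, %d segments, %d junction clusters, total %.2f um\n",
    nrow(x$pixels), nrow(x$segments), nrow(x$junctions), total_length(x)))
  invisible(x)
}

#' Total calibrated skeleton length
#'
#' Sum of all segment lengths in micrometres. Invariant to segment order,
#' and equal to the sum over all adjacent skeleton pixel pairs (orthogonal
#' pairs x `pixel_size`, diagonal pairs x `sqrt(2) * pixel_size`), each pair
#' counted once.
#'
#' @param graph A [build_graph()] result.
#' @return Total length in micrometres.
#' @export
total_length <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  sum(graph$segments$length_um)
}

#' Number of branch points
#'
#' Counts junction clusters (groups of 8-adjacent junction pixels), not
#' individual junction pixels: a thick crossing produces several adjacent
#' pixels with 3+ neighbours that are anatomically one branch point.
#'
#' @param graph A [build_graph()] result.
#' @return Integer count of junction clusters.
#' @export
count_branch_points <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  nrow(graph$junctions)
}

#' @method tidy skeleton_graph
#' @export
tidy.skeleton_graph <- function(x, ...) {
  x$segments
}

#' @method glance skeleton_graph
#' @export
glance.skeleton_graph <- function(x, ...) {
  tibble::tibble(
    n_pixels = nrow(x$pixels),
    n_segments = nrow(x$segments),
    n_junctions = nrow(x$junctions),
    n_endpoints = sum(x$pixels$class == "endpoint"),
    total_length_um = total_length(x),
    pixel_size_um = x$pixel_size
  )
}
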