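#' Parameters for the synthetic vascular-network generator
#'
#' Bundles and validates every knob of the generator. The defaults emulate
#' a developing retinal plexus imaged en face: an interconnected curvilinear
#' network radiating from a central point (the optic-nerve-head analogue)
#' across a field of a few hundred micrometres, with capillary-calibre
#' vessels, additive sensor noise and a mild illumination ramp.
#'
#' @param field_size Side of the square field in micrometres.
#' @param outgrowth_fraction Radial extent of the network relative to the
#'   field radius, in `[0, 1]`.
#' @param branch_rate Branching rate per micrometre of tip advance.
#' @param branch_rate_dispersion Spatial heterogeneity of branching: each
#'   tip's personal branch rate is `branch_rate` times a lognormal
#'   multiplier with this log-sd (0 = homogeneous). High dispersion gives
#'   the clumpy, irregular mesh of an immature plexus.
#' @param anastomosis_probability Probability in `[0, 1]` that a tip
#'   meeting an existing vessel fuses with it (otherwise it terminates;
#'   tips never cross, as a single plexus is planar).
#' @param vessel_radius_range Min/max vessel radius in micrometres.
#' @param n_layers 1 for a flat plexus, 3 for a three-layer stack.
#' @param layer_z_positions Depths of the three layers in micrometres
#'   (strictly increasing; used when `n_layers = 3`).
#' @param noise_sd Additive Gaussian noise standard deviation, in intensity
#'   units on the 8-bit scale.
#' @param illumination_gradient Fractional amplitude of the multiplicative
#'   linear illumination ramp across the field.
#' @param seed Integer seed; together with the other parameters it fully
#'   determines the generated network and image.
#' @param n_initial_tips Number of sprouts leaving the centre.
#' @param step_um Tip advance per growth step, micrometres.
#' @param heading_sd Standard deviation of the per-step heading jitter
#'   (radians, wrapped normal).
#' @param radial_bias Strength in `[0, 1]` of the outward drift of growing
#'   tips: each step the heading relaxes by this fraction towards the
#'   radial direction, emulating the peripheral migration of the vascular
#'   front; 0 gives an unbiased persistent random walk.
#' @param branch_angle Mean angle between parent and child at a branch
#'   (radians).
#' @param min_branch_separation_um Refractory arc distance after a node
#'   before a tip may branch again (lateral inhibition of sprouting).
#' @param frontier_fraction Radius (as a fraction of the outgrowth limit)
#'   beyond which the network is an immature vascular front; 1 disables
#'   the front.
#' @param peripheral_branch_mult Branch-rate multiplier beyond the
#'   frontier: small values give the sparse brush of pioneer sprouts that
#'   precedes the maturing plexus.
#' @param capture_radius_um Fusion capture radius; the effective collision
#'   detection radius is `max(capture_radius_um, 2 * max radius + step/2)`
#'   so that strokes never overlap without an explicit junction.
#' @param retract_below_um Failed sprouts (tips that die without fusing)
#'   shorter than this retract completely, as abortive sprouts do in vivo;
#'   keeps the ground-truth graph free of sub-resolution stubs.
#' @param prune_below_um After growth, remove redundant capillary loops
#'   shorter than this (see [prune_network()]); 0 disables pruning.
#'   Models the remodeling that turns the dense immature mesh into the
#'   sparser, more regular adult network.
#' @param max_tip_steps Per-tip step budget.
#' @param max_total_points Global growth budget (total polyline vertices).
#'
#' @return A validated list of class `synth_params`.
#' @export
synth_params <- function(field_size = 600,
                         outgrowth_fraction = 0.9,
                         branch_rate = 0.02,
                         branch_rate_dispersion = 0,
                         anastomosis_probability = 0.7,
                         vessel_radius_range = c(2, 3),
                         n_layers = 1L,
                         layer_z_positions = c(10, 30, 50),
                         noise_sd = 3,
                         illumination_gradient = 0.1,
                         seed = 1L,
                         n_initial_tips = 8L,
                         step_um = 4,
                         heading_sd = 0.25,
                         radial_bias = 0.1,
                         branch_angle = 1.2,
                         min_branch_separation_um = 12,
                         frontier_fraction = 1,
                         peripheral_branch_mult = 1,
                         capture_radius_um = 2,
                         retract_below_um = 10,
                         prune_below_um = 0,
                         max_tip_steps = NULL,
                         max_total_points = 60000L) {
  p <- list(field_size = field_size, outgrowth_fraction = outgrowth_fraction,
            branch_rate = branch_rate,
            branch_rate_dispersion = branch_rate_dispersion,
            anastomosis_probability = anastomosis_probability,
            vessel_radius_range = sort(as.numeric(vessel_radius_range)),
            n_layers = as.integer(n_layers),
            layer_z_positions = as.numeric(layer_z_positions),
            noise_sd = noise_sd,
            illumination_gradient = illumination_gradient,
            seed = as.integer(seed),
            n_initial_tips = as.integer(n_initial_tips),
            step_um = step_um, heading_sd = heading_sd,
            radial_bias = radial_bias,
            branch_angle = branch_angle,
            min_branch_separation_um = min_branch_separation_um,
            frontier_fraction = frontier_fraction,
            peripheral_branch_mult = peripheral_branch_mult,
            capture_radius_um = capture_radius_um,
            retract_below_um = retract_below_um,
            prune_below_um = prune_below_um,
            max_tip_steps = max_tip_steps %||%
              as.integer(ceiling(field_size / step_um) * 2),
            max_total_points = as.integer(max_total_points))
  with(p, {
    if (!is.finite(field_size) || field_size <= 0) {
      abort("`field_size` must be positive")
    }
    if (outgrowth_fraction < 0 || outgrowth_fraction > 1) {
      abort("`outgrowth_fraction` must be in [0, 1]")
    }
    if (branch_rate < 0) abort("`branch_rate` must be >= 0")
    if (branch_rate_dispersion < 0) {
      abort("`branch_rate_dispersion` must be >= 0")
    }
    if (anastomosis_probability < 0 || anastomosis_probability > 1) {
      abort("`anastomosis_probability` must be in [0, 1]")
    }
    if (any(vessel_radius_range <= 0)) abort("vessel radii must be positive")
    if (!n_layers %in% c(1L, 3L)) abort("`n_layers` must be 1 or 3")
    if (n_layers == 3L &&
        (length(layer_z_positions) != 3L || any(diff(layer_z_positions) <= 0))) {
      abort("`layer_z_positions` must be 3 strictly increasing depths")
    }
    if (noise_sd < 0) abort("`noise_sd` must be >= 0")
    if (radial_bias < 0 || radial_bias > 1) {
      abort("`radial_bias` must be in [0, 1]")
    }
    if (n_initial_tips < 1L) abort("need at least one initial tip")
    if (step_um <= 0) abort("`step_um` must be positive")
  })
  structure(p, class = "synth_params")
}

# deterministic per-tip RNG substream, so a tip's draw schedule does not
# depend on how many other tips exist (branch-rate monotonicity)
tip_seed <- function(seed, tip_id) {
  as.integer((as.numeric(seed) + as.numeric(tip_id) * 7919) %% 2147483647)
}

tip_draws <- function(tip) {
  old <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", tip$rng, envir = globalenv())
  d <- list(jitter = rnorm(1), u_branch = runif(1), u_fuse = runif(1),
            branch_jitter = rnorm(1), u_side = runif(1))
  tip$rng <- get(".Random.seed", envir = globalenv())
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  d
}

#' Generate a synthetic vascular network with exact ground truth
#'
#' Grows a planar vessel network from a central point by iterative tip
#' extension: each active tip advances a fixed step with wrapped-normal
#' heading jitter, branches stochastically at `branch_rate` per micrometre,
#' and on encountering an existing vessel either fuses with it
#' (anastomosis, closing a loop and splitting the target edge at a new
#' node) or terminates. Tips also stop at the outgrowth limit
#' (`outgrowth_fraction` times the field radius) and at the field border,
#' so every vessel point stays inside both. The result is a geometric
#' graph whose total length, junction count and radial extent are known
#' exactly and serve as ground truth for the image-analysis pipeline.
#'
#' @param params A [synth_params()] object.
#' @param seed_offset Integer added to the seed (used to derive independent
#'   layers of a stack from one parameter set).
#'
#' @return An object of class `vessel_graph`: list with `nodes` (tibble:
#'   `node_id`, `x_um`, `y_um`, `degree`), `edges` (tibble: `edge_id`,
#'   `node_a`, `node_b`, `radius_um`, `length_um`, `polyline` list-column of
#'   x/y matrices), `center`, `field_size`.
#' @export
generate_network <- function(params, seed_offset = 0L) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  seed <- p$seed + as.integer(seed_offset)
  center <- c(p$field_size / 2, p$field_size / 2)
  r_limit <- p$outgrowth_fraction * p$field_size / 2
  detect <- max(p$capture_radius_um,
                2 * max(p$vessel_radius_range) + p$step_um / 2)

  # a tip ignores the neighbourhood of its start node until it has
  # travelled clear of it
  young_steps <- ceiling(2 * detect / p$step_um) + 1L

  cap <- p$max_total_points
  st <- new.env(parent = emptyenv())
  st$X <- numeric(cap); st$Y <- numeric(cap)
  st$kind <- integer(cap)   # 1 = edge interior, 2 = tip path, 3 = node
  st$oid <- integer(cap); st$idx <- integer(cap)
  st$nreg <- 0L
  st$nodes <- matrix(NA_real_, 4096L, 2L)
  st$n_nodes <- 0L
  st$edges <- list()

  reg_point <- function(x, y, kind, oid, idx) {
    st$nreg <- st$nreg + 1L
    i <- st$nreg
    st$X[i] <- x; st$Y[i] <- y
    st$kind[i] <- kind; st$oid[i] <- oid; st$idx[i] <- idx
    i
  }
  new_node <- function(x, y) {
    st$n_nodes <- st$n_nodes + 1L
    if (st$n_nodes > nrow(st$nodes)) {
      st$nodes <- rbind(st$nodes, matrix(NA_real_, nrow(st$nodes), 2L))
    }
    st$nodes[st$n_nodes, ] <- c(x, y)
    reg_point(x, y, 3L, st$n_nodes, 1L)
    st$n_nodes
  }
  new_edge <- function(a, b, poly, radius) {
    st$edges[[length(st$edges) + 1L]] <- list(a = a, b = b, poly = poly,
                                              radius = radius)
    length(st$edges)
  }

  tips <- list()
  tip_count <- 0L
  spawn_tip <- function(start_node, heading, radius) {
    tip_count <<- tip_count + 1L
    tip <- new.env(parent = emptyenv())
    tip$id <- tip_count
    tip$start_node <- start_node
    tip$pos <- st$nodes[start_node, ]
    tip$heading <- heading
    tip$radius <- radius
    tip$poly <- matrix(tip$pos, 1L, 2L)
    tip$rows <- integer(0)   # registry rows of poly vertices 2..len
    tip$steps <- 0L
    tip$node_steps <- 0L     # steps since leaving the last node
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(tip_seed(seed, tip_count))
    tip$rng <- get(".Random.seed", envir = globalenv())
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    # sector heterogeneity: every third founder heads a dense sector,
    # the rest sparse ones; descendants inherit their founder's
    # multiplier, so the patchiness has the angular grain of the
    # founding sprouts
    tip$rate_mult <- exp(if (tip_count %% 3L == 1L) {
      p$branch_rate_dispersion
    } else {
      -p$branch_rate_dispersion
    })
    tips[[length(tips) + 1L]] <<- tip
    tip
  }

  # finalize a tip's pending polyline up to vertex k as an edge ending at
  # node `b`; the tip continues (or dies) from that node
  finalize_to <- function(tip, k, b) {
    poly <- tip$poly[seq_len(k), , drop = FALSE]
    if (k >= 2L) {
      e <- new_edge(tip$start_node, b, poly, tip$radius)
      rows <- tip$rows[tip$rows > 0L]
      rows <- head(rows, k - 1L)
      if (length(rows) >= 2L) {
        inner <- rows[-length(rows)]
        st$kind[inner] <- 1L
        st$oid[inner] <- e
        st$idx[inner] <- seq_along(inner) + 1L
      }
      if (length(rows) >= 1L) {
        last <- rows[length(rows)]
        st$kind[last] <- 3L; st$oid[last] <- b; st$idx[last] <- 1L
      }
    }
    len <- nrow(tip$poly)
    if (k < len) {
      tip$start_node <- b
      tip$poly <- tip$poly[k:len, , drop = FALSE]
      rest <- tail(tip$rows, len - k)
      st$idx[rest] <- seq_along(rest) + 1L
      tip$rows <- rest
    } else {
      tip$start_node <- b
      tip$poly <- matrix(st$nodes[b, ], 1L, 2L)
      tip$rows <- integer(0)
    }
  }

  # resolve a captured registry point into a graph node, splitting the
  # owning edge or tip path when the point is interior
  capture_node <- function(row) {
    kind <- st$kind[row]; oid <- st$oid[row]; k <- st$idx[row]
    if (kind == 3L) return(oid)
    if (kind == 1L) {
      e <- st$edges[[oid]]
      npoly <- nrow(e$poly)
      nd <- new_node(e$poly[k, 1], e$poly[k, 2])
      e1 <- list(a = e$a, b = nd, poly = e$poly[seq_len(k), , drop = FALSE],
                 radius = e$radius)
      st$edges[[oid]] <- e1
      e2_id <- new_edge(nd, e$b, e$poly[k:npoly, , drop = FALSE], e$radius)
      rows <- which(st$kind == 1L & st$oid == oid)
      late <- rows[st$idx[rows] > k]
      st$oid[late] <- e2_id
      st$idx[late] <- st$idx[late] - k + 1L
      st$kind[row] <- 3L; st$oid[row] <- nd; st$idx[row] <- 1L
      return(nd)
    }
    # kind == 2: interior of another active tip's pending path
    owner <- tips[[oid]]
    nd <- new_node(owner$poly[k, 1], owner$poly[k, 2])
    finalize_to(owner, k, nd)
    nd
  }

  terminate_tip <- function(tip) {
    len <- nrow(tip$poly)
    if (len >= 2L && polyline_length(tip$poly) < p$retract_below_um) {
      # abortive sprout: retract instead of leaving a sub-resolution stub
      rows <- tip$rows[tip$rows > 0L]
      st$X[rows] <- Inf
      st$Y[rows] <- Inf
      tip$alive <- FALSE
      return(invisible(NULL))
    }
    if (len >= 2L) {
      nd <- new_node(tip$poly[len, 1], tip$poly[len, 2])
      # the end vertex row gets re-tagged to the node inside finalize_to
      finalize_to(tip, len, nd)
    }
    tip$alive <- FALSE
  }

  # founders start on a ring around the centre (vessel trunks leave the
  # optic-nerve-head rim separately, not from a single point); the ring is
  # wide enough that neighbouring trunks are outside each other's
  # collision radius
  ring <- max(2 * p$step_um, 1.2 * p$n_initial_tips * detect / (2 * pi))
  r0 <- runif_det(seed, p$n_initial_tips)  # initial radii schedule
  for (i in seq_len(p$n_initial_tips)) {
    h <- 2 * pi * (i - 1) / p$n_initial_tips
    radius <- p$vessel_radius_range[1] +
      r0[i] * diff(p$vessel_radius_range)
    start <- new_node(center[1] + ring * cos(h), center[2] + ring * sin(h))
    t <- spawn_tip(start, h, radius)
    t$alive <- TRUE
  }

  repeat {
    active <- Filter(function(t) isTRUE(t$alive), tips)
    if (length(active) == 0L || st$nreg > cap - 10L) break
    for (tip in active) {
      if (!isTRUE(tip$alive)) next
      if (st$nreg > cap - 10L) break
      d <- tip_draws(tip)
      tip$steps <- tip$steps + 1L
      tip$node_steps <- tip$node_steps + 1L
      if (tip$steps > p$max_tip_steps) { terminate_tip(tip); next }
      heading <- tip$heading
      if (p$radial_bias > 0 && any(tip$pos != center)) {
        radial <- atan2(tip$pos[2] - center[2], tip$pos[1] - center[1])
        delta <- (radial - heading + pi) %% (2 * pi) - pi
        heading <- heading + p$radial_bias * delta
      }
      heading <- heading + d$jitter * p$heading_sd
      new_pos <- tip$pos + p$step_um * c(cos(heading), sin(heading))
      # outgrowth limit and field border stop growth
      if (sqrt(sum((new_pos - center)^2)) > r_limit ||
          any(new_pos < 0) || any(new_pos > p$field_size)) {
        terminate_tip(tip)
        next
      }
      # collision with existing vasculature
      n <- st$nreg
      d2 <- (st$X[seq_len(n)] - new_pos[1])^2 +
        (st$Y[seq_len(n)] - new_pos[2])^2
      excl <- st$kind[seq_len(n)] == 2L & st$oid[seq_len(n)] == tip$id
      # just after leaving a node a tip ignores its immediate
      # surroundings there, so siblings and the continuing parent do not
      # instantly collide with each other or with the node itself
      if (tip$node_steps <= young_steps) {
        sp <- st$nodes[tip$start_node, ]
        near_start <- (st$X[seq_len(n)] - sp[1])^2 +
          (st$Y[seq_len(n)] - sp[2])^2 < (2 * detect)^2
        excl <- excl | near_start
      }
      d2[excl] <- Inf
      hit <- which.min(d2)
      if (length(hit) == 1L && is.finite(d2[hit]) && d2[hit] < detect^2) {
        if (d$u_fuse < p$anastomosis_probability) {
          nd <- capture_node(hit)
          tip$poly <- rbind(tip$poly, st$nodes[nd, ])
          tip$rows <- c(tip$rows, 0L)  # placeholder; node already registered
          len <- nrow(tip$poly)
          if (len >= 2L) {
            poly <- tip$poly
            e <- new_edge(tip$start_node, nd, poly, tip$radius)
            rows <- tip$rows[tip$rows > 0L]
            if (length(rows)) {
              st$kind[rows] <- 1L
              st$oid[rows] <- e
              st$idx[rows] <- seq_along(rows) + 1L
            }
          }
          tip$alive <- FALSE
        } else {
          terminate_tip(tip)
        }
        next
      }
      # advance
      tip$heading <- heading
      tip$pos <- new_pos
      row <- reg_point(new_pos[1], new_pos[2], 2L, tip$id,
                       nrow(tip$poly) + 1L)
      tip$poly <- rbind(tip$poly, new_pos)
      tip$rows <- c(tip$rows, row)
      # branching: the tip's current position becomes a junction node
      rate_here <- p$branch_rate * tip$rate_mult
      if (p$frontier_fraction < 1 &&
          sqrt(sum((tip$pos - center)^2)) > p$frontier_fraction * r_limit) {
        rate_here <- rate_here * p$peripheral_branch_mult
      }
      if (d$u_branch < rate_here * p$step_um &&
          nrow(tip$poly) >= 2L &&
          tip$node_steps * p$step_um >= p$min_branch_separation_um) {
        nd <- new_node(new_pos[1], new_pos[2])
        finalize_to(tip, nrow(tip$poly), nd)
        tip$node_steps <- 0L
        side <- if (d$u_side < 0.5) -1 else 1
        child <- spawn_tip(nd, tip$heading +
                             side * (p$branch_angle +
                                       0.2 * d$branch_jitter), tip$radius)
        child$rate_mult <- tip$rate_mult
        child$alive <- TRUE
      }
    }
  }
  for (tip in tips) if (isTRUE(tip$alive)) terminate_tip(tip)

  edges <- st$edges
  deg <- integer(st$n_nodes)
  for (e in edges) {
    deg[e$a] <- deg[e$a] + 1L
    deg[e$b] <- deg[e$b] + 1L
  }
  nodes <- tibble::tibble(node_id = seq_len(st$n_nodes),
                          x_um = st$nodes[seq_len(st$n_nodes), 1],
                          y_um = st$nodes[seq_len(st$n_nodes), 2],
                          degree = deg)
  edge_tbl <- purrr::imap_dfr(edges, function(e, i) {
    tibble::tibble(edge_id = i, node_a = e$a, node_b = e$b,
                   radius_um = e$radius,
                   length_um = polyline_length(e$poly),
                   polyline = list(unname(e$poly)))
  })
  if (nrow(edge_tbl) == 0L) {
    edge_tbl <- tibble::tibble(edge_id = integer(), node_a = integer(),
                               node_b = integer(), radius_um = numeric(),
                               length_um = numeric(), polyline = list())
  }
  g <- structure(list(nodes = nodes, edges = edge_tbl, center = center,
                      field_size = p$field_size, params = p),
                 class = "vessel_graph")
  if (p$prune_below_um > 0 && nrow(edge_tbl) > 0) {
    g <- prune_network(g, p$prune_below_um)
  }
  g
}

# deterministic uniforms independent of the global RNG state
runif_det <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed %% 2147483647))
  x <- runif(n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  x
}

polyline_length <- function(poly) {
  if (nrow(poly) < 2L) return(0)
  sum(sqrt(rowSums(diff(poly)^2)))
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf(
    "<vessel_graph> %d nodes, %d edges, %.1f um total, %d junction nodes\n",
    nrow(x$nodes), nrow(x$edges), network_total_length(x),
    network_junction_count(x)))
  invisible(x)
}

#' Ground-truth total vessel length of a synthetic network
#'
#' Sum of the chord lengths of all edge polylines, in micrometres.
#' Invariant under rasterization parameters.
#'
#' @param graph A [generate_network()] result.
#' @return Length in micrometres.
#' @export
network_total_length <- function(graph) {
  stopifnot(inherits(graph, "vessel_graph"))
  sum(graph$edges$length_um)
}

#' Ground-truth junction count of a synthetic network
#'
#' Number of nodes of degree 3 or more (branch points and anastomoses).
#'
#' @param graph A [generate_network()] result.
#' @return Integer count.
#' @export
network_junction_count <- function(graph) {
  stopifnot(inherits(graph, "vessel_graph"))
  sum(graph$nodes$degree >= 3L)
}

#' Ground-truth radial outgrowth of a synthetic network
#'
#' Maximum distance from the centre to any polyline vertex, relative to the
#' field radius.
#'
#' @param graph A [generate_network()] result.
#' @return Fraction in `[0, 1]`.
#' @export
network_outgrowth <- function(graph) {
  stopifnot(inherits(graph, "vessel_graph"))
  if (nrow(graph$edges) == 0L) return(0)
  pts <- do.call(rbind, graph$edges$polyline)
  d <- sqrt((pts[, 1] - graph$center[1])^2 + (pts[, 2] - graph$center[2])^2)
  min(1, max(d) / (graph$field_size / 2))
}

#' Exact stroke mask of a synthetic network
#'
#' Rasterizes the network as hard (non-anti-aliased) strokes: a pixel is
#' foreground iff its centre lies within the edge radius of the edge's
#' polyline (round caps). This analytic mask is the ground-truth
#' binarization of the network.
#'
#' @param graph A [generate_network()] result.
#' @param pixel_size Micrometres per pixel.
#' @return A [binary_mask()] with the network centre attached (in pixel
#'   coordinates).
#' @export
rasterize_mask <- function(graph, pixel_size = 1) {
  stopifnot(inherits(graph, "vessel_graph"))
  if (pixel_size <= 0) abort("`pixel_size` must be positive")
  n <- floor(graph$field_size / pixel_size) + 1L
  m <- matrix(FALSE, n, n)
  for (i in seq_len(nrow(graph$edges))) {
    poly <- graph$edges$polyline[[i]]
    r <- graph$edges$radius_um[i]
    if (nrow(poly) < 2L) next
    for (s in seq_len(nrow(poly) - 1L)) {
      m <- stamp_segment(m, poly[s, ], poly[s + 1L, ], r, pixel_size)
    }
  }
  center_px <- graph$center / pixel_size + 1
  binary_mask(m, pixel_size, center = center_px)
}

# mark pixels whose centre is within `r` of segment pq (um coordinates)
stamp_segment <- function(m, p, q, r, psz) {
  n <- nrow(m)
  ymin <- min(p[2], q[2]) - r; ymax <- max(p[2], q[2]) + r
  xmin <- min(p[1], q[1]) - r; xmax <- max(p[1], q[1]) + r
  ri <- max(1L, floor(ymin / psz) + 1L):min(n, ceiling(ymax / psz) + 1L)
  ci <- max(1L, floor(xmin / psz) + 1L):min(ncol(m), ceiling(xmax / psz) + 1L)
  gy <- (ri - 1) * psz
  gx <- (ci - 1) * psz
  v <- q - p
  vv <- sum(v^2)
  GX <- matrix(gx, length(ri), length(ci), byrow = TRUE)
  GY <- matrix(gy, length(ri), length(ci))
  tt <- if (vv > 0) ((GX - p[1]) * v[1] + (GY - p[2]) * v[2]) / vv else 0
  tt <- pmin(pmax(tt, 0), 1)
  d2 <- (GX - (p[1] + tt * v[1]))^2 + (GY - (p[2] + tt * v[2]))^2
  sub <- m[ri, ci, drop = FALSE]
  m[ri, ci] <- sub | (d2 <= r^2)
  m
}

#' Rasterize a synthetic network into a retina-like grayscale image
#'
#' Draws each vessel as a hard stroke of width twice its radius (bright
#' foreground on a dark background), applies a multiplicative linear
#' illumination ramp across the field, and adds Gaussian sensor noise.
#' If the narrowest stroke is under 1 px wide, a warning is recorded in the
#' image metadata (vessels may vanish at that calibration).
#'
#' @param graph A [generate_network()] result.
#' @param pixel_size Micrometres per pixel.
#' @param noise_sd Gaussian noise standard deviation (8-bit intensity units).
#' @param illumination_gradient Fractional amplitude of the ramp (0 = flat).
#' @param fg,bg Foreground/background intensity levels.
#' @param seed Optional seed for the noise; if `NULL` the current RNG
#'   stream is used.
#' @return A [calibrated_image()] with the network centre attached.
#' @export
rasterize <- function(graph, pixel_size = 1, noise_sd = 0,
                      illumination_gradient = 0, fg = 200, bg = 25,
                      seed = NULL) {
  mask <- rasterize_mask(graph, pixel_size)
  meta <- list()
  min_width_px <- 2 * min(c(graph$edges$radius_um, Inf)) / pixel_size
  if (is.finite(min_width_px) && min_width_px < 1) {
    meta$warnings <- sprintf(
      "narrowest stroke is %.2f px wide; vessels may vanish", min_width_px)
    warn(meta$warnings)
  }
  px <- bg + (fg - bg) * mask$pixels
  nc <- ncol(px)
  if (illumination_gradient != 0 && nc > 1L) {
    ramp <- 1 + illumination_gradient *
      ((seq_len(nc) - 1) / (nc - 1) - 0.5)
    px <- sweep(px, 2L, ramp, `*`)
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    px <- px + rnorm(length(px), sd = noise_sd)
  }
  px <- pmin(pmax(px, 0), 255)
  calibrated_image(matrix(px, nrow(mask$pixels), nc), pixel_size,
                   center = mask$center, metadata = meta)
}

#' Rasterize three network layers into a 3D z-stack
#'
#' Each layer's vessels occupy a Gaussian-weighted z-band centred on its
#' depth (weight `exp(-(z - z_l)^2 / (2 sigma_z^2))`, truncated at 3
#' sigma), so the per-slice foreground profile has three local maxima at
#' the layer depths. A warning is raised when adjacent bands overlap
#' (separation under 6 sigma).
#'
#' @param graphs List of three [generate_network()] results (primary,
#'   intermediate, deep).
#' @param layer_z Depths of the three layers in micrometres, strictly
#'   increasing.
#' @param pixel_size In-plane micrometres per pixel.
#' @param pixel_size_z Slice spacing in micrometres.
#' @param sigma_z Axial extent (standard deviation) of each vessel layer.
#' @param z_margin Extra depth below the first and beyond the last layer.
#' @inheritParams rasterize
#' @return A 3D [calibrated_image()] ordered `(z, y, x)`.
#' @export
rasterize_stack <- function(graphs, layer_z = c(10, 30, 50),
                            pixel_size = 1, pixel_size_z = 1, sigma_z = 2,
                            z_margin = 10, noise_sd = 0,
                            illumination_gradient = 0, fg = 200, bg = 25,
                            seed = NULL) {
  stopifnot(is.list(graphs), length(graphs) == 3L)
  layer_z <- as.numeric(layer_z)
  if (length(layer_z) != 3L || any(diff(layer_z) <= 0)) {
    abort("`layer_z` must be 3 strictly increasing depths")
  }
  if (any(diff(layer_z) < 6 * sigma_z)) {
    warn("layer z-bands overlap: separation under 6 * sigma_z")
  }
  masks <- lapply(graphs, function(g) rasterize_mask(g, pixel_size)$pixels)
  ny <- nrow(masks[[1]]); nx <- ncol(masks[[1]])
  zs <- seq(0, max(layer_z) + z_margin, by = pixel_size_z)
  nz <- length(zs)
  ramp <- if (illumination_gradient != 0 && nx > 1L) {
    1 + illumination_gradient * ((seq_len(nx) - 1) / (nx - 1) - 0.5)
  } else {
    rep(1, nx)
  }
  stack <- array(0, dim = c(nz, ny, nx))
  for (zi in seq_len(nz)) {
    w <- exp(-(zs[zi] - layer_z)^2 / (2 * sigma_z^2))
    w[abs(zs[zi] - layer_z) > 3 * sigma_z] <- 0
    sl <- matrix(0, ny, nx)
    for (l in 1:3) {
      if (w[l] > 0) sl <- pmax(sl, w[l] * masks[[l]])
    }
    px <- bg + (fg - bg) * sl
    px <- sweep(px, 2L, ramp, `*`)
    stack[zi, , ] <- px
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    stack <- stack + rnorm(length(stack), sd = noise_sd)
  }
  stack <- pmin(pmax(stack, 0), 255)
  center_px <- graphs[[1]]$center / pixel_size + 1
  calibrated_image(stack, c(pixel_size_z, pixel_size, pixel_size),
                   center = center_px,
                   metadata = list(layer_z = layer_z, sigma_z = sigma_z))
}

#' Generate a complete synthetic image (or stack) from parameters
#'
#' Seed-driven wrapper tying the generator and rasterizer together:
#' identical parameters (including the seed) give bit-identical output.
#' With `n_layers = 1` the result is a 2D flatmount-like image; with
#' `n_layers = 3`, a three-layer z-stack whose per-layer networks are
#' grown from seeds derived from the main seed.
#'
#' @param params A [synth_params()] object.
#' @param pixel_size Micrometres per pixel (in-plane).
#' @return A list with `image` (a [calibrated_image()]), `graphs` (list of
#'   [generate_network()] results, one per layer) and `params`.
#' @export
synth_image <- function(params, pixel_size = 1) {
  stopifnot(inherits(params, "synth_params"))
  if (params$n_layers == 1L) {
    g <- generate_network(params)
    img <- rasterize(g, pixel_size = pixel_size, noise_sd = params$noise_sd,
                     illumination_gradient = params$illumination_gradient,
                     seed = params$seed + 500009L)
    list(image = img, graphs = list(g), params = params)
  } else {
    graphs <- lapply(0:2, function(l) {
      generate_network(params, seed_offset = l * 1009L)
    })
    img <- rasterize_stack(graphs, layer_z = params$layer_z_positions,
                           pixel_size = pixel_size,
                           noise_sd = params$noise_sd,
                           illumination_gradient = params$illumination_gradient,
                           seed = params$seed + 500009L)
    list(image = img, graphs = graphs, params = params)
  }
}

#' Preset parameter sets for developmental stages
#'
#' Two study conditions: `"p10"` emulates the dense, irregular capillary
#' mesh at the peak of developmental angiogenesis (high branching, strong
#' heading jitter, full-field outgrowth), `"p60"` the pruned, regular adult
#' network (lower branching, straighter vessels). Pushing a synthetic pair
#' through the pipeline should rank them the way remodeling does: area
#' fraction and branch density fall from p10 to p60, and the variability of
#' the nearest-neighbour distance falls as spacing becomes regular.
#'
#' @param stage `"p10"` or `"p60"`.
#' @param seed Integer seed.
#' @param n_layers 1 or 3.
#' @return A [synth_params()] object.
#' @export
synth_preset <- function(stage = c("p10", "p60"), seed = 1L, n_layers = 1L) {
  stage <- match.arg(stage)
  if (stage == "p10") {
    synth_params(field_size = 600, outgrowth_fraction = 0.94,
                 branch_rate = 0.035, branch_rate_dispersion = 0.6,
                 anastomosis_probability = 0.7, n_initial_tips = 12L,
                 min_branch_separation_um = 10,
                 frontier_fraction = 0.85, peripheral_branch_mult = 0.04,
                 vessel_radius_range = c(2.8, 3.8), heading_sd = 0.35,
                 noise_sd = 3, illumination_gradient = 0.1,
                 seed = seed, n_layers = n_layers)
  } else {
    synth_params(field_size = 600, outgrowth_fraction = 1,
                 branch_rate = 0.1, anastomosis_probability = 0.7,
                 n_initial_tips = 10L, heading_sd = 0.02,
                 min_branch_separation_um = 25, radial_bias = 0.3,
                 capture_radius_um = 8.8,
                 vessel_radius_range = c(1.8, 2.5),
                 noise_sd = 3, illumination_gradient = 0.1,
                 seed = seed, n_layers = n_layers)
  }
}

#' @method tidy vessel_graph
#' @export
tidy.vessel_graph <- function(x, ...) {
  dplyr::select(x$edges, -"polyline")
}

#' @method glance vessel_graph
#' @export
glance.vessel_graph <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_junctions = network_junction_count(x),
    total_length_um = network_total_length(x),
    outgrowth = network_outgrowth(x),
    field_size_um = x$field_size
  )
}

#' Prune a synthetic network the way remodeling does
#'
#' Developmental remodeling reduces an initially dense plexus by removing
#' short, redundant capillary loops while keeping the network connected.
#' This operation removes edges shorter than `min_length_um`, shortest
#' first, but only when the edge lies on a cycle and both endpoints remain
#' branch points (degree 3 or more) before removal — so no vessel is left
#' dangling and no territory is disconnected. The result has fewer
#' branches, lower area coverage and more regular spacing, with ground
#' truth still exact.
#'
#' @param graph A [generate_network()] result.
#' @param min_length_um Edges shorter than this are candidates for
#'   removal.
#' @return A pruned `vessel_graph`.
#' @export
prune_network <- function(graph, min_length_um) {
  stopifnot(inherits(graph, "vessel_graph"))
  edges <- graph$edges
  keep <- rep(TRUE, nrow(edges))
  deg <- function() {
    d <- integer(nrow(graph$nodes))
    for (i in which(keep)) {
      d[edges$node_a[i]] <- d[edges$node_a[i]] + 1L
      d[edges$node_b[i]] <- d[edges$node_b[i]] + 1L
    }
    d
  }
  connected_without <- function(drop) {
    a <- edges$node_a[drop]; b <- edges$node_b[drop]
    if (a == b) return(TRUE)
    adj <- list()
    for (i in which(keep)) {
      if (i == drop) next
      adj[[as.character(edges$node_a[i])]] <-
        c(adj[[as.character(edges$node_a[i])]], edges$node_b[i])
      adj[[as.character(edges$node_b[i])]] <-
        c(adj[[as.character(edges$node_b[i])]], edges$node_a[i])
    }
    seen <- a
    queue <- a
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[as.character(v)]]) {
        if (w == b) return(TRUE)
        if (!(w %in% seen)) {
          seen <- c(seen, w)
          queue <- c(queue, w)
        }
      }
    }
    FALSE
  }
  ord <- order(edges$length_um)
  for (i in ord) {
    if (!keep[i]) next
    if (edges$length_um[i] >= min_length_um) break
    d <- deg()
    if (d[edges$node_a[i]] < 3L || d[edges$node_b[i]] < 3L) next
    if (!connected_without(i)) next
    keep[i] <- FALSE
  }
  out <- graph
  out$edges <- edges[keep, , drop = FALSE]
  out$edges$edge_id <- seq_len(nrow(out$edges))
  d <- integer(nrow(graph$nodes))
  for (i in seq_len(nrow(out$edges))) {
    d[out$edges$node_a[i]] <- d[out$edges$node_a[i]] + 1L
    d[out$edges$node_b[i]] <- d[out$edges$node_b[i]] + 1L
  }
  out$nodes$degree <- d
  out
}
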