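# Alpha-shape search polygons. A player's search area is the tightest
# single-component polygon containing its visited positions: the alpha
# complex (Delaunay triangles with circumradius below a threshold) for the
# smallest threshold that still covers every point in one connected piece,
# falling back to the convex hull (the full triangulation) when no tighter
# complex qualifies.

tri_circumradius <- function(p1, p2, p3) {
  a <- sqrt(sum((p2 - p3)^2))
  b <- sqrt(sum((p1 - p3)^2))
  c <- sqrt(sum((p1 - p2)^2))
  K <- 0.5 * abs((p2[1L] - p1[1L]) * (p3[2L] - p1[2L]) -
                   (p3[1L] - p1[1L]) * (p2[2L] - p1[2L]))
  if (K <= 0) return(Inf)
  a * b * c / (4 * K)
}

tri_area <- function(p1, p2, p3) {
  0.5 * abs((p2[1L] - p1[1L]) * (p3[2L] - p1[2L]) -
              (p3[1L] - p1[1L]) * (p2[2L] - p1[2L]))
}

# Delaunay triangulation as an index matrix (rows = triangles); deldir
# narrates its retries on degenerate inputs, so swallow its console output
delaunay_index <- function(pts) {
  dd <- NULL
  utils::capture.output(
    dd <- deldir::deldir(pts[, 1L], pts[, 2L], suppressMsge = TRUE)
  )
  tl <- deldir::triang.list(dd)
  t(vapply(tl, function(tr) as.integer(tr$ptNum), integer(3L)))
}

# connected components of a triangle set under shared-edge adjacency;
# returns TRUE when the set is a single component
tris_connected <- function(tris) {
  nt <- nrow(tris)
  if (nt <= 1L) return(TRUE)
  edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  keys <- c(edge_key(tris[, 1L], tris[, 2L]),
            edge_key(tris[, 2L], tris[, 3L]),
            edge_key(tris[, 1L], tris[, 3L]))
  owner <- rep(seq_len(nt), 3L)
  # union-find over triangles sharing an edge
  parent <- seq_len(nt)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  sp <- split(owner, keys)
  for (g in sp) {
    if (length(g) > 1L) {
      r <- find(g[1L])
      for (j in g[-1L]) parent[find(j)] <- r
    }
  }
  length(unique(vapply(seq_len(nt), find, integer(1L)))) == 1L
}

# boundary rings of a triangle set, merged with polyclip
tris_rings <- function(pts, tris) {
  polys <- lapply(seq_len(nrow(tris)), function(i) {
    v <- tris[i, ]
    list(x = pts[v, 1L], y = pts[v, 2L])
  })
  polyclip::polyclip(polys, polys, op = "union",
                     fillA = "nonzero", fillB = "nonzero")
}

ring_signed_area <- function(r) {
  x <- r$x
  y <- r$y
  0.5 * sum(x * (c(y[-1L], y[1L])) - y * c(x[-1L], x[1L]))
}

#' Total area of a polygonal region
#'
#' Sum of signed shoelace areas over rings (holes carry opposite
#' orientation, so they are subtracted).
#'
#' @param rings List of rings, each `list(x, y)`.
#' @return Area (>= 0 for validly oriented regions).
#' @export
region_area <- function(rings) {
  if (!length(rings)) return(0)
  sum(vapply(rings, ring_signed_area, numeric(1L)))
}

#' Alpha-shape bounding polygon of a point set
#'
#' Computes the Delaunay triangulation, then selects the alpha complex with
#' the smallest circumradius threshold under which every input point is
#' still a vertex of the kept triangles and the kept triangles form a
#' single edge-connected component. The candidate thresholds are exactly
#' the triangle circumradii (the complex is piecewise constant in the
#' shape parameter), so a binary search over the sorted radii finds the
#' tightest admissible shape without an iterative tolerance. When only the
#' full triangulation qualifies, the result is the convex hull
#' (`method = "convex_hull"`). Holes are permitted and subtracted from the
#' area. Fewer than three distinct non-collinear points yield a degenerate
#' result with zero area.
#'
#' @param points Two-column matrix of positions (m). Typically a trajectory
#'   already decimated to the analysis rate (see [downsample_track()]).
#' @param player Optional identifier stored with the polygon.
#' @return A `herd_search_polygon`: `rings` (boundary, holes included),
#'   `area` (m^2), `method` (`"alpha_shape"`, `"convex_hull"`, or
#'   `"degenerate"`), `triangles`, `points`, `player`.
#' @export
alpha_shape <- function(points, player = NA) {
  pts <- unique(as.matrix(points))
  storage.mode(pts) <- "double"
  degenerate <- function() {
    structure(list(rings = list(), area = 0, method = "degenerate",
                   triangles = NULL, points = pts, player = player),
              class = "herd_search_polygon")
  }
  if (nrow(pts) < 3L) return(degenerate())
  # collinearity check
  v <- sweep(pts[-1L, , drop = FALSE], 2L, pts[1L, ])
  cr <- v[, 1L] * v[1L, 2L] - v[, 2L] * v[1L, 1L]
  if (all(abs(cr) < 1e-12)) return(degenerate())

  # Trajectories contain long runs of exactly collinear points that can
  # defeat the triangulation; retry once with a deterministic sub-micrometer
  # jitter, then fall back to the convex hull (the documented fallback).
  tris <- tryCatch(delaunay_index(pts), error = function(e) NULL)
  if (is.null(tris)) {
    scale <- max(diff(range(pts[, 1L])), diff(range(pts[, 2L])), 1e-9)
    i <- seq_len(nrow(pts))
    jit <- cbind(sin(i * 12.9898), cos(i * 78.233)) * (1e-7 * scale)
    tris <- tryCatch(delaunay_index(pts + jit), error = function(e) NULL)
    if (!is.null(tris)) pts <- pts + jit
  }
  if (is.null(tris)) return(convex_hull_polygon(points, player = player))
  radii <- vapply(seq_len(nrow(tris)), function(i) {
    tri_circumradius(pts[tris[i, 1L], ], pts[tris[i, 2L], ], pts[tris[i, 3L], ])
  }, numeric(1L))
  cand <- sort(unique(radii))

  admissible <- function(r) {
    keep <- tris[radii <= r, , drop = FALSE]
    if (!nrow(keep)) return(FALSE)
    if (length(unique(as.vector(keep))) != nrow(pts)) return(FALSE)
    tris_connected(keep)
  }

  lo <- 1L
  hi <- length(cand)
  if (!admissible(cand[hi])) {
    # cannot happen for a valid triangulation, but guard anyway
    return(degenerate())
  }
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (admissible(cand[mid])) hi <- mid else lo <- mid + 1L
  }
  keep <- tris[radii <= cand[lo], , drop = FALSE]
  area <- sum(vapply(seq_len(nrow(keep)), function(i) {
    tri_area(pts[keep[i, 1L], ], pts[keep[i, 2L], ], pts[keep[i, 3L], ])
  }, numeric(1L)))
  structure(list(
    rings = tris_rings(pts, keep),
    area = area,
    method = if (lo == length(cand)) "convex_hull" else "alpha_shape",
    triangles = keep,
    points = pts,
    player = player
  ), class = "herd_search_polygon")
}

#' @export
print.herd_search_polygon <- function(x, ...) {
  cat("<herd_search_polygon> method:", x$method,
      "| area:", format(x$area, digits = 6),
      "| rings:", length(x$rings),
      "| points:", nrow(x$points), "\n")
  invisible(x)
}

#' Convex hull as a search polygon
#'
#' The convex-hull counterpart of [alpha_shape()], used for comparisons.
#'
#' @inheritParams alpha_shape
#' @return A `herd_search_polygon` with `method = "convex_hull"`.
#' @export
convex_hull_polygon <- function(points, player = NA) {
  pts <- unique(as.matrix(points))
  storage.mode(pts) <- "double"
  if (nrow(pts) < 3L) {
    return(structure(list(rings = list(), area = 0, method = "degenerate",
                          triangles = NULL, points = pts, player = player),
                     class = "herd_search_polygon"))
  }
  h <- chull(pts[, 1L], pts[, 2L])
  ring <- list(x = pts[h, 1L], y = pts[h, 2L])
  a <- ring_signed_area(ring)
  if (a < 0) {
    ring <- list(x = rev(ring$x), y = rev(ring$y))
    a <- -a
  }
  structure(list(rings = list(ring), area = a, method = "convex_hull",
                 triangles = NULL, points = pts, player = player),
            class = "herd_search_polygon")
}

#' Search polygons of all players in a trial
#'
#' Applies the standard preprocessing (decimation to `to_hz`, first second
#' deleted, no smoothing) to each player track and computes its alpha-shape
#' search polygon.
#'
#' @param log A `herd_trial_log`.
#' @param to_hz Analysis rate, Hz.
#' @return List of three `herd_search_polygon` objects.
#' @export
search_polygons <- function(log, to_hz = 5) {
  stopifnot(inherits(log, "herd_trial_log"))
  lapply(1:3, function(i) {
    pos <- cbind(log$player_x[, i], log$player_y[, i])
    pos <- downsample_track(pos, log$sample_rate, to_hz)
    alpha_shape(pos, player = i)
  })
}
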