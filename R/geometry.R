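#' Polygon geometries for slide annotations
#'
#' A geometry is a list of polygons; each polygon is a list of rings; each
#' ring is a two-column numeric matrix of (x, y) vertices in "open" form (the
#' first vertex is not repeated at the end). The first ring of a polygon is
#' the exterior shell, any further rings are holes. After normalization,
#' shells have positive signed (shoelace) area and holes negative; with the
#' image convention used throughout the package (x to the right, y growing
#' downward), a positive shoelace sign is what "counter-clockwise" means.
#'
#' Coordinates are level-0 slide pixels (or tile-local mask pixels after
#' clipping); pixel (row r, col c) covers the half-open cell
#' `[c, c+1) x [r, r+1)` with its sampling center at `(c + 0.5, r + 0.5)`.
#'
#' @param shell two-column matrix of vertices (closed or open form).
#' @param holes optional list of hole rings.
#' @return An object of class `tile_geometry`.
#' @examples
#' sq <- polygon_geometry(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' geom_area(sq)
#' @export
polygon_geometry <- function(shell, holes = list()) {
  new_geometry(list(c(list(shell), holes)))
}

#' @rdname polygon_geometry
#' @param polygons list of polygons, each a list of rings (shell first).
#' @export
multipolygon_geometry <- function(polygons) {
  new_geometry(polygons)
}

#' @rdname polygon_geometry
#' @param x object to test.
#' @export
is_geometry <- function(x) inherits(x, "tile_geometry")

new_geometry <- function(polygons) {
  polygons <- lapply(polygons, function(poly) lapply(poly, as_ring))
  structure(polygons, class = "tile_geometry")
}

# Coerce to an open two-column matrix; drops a repeated closing vertex and
# consecutive duplicates.
as_ring <- function(ring) {
  m <- as.matrix(ring)
  if (ncol(m) != 2L) stop("a ring must have two coordinate columns", call. = FALSE)
  storage.mode(m) <- "double"
  n <- nrow(m)
  if (n >= 2L && all(m[1L, ] == m[n, ])) m <- m[-n, , drop = FALSE]
  if (nrow(m) >= 2L) {
    dup <- c(FALSE, rowSums(abs(m[-1L, , drop = FALSE] -
                                  m[-nrow(m), , drop = FALSE])) == 0)
    m <- m[!dup, , drop = FALSE]
  }
  dimnames(m) <- NULL
  m
}

#' @export
print.tile_geometry <- function(x, ...) {
  np <- length(x)
  nr <- sum(lengths(x))
  cat(sprintf("<tile_geometry: %d polygon%s, %d ring%s, area %.6g>\n",
              np, if (np == 1) "" else "s", nr, if (nr == 1) "" else "s",
              geom_area(x)))
  invisible(x)
}

#' Signed shoelace area of a ring
#'
#' Positive for counter-clockwise rings (shoelace convention), negative for
#' clockwise ones.
#'
#' @param ring two-column vertex matrix.
#' @return Signed area.
#' @export
ring_area <- function(ring) {
  n <- nrow(ring)
  if (n < 3L) return(0)
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Total enclosed area of a geometry
#'
#' Shell areas minus hole areas, over all polygons.
#'
#' @param geom a `tile_geometry`.
#' @return Non-negative area.
#' @export
geom_area <- function(geom) {
  sum(vapply(unlist_rings(geom), ring_area, numeric(1)))
}

# Flat list of rings, each normalized so the signed area carries the
# shell (+) / hole (-) role.
unlist_rings <- function(geom) {
  out <- list()
  for (poly in geom) out <- c(out, poly)
  out
}

#' Bounding box of a geometry
#'
#' @param geom a `tile_geometry`.
#' @return Named numeric vector `c(xmin, ymin, xmax, ymax)`.
#' @export
geom_bbox <- function(geom) {
  xs <- unlist(lapply(unlist_rings(geom), function(r) r[, 1L]))
  ys <- unlist(lapply(unlist_rings(geom), function(r) r[, 2L]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

#' Affine map of a geometry
#'
#' Applies `(x, y) -> ((x + dx) * sx, (y + dy) * sy)` to every vertex:
#' translation first, then scaling, matching the tile-local mapping
#' (subtract the tile origin, divide by the downsample).
#'
#' @param geom a `tile_geometry`.
#' @param dx,dy translation applied before scaling.
#' @param sx,sy scale factors.
#' @return Transformed `tile_geometry`.
#' @export
geom_affine <- function(geom, dx = 0, dy = 0, sx = 1, sy = sx) {
  new_geometry(lapply(geom, function(poly) {
    lapply(poly, function(r) {
      cbind((r[, 1L] + dx) * sx, (r[, 2L] + dy) * sy)
    })
  }))
}

#' Normalize ring orientation
#'
#' Forces exterior shells to positive shoelace sign and holes to negative,
#' leaving vertex order otherwise untouched.
#'
#' @param geom a `tile_geometry`.
#' @return Normalized geometry.
#' @export
geom_normalize <- function(geom) {
  new_geometry(lapply(geom, function(poly) {
    lapply(seq_along(poly), function(i) {
      a <- ring_area(poly[[i]])
      want_pos <- i == 1L
      if ((a > 0) != want_pos && a != 0) poly[[i]][rev(seq_len(nrow(poly[[i]]))), , drop = FALSE]
      else poly[[i]]
    })
  }))
}

#' Validate a geometry
#'
#' Checks that every ring has at least three vertices and non-zero area,
#' that rings are simple (no proper self-intersections), and that hole
#' representatives lie inside their shell. Returns the orientation-normalized
#' geometry or raises an error describing the defect.
#'
#' @param geom a `tile_geometry`.
#' @param check_simple test each ring for self-intersection (O(n^2) per
#'   ring; skipped for rings with more than `simple_limit` vertices).
#' @param simple_limit vertex-count cutoff for the simplicity test.
#' @return The validated, normalized geometry.
#' @export
validate_geometry <- function(geom, check_simple = TRUE, simple_limit = 512L) {
  for (poly in geom) {
    for (ring in poly) {
      if (nrow(ring) < 3L) stop("ring has fewer than 3 distinct vertices", call. = FALSE)
      if (abs(ring_area(ring)) < 1e-12) stop("ring has zero area", call. = FALSE)
      if (check_simple && nrow(ring) <= simple_limit && !is_simple_ring(ring))
        stop("ring is self-intersecting", call. = FALSE)
    }
  }
  geom <- geom_normalize(geom)
  for (poly in geom) {
    if (length(poly) > 1L) {
      shell <- list(list(poly[[1L]]))
      shell <- structure(shell, class = "tile_geometry")
      for (h in poly[-1L]) {
        probe <- colMeans(h[1:2, , drop = FALSE])
        if (!point_in_geometry(probe, shell))
          stop("hole lies outside its shell", call. = FALSE)
      }
    }
  }
  geom
}

# Proper-intersection test between all non-adjacent segment pairs of a ring.
is_simple_ring <- function(ring) {
  n <- nrow(ring)
  p1 <- ring
  p2 <- ring[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]            # skip adjacent wrap-around pair
    if (!length(js)) next
    if (any(segments_cross(p1[i, ], p2[i, ], p1[js, , drop = FALSE],
                           p2[js, , drop = FALSE]))) return(FALSE)
  }
  TRUE
}

# Proper crossing (interiors intersect) of segment a-b against rows of c-d.
segments_cross <- function(a, b, c, d) {
  o <- function(p, q, r1, r2) {
    (q[1L] - p[1L]) * (r2 - p[2L]) - (q[2L] - p[2L]) * (r1 - p[1L])
  }
  d1 <- o(a, b, c[, 1L], c[, 2L])
  d2 <- o(a, b, d[, 1L], d[, 2L])
  d3 <- (d[, 1L] - c[, 1L]) * (a[2L] - c[, 2L]) - (d[, 2L] - c[, 2L]) * (a[1L] - c[, 1L])
  d4 <- (d[, 1L] - c[, 1L]) * (b[2L] - c[, 2L]) - (d[, 2L] - c[, 2L]) * (b[1L] - c[, 1L])
  d1 * d2 < 0 & d3 * d4 < 0
}

#' Even-odd point-in-polygon test with a half-open boundary rule
#'
#' A point exactly on the boundary is counted as inside when the interior
#' lies to its lower-right: the test point is perturbed by `(+eps, +eps)`
#' before an even-odd ray cast, so left and top edges of an axis-aligned
#' region are inside while right and bottom edges are outside. This is the
#' tie rule that makes half-pixel-offset shapes discretize reproducibly.
#'
#' @param point numeric length-2 `(x, y)`.
#' @param geom a `tile_geometry` (holes respected via even-odd parity).
#' @param eps tie-breaking perturbation, default `1e-9`.
#' @return `TRUE` if the (perturbed) point lies inside.
#' @examples
#' sq <- polygon_geometry(rbind(c(0.5, 0.5), c(5.5, 0.5), c(5.5, 5.5), c(0.5, 5.5)))
#' point_in_geometry(c(0.5, 0.5), sq)   # on a left/top boundary: inside
#' point_in_geometry(c(5.5, 5.5), sq)   # on a right/bottom boundary: outside
#' @export
point_in_geometry <- function(point, geom, eps = 1e-9) {
  px <- point[1L] + eps
  py <- point[2L] + eps
  for (poly in geom) {
    crossings <- 0L
    for (ring in poly) {
      n <- nrow(ring)
      x1 <- ring[, 1L]; y1 <- ring[, 2L]
      x2 <- c(x1[-1L], x1[1L]); y2 <- c(y1[-1L], y1[1L])
      cr <- (y1 <= py) != (y2 <= py)
      if (any(cr)) {
        xi <- x1[cr] + (py - y1[cr]) * (x2[cr] - x1[cr]) / (y2[cr] - y1[cr])
        crossings <- crossings + sum(xi > px)
      }
    }
    if (crossings %% 2L == 1L) return(TRUE)
  }
  FALSE
}

# ---- rectangle clipping --------------------------------------------------

# Sutherland-Hodgman clip of one ring against an axis-aligned rectangle.
# The result may contain degenerate zero-width bridges when the true
# intersection is disconnected; its signed area is exact regardless.
clip_ring_rect <- function(ring, xmin, ymin, xmax, ymax) {
  clip_half <- function(pts, keep, intersect) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    inside <- keep(pts)
    if (all(inside)) return(pts)
    if (!any(inside)) return(pts[0L, , drop = FALSE])
    out <- vector("list", 2L * n)
    k <- 0L
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      if (inside[i]) {
        k <- k + 1L; out[[k]] <- pts[i, ]
        if (!inside[j]) { k <- k + 1L; out[[k]] <- intersect(pts[i, ], pts[j, ]) }
      } else if (inside[j]) {
        k <- k + 1L; out[[k]] <- intersect(pts[i, ], pts[j, ])
      }
    }
    do.call(rbind, out[seq_len(k)])
  }
  ix <- function(p, q, xv) c(xv, p[2L] + (xv - p[1L]) * (q[2L] - p[2L]) / (q[1L] - p[1L]))
  iy <- function(p, q, yv) c(p[1L] + (yv - p[2L]) * (q[1L] - p[1L]) / (q[2L] - p[2L]), yv)
  pts <- ring
  pts <- clip_half(pts, function(p) p[, 1L] >= xmin, function(p, q) ix(p, q, xmin))
  pts <- clip_half(pts, function(p) p[, 1L] <= xmax, function(p, q) ix(p, q, xmax))
  pts <- clip_half(pts, function(p) p[, 2L] >= ymin, function(p, q) iy(p, q, ymin))
  pts <- clip_half(pts, function(p) p[, 2L] <= ymax, function(p, q) iy(p, q, ymax))
  pts
}

#' Exact area of a geometry clipped to a rectangle
#'
#' Clips every ring against the rectangle and sums the signed shoelace
#' areas, so holes subtract correctly. Exact for valid geometries because
#' the clip window is convex.
#'
#' @param geom a normalized `tile_geometry`.
#' @param xmin,ymin,xmax,ymax rectangle bounds.
#' @return `area(geom` \eqn{\cap} `rectangle)`, non-negative.
#' @export
clip_area_rect <- function(geom, xmin, ymin, xmax, ymax) {
  a <- 0
  for (ring in unlist_rings(geom)) {
    rb <- range(ring[, 1L]); cb <- range(ring[, 2L])
    if (rb[2L] <= xmin || rb[1L] >= xmax || cb[2L] <= ymin || cb[1L] >= ymax) next
    cl <- clip_ring_rect(ring, xmin, ymin, xmax, ymax)
    if (nrow(cl) >= 3L) a <- a + ring_area(cl)
  }
  max(a, 0)
}

#' Clip a geometry to a rectangle
#'
#' Ring-wise Sutherland-Hodgman clipping. Rings whose clipped area falls
#' below `min_area` (zero-area boundary slivers) are dropped entirely, and a
#' geometry with no surviving shell returns `NULL`. When the rectangle cuts
#' an annotation into disconnected parts the clipped shell may carry
#' zero-width bridges between them; areas, rasterization under the even-odd
#' rule, and downstream metrics are unaffected.
#'
#' @param geom a normalized `tile_geometry`.
#' @param xmin,ymin,xmax,ymax rectangle bounds.
#' @param min_area drop clipped rings below this absolute area.
#' @return A `tile_geometry`, or `NULL` for an empty intersection.
#' @export
clip_geom_rect <- function(geom, xmin, ymin, xmax, ymax, min_area = 1e-12) {
  polys <- list()
  for (poly in geom) {
    rings <- list()
    for (i in seq_along(poly)) {
      cl <- clip_ring_rect(poly[[i]], xmin, ymin, xmax, ymax)
      if (nrow(cl) >= 3L && abs(ring_area(cl)) > min_area) {
        if (i == 1L || length(rings)) rings <- c(rings, list(cl))
      } else if (i == 1L) break                 # shell gone: whole polygon gone
    }
    if (length(rings)) polys <- c(polys, list(rings))
  }
  if (!length(polys)) return(NULL)
  new_geometry(polys)
}

# ---- distances -----------------------------------------------------------

# Minimum distance from points (px, py) to segments (x1,y1)-(x2,y2);
# returns the npts-vector of minima over all segments.
dist_points_segments <- function(px, py, x1, y1, x2, y2) {
  best <- rep(Inf, length(px))
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  for (j in seq_along(x1)) {
    if (len2[j] == 0) {
      d2 <- (px - x1[j])^2 + (py - y1[j])^2
    } else {
      t <- ((px - x1[j]) * dx[j] + (py - y1[j]) * dy[j]) / len2[j]
      t <- pmin(1, pmax(0, t))
      qx <- x1[j] + t * dx[j]; qy <- y1[j] + t * dy[j]
      d2 <- (px - qx)^2 + (py - qy)^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# All boundary segments of a geometry as a list of coordinate vectors.
geom_segments <- function(geom) {
  rings <- unlist_rings(geom)
  x1 <- y1 <- x2 <- y2 <- numeric(0)
  for (r in rings) {
    n <- nrow(r)
    x1 <- c(x1, r[, 1L]); y1 <- c(y1, r[, 2L])
    x2 <- c(x2, r[c(2:n, 1L), 1L]); y2 <- c(y2, r[c(2:n, 1L), 2L])
  }
  list(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
}

#' Euclidean distance between two geometries
#'
#' Zero when the geometries intersect or touch (including full containment);
#' otherwise the minimum distance between their boundaries.
#'
#' @param g1,g2 `tile_geometry` objects.
#' @return Distance in coordinate units.
#' @export
geom_distance <- function(g1, g2) {
  s1 <- geom_segments(g1); s2 <- geom_segments(g2)
  # containment: any vertex of one inside the other
  if (point_in_geometry(c(s1$x1[1L], s1$y1[1L]), g2)) return(0)
  if (point_in_geometry(c(s2$x1[1L], s2$y1[1L]), g1)) return(0)
  d <- min(dist_points_segments(s1$x1, s1$y1, s2$x1, s2$y1, s2$x2, s2$y2))
  if (d == 0) return(0)
  # boundary crossings not at vertices
  for (j in seq_along(s1$x1)) {
    if (any(segments_cross(c(s1$x1[j], s1$y1[j]), c(s1$x2[j], s1$y2[j]),
                           cbind(s2$x1, s2$y1), cbind(s2$x2, s2$y2)))) return(0)
  }
  d
}

#' Does a geometry intersect an axis-aligned rectangle?
#'
#' True when the overlap has positive area or the boundaries touch.
#'
#' @param geom a `tile_geometry`.
#' @param xmin,ymin,xmax,ymax rectangle bounds.
#' @param tol touch tolerance.
#' @return Logical.
#' @export
geom_intersects_rect <- function(geom, xmin, ymin, xmax, ymax, tol = 1e-12) {
  if (clip_area_rect(geom, xmin, ymin, xmax, ymax) > tol) return(TRUE)
  rect <- polygon_geometry(rbind(c(xmin, ymin), c(xmax, ymin),
                                 c(xmax, ymax), c(xmin, ymax)))
  geom_distance(geom, rect) <= tol
}
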