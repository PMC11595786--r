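#' Merge touching annotations of the same class
#'
#' Computes the transitive closure of the relation "same class AND geometric
#' distance at most `distance`" (distance 0 means touching or overlapping)
#' and replaces each connected group by the union of its members, dissolving
#' the internal tile borders left behind by per-tile mask import.
#' Annotations of different classes are never merged, the covered area per
#' class is preserved exactly, and the output keeps untouched annotations
#' first (in their original order) followed by the merged unions.
#'
#' The union is computed exactly for rectilinear geometries (all edges
#' axis-parallel) on a coordinate-compressed grid; mask-derived annotations
#' are rectilinear by construction, which is the intended input of this
#' step. A group with non-rectilinear members raises an error. If members
#' of a group only touch at corners the union is kept as one annotation
#' with a multipolygon geometry.
#'
#' @param ann annotation tibble.
#' @param distance merge radius in level-0 pixels (default 0 = touching).
#' @param tol numeric tolerance for the touch test and for collapsing
#'   nearly-equal coordinates of different tiles.
#' @return Merged annotation tibble.
#' @examples
#' a <- polygon_geometry(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' b <- polygon_geometry(rbind(c(1, 0), c(2, 0), c(2, 1), c(1, 1)))
#' merged <- merge_annotations(annotations(list(a, b), "A"))
#' geom_area(merged$geometry[[1]])  # 2
#' @export
merge_annotations <- function(ann, distance = 0, tol = 1e-9) {
  if (distance < 0) stop("merge distance must be >= 0", call. = FALSE)
  stopifnot(is_annotations(ann))
  n <- nrow(ann)
  if (n < 2L) return(ann)

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  boxes <- t(vapply(ann$geometry, geom_bbox, numeric(4)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (ann$class_name[i] != ann$class_name[j]) next
      # envelope prescreen with the merge radius
      if (boxes[i, 1L] > boxes[j, 3L] + distance + tol ||
          boxes[j, 1L] > boxes[i, 3L] + distance + tol ||
          boxes[i, 2L] > boxes[j, 4L] + distance + tol ||
          boxes[j, 2L] > boxes[i, 4L] + distance + tol) next
      if (geom_distance(ann$geometry[[i]], ann$geometry[[j]]) <= distance + tol)
        unite(i, j)
    }
  }
  groups <- vapply(seq_len(n), find, integer(1))
  sizes <- table(groups)
  singles <- which(as.integer(sizes[as.character(groups)]) == 1L)
  merged_roots <- sort(unique(groups[!seq_len(n) %in% singles]))

  out <- ann[singles, , drop = FALSE]
  for (root in merged_roots) {
    members <- which(groups == root)
    union_geom <- rectilinear_union(ann$geometry[members], tol = tol)
    out <- dplyr::bind_rows(out, tibble::tibble(
      id = ann$id[members[1L]],
      class_name = ann$class_name[members[1L]],
      geometry = list(union_geom)
    ))
  }
  out
}

#' Exact union of rectilinear geometries
#'
#' All edges must be axis-parallel. The union is built on the coordinate-
#' compressed grid of all vertex ordinates: a compressed cell belongs to the
#' union iff its midpoint lies inside any member (exact, because member
#' edges can only sit on compressed grid lines), and the covered cells are
#' traced back into boundary polygons with holes.
#'
#' @param geoms list of rectilinear `tile_geometry` objects.
#' @param tol collapse coordinates closer than this before compression.
#' @return A `tile_geometry` (possibly a multipolygon).
#' @export
rectilinear_union <- function(geoms, tol = 1e-9) {
  for (g in geoms) {
    s <- geom_segments(g)
    if (any(abs(s$x1 - s$x2) > tol & abs(s$y1 - s$y2) > tol))
      stop("union requires rectilinear geometries (axis-parallel edges); ",
           "merge is designed for mask-derived annotations", call. = FALSE)
  }
  xs <- snap_sorted(unlist(lapply(geoms, function(g)
    unlist(lapply(unlist_rings(g), function(r) r[, 1L])))), tol)
  ys <- snap_sorted(unlist(lapply(geoms, function(g)
    unlist(lapply(unlist_rings(g), function(r) r[, 2L])))), tol)
  nx <- length(xs) - 1L; ny <- length(ys) - 1L
  if (nx < 1L || ny < 1L) stop("degenerate union input", call. = FALSE)
  cxs <- (xs[-1L] + xs[-length(xs)]) / 2
  cys <- (ys[-1L] + ys[-length(ys)]) / 2
  covered <- matrix(FALSE, ny, nx)
  for (g in geoms) {
    bb <- geom_bbox(g)
    ri <- which(cys > bb["ymin"] & cys < bb["ymax"])
    ci <- which(cxs > bb["xmin"] & cxs < bb["xmax"])
    for (r in ri) for (cc in ci) {
      if (!covered[r, cc] && point_in_geometry(c(cxs[cc], cys[r]), g))
        covered[r, cc] <- TRUE
    }
  }
  comp <- label_components(covered)
  polys <- list()
  for (cid in seq_len(attr(comp, "n"))) {
    g <- trace_component(comp == cid)
    # map compressed grid vertices back to real coordinates
    g <- new_geometry(lapply(g, function(poly) lapply(poly, function(ring) {
      cbind(xs[ring[, 1L] + 1L], ys[ring[, 2L] + 1L])
    })))
    polys <- c(polys, unclass(g))
  }
  new_geometry(polys)
}

# sorted unique values after collapsing near-duplicates
snap_sorted <- function(v, tol) {
  v <- sort(v)
  keep <- c(TRUE, diff(v) > tol)
  v[keep]
}
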