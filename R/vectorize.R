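#' Vectorize a label mask into rectilinear polygons
#'
#' For every label > 0, each 4-connected component of the mask becomes one
#' polygon whose boundary follows the pixel-cell edges exactly (vertices at
#' integer tile-local coordinates, staircase corners preserved — no
#' simplification). Enclosed background regions become interior rings.
#' 4-connectivity is used because 8-connected components can corner-touch,
#' which has no representation as a valid simple polygon. The construction
#' is an exact inverse of center-strategy rasterization:
#' `rasterize(vectorize(M)) == M` bit-exactly.
#'
#' @param mask a [tile_mask()].
#' @return Annotation tibble in tile-local coordinates, one row per
#'   component, with a `label` column alongside `class_name`.
#' @examples
#' lm <- label_map("A")
#' g <- matrix(0L, 8, 8); g[3:5, 3:5] <- 1L
#' vectorize_mask(tile_mask(g, tile_spec(0, 0, 8, 8), lm))
#' @export
vectorize_mask <- function(mask) {
  stopifnot(inherits(mask, "tile_mask"))
  grid <- mask$grid
  lm <- mask$label_map
  rows <- list()
  for (lab in sort(unique(grid[grid > 0L]))) {
    comp <- label_components(grid == lab)
    for (cid in seq_len(attr(comp, "n"))) {
      geom <- trace_component(comp == cid)
      rows <- c(rows, list(tibble::tibble(
        id = NA_character_,
        class_name = class_of(lm, lab),
        label = as.integer(lab),
        geometry = list(geom)
      )))
    }
  }
  if (!length(rows)) {
    out <- empty_annotations()
    out$label <- integer(0)
    return(out[, c("id", "class_name", "label", "geometry")])
  }
  dplyr::bind_rows(rows)
}

# 4-connected component labelling by row-run merging with union-find.
# Returns an integer matrix with attr "n" = number of components.
label_components <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  out <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  prev_runs <- NULL      # matrix cols: start, end, id (runs of previous row)
  next_id <- 0L
  for (r in seq_len(nr)) {
    v <- bin[r, ]
    if (!any(v)) { prev_runs <- NULL; next }
    d <- diff(c(FALSE, v, FALSE))
    starts <- which(d == 1L); ends <- which(d == -1L) - 1L
    ids <- integer(length(starts))
    for (k in seq_along(starts)) {
      id <- NA_integer_
      if (!is.null(prev_runs)) {
        ov <- prev_runs[, 1L] <= ends[k] & prev_runs[, 2L] >= starts[k]
        if (any(ov)) {
          roots <- unique(vapply(prev_runs[ov, 3L], find, integer(1)))
          id <- min(roots)
          for (rt in roots) parent[rt] <- id
        }
      }
      if (is.na(id)) {
        next_id <- next_id + 1L
        parent[next_id] <- next_id
        id <- next_id
      }
      ids[k] <- id
      out[r, starts[k]:ends[k]] <- id
    }
    prev_runs <- cbind(starts, ends, ids)
  }
  # flatten union-find and relabel 1..n
  if (next_id) {
    roots <- vapply(seq_len(next_id), find, integer(1))
    lut <- match(roots, sort(unique(roots)))
    pos <- out > 0L
    out[pos] <- lut[out[pos]]
    attr(out, "n") <- max(lut)
  } else attr(out, "n") <- 0L
  out
}

# Trace the boundary of one 4-connected binary component into a polygon
# with holes. Directed unit edges are emitted with the interior on the
# mathematical left (shell gets positive shoelace sign, holes negative);
# at pinch vertices the sharpest right turn is taken, which splits the
# pinch into separate simple loops.
trace_component <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  W <- nc + 1L
  vkey <- function(x, y) y * W + x + 1L
  # collect directed edges: from-vertex key, direction (0:+x 1:+y 2:-x 3:-y)
  cells <- which(bin, arr.ind = TRUE)
  r0 <- cells[, 1L] - 1L; c0 <- cells[, 2L] - 1L   # 0-based cell coords
  inside <- function(rr, cc) {
    ok <- rr >= 0L & rr < nr & cc >= 0L & cc < nc
    res <- logical(length(rr))
    res[ok] <- bin[cbind(rr[ok] + 1L, cc[ok] + 1L)]
    res
  }
  efrom <- integer(0); edir <- integer(0)
  top <- !inside(r0 - 1L, c0)
  efrom <- c(efrom, vkey(c0[top], r0[top]));           edir <- c(edir, rep(0L, sum(top)))
  rgt <- !inside(r0, c0 + 1L)
  efrom <- c(efrom, vkey(c0[rgt] + 1L, r0[rgt]));      edir <- c(edir, rep(1L, sum(rgt)))
  bot <- !inside(r0 + 1L, c0)
  efrom <- c(efrom, vkey(c0[bot] + 1L, r0[bot] + 1L)); edir <- c(edir, rep(2L, sum(bot)))
  lft <- !inside(r0, c0 - 1L)
  efrom <- c(efrom, vkey(c0[lft], r0[lft] + 1L));      edir <- c(edir, rep(3L, sum(lft)))

  dxs <- c(1L, 0L, -1L, 0L); dys <- c(0L, 1L, 0L, -1L)
  # outgoing edge lookup: vertex key -> indices into edge arrays
  ord <- order(efrom)
  efrom_s <- efrom[ord]
  first <- match(unique(efrom_s), efrom_s)
  vstart <- unique(efrom_s)
  used <- logical(length(efrom))
  out_at <- function(v) {
    p <- match(v, vstart)
    if (is.na(p)) return(integer(0))
    i <- first[p]
    j <- if (p < length(first)) first[p + 1L] - 1L else length(efrom_s)
    ord[i:j]
  }
  rings <- list()
  for (start_e in seq_along(efrom)) {
    if (used[start_e]) next
    verts_x <- integer(0); verts_y <- integer(0)
    e <- start_e
    repeat {
      used[e] <- TRUE
      v <- efrom[e]; d <- edir[e]
      x <- (v - 1L) %% W; y <- (v - 1L) %/% W
      verts_x <- c(verts_x, x); verts_y <- c(verts_y, y)
      nv <- vkey(x + dxs[d + 1L], y + dys[d + 1L])
      if (nv == efrom[start_e]) break
      cand <- out_at(nv)
      cand <- cand[!used[cand]]
      if (!length(cand)) stop("boundary tracing failed: open loop", call. = FALSE)
      if (length(cand) == 1L) e <- cand[1L]
      else {
        # prefer right turn, then straight, then left
        pref <- c((d - 1L) %% 4L, d, (d + 1L) %% 4L)
        e <- cand[order(match(edir[cand], pref))][1L]
      }
    }
    # merge collinear runs, keep staircase corners
    n <- length(verts_x)
    keep <- logical(n)
    for (i in seq_len(n)) {
      ip <- if (i == 1L) n else i - 1L
      im <- if (i == n) 1L else i + 1L
      keep[i] <- (verts_x[ip] == verts_x[i]) != (verts_x[i] == verts_x[im]) ||
                 (verts_y[ip] == verts_y[i]) != (verts_y[i] == verts_y[im])
    }
    rings <- c(rings, list(cbind(verts_x[keep], verts_y[keep])))
  }
  areas <- vapply(rings, ring_area, numeric(1))
  shell <- rings[areas > 0]
  holes <- rings[areas < 0]
  if (length(shell) != 1L)
    stop("component tracing produced ", length(shell), " shells", call. = FALSE)
  new_geometry(list(c(shell, holes)))
}

#' Map tile-local polygons to slide coordinates
#'
#' Applies the inverse of the tile-local mapping to every vertex:
#' `(u, v) -> (spec$x + u * d, spec$y + v * d)` with `d = spec$downsample`.
#'
#' @param polys annotation tibble in tile-local mask coordinates (e.g. from
#'   [vectorize_mask()]).
#' @param spec the [tile_spec()] the coordinates refer to.
#' @return Annotation tibble in level-0 slide coordinates.
#' @export
to_slide_coords <- function(polys, spec) {
  stopifnot(is_annotations(polys))
  d <- spec$downsample
  dplyr::mutate(polys, geometry = lapply(.data$geometry, function(g) {
    geom_affine(geom_affine(g, sx = d), dx = spec$x, dy = spec$y)
  }))
}

#' Import a mask's components into an annotation store
#'
#' Vectorizes the mask, rescales and translates the components to slide
#' coordinates, and appends them to the store with deterministic ids of the
#' form `tile_x{X}_y{Y}_{class}_{k}`. Re-running the import of the same
#' tile is a no-op (ids already present are skipped), and an all-background
#' mask leaves the store unchanged.
#'
#' @param store annotation tibble (possibly empty, see [annotations()]).
#' @param mask a [tile_mask()] whose spec carries the slide offset.
#' @return The updated annotation tibble.
#' @export
save_mask_annotations <- function(store, mask) {
  stopifnot(is_annotations(store))
  polys <- vectorize_mask(mask)
  if (!nrow(polys)) return(store)
  slide <- to_slide_coords(polys, mask$spec)
  slide <- dplyr::mutate(
    slide,
    id = sprintf("tile_x%g_y%g_%s_%d", mask$spec$x, mask$spec$y,
                 .data$class_name,
                 stats::ave(seq_len(dplyr::n()), .data$class_name,
                            FUN = seq_along))
  )
  slide$label <- NULL
  new_rows <- slide[!slide$id %in% store$id, , drop = FALSE]
  dplyr::bind_rows(store, new_rows)
}
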