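#' Build a packed STR R-tree over annotations
#'
#' Bulk-loads a Sort-Tile-Recursive R-tree over the annotation bounding
#' boxes. This is the once-per-image initialization of the on-the-fly
#' workflow; afterwards any tile's annotations are retrieved by descending
#' the tree and post-filtering candidate envelopes with an exact geometric
#' intersection test (an envelope tree alone over-returns).
#'
#' @param ann annotation tibble (see [annotations()]).
#' @param node_capacity maximum entries per tree node.
#' @return An object of class `annotation_index`.
#' @export
build_index <- function(ann, node_capacity = 10L) {
  stopifnot(is_annotations(ann))
  n <- nrow(ann)
  boxes <- if (n) t(vapply(ann$geometry, geom_bbox, numeric(4))) else
    matrix(numeric(0), 0L, 4L)
  colnames(boxes) <- c("xmin", "ymin", "xmax", "ymax")
  tree <- if (n) str_pack_leaves(boxes, seq_len(n), node_capacity) else NULL
  structure(list(annotations = ann, boxes = boxes, tree = tree,
                 node_capacity = as.integer(node_capacity)),
            class = "annotation_index")
}

#' @export
print.annotation_index <- function(x, ...) {
  cat(sprintf("<annotation_index: %d annotations, STR-tree capacity %d>\n",
              nrow(x$annotations), x$node_capacity))
  invisible(x)
}

# STR packing: sort by x-center, slice into ~sqrt(n/cap) vertical slices,
# sort each slice by y-center, cut runs of `cap` into leaves; then pack
# levels upward the same way until a single root remains.
str_pack_leaves <- function(boxes, ids, cap) {
  entries <- lapply(ids, function(i) {
    list(bbox = boxes[i, ], leaf = TRUE, id = i)
  })
  pack_level(entries, cap)
}

pack_level <- function(entries, cap) {
  if (length(entries) == 1L && !isTRUE(entries[[1L]]$leaf)) return(entries[[1L]])
  cx <- vapply(entries, function(e) (e$bbox[1L] + e$bbox[3L]) / 2, numeric(1))
  cy <- vapply(entries, function(e) (e$bbox[2L] + e$bbox[4L]) / 2, numeric(1))
  n <- length(entries)
  n_nodes <- ceiling(n / cap)
  n_slices <- max(1L, ceiling(sqrt(n_nodes)))
  per_slice <- ceiling(n / n_slices)
  ord_x <- order(cx)
  nodes <- list()
  for (s in seq_len(n_slices)) {
    idx <- ord_x[seq.int((s - 1L) * per_slice + 1L, min(s * per_slice, n))]
    if (!length(idx)) next
    idx <- idx[order(cy[idx])]
    starts <- seq.int(1L, length(idx), by = cap)
    for (st in starts) {
      kids <- entries[idx[st:min(st + cap - 1L, length(idx))]]
      bb <- c(min(vapply(kids, function(e) e$bbox[1L], numeric(1))),
              min(vapply(kids, function(e) e$bbox[2L], numeric(1))),
              max(vapply(kids, function(e) e$bbox[3L], numeric(1))),
              max(vapply(kids, function(e) e$bbox[4L], numeric(1))))
      nodes <- c(nodes, list(list(bbox = bb, leaf = FALSE, children = kids)))
    }
  }
  if (length(nodes) == 1L) nodes[[1L]] else pack_level(nodes, cap)
}

# ids of entries whose bbox overlaps (touch included) the query rectangle
str_query <- function(node, xmin, ymin, xmax, ymax) {
  if (is.null(node)) return(integer(0))
  bb <- node$bbox
  if (bb[1L] > xmax || bb[3L] < xmin || bb[2L] > ymax || bb[4L] < ymin)
    return(integer(0))
  if (isTRUE(node$leaf)) return(node$id)
  unlist(lapply(node$children, str_query, xmin = xmin, ymin = ymin,
                xmax = xmax, ymax = ymax))
}

#' Query an annotation index with a rectangle
#'
#' Returns the rows of the backing annotation table whose geometry (not
#' merely envelope) intersects the rectangle with positive area or touches
#' its boundary.
#'
#' @param index an `annotation_index`.
#' @param xmin,ymin,xmax,ymax query rectangle in level-0 pixels.
#' @return Integer vector of annotation row indices, ascending.
#' @export
query_index <- function(index, xmin, ymin, xmax, ymax) {
  cand <- sort(str_query(index$tree, xmin, ymin, xmax, ymax))
  keep <- vapply(cand, function(i) {
    geom_intersects_rect(index$annotations$geometry[[i]], xmin, ymin, xmax, ymax)
  }, logical(1))
  cand[keep]
}

#' Annotations of one tile, clipped and in tile-local coordinates
#'
#' Queries the index with the tile rectangle, intersects each hit with it,
#' and maps the clipped geometry into the tile's mask coordinate frame
#' (translate by minus the origin, scale by 1/downsample). Intersections of
#' zero area (pure boundary touches) are filtered out: a zero-area sliver
#' can set no pixel. Clipping a concave annotation may split it into
#' several parts, kept together as one (multi)polygon row.
#'
#' @param index an `annotation_index`.
#' @param spec a [tile_spec()].
#' @return Annotation tibble in tile-local mask coordinates.
#' @export
get_tile_annotations <- function(index, spec) {
  hits <- query_index(index, spec$x, spec$y,
                      spec$x + spec$width, spec$y + spec$height)
  rows <- list()
  for (i in hits) {
    cl <- clip_geom_rect(index$annotations$geometry[[i]],
                         spec$x, spec$y,
                         spec$x + spec$width, spec$y + spec$height)
    if (is.null(cl)) next
    local <- geom_affine(cl, dx = -spec$x, dy = -spec$y, sx = 1 / spec$downsample)
    rows <- c(rows, list(tibble::tibble(
      id = index$annotations$id[i],
      class_name = index$annotations$class_name[i],
      geometry = list(local)
    )))
  }
  if (!length(rows)) return(empty_annotations())
  dplyr::bind_rows(rows)
}

#' Regular tile grid covering an image
#'
#' Ceil-cover grid with stride `tile_size - overlap` starting at the image
#' origin; the last row/column of tiles may overhang the image (overhang is
#' zero-padded on read), so no pixel is unreachable.
#'
#' @param width,height image extent in level-0 pixels.
#' @param tile_size tile side length in level-0 pixels.
#' @param overlap overlap between neighboring tiles (`0 <= overlap <
#'   tile_size`).
#' @param downsample downsample factor stored in each spec.
#' @return Tibble with columns `x`, `y` and a `spec` list-column.
#' @examples
#' nrow(tile_grid(1024, 1024, 512))            # 4 tiles
#' nrow(tile_grid(1024, 1024, 512, overlap = 256))  # 9 tiles
#' @export
tile_grid <- function(width, height, tile_size, overlap = 0, downsample = 1) {
  if (tile_size <= overlap || overlap < 0)
    stop("tile_size must exceed overlap and overlap must be >= 0", call. = FALSE)
  stride <- tile_size - overlap
  nx <- max(1L, as.integer(ceiling((width - tile_size) / stride)) + 1L)
  ny <- max(1L, as.integer(ceiling((height - tile_size) / stride)) + 1L)
  xs <- (seq_len(nx) - 1L) * stride
  ys <- (seq_len(ny) - 1L) * stride
  g <- tidyr::expand_grid(y = ys, x = xs)[, c("x", "y")]
  g$spec <- purrr::map2(g$x, g$y,
                        function(x, y) tile_spec(x, y, tile_size, tile_size,
                                                 downsample = downsample))
  g
}

#' Stream (image tile, mask) pairs on the fly
#'
#' Lazily yields pairs over a regular tile grid: each call of the returned
#' `next_pair()` function extracts the image region, queries and clips the
#' annotations of that tile, rasterizes them, and returns
#' `list(spec, image, mask)` — or `NULL` once the grid is exhausted. Nothing
#' is written to disk, and two streams built with identical arguments yield
#' bit-identical sequences.
#'
#' @param image flat raster array (rows x cols, optionally x channels).
#' @param index an `annotation_index` over the image's annotations.
#' @param lm a [label_map()].
#' @param tile_size,overlap,downsample grid parameters, see [tile_grid()].
#' @param strategy,mode rasterization parameters, see
#'   [rasterize_annotations()].
#' @param annotated_only skip tiles that intersect no annotation.
#' @return A function `next_pair()`; see also [collect_tile_pairs()].
#' @export
tile_pair_stream <- function(image, index, lm, tile_size, overlap = 0,
                             downsample = 1, strategy = "center",
                             mode = "single", annotated_only = FALSE) {
  grid <- tile_grid(ncol(image), nrow(image), tile_size, overlap, downsample)
  i <- 0L
  function() {
    repeat {
      i <<- i + 1L
      if (i > nrow(grid)) return(NULL)
      spec <- grid$spec[[i]]
      clipped <- get_tile_annotations(index, spec)
      if (annotated_only && !nrow(clipped)) next
      mask <- rasterize_annotations(clipped, spec, lm,
                                    strategy = strategy, mode = mode)
      return(list(spec = spec, image = read_image_region(image, spec),
                  mask = mask))
    }
  }
}

#' @rdname tile_pair_stream
#' @param ... passed on to [tile_pair_stream()].
#' @return `collect_tile_pairs()`: list of all pairs.
#' @export
collect_tile_pairs <- function(...) {
  nxt <- tile_pair_stream(...)
  out <- list()
  while (!is.null(p <- nxt())) out <- c(out, list(p))
  out
}
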