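#' Tile specification
#'
#' A tile spec names a rectangular slide region and the pixel grid of its
#' mask: origin `(x, y)` in level-0 pixels, extent `width x height` in
#' level-0 pixels, and a `downsample` factor. The mask grid has
#' `ceil(height / downsample)` rows and `ceil(width / downsample)` columns;
#' mask pixel (row r, col c) covers the level-0 half-open cell
#' `[x + c*d, x + (c+1)*d) x [y + r*d, y + (r+1)*d)` with `d = downsample`,
#' and its sampling center is the midpoint of that cell.
#'
#' @param x,y integer level-0 offset of the tile's top-left corner.
#' @param width,height positive integer extent in level-0 pixels.
#' @param downsample positive downsample factor (default 1).
#' @return An object of class `tile_spec`.
#' @examples
#' tile_spec(0, 0, 512, 512)
#' mask_dim(tile_spec(0, 0, 375, 375, downsample = 2))
#' @export
tile_spec <- function(x, y, width, height, downsample = 1) {
  stopifnot(length(x) == 1L, length(y) == 1L,
            width > 0, height > 0, downsample > 0,
            x == round(x), y == round(y),
            width == round(width), height == round(height))
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 width = as.numeric(width), height = as.numeric(height),
                 downsample = as.numeric(downsample)),
            class = "tile_spec")
}

#' @rdname tile_spec
#' @param spec a `tile_spec`.
#' @return `mask_dim()`: integer `c(rows, cols)` of the mask grid.
#' @export
mask_dim <- function(spec) {
  c(rows = as.integer(ceiling(spec$height / spec$downsample)),
    cols = as.integer(ceiling(spec$width / spec$downsample)))
}

#' @export
print.tile_spec <- function(x, ...) {
  d <- mask_dim(x)
  cat(sprintf("<tile_spec (%g, %g) %gx%g px, downsample %g -> %d x %d grid>\n",
              x$x, x$y, x$width, x$height, x$downsample, d[1L], d[2L]))
  invisible(x)
}

#' Class-label mapping
#'
#' An ordered bijection between class names and positive integer labels:
#' class `i` of the list gets label `i` (and channel `i` of a multi-channel
#' mask); 0 is reserved for background.
#'
#' @param classes character vector of unique class names.
#' @return An object of class `label_map`.
#' @examples
#' lm <- label_map(c("Tumor", "Stroma"))
#' label_of(lm, "Stroma")
#' class_of(lm, 1)
#' @export
label_map <- function(classes) {
  classes <- as.character(classes)
  if (anyDuplicated(classes)) stop("class names must be unique", call. = FALSE)
  if (!length(classes)) stop("a label map needs at least one class", call. = FALSE)
  structure(classes, class = "label_map")
}

#' @rdname label_map
#' @param lm a `label_map`.
#' @param name class name(s).
#' @export
label_of <- function(lm, name) {
  idx <- match(name, unclass(lm))
  if (anyNA(idx))
    stop("class not in label map: ",
         paste(unique(name[is.na(idx)]), collapse = ", "), call. = FALSE)
  idx
}

#' @rdname label_map
#' @param label integer label(s) in `1..length(lm)`.
#' @export
class_of <- function(lm, label) {
  if (any(label < 1L | label > length(lm)))
    stop("label outside label map range 1..", length(lm), call. = FALSE)
  unclass(lm)[label]
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map>\n")
  for (i in seq_along(x)) cat(sprintf("  %d: %s\n", i, unclass(x)[i]))
  cat("  0: (background)\n")
  invisible(x)
}
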